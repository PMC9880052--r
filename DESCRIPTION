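Package: pepperberg
Title: Well-Stirred Modeling of Rod Photoreceptor Saturation and Pepperberg Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of the mouse rod
    phototransduction cascade under a globally well-stirred assumption, with
    calcium feedback onto guanylate cyclase, rhodopsin kinase (via recoverin)
    and the CNG channel, a multi-state rhodopsin phosphorylation/arrestin
    chain, and explicit RGS9-mediated shutoff of transducin-activated
    phosphodiesterase. Includes saturation-time ("Pepperberg plot") analysis:
    criterion-recovery measurement of time in saturation, linear fits yielding
    the dominant shutoff time constant and the just-saturating flash strength,
    detection of the upward bend caused by RGS9 depletion and of the plateau
    caused by PDE exhaustion, a closed-form saturation theory, named mutant
    presets, and scripted in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
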