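## Named mutant presets: parameter-override maps emulating the transgenic
## mouse lines whose saturation behavior the model reproduces.

#' Names of the packaged mutant presets
#'
#' @return character vector of valid preset names.
#' @export
presetNames <- function() names(.loadPresets())

.presetCache <- new.env(parent = emptyenv())

.loadPresets <- function() {
  if (!is.null(.presetCache$defs)) return(.presetCache$defs)
  path <- system.file("extdata", "presets.yaml", package = "pepperberg")
  if (!nzchar(path)) stop("packaged preset file not found")
  .presetCache$defs <- yaml::read_yaml(path)
  .presetCache$defs
}

#' Apply a mutant preset to a parameter set
#'
#' Returns a new \linkS4class{RodParams} with the preset's overrides
#' applied; the input is unchanged. Packaged presets:
#' \describe{
#'   \item{WT}{identity.}
#'   \item{RGS9_0.2x / RGS9_2x / RGS9_4x}{RGS9 complex expression scaled
#'     0.2x, 2x, 4x.}
#'   \item{RK_0.3x}{hemizygous rhodopsin-kinase knockout: all
#'     phosphorylation rates scaled by 1/3.}
#'   \item{RK_S561L}{membrane-enhanced mutant kinase overexpression: all
#'     phosphorylation rates scaled by 3.}
#'   \item{GCAP2_KO}{GCAP2 knockout: maximal low-Ca2+ cGMP synthesis
#'     reduced to 40 percent of wild type and the overall Ca2+ K1/2
#'     shifted to 47 nM (all cyclase weight on the GCAP1 component).}
#'   \item{GCAPs_KO}{knockout of both GCAPs: Ca2+ feedback onto the
#'     cyclase removed by freezing the synthesis rate at its dark-adapted
#'     wild-type value, preserving the dark current.}
#'   \item{CNG_CaM_null}{channel lacking calmodulin modulation: K_cG fixed
#'     at its low-Ca2+ minimum.}
#'   \item{PDE_0.1x / PDE_10x}{PDE expression (and with it basal
#'     hydrolysis capacity) scaled 0.1x / 10x.}
#'   \item{Rec_KO}{recoverin knockout: rhodopsin kinase fully free at all
#'     Ca2+.}
#' }
#' A custom override may be supplied instead of a name as a list with
#' elements \code{scale} and/or \code{set} (named numeric vectors).
#'
#' @param p a \linkS4class{RodParams}.
#' @param preset a preset name, a character vector of names (applied in
#'   order), or a custom override list.
#' @return a new validated \linkS4class{RodParams}.
#' @export
applyPreset <- function(p, preset) {
  if (is.character(preset)) {
    for (nm in preset) p <- .applyOnePreset(p, nm)
    return(p)
  }
  if (is.list(preset)) return(.applyOverrides(p, preset))
  stop("preset must be a name or an override list")
}

.applyOnePreset <- function(p, name) {
  defs <- .loadPresets()
  if (!name %in% names(defs))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(defs), collapse = ", "))
  .applyOverrides(p, defs[[name]])
}

.applyOverrides <- function(p, ov) {
  v <- p@values
  known <- function(f) {
    bad <- setdiff(f, names(.PARAM_FIELDS))
    if (length(bad)) stop("preset touches unknown field(s): ",
                          paste(bad, collapse = ", "))
  }
  if (isTRUE(ov$freeze_cyclase)) {
    ## remove Ca2+ feedback onto the cyclase while preserving the dark
    ## current: pin the synthesis rate at its current dark value
    dark <- darkSteadyState(p)
    aDark <- cyclaseRate(dark[["ca"]], p)
    v$alpha_min <- aDark
    v$alpha_max <- aDark
  }
  if (!is.null(ov$scale)) {
    sc <- unlist(ov$scale)
    known(names(sc))
    for (f in names(sc)) v[[f]] <- v[[f]] * sc[[f]]
  }
  if (!is.null(ov$set)) {
    st <- ov$set
    known(names(st))
    for (f in names(st)) {
      val <- st[[f]]
      if (is.character(val) && identical(val, "K_cG_min")) val <- v$K_cG_min
      v[[f]] <- as.numeric(val)
    }
  }
  extra <- setdiff(names(ov), c("scale", "set", "freeze_cyclase", "description"))
  if (length(extra)) stop("unknown preset directive(s): ",
                          paste(extra, collapse = ", "))
  .newRodParams(v, provenance = p@provenance, schema = p@schema)
}

#' Invert a scaling preset
#'
#' For presets expressed purely as scale factors, returns the override that
#' undoes them; applying a preset and then its inverse reproduces the
#' original parameters.
#'
#' @param preset a preset name or an override list with a \code{scale}
#'   element only.
#' @return an override list.
#' @export
invertPreset <- function(preset) {
  if (is.character(preset)) {
    stopifnot(length(preset) == 1)
    preset <- .loadPresets()[[preset]] %||%
      stop("unknown preset '", preset, "'")
  }
  if (!is.null(preset$set) || isTRUE(preset$freeze_cyclase))
    stop("only pure scaling presets are invertible")
  if (is.null(preset$scale)) return(list())
  list(scale = as.list(1 / unlist(preset$scale)))
}

#' Reduce a parameter set to a single active rhodopsin state
#'
#' Collapses the phosphorylation chain to one active state quenched at
#' rate \code{1/tauR}, with recoverin feedback removed so the quench rate
#' is Ca2+-independent. This is the configuration under which the
#' closed-form saturation theory (single R* species, first-order E*
#' shutoff) can be compared with simulation.
#'
#' @param p a \linkS4class{RodParams}.
#' @param tauR R* lifetime (s); default preserves the lifetime of the
#'   first state at low Ca2+, \code{1/lambda_max[1]}.
#' @return a new \linkS4class{RodParams} with \code{n_sites = 1}.
#' @export
singleStateParams <- function(p, tauR = NULL) {
  lam1 <- lambdaMaxVector(p)[1]
  if (is.null(tauR)) tauR <- 1 / lam1
  setParams(p, n_sites = 1, lambda_max = 1 / tauR, mu_max = 0,
            nu_per_state = c(1, 0), Rec_tot = 0)
}
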