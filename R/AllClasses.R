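#' @import methods
NULL

## 1 molecule per cubic micrometre expressed in micromolar; used everywhere a
## molecule count is converted to a volumetric concentration.
.AVOGADRO_UM3 <- 602.214

#' Full parameter bundle for the well-stirred rod phototransduction model
#'
#' A validated, immutable collection of every model constant: guanylate
#' cyclase activation (two GCAP-regulated components), basal and activated
#' PDE hydrolysis, CNG channel and exchanger currents, calcium buffering and
#' cell geometry, the rhodopsin phosphorylation/arrestin chain, the
#' recoverin--rhodopsin-kinase equilibrium, and the transducin/PDE/RGS9
#' front end. All concentrations are volumetric (uM) referred to the
#' cytosolic outer-segment volume \code{V_cyt}; bimolecular rate constants
#' are in 1/(uM s).
#'
#' @slot values named list of numeric parameter values (flat keys).
#' @slot provenance named character vector; one note per parameter stating
#'   where its default comes from.
#' @slot schema schema identifier of the parameter file format.
#' @export
setClass("RodParams",
  representation(values = "list", provenance = "character", schema = "character"))

#' Time-stamped trajectory of a single simulated flash response
#'
#' @slot time time grid in seconds, flash at t = 0.
#' @slot state matrix of model state variables (uM), one row per time point.
#' @slot currents matrix with columns \code{J_cG}, \code{J_ex}, \code{J} (pA).
#' @slot phi flash strength in photoisomerizations.
#' @slot jDark dark (circulating) current in pA.
#' @slot dark named numeric vector, the dark steady state used as t < 0 state.
#' @slot params the \linkS4class{RodParams} used.
#' @slot solver list of solver settings (tolerances, model variant).
#' @export
setClass("FlashResponse",
  representation(time = "numeric", state = "matrix", currents = "matrix",
                 phi = "numeric", jDark = "numeric", dark = "numeric",
                 params = "RodParams", solver = "list"))

#' A Pepperberg curve: saturation time against log flash strength
#'
#' @slot points data.frame with columns \code{phi}, \code{ln_phi},
#'   \code{t_sat} (s) for saturating flashes.
#' @slot dropped data.frame of non-saturating flashes (\code{phi},
#'   \code{ln_phi}, \code{min_frac}).
#' @slot criterion criterion fractional recovery used to measure saturation
#'   time (e.g. 0.02 for 2 percent).
#' @slot origin measurement origin, \code{"mid_flash"} or \code{"flash_onset"}.
#' @slot paramsHash fingerprint of the parameter set that generated the curve.
#' @export
setClass("PepperbergCurve",
  representation(points = "data.frame", dropped = "data.frame",
                 criterion = "numeric", origin = "character",
                 paramsHash = "character"))

#' Linear fit of the Pepperberg relation
#'
#' @slot tauD fitted slope in seconds: the dominant shutoff time constant.
#' @slot lnPhi0 X-intercept in ln units: the just-saturating flash strength.
#' @slot window ln-phi bounds of the points used.
#' @slot residuals fit residuals (s).
#' @slot r2 coefficient of determination.
#' @slot points data.frame of the points used in the fit.
#' @export
setClass("PepperbergFit",
  representation(tauD = "numeric", lnPhi0 = "numeric", window = "numeric",
                 residuals = "numeric", r2 = "numeric", points = "data.frame"))

#' Closed-form saturation theory report
#'
#' @slot cgSat,caSat cGMP and Ca2+ (uM) in the quasi-steady saturation state.
#' @slot eChar activated-effector level at exit from saturation (uM).
#' @slot phi0 just-saturating flash strength (photoisomerizations).
#' @slot cConst the additive constant of the linear Pepperberg relation (s).
#' @slot epsilon criterion fraction defining exit from saturation.
#' @slot tauE dominant shutoff time constant used (s).
#' @export
setClass("SaturationTheory",
  representation(cgSat = "numeric", caSat = "numeric", eChar = "numeric",
                 phi0 = "numeric", cConst = "numeric", epsilon = "numeric",
                 tauE = "numeric"))

setValidity("RodParams", function(object) .validateParamValues(object@values))

setValidity("PepperbergCurve", function(object) {
  pts <- object@points
  msgs <- character()
  if (nrow(pts) > 1 && any(diff(pts$ln_phi) <= 0))
    msgs <- c(msgs, "ln_phi must be strictly increasing")
  if (length(object@criterion) != 1 || object@criterion <= 0 || object@criterion >= 1)
    msgs <- c(msgs, "criterion must lie in (0,1)")
  if (!object@origin %in% c("mid_flash", "flash_onset"))
    msgs <- c(msgs, "origin must be 'mid_flash' or 'flash_onset'")
  if (length(msgs)) msgs else TRUE
})

setValidity("PepperbergFit", function(object) {
  msgs <- character()
  if (object@tauD <= 0) msgs <- c(msgs, "tauD must be positive")
  if (nrow(object@points) < 3) msgs <- c(msgs, "fit needs at least 3 points")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RodParams", function(object) {
  v <- object@values
  cat("RodParams (", object@schema, ")\n", sep = "")
  cat(sprintf("  rhodopsin chain: n = %d phosphorylation states, lambda_max = %s /s\n",
              as.integer(v$n_sites),
              paste(format(unique(v$lambda_max)), collapse = "/")))
  cat(sprintf("  front end: T0 = %.3g uM, E0 = %.3g uM, RGS9_0 = %.3g uM\n",
              v$T0, v$E0, v$RGS9_0))
  cat(sprintf("  channel: K_cG in [%.3g, %.3g] uM, m_cG = %.3g; V_cyt = %.3g um^3\n",
              v$K_cG_min, v$K_cG_max, v$m_cG, v$V_cyt))
  invisible(object)
})

setMethod("show", "FlashResponse", function(object) {
  cat(sprintf("FlashResponse: phi = %.4g photoisomerizations, %d time points to %.3g s\n",
              object@phi, length(object@time), max(object@time)))
  cat(sprintf("  J_dark = %.4g pA, min J = %.4g pA (%.2f%% of dark)\n",
              object@jDark, min(object@currents[, "J"]),
              100 * min(object@currents[, "J"]) / object@jDark))
  invisible(object)
})

setMethod("show", "PepperbergCurve", function(object) {
  cat(sprintf("PepperbergCurve: %d saturating flashes (criterion %.3g, origin %s)\n",
              nrow(object@points), object@criterion, object@origin))
  if (nrow(object@dropped)) cat(sprintf("  %d non-saturating flashes dropped\n",
                                        nrow(object@dropped)))
  if (nrow(object@points))
    cat(sprintf("  LnPhi %.2f..%.2f, T_sat %.3g..%.3g s\n",
                min(object@points$ln_phi), max(object@points$ln_phi),
                min(object@points$t_sat), max(object@points$t_sat)))
  invisible(object)
})

setMethod("show", "PepperbergFit", function(object) {
  cat(sprintf("PepperbergFit: tau_D = %.1f ms, LnPhi0 = %.3g (window %.2f..%.2f, n = %d, r2 = %.4f)\n",
              1e3 * object@tauD, object@lnPhi0, object@window[1], object@window[2],
              nrow(object@points), object@r2))
  invisible(object)
})

setMethod("show", "SaturationTheory", function(object) {
  cat(sprintf("SaturationTheory (epsilon = %.3g):\n", object@epsilon))
  cat(sprintf("  cg_sat = %.4g uM, ca_sat = %.4g uM, E*_char = %.4g uM\n",
              object@cgSat, object@caSat, object@eChar))
  cat(sprintf("  Phi0 = %.4g photoisomerizations (LnPhi0 = %.3g), tau_E* = %.1f ms, C = %.3g s\n",
              object@phi0, log(object@phi0), 1e3 * object@tauE, object@cConst))
  invisible(object)
})

#' @describeIn PepperbergCurve-class points as a data.frame
#' @param x a \code{PepperbergCurve}
#' @param ... unused
#' @export
as.data.frame.PepperbergCurve <- function(x, ...) x@points

#' Accessors for fit and curve components
#'
#' \code{tauD} returns the fitted Pepperberg slope (s), \code{lnPhi0} the
#' fitted X-intercept (ln units), \code{curvePoints} the measured
#' (phi, ln_phi, t_sat) table, and \code{param} a single parameter value.
#'
#' @param object a fitted or measured object
#' @export
setGeneric("tauD", function(object) standardGeneric("tauD"))

#' @rdname tauD
#' @export
setGeneric("lnPhi0", function(object) standardGeneric("lnPhi0"))

#' @rdname tauD
#' @export
setGeneric("curvePoints", function(object) standardGeneric("curvePoints"))

#' @rdname tauD
#' @export
setMethod("tauD", "PepperbergFit", function(object) object@tauD)

#' @rdname tauD
#' @export
setMethod("lnPhi0", "PepperbergFit", function(object) object@lnPhi0)

#' @rdname tauD
#' @export
setMethod("curvePoints", "PepperbergCurve", function(object) object@points)
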