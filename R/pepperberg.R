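## Saturation-time measurement, Pepperberg curves, linear fits and shape
## characterization (upward bend, plateau).

#' Measure the time in saturation of a flash response
#'
#' Returns the first time, measured from the stated origin, at which the
#' photocurrent rises back through \code{criterion * J_dark} after the
#' response minimum. With the instantaneous-flash idealization the
#' mid-flash and flash-onset origins coincide at t = 0; the origin is
#' recorded with the measurement. The crossing is localized by monotone
#' cubic interpolation of J(t) around the bracketing grid interval.
#'
#' @param resp a \linkS4class{FlashResponse}.
#' @param criterion criterion fractional recovery in (0, 1).
#' @param origin \code{"mid_flash"} (default) or \code{"flash_onset"}.
#' @return saturation time in seconds, or \code{NA} (with attribute
#'   \code{min_frac}) when the response never falls below the criterion.
#' @export
measureTsat <- function(resp, criterion = 0.02,
                        origin = c("mid_flash", "flash_onset")) {
  origin <- match.arg(origin)
  if (criterion <= 0 || criterion >= 1) stop("criterion must lie in (0,1)")
  tt <- resp@time
  frac <- resp@currents[, "J"] / resp@jDark
  iMin <- which.min(frac)
  if (frac[iMin] >= criterion) {
    out <- NA_real_
    attr(out, "min_frac") <- frac[iMin]
    return(out)
  }
  post <- seq(iMin, length(frac))
  iUp <- post[which(frac[post] >= criterion)[1]]
  if (is.na(iUp))
    stop("trajectory ends below the criterion recovery; extend t_max")
  lo <- max(iMin, iUp - 4L); hi <- min(length(tt), iUp + 3L)
  seg <- lo:hi
  f <- stats::splinefun(tt[seg], frac[seg], method = "monoH.FC")
  tsat <- stats::uniroot(function(t) f(t) - criterion,
                         c(tt[iUp - 1L], tt[iUp]), tol = 1e-8)$root
  attr(tsat, "origin") <- origin
  tsat
}

#' Build a Pepperberg curve
#'
#' Simulates the response to each flash strength, measures the saturation
#' time at the criterion recovery, and collects the (phi, LnPhi, T_sat)
#' points. Non-saturating flashes (minimum J above the criterion) are
#' dropped from the curve and recorded separately. Fully deterministic.
#'
#' @param p a \linkS4class{RodParams}.
#' @param phis flash strengths in photoisomerizations, positive and sorted.
#' @param criterion criterion fractional recovery; if a vector, one curve
#'   per criterion is measured from the same simulations and a named list
#'   is returned.
#' @param origin measurement origin, recorded with the curve.
#' @param tMax integration window per flash (s).
#' @param model model variant passed to \code{\link{simulateFlash}}.
#' @param ... further arguments to \code{\link{simulateFlash}}.
#' @return a \linkS4class{PepperbergCurve}, or a named list of them when
#'   \code{criterion} has length > 1.
#' @export
pepperbergCurve <- function(p, phis, criterion = 0.02,
                            origin = c("mid_flash", "flash_onset"),
                            tMax = 60, model = "full", ...) {
  origin <- match.arg(origin)
  if (any(phis <= 0)) stop("phis must be positive")
  if (is.unsorted(phis, strictly = TRUE)) stop("phis must be sorted, strictly increasing")
  resps <- lapply(phis, function(phi)
    simulateFlash(p, phi, tMax = tMax, model = model, ...))
  hash <- paramsFingerprint(p)
  one <- function(cr) {
    ts <- vapply(resps, function(r) {
      v <- measureTsat(r, cr, origin)
      if (is.na(v)) c(NA_real_, attr(v, "min_frac")) else c(v, NA_real_)
    }, numeric(2))
    sat <- !is.na(ts[1, ])
    new("PepperbergCurve",
        points = data.frame(phi = phis[sat], ln_phi = log(phis[sat]),
                            t_sat = ts[1, sat]),
        dropped = data.frame(phi = phis[!sat], ln_phi = log(phis[!sat]),
                             min_frac = ts[2, !sat]),
        criterion = cr, origin = origin, paramsHash = hash)
  }
  if (length(criterion) == 1) return(one(criterion))
  out <- lapply(criterion, one)
  names(out) <- paste0("criterion_", criterion)
  out
}

#' Fit the linear domain of a Pepperberg curve
#'
#' Ordinary least squares of T_sat on LnPhi inside the stated window. The
#' slope estimates the dominant shutoff time constant tau_D (identified
#' with the T*--E deactivation time constant) and the X-intercept the
#' just-saturating flash strength LnPhi0. The default window runs from
#' half a ln unit above the dimmest saturating flash up to LnPhi = 8, the
#' upper bound of the essentially linear domain.
#'
#' @param curve a \linkS4class{PepperbergCurve}.
#' @param window numeric length-2 LnPhi bounds; \code{NULL} for the default.
#' @return a \linkS4class{PepperbergFit}.
#' @export
fitLinear <- function(curve, window = NULL) {
  pts <- curve@points
  if (is.null(window)) {
    if (!nrow(pts)) stop("empty curve")
    window <- c(min(pts$ln_phi) + 0.5, 8)
  }
  use <- pts[pts$ln_phi >= window[1] & pts$ln_phi <= window[2], , drop = FALSE]
  if (nrow(use) < 3)
    stop(sprintf("need >= 3 points in the fit window [%.2f, %.2f]; have %d",
                 window[1], window[2], nrow(use)))
  fit <- stats::lm(t_sat ~ ln_phi, data = use)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate Pepperberg curve: non-positive fitted slope")
  new("PepperbergFit",
      tauD = slope,
      lnPhi0 = -unname(stats::coef(fit)[1]) / slope,
      window = as.numeric(window),
      residuals = unname(stats::residuals(fit)),
      r2 = suppressWarnings(summary(fit)$r.squared),
      points = use)
}

#' Characterize the bend and plateau of a Pepperberg curve
#'
#' Local slopes are estimated by centered finite differences on the
#' (LnPhi, T_sat) points. The upward bend starts at the first LnPhi where
#' the local slope exceeds the fitted linear-domain slope by more than
#' \code{bendFactor - 1}; a plateau is declared where, at the bright end,
#' the local slope falls below \code{plateauFraction} of its maximum.
#'
#' @param curve a \linkS4class{PepperbergCurve}.
#' @param tauD linear-domain slope (s); computed by \code{\link{fitLinear}}
#'   with the default window when \code{NULL}.
#' @param bendFactor multiple of \code{tauD} that the local slope must
#'   exceed to mark the bend (default 1.2, i.e. +20 percent).
#' @param plateauFraction fraction of the maximal local slope below which
#'   the curve counts as flat (default 0.05).
#' @return list with \code{bend_onset_ln_phi}, \code{max_local_slope_s},
#'   \code{plateau_tsat_s}, \code{plateau_onset_ln_phi}, \code{tau_d_s}
#'   and the per-point \code{local_slopes}; absent features are \code{NA}.
#' @export
curveShape <- function(curve, tauD = NULL, bendFactor = 1.2,
                       plateauFraction = 0.05) {
  pts <- curve@points
  if (nrow(pts) < 3) stop("curve too short to characterize")
  if (is.null(tauD)) tauD <- fitLinear(curve)@tauD
  ln <- pts$ln_phi; ts <- pts$t_sat
  n <- length(ln)
  mid <- 2:(n - 1)
  slopes <- (ts[mid + 1] - ts[mid - 1]) / (ln[mid + 1] - ln[mid - 1])
  maxSlope <- max(slopes)
  bendIdx <- which(slopes > bendFactor * tauD)[1]
  bend <- if (is.na(bendIdx)) NA_real_ else ln[mid[bendIdx]]
  flat <- slopes < plateauFraction * maxSlope
  plateauIdx <- NA_integer_
  if (any(flat)) {
    run <- rev(cumprod(rev(flat)))  # trailing run of flat points
    if (run[length(run)] == 1) plateauIdx <- mid[which(run == 1)[1]]
  }
  hasPlateau <- !is.na(plateauIdx) && !is.na(bendIdx)
  list(bend_onset_ln_phi = bend,
       max_local_slope_s = maxSlope,
       plateau_tsat_s = if (hasPlateau) max(ts) else NA_real_,
       plateau_onset_ln_phi = if (hasPlateau) ln[plateauIdx] else NA_real_,
       tau_d_s = tauD,
       local_slopes = data.frame(ln_phi = ln[mid], slope_s = slopes))
}

#' Export a Pepperberg curve as CSV
#'
#' @param curve a \linkS4class{PepperbergCurve}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# criterion: %.10g", curve@criterion), con)
  writeLines(sprintf("# origin: %s", curve@origin), con)
  writeLines(sprintf("# params_hash: %s", curve@paramsHash), con)
  utils::write.csv(curve@points[, c("ln_phi", "phi", "t_sat")], con,
                   row.names = FALSE)
  invisible(path)
}

#' Export a fit summary as JSON
#'
#' @param fit a \linkS4class{PepperbergFit}.
#' @param curve the fitted \linkS4class{PepperbergCurve} (for criterion and
#'   origin metadata).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFit <- function(fit, curve, path) {
  jsonlite::write_json(
    list(tau_d_s = fit@tauD, ln_phi0 = fit@lnPhi0,
         window = fit@window, r2 = fit@r2,
         criterion = curve@criterion, origin = curve@origin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
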