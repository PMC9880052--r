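## Closed-form saturation theory: quasi-steady saturation state, the
## characteristic effector level at exit from saturation, the
## just-saturating flash strength Phi0, and the closed-form T_sat(Phi).

#' Quasi-steady state at exit from saturation
#'
#' During saturation the second messengers are in quasi-steady state and
#' the exchanger balance \eqn{\tfrac12 f_{Ca} J_{cG} = J_{ex}} makes the
#' total current \eqn{J = (1+\tfrac12 f_{Ca}) J_{cG}}. Exit from
#' saturation is defined by \eqn{J = \varepsilon J_{max}} with
#' \eqn{J_{max} = J_{dark}}. The resulting 2x2 system for (cGMP, Ca2+) is
#' solved in closed form: the exchanger relation is inverted for Ca2+ and
#' the channel Hill function for cGMP.
#'
#' @param p a \linkS4class{RodParams}.
#' @param eps criterion fraction in (0, 1); default the packaged
#'   \code{epsilon}.
#' @return named vector \code{c(cg_sat =, ca_sat =)} in uM.
#' @export
saturationState <- function(p, eps = param(p, "epsilon")) {
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0,1)")
  v <- p@values
  jMax <- attr(darkSteadyState(p), "J_dark")
  jcgTarget <- eps * jMax / (1 + 0.5 * v$f_Ca)
  jexTarget <- 0.5 * v$f_Ca * jcgTarget
  if (jexTarget >= v$j_ex_sat)
    stop("saturation state: exchanger cannot balance the target current")
  ca <- v$K_ex * jexTarget / (v$j_ex_sat - jexTarget)
  r <- jcgTarget / v$j_cG_max
  if (r >= 1) stop("saturation state: target current exceeds the maximal CNG current")
  kcg <- channelAffinity(ca, p)
  cg <- kcg * (r / (1 - r))^(1 / v$m_cG)
  res <- c((1 + 0.5 * v$f_Ca) * cngCurrent(cg, ca, p) - eps * jMax,
           0.5 * v$f_Ca * cngCurrent(cg, ca, p) - exchangerCurrent(ca, p))
  if (max(abs(res)) > 1e-10 * jMax)
    stop("saturation state residual too large: ", max(abs(res)))
  c(cg_sat = cg, ca_sat = ca)
}

#' Characteristic activated-effector level at exit from saturation
#'
#' From the quasi-steady cGMP balance at saturation,
#' \deqn{\alpha - k_{hyd} E_{tot}\, cG_{sat} - k_{\sigma hyd}
#'   E^*_{char} cG_{sat} = 0,}
#' solved for \eqn{E^*_{char}}. Both hydrolysis terms are kept. By default
#' the synthesis rate is evaluated at the (near-minimal) saturation Ca2+;
#' \code{alphaAt = "max"} uses the pure low-Ca2+ limit \code{alpha_max}.
#'
#' @inheritParams saturationState
#' @param alphaAt \code{"ca_sat"} (default) or \code{"max"}.
#' @return effector concentration in uM.
#' @export
eChar <- function(p, eps = param(p, "epsilon"), alphaAt = c("ca_sat", "max")) {
  alphaAt <- match.arg(alphaAt)
  v <- p@values
  ss <- saturationState(p, eps)
  a <- if (alphaAt == "max") v$alpha_max else cyclaseRate(ss[["ca_sat"]], p)
  e <- (a - v$k_hyd * v$E0 * ss[["cg_sat"]]) / (v$k_sigma_hyd * ss[["cg_sat"]])
  if (e <= 0)
    stop("inconsistent parameters: negative characteristic effector level")
  e
}

#' Just-saturating flash strength and the Pepperberg intercept constant
#'
#' \eqn{\Phi_0 = E^*_{char} / (\nu_{RE} \tau_{R^*})}: the flash strength
#' for which the time in saturation extrapolates to zero. \eqn{\tau_{R^*}}
#' is the lifetime of the unphosphorylated R* state at low Ca2+,
#' \eqn{1/(\lambda_1 + \mu_1)}; \eqn{\nu_{RE}} is the lumped R* -> E*
#' activation rate. Because in the front end every activated transducin
#' binds a free effector subunit (there is no competing T* loss channel),
#' the derived default is \eqn{\nu_{RE} = \nu_{RT}}; a different value may
#' be stored in the \code{nu_RE} parameter. Also returns
#' \eqn{C = -\tau_{E^*} \ln \Phi_0}, the additive constant of the linear
#' Pepperberg relation.
#'
#' @inheritParams saturationState
#' @param alphaAt passed to \code{\link{eChar}}.
#' @return a \linkS4class{SaturationTheory}.
#' @export
phiNaught <- function(p, eps = param(p, "epsilon"),
                      alphaAt = c("ca_sat", "max")) {
  alphaAt <- match.arg(alphaAt)
  v <- p@values
  ss <- saturationState(p, eps)
  e <- eChar(p, eps, alphaAt)
  nuRE <- if (is.na(v$nu_RE)) v$nu_RT else v$nu_RE
  tauR <- 1 / (lambdaMaxVector(p)[1] + muVector(p)[1])
  phi0uM <- e / (nuRE * tauR)
  phi0 <- concToPhi(phi0uM, p)
  tauE <- tauEStar(p)
  new("SaturationTheory", cgSat = ss[["cg_sat"]], caSat = ss[["ca_sat"]],
      eChar = e, phi0 = phi0, cConst = -tauE * log(phi0), epsilon = eps,
      tauE = tauE)
}

#' Closed-form saturation time
#'
#' The linear Pepperberg relation
#' \eqn{T_{sat} = \tau_{E^*} \ln(\Phi/\Phi_0)}. Flashes at or below
#' \eqn{\Phi_0} do not saturate; for them 0 is returned with attribute
#' \code{subsaturating = TRUE}.
#'
#' @param p a \linkS4class{RodParams}.
#' @param phi flash strength in photoisomerizations (vectorized).
#' @param eps criterion fraction.
#' @param theory optionally a precomputed \linkS4class{SaturationTheory}.
#' @return saturation times in seconds.
#' @export
tsatClosed <- function(p, phi, eps = param(p, "epsilon"), theory = NULL) {
  th <- theory %||% phiNaught(p, eps)
  out <- th@tauE * log(phi / th@phi0)
  sub <- phi <= th@phi0
  out[sub] <- 0
  if (any(sub)) attr(out, "subsaturating") <- sub
  out
}

#' Saturation time from the un-approximated two-exponential relation
#'
#' Without the fast-R* approximation, the activated effector after a flash
#' is \deqn{E^*(t) = \nu_{RE}\Phi \frac{\tau_{R^*}\tau_{E^*}}
#' {\tau_{E^*}-\tau_{R^*}} (e^{-t/\tau_{E^*}} - e^{-t/\tau_{R^*}}),}
#' and the saturation time solves \eqn{E^*(T_{sat}) = E^*_{char}} on the
#' decaying branch. Solved numerically; agrees with
#' \code{\link{tsatClosed}} when \eqn{\tau_{R^*} \ll \tau_{E^*}}.
#'
#' @inheritParams tsatClosed
#' @param phi flash strength (scalar).
#' @return saturation time in seconds (0 with attribute
#'   \code{subsaturating} when the flash never reaches the characteristic
#'   level).
#' @export
tsatTwoExp <- function(p, phi, eps = param(p, "epsilon"), theory = NULL) {
  th <- theory %||% phiNaught(p, eps)
  v <- p@values
  nuRE <- if (is.na(v$nu_RE)) v$nu_RT else v$nu_RE
  tauR <- 1 / (lambdaMaxVector(p)[1] + muVector(p)[1])
  tauE <- th@tauE
  phiUM <- phiToConc(phi, p)
  eOf <- function(t) nuRE * phiUM * tauR * tauE / (tauE - tauR) *
    (exp(-t / tauE) - exp(-t / tauR))
  tPeak <- log(tauE / tauR) * tauR * tauE / (tauE - tauR)
  if (eOf(tPeak) <= th@eChar) {
    out <- 0
    attr(out, "subsaturating") <- TRUE
    return(out)
  }
  upper <- tPeak + tauE * (log(eOf(tPeak) / th@eChar) + 50)
  stats::uniroot(function(t) eOf(t) - th@eChar, c(tPeak, upper), tol = 1e-12)$root
}

#' JSON report of the closed-form saturation theory
#'
#' @param p a \linkS4class{RodParams}.
#' @param eps criterion fraction.
#' @param path optional output path; when given the report is written as
#'   JSON.
#' @return the report as a named list, invisibly when written to file.
#' @export
analyticReport <- function(p, eps = param(p, "epsilon"), path = NULL) {
  th <- phiNaught(p, eps)
  rep <- list(cg_sat = th@cgSat, ca_sat = th@caSat, e_char = th@eChar,
              phi0 = th@phi0, ln_phi0 = log(th@phi0),
              c_const_s = th@cConst, tau_e_star_s = th@tauE, eps = th@epsilon)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
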