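## Pointwise biochemical rate laws. All are pure functions of (Ca2+, cGMP)
## and a RodParams bundle; the ODE right-hand sides are assembled from
## internal scalar kernels that take unpacked constants for speed.

#' Ca2+-dependent rate of cGMP synthesis by guanylate cyclase
#'
#' Two Ca2+-inhibited components (GCAP1- and GCAP2-regulated membrane
#' guanylate cyclase activities) with weights \code{beta} and
#' \code{1 - beta}:
#' \deqn{\alpha(Ca) = \alpha_{min} + (\alpha_{max}-\alpha_{min})
#'   [\beta/(1+(Ca/K_{cyc1})^{m_1}) + (1-\beta)/(1+(Ca/K_{cyc2})^{m_2})]}
#' The rate falls monotonically from \code{alpha_max} (Ca -> 0) to
#' \code{alpha_min} (Ca -> Inf).
#'
#' @param ca Ca2+ concentration (uM), non-negative; may be a vector.
#' @param p a \linkS4class{RodParams}.
#' @return synthesis rate in uM/s.
#' @export
cyclaseRate <- function(ca, p) {
  .checkCa(ca)
  v <- p@values
  .cyclaseRate(ca, v$alpha_min, v$alpha_max, v$beta,
               v$K_cyc1, v$K_cyc2, v$m_cyc1, v$m_cyc2)
}

.cyclaseRate <- function(ca, amin, amax, beta, K1, K2, m1, m2) {
  f <- beta / (1 + (ca / K1)^m1) + (1 - beta) / (1 + (ca / K2)^m2)
  f[is.infinite(ca)] <- 0
  amin + (amax - amin) * f
}

#' Ca2+/calmodulin-modulated cGMP affinity of the CNG channel
#'
#' \deqn{K_{cG}(Ca) = K_{cG,max} + (K_{cG,min}-K_{cG,max})
#'   \frac{K_{CaM}^{m}}{K_{CaM}^{m} + Ca^{m}}}
#' increases monotonically from \code{K_cG_min} at low Ca2+ to
#' \code{K_cG_max} at high Ca2+ (calmodulin lowers channel affinity).
#'
#' @inheritParams cyclaseRate
#' @return half-activating cGMP concentration (uM).
#' @export
channelAffinity <- function(ca, p) {
  .checkCa(ca)
  v <- p@values
  .channelAffinity(ca, v$K_cG_min, v$K_cG_max, v$K_CaM, v$m_CaM)
}

.channelAffinity <- function(ca, kmin, kmax, kcam, m) {
  w <- ifelse(is.infinite(ca), 0, kcam^m / (kcam^m + ca^m))
  kmax + (kmin - kmax) * w
}

#' Current carried by the CNG channels
#'
#' Hill function of cGMP with Ca2+-dependent affinity
#' \code{channelAffinity(ca, p)}:
#' \deqn{J_{cG} = j_{cG}^{max} \frac{cG^{m}}{K_{cG}(Ca)^{m} + cG^{m}}}
#'
#' @param cg cGMP concentration (uM), non-negative; may be a vector.
#' @inheritParams cyclaseRate
#' @return current in pA.
#' @export
cngCurrent <- function(cg, ca, p) {
  if (any(cg < 0, na.rm = TRUE)) stop("cg must be non-negative")
  .checkCa(ca)
  v <- p@values
  .cngCurrent(cg, .channelAffinity(ca, v$K_cG_min, v$K_cG_max, v$K_CaM, v$m_CaM),
              v$j_cG_max, v$m_cG)
}

.cngCurrent <- function(cg, kcg, jmax, m) {
  x <- (cg / kcg)^m
  ifelse(is.infinite(cg), jmax, jmax * x / (1 + x))
}

#' Current carried by the Na+/Ca2+,K+ exchanger
#'
#' Saturating Michaelis form \eqn{J_{ex} = j_{ex}^{sat} Ca/(K_{ex}+Ca)}.
#'
#' @inheritParams cyclaseRate
#' @return current in pA.
#' @export
exchangerCurrent <- function(ca, p) {
  .checkCa(ca)
  v <- p@values
  .exchangerCurrent(ca, v$j_ex_sat, v$K_ex)
}

.exchangerCurrent <- function(ca, jsat, kex)
  ifelse(is.infinite(ca), jsat, jsat * ca / (kex + ca))

#' Free fraction of rhodopsin kinase at a given Ca2+
#'
#' Recoverin binds Ca2+ and sequesters rhodopsin kinase (RK). The fraction
#' of free RK follows from the recoverin/RK equilibrium: with
#' \deqn{C_1 = (Ca/K_1)^2 (1/K_3 + M/(K_2 K_4)) Rec_{tot}, \quad
#'       C_2 = 1 + (Ca/K_1)^2 (1 + M/K_2)}
#' the free-recoverin fraction \eqn{x = [Rec]/[Rec]_{tot}} solves the
#' quadratic
#' \deqn{C_1 C_2 x^2 + [C_1(RK_{tot}/Rec_{tot} - 1) + C_2] x - 1 = 0}
#' (the unique root in (0, 1]), and
#' \eqn{[RK]/[RK]_{tot} = 1/(1 + C_1 x)}.
#' The solver uses the cancellation-free quadratic formula; for valid
#' positive parameters exactly one root lies in (0, 1].
#'
#' @inheritParams cyclaseRate
#' @return free RK fraction in (0, 1].
#' @export
rkFraction <- function(ca, p) {
  .checkCa(ca)
  v <- p@values
  vapply(ca, .rkFraction, numeric(1),
         K1 = v$K1, K2 = v$K2, K3 = v$K3, K4 = v$K4, M = v$M_rec,
         RKtot = v$RK_tot, Rectot = v$Rec_tot)
}

.rkFraction <- function(ca, K1, K2, K3, K4, M, RKtot, Rectot) {
  if (Rectot == 0 || ca == 0) return(1)
  if (is.infinite(ca)) return(0)
  A <- (ca / K1)^2
  C1 <- A * (1 / K3 + M / (K2 * K4)) * Rectot
  C2 <- 1 + A * (1 + M / K2)
  a <- C1 * C2
  b <- C1 * (RKtot / Rectot - 1) + C2
  ## roots of a x^2 + b x - 1 = 0; a > 0, c = -1 < 0 so there is exactly one
  ## positive root, and it lies in (0, 1]; avoid cancellation by branch.
  disc <- sqrt(b * b + 4 * a)
  x <- if (b >= 0) 2 / (b + disc) else (-b + disc) / (2 * a)
  if (x < 0 || x > 1 + 1e-9)
    stop(sprintf("recoverin equilibrium root outside [0,1]: x = %.6g at ca = %.6g", x, ca))
  1 / (1 + C1 * min(x, 1))
}

#' Ca2+-dependent phosphorylation and arrestin-binding rates of R*
#'
#' Phosphorylation rates scale with the free fraction of rhodopsin kinase,
#' \eqn{\lambda_j(Ca) = \lambda_{j,max} [RK]/[RK]_{tot}}, with
#' \eqn{\lambda_{n+1} = 0}. Arrestin binding is Ca2+-independent: zero for
#' states carrying fewer than 3 phosphates and \code{mu_max} from the
#' fourth state on.
#'
#' @param ca Ca2+ concentration (uM), scalar.
#' @param p a \linkS4class{RodParams}.
#' @return list with per-state vectors \code{lambda} and \code{mu}
#'   (1/s, length n+1).
#' @export
phosphoRates <- function(ca, p) {
  stopifnot(length(ca) == 1)
  .checkCa(ca)
  list(lambda = lambdaMaxVector(p) * rkFraction(ca, p),
       mu = muVector(p))
}

.checkCa <- function(ca) {
  if (any(ca < 0, na.rm = TRUE)) stop("ca must be non-negative")
  invisible(TRUE)
}
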