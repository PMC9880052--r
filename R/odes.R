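## Assembly of the coupled ODE right-hand sides.
##
## State layout (full model), all uM referred to V_cyt:
##   cg, ca, r1..r_{n+1}, T, Tst, E, TE, RGS9, RGS9TE, quench
## where r_j is photoactivated rhodopsin carrying j-1 phosphates, T/Tst are
## inactive/active transducin, E free PDE catalytic subunits, TE the T*--E
## complex, RGS9 the free GTPase-accelerating complex, RGS9TE its complex
## with T*--E, and quench the cumulative arrestin-quenched rhodopsin
## (bookkeeping only). The activated effector E* that hydrolyzes cGMP is
## TE + RGS9TE: an effector subunit stays catalytically active while
## RGS9-bound, until GTP hydrolysis (k_cat) returns T and E to their free
## pools.
##
## Simplified (validation) variant: cg, ca, r1..r_{n+1}, Tst, Estar, quench
## with first-order E* shutoff at rate k_E.

stateNames <- function(p, model = c("full", "simplified")) {
  model <- match.arg(model)
  n1 <- param(p, "n_sites") + 1
  rn <- paste0("r", seq_len(n1))
  if (model == "full")
    c("cg", "ca", rn, "T", "Tst", "E", "TE", "RGS9", "RGS9TE", "quench")
  else
    c("cg", "ca", rn, "Tst", "Estar", "quench")
}

#' Right-hand side of the rhodopsin phosphorylation chain
#'
#' Linear chain with Ca2+-dependent phosphorylation rates and
#' Ca2+-independent arrestin quench:
#' \deqn{dr_1/dt = -(\lambda_1+\mu_1) r_1, \quad
#'       dr_j/dt = \lambda_{j-1} r_{j-1} - (\lambda_j+\mu_j) r_j}
#' The flash impulse is not part of the right-hand side; it is applied as a
#' jump of \code{r1} at t = 0 by the simulator.
#'
#' @param r vector of R* state concentrations (uM, length n+1).
#' @param ca Ca2+ concentration (uM) at which the rates are evaluated.
#' @param p a \linkS4class{RodParams}.
#' @return list with \code{dr} (uM/s, length n+1) and \code{quenchRate}
#'   (total arrestin quench flux, uM/s).
#' @export
rhodopsinRhs <- function(r, ca, p) {
  n1 <- param(p, "n_sites") + 1
  stopifnot(length(r) == n1)
  rates <- phosphoRates(ca, p)
  .rhodopsinRhs(r, rates$lambda, rates$mu)
}

.rhodopsinRhs <- function(r, lam, mu) {
  n1 <- length(r)
  influx <- c(0, lam[-n1] * r[-n1])
  dr <- influx - (lam + mu) * r
  list(dr = dr, quenchRate = sum(mu * r))
}

#' Right-hand side of the transducin/PDE/RGS9 front end
#'
#' Mass-action kinetics of transducin activation by R*, T*--E complex
#' formation, RGS9 binding/dissociation and GTP hydrolysis:
#' activation \eqn{\nu_{RT} \sum_j \nu_j r_j \, T/T_0}, complex formation
#' \eqn{k_{T*E} E T^*}, RGS9 binding \eqn{k_f RGS9 \cdot T^*E}, dissociation
#' \eqn{k_b RGS9T^*E} and catalysis \eqn{k_{cat} RGS9T^*E} (returning T and
#' E to their free pools). Three pools are conserved exactly:
#' T + T* + T*E + RGS9T*E, E + T*E + RGS9T*E and RGS9 + RGS9T*E.
#'
#' @param state named numeric vector with elements \code{T}, \code{Tst},
#'   \code{E}, \code{TE}, \code{RGS9}, \code{RGS9TE}.
#' @param r R* chain concentrations (uM, length n+1).
#' @param p a \linkS4class{RodParams}.
#' @return named vector of time derivatives (uM/s).
#' @export
frontEndRhs <- function(state, r, p) {
  v <- p@values
  act <- sum(nuVector(p) * r) * state[["T"]] / v$T0
  .frontEndRhs(state[["T"]], state[["Tst"]], state[["E"]], state[["TE"]],
               state[["RGS9"]], state[["RGS9TE"]], act,
               v$k_TE, v$k_f, v$k_b, v$k_cat)
}

.frontEndRhs <- function(T, Tst, E, TE, R9, R9TE, act, kTE, kf, kb, kcat) {
  form <- kTE * E * Tst
  bind <- kf * R9 * TE
  dis <- kb * R9TE
  cat <- kcat * R9TE
  c(T = -act + cat,
    Tst = act - form,
    E = -form + cat,
    TE = form - bind + dis,
    RGS9 = -bind + dis + cat,
    RGS9TE = bind - dis - cat)
}

#' Right-hand side of the second messengers cGMP and Ca2+
#'
#' \deqn{d[cG]/dt = \alpha(Ca) - k_{hyd}(E_{tot}-E^*)\,cG
#'       - k_{\sigma hyd} E^* cG}
#' \deqn{d[Ca]/dt = \eta\,(\tfrac12 f_{Ca} J_{cG} - J_{ex})}
#' with \eqn{E^* = T^*E + RGS9T^*E} and
#' \eqn{\eta = 10^9/(2 F B_{Ca} V_{cyt})} converting pA to uM/s (divalent
#' Ca2+, cytosolic volume, buffering).
#'
#' @param cg,ca cGMP and Ca2+ concentrations (uM).
#' @param eStar total activated effector (uM).
#' @param p a \linkS4class{RodParams}.
#' @return named vector \code{c(cg =, ca =)} of derivatives (uM/s).
#' @export
messengerRhs <- function(cg, ca, eStar, p) {
  v <- p@values
  eta <- .etaFactor(v)
  a <- .cyclaseRate(ca, v$alpha_min, v$alpha_max, v$beta,
                    v$K_cyc1, v$K_cyc2, v$m_cyc1, v$m_cyc2)
  kcg <- .channelAffinity(ca, v$K_cG_min, v$K_cG_max, v$K_CaM, v$m_CaM)
  jcg <- .cngCurrent(cg, kcg, v$j_cG_max, v$m_cG)
  jex <- .exchangerCurrent(ca, v$j_ex_sat, v$K_ex)
  c(cg = a - v$k_hyd * (v$E0 - eStar) * cg - v$k_sigma_hyd * eStar * cg,
    ca = eta * (0.5 * v$f_Ca * jcg - jex))
}

## pA -> uM/s conversion for divalent Ca2+ with buffering:
## 1 pA = 1e-12 C/s; / (2 F) mol/s; / (V_cyt 1e-15 L) mol/L/s; * 1e6 uM.
.etaFactor <- function(v) 1e9 / (2 * v$F_const * v$B_Ca * v$V_cyt)

#' Right-hand side of the simplified transducin/PDE front end
#'
#' The widely used two-species activation/deactivation variant with
#' first-order E* shutoff:
#' \deqn{dT^*/dt = (1 - T^*/T_0)\sum_j \nu_j r_j - k_{T*E}(E_0-E^*)T^*}
#' \deqn{dE^*/dt = k_{T*E}(E_0-E^*)T^* - k_E E^*}
#' Used as a validation oracle: when RGS9 binding is fast and dissociation
#' negligible, the full front end approaches this variant with
#' \code{k_E = k_f * RGS9_0}.
#'
#' @param state named vector with elements \code{Tst} and \code{Estar}.
#' @inheritParams frontEndRhs
#' @return named vector of derivatives (uM/s).
#' @export
simplifiedFrontEndRhs <- function(state, r, p) {
  v <- p@values
  act <- sum(nuVector(p) * r) * (v$T0 - state[["Tst"]]) / v$T0
  form <- v$k_TE * (v$E0 - state[["Estar"]]) * state[["Tst"]]
  c(Tst = act - form, Estar = form - v$k_E * state[["Estar"]])
}

#' Full model right-hand side at an arbitrary state
#'
#' Combines the rhodopsin chain, front end and second messengers into the
#' complete derivative vector; used by the simulator and directly useful
#' for steady-state residual checks.
#'
#' @param y named state vector in the layout of \code{stateNames(p, model)}.
#' @param p a \linkS4class{RodParams}.
#' @param model \code{"full"} or \code{"simplified"}.
#' @return named derivative vector (uM/s).
#' @export
cascadeRhs <- function(y, p, model = c("full", "simplified")) {
  model <- match.arg(model)
  f <- makeRhs(p, model)
  d <- f(0, unname(y), NULL)[[1]]
  names(d) <- stateNames(p, model)
  d
}

## Builds a deSolve-compatible rhs closure with all constants unpacked.
makeRhs <- function(p, model = c("full", "simplified")) {
  model <- match.arg(model)
  v <- p@values
  n1 <- v$n_sites + 1
  lamMax <- lambdaMaxVector(p)
  mu <- muVector(p)
  nu <- nuVector(p)
  eta <- .etaFactor(v)
  amin <- v$alpha_min; amax <- v$alpha_max; bet <- v$beta
  Kc1 <- v$K_cyc1; Kc2 <- v$K_cyc2; mc1 <- v$m_cyc1; mc2 <- v$m_cyc2
  khyd <- v$k_hyd; ksig <- v$k_sigma_hyd
  jmax <- v$j_cG_max; kcgmin <- v$K_cG_min; kcgmax <- v$K_cG_max
  mcg <- v$m_cG; mcam <- v$m_CaM; kcam <- v$K_CaM; fca <- v$f_Ca
  jex0 <- v$j_ex_sat; kex <- v$K_ex
  K1 <- v$K1; K2 <- v$K2; K3 <- v$K3; K4 <- v$K4; M <- v$M_rec
  RKtot <- v$RK_tot; Rectot <- v$Rec_tot
  kTE <- v$k_TE; kf <- v$k_f; kb <- v$k_b; kcat <- v$k_cat; kE <- v$k_E
  T0 <- v$T0; E0 <- v$E0

  iR <- 3:(2 + n1)

  if (model == "full") {
    iT <- 3 + n1; iTs <- 4 + n1; iE <- 5 + n1; iTE <- 6 + n1
    iR9 <- 7 + n1; iR9TE <- 8 + n1; iQ <- 9 + n1
    function(t, y, parms) {
      cg <- y[1]; ca <- max(y[2], 0); r <- y[iR]
      Tfree <- y[iT]; Tst <- y[iTs]; E <- y[iE]; TE <- y[iTE]
      R9 <- y[iR9]; R9TE <- y[iR9TE]
      w <- .rkFraction(ca, K1, K2, K3, K4, M, RKtot, Rectot)
      lam <- lamMax * w
      influx <- c(0, lam[-n1] * r[-n1])
      dr <- influx - (lam + mu) * r
      act <- sum(nu * r) * Tfree / T0
      form <- kTE * E * Tst
      bind <- kf * R9 * TE
      dis <- kb * R9TE
      hyd <- kcat * R9TE
      eStar <- TE + R9TE
      a <- .cyclaseRate(ca, amin, amax, bet, Kc1, Kc2, mc1, mc2)
      kcg <- kcgmax + (kcgmin - kcgmax) * kcam^mcam / (kcam^mcam + ca^mcam)
      x <- (max(cg, 0) / kcg)^mcg
      jcg <- jmax * x / (1 + x)
      jex <- jex0 * ca / (kex + ca)
      dcg <- a - khyd * (E0 - eStar) * cg - ksig * eStar * cg
      dca <- eta * (0.5 * fca * jcg - jex)
      list(c(dcg, dca, dr,
             -act + hyd,
             act - form,
             -form + hyd,
             form - bind + dis,
             -bind + dis + hyd,
             bind - dis - hyd,
             sum(mu * r)))
    }
  } else {
    iTs <- 3 + n1; iEs <- 4 + n1; iQ <- 5 + n1
    function(t, y, parms) {
      cg <- y[1]; ca <- max(y[2], 0); r <- y[iR]
      Tst <- y[iTs]; Estar <- y[iEs]
      w <- .rkFraction(ca, K1, K2, K3, K4, M, RKtot, Rectot)
      lam <- lamMax * w
      influx <- c(0, lam[-n1] * r[-n1])
      dr <- influx - (lam + mu) * r
      act <- sum(nu * r) * (T0 - Tst) / T0
      form <- kTE * (E0 - Estar) * Tst
      a <- .cyclaseRate(ca, amin, amax, bet, Kc1, Kc2, mc1, mc2)
      kcg <- kcgmax + (kcgmin - kcgmax) * kcam^mcam / (kcam^mcam + ca^mcam)
      x <- (max(cg, 0) / kcg)^mcg
      jcg <- jmax * x / (1 + x)
      jex <- jex0 * ca / (kex + ca)
      dcg <- a - khyd * (E0 - Estar) * cg - ksig * Estar * cg
      dca <- eta * (0.5 * fca * jcg - jex)
      list(c(dcg, dca, dr,
             act - form,
             form - kE * Estar,
             sum(mu * r)))
    }
  }
}

#' Conservation sums of the front-end pools
#'
#' Returns the three conserved combinations (transducin, effector, RGS9
#' totals) evaluated along a trajectory, and their maximal relative drift
#' from the basal values, together with the rhodopsin budget
#' (sum of R* states plus cumulative arrestin quench versus the flash
#' strength).
#'
#' @param resp a \linkS4class{FlashResponse} from the full model.
#' @return list with \code{drift} (named maximal relative drifts) and
#'   \code{sums} (matrix of the conserved sums over time).
#' @export
conservationDrift <- function(resp) {
  p <- resp@params
  stopifnot(identical(resp@solver$model, "full"))
  s <- resp@state
  v <- p@values
  tSum <- s[, "T"] + s[, "Tst"] + s[, "TE"] + s[, "RGS9TE"]
  eSum <- s[, "E"] + s[, "TE"] + s[, "RGS9TE"]
  rSum <- s[, "RGS9"] + s[, "RGS9TE"]
  n1 <- v$n_sites + 1
  rhod <- rowSums(s[, paste0("r", seq_len(n1)), drop = FALSE]) + s[, "quench"]
  phiConc <- phiToConc(resp@phi, p)
  drift <- c(transducin = max(abs(tSum - v$T0)) / v$T0,
             effector = max(abs(eSum - v$E0)) / v$E0,
             rgs9 = max(abs(rSum - v$RGS9_0)) / v$RGS9_0,
             rhodopsin = if (phiConc > 0) max(abs(rhod - phiConc)) / phiConc else max(abs(rhod)))
  list(drift = drift,
       sums = cbind(transducin = tSum, effector = eSum, rgs9 = rSum, rhodopsin = rhod))
}

#' Dominant shutoff time constant of the linearized front end
#'
#' In the linear (small-flash) regime the (T*, T*--E, RGS9--T*--E)
#' subsystem decays with the eigenvalues of its Jacobian at the dark state;
#' the slowest eigenvalue sets the dominant time constant that the linear
#' domain of the Pepperberg relation measures.
#'
#' @param p a \linkS4class{RodParams}.
#' @param model \code{"full"} (RGS9 kinetics) or \code{"simplified"}
#'   (first-order shutoff, \code{1/k_E}).
#' @return time constant in seconds.
#' @export
tauEStar <- function(p, model = c("full", "simplified")) {
  model <- match.arg(model)
  v <- p@values
  if (model == "simplified") return(1 / v$k_E)
  1 / min(abs(frontEndEigenvalues(p)))
}

#' @rdname tauEStar
#' @export
frontEndEigenvalues <- function(p) {
  v <- p@values
  J <- matrix(c(-v$k_TE * v$E0, 0, 0,
                v$k_TE * v$E0, -v$k_f * v$RGS9_0, v$k_b,
                0, v$k_f * v$RGS9_0, -(v$k_b + v$k_cat)),
              nrow = 3, byrow = TRUE)
  Re(eigen(J, only.values = TRUE)$values)
}
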