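test_that("rhodopsin chain matches the clamped-calcium closed form", {
  p <- wtParams
  n1 <- param(p, "n_sites") + 1
  expect_equal(rhodopsinRhs(rep(0, n1), 0.2, p)$dr, rep(0, n1))

  ## with calcium clamped at zero the rates are constant (lambda = lambda_max,
  ## mu = 0 below state 4) and the first three states follow the Poisson
  ## chain solution r_j(t) = Phi e^(-lambda t) (lambda t)^(j-1)/(j-1)!
  phi <- 5; lam <- param(p, "lambda_max")
  f <- function(t, y, parms) list(rhodopsinRhs(y, 0, p)$dr)
  sol <- deSolve::lsoda(c(phi, rep(0, n1 - 1)), seq(0, 0.1, by = 0.005), f,
                        NULL, rtol = 1e-10, atol = 1e-12)
  tt <- sol[, 1]
  for (j in 1:3)
    expect_equal(sol[, j + 1], phi * exp(-lam * tt) * (lam * tt)^(j - 1) /
                   factorial(j - 1), tolerance = 1e-7)

  ## telescoping: total R* decays only through arrestin quench
  set.seed(2)
  r <- runif(n1)
  rates <- phosphoRates(0.1, p)
  rhs <- rhodopsinRhs(r, 0.1, p)
  expect_equal(sum(rhs$dr), -sum(rates$mu * r))
  expect_equal(rhs$quenchRate, sum(rates$mu * r))
})

test_that("front end conserves its three pools exactly and is quiet in the dark", {
  p <- wtParams
  v <- p@values
  dark <- c(T = v$T0, Tst = 0, E = v$E0, TE = 0, RGS9 = v$RGS9_0, RGS9TE = 0)
  expect_equal(unname(frontEndRhs(dark, rep(0, 7), p)), rep(0, 6))

  set.seed(3)
  for (i in 1:20) {
    s <- c(T = runif(1, 0, v$T0), Tst = runif(1, 0, 50), E = runif(1, 0, v$E0),
           TE = runif(1, 0, 50), RGS9 = runif(1, 0, v$RGS9_0),
           RGS9TE = runif(1, 0, 20))
    d <- frontEndRhs(s, runif(7, 0, 1), p)
    scale <- max(abs(d))
    expect_equal((d[["T"]] + d[["Tst"]] + d[["TE"]] + d[["RGS9TE"]]) / scale, 0,
                 tolerance = 1e-12)
    expect_equal((d[["E"]] + d[["TE"]] + d[["RGS9TE"]]) / scale, 0,
                 tolerance = 1e-12)
    expect_equal((d[["RGS9"]] + d[["RGS9TE"]]) / scale, 0, tolerance = 1e-12)
  }
})

test_that("linearized front-end eigenvalues match a finite-difference Jacobian", {
  p <- wtParams
  v <- p@values
  ## numerical Jacobian of the (Tst, TE, RGS9TE) subsystem at the dark state,
  ## eliminating T, E, RGS9 through the conservation laws
  rhs3 <- function(x) {
    s <- c(T = v$T0 - x[1] - x[2] - x[3], Tst = x[1],
           E = v$E0 - x[2] - x[3], TE = x[2],
           RGS9 = v$RGS9_0 - x[3], RGS9TE = x[3])
    unname(frontEndRhs(s, rep(0, 7), p)[c("Tst", "TE", "RGS9TE")])
  }
  h <- 1e-6
  J <- sapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (rhs3(e) - rhs3(-e)) / (2 * h)
  })
  evNum <- sort(Re(eigen(J, only.values = TRUE)$values))
  evAna <- sort(frontEndEigenvalues(p))
  expect_equal(evNum, evAna, tolerance = 1e-6)
  ## the slowest mode defines the dominant shutoff time constant
  expect_equal(tauEStar(p), 1 / min(abs(evAna)))
})

test_that("messenger derivatives vanish at their respective balances", {
  p <- wtParams
  v <- p@values
  dark <- darkSteadyState(p)
  d <- messengerRhs(dark[["cg"]], dark[["ca"]], 0, p)
  expect_lt(max(abs(d)), 1e-9)

  ## full activation: hydrolysis term is k_sigma_hyd * E_tot * cg
  d2 <- messengerRhs(2, 0.1, v$E0, p)
  expect_equal(d2[["cg"]],
               cyclaseRate(0.1, p) - v$k_sigma_hyd * v$E0 * 2)

  ## calcium balance located by an independent scalar root-find
  cg <- 1.5
  caStar <- uniroot(function(ca) 0.5 * v$f_Ca * cngCurrent(cg, ca, p) -
                      exchangerCurrent(ca, p), c(1e-6, 10), tol = 1e-14)$root
  expect_equal(messengerRhs(cg, caStar, 0, p)[["ca"]], 0, tolerance = 1e-12)
})

test_that("simplified front end reduces to first-order E* shutoff", {
  p <- wtParams
  ## isolated E* (no R*, no T*) decays exponentially at k_E
  kE <- param(p, "k_E")
  d <- simplifiedFrontEndRhs(c(Tst = 0, Estar = 3), rep(0, 7), p)
  expect_equal(d[["Estar"]], -kE * 3)
  expect_equal(d[["Tst"]], 0)

  ## zero R*: both species decay monotonically to zero
  f <- function(t, y, parms)
    list(unname(simplifiedFrontEndRhs(c(Tst = y[1], Estar = y[2]), rep(0, 7), p)))
  sol <- deSolve::lsoda(c(5, 3), seq(0, 3, by = 0.05), f, NULL,
                        rtol = 1e-8, atol = 1e-12)
  ## monotone decay down to solver noise level
  expect_true(all(diff(sol[, 2]) < 0 | sol[-1, 2] < 1e-9))
  expect_lt(sol[nrow(sol), 3], 3)
  expect_lt(max(sol[nrow(sol), 2:3]), 1e-2)
})

test_that("full front end approaches the simplified limit as RGS9 binding speeds up", {
  ## when RGS9 binding is rate-limiting (dissociation negligible, GTP
  ## hydrolysis fast) the E* trajectory of the full model converges on the
  ## simplified model with k_E = k_f * RGS9_0; the gap shrinks as the
  ## post-binding hydrolysis step gets faster
  p0 <- setParams(wtParams, k_b = 1e-4)
  kE <- param(p0, "k_f") * param(p0, "RGS9_0")
  gap <- sapply(c(10, 100), function(fac) {
    p <- setParams(p0, k_E = kE, k_cat = fac * kE)
    rFull <- simulateFlash(p, 1000, tMax = 2, dt = 0.005)
    rSimp <- simulateFlash(p, 1000, tMax = 2, dt = 0.005, model = "simplified")
    eF <- rFull@state[, "TE"] + rFull@state[, "RGS9TE"]
    eS <- rSimp@state[, "Estar"]
    max(abs(eF - eS)) / max(eS)
  })
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 0.05)
})
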