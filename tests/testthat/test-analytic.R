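test_that("saturation state solves the exchanger/criterion system", {
  p <- wtParams
  eps <- 0.02
  ss <- saturationState(p, eps)
  jMax <- attr(darkSteadyState(p), "J_dark")
  fca <- param(p, "f_Ca")
  ## both defining relations hold at the solution
  expect_equal((1 + 0.5 * fca) * cngCurrent(ss[["cg_sat"]], ss[["ca_sat"]], p),
               eps * jMax, tolerance = 1e-10)
  expect_equal(0.5 * fca * cngCurrent(ss[["cg_sat"]], ss[["ca_sat"]], p),
               exchangerCurrent(ss[["ca_sat"]], p), tolerance = 1e-10)

  ## brute-force 2-D grid + refine oracle around the solution
  resid <- function(cg, ca) {
    abs((1 + 0.5 * fca) * cngCurrent(cg, ca, p) - eps * jMax) +
      abs(0.5 * fca * cngCurrent(cg, ca, p) - exchangerCurrent(ca, p))
  }
  cgGrid <- seq(0.5, 1.5, length.out = 201) * ss[["cg_sat"]]
  caGrid <- seq(0.5, 1.5, length.out = 201) * ss[["ca_sat"]]
  rmat <- outer(cgGrid, caGrid, Vectorize(resid))
  best <- which(rmat == min(rmat), arr.ind = TRUE)[1, ]
  expect_equal(cgGrid[best[1]], ss[["cg_sat"]], tolerance = 0.01)
  expect_equal(caGrid[best[2]], ss[["ca_sat"]], tolerance = 0.01)

  ## as the criterion approaches the full dark current the dark state returns
  ssD <- saturationState(p, 1 - 1e-10)
  dark <- darkSteadyState(p)
  expect_equal(ssD[["cg_sat"]], dark[["cg"]], tolerance = 1e-4)
  expect_equal(ssD[["ca_sat"]], dark[["ca"]], tolerance = 1e-4)
})

test_that("characteristic effector level follows the cyclase/hydrolysis balance", {
  p <- wtParams
  eps <- 0.02
  ss <- saturationState(p, eps)
  v <- p@values
  e <- eChar(p, eps)
  ## definition, both hydrolysis terms kept
  expect_equal(v$k_sigma_hyd * e * ss[["cg_sat"]] +
                 v$k_hyd * v$E0 * ss[["cg_sat"]],
               cyclaseRate(ss[["ca_sat"]], p), tolerance = 1e-10)
  expect_lte(e, v$E0)
  ## neglecting basal hydrolysis recovers E*char = alpha_max/(k_sigma_hyd
  ## cg_sat): the basal term enters purely additively as k_hyd E0/k_sigma_hyd
  expect_equal(eChar(p, eps, alphaAt = "max") + v$k_hyd * v$E0 / v$k_sigma_hyd,
               v$alpha_max / (v$k_sigma_hyd * ss[["cg_sat"]]),
               tolerance = 1e-10)
  ## more cyclase activity raises the exit threshold
  expect_gt(eChar(setParams(p, alpha_max = 2 * v$alpha_max), eps), e)
})

test_that("Phi0 scales and the closed-form line passes through it", {
  p <- wtParams
  th <- phiNaught(p)
  expect_gt(th@phi0, 0)
  expect_equal(th@cConst, -th@tauE * log(th@phi0))

  ## doubling the lumped activation rate halves Phi0
  th2 <- phiNaught(setParams(p, nu_RE = 2 * param(p, "nu_RT")))
  expect_equal(th2@phi0, th@phi0 / 2, tolerance = 1e-12)

  ## removing cyclase feedback (lower effective synthesis in saturation)
  ## shifts the just-saturating flash to dimmer values
  thG <- phiNaught(applyPreset(p, "GCAPs_KO"))
  expect_lt(thG@phi0, th@phi0)

  ## T_sat(Phi0) = 0 exactly, with the sub-saturation flag below it
  expect_equal(tsatClosed(p, th@phi0, theory = th), 0, ignore_attr = TRUE)
  sub <- tsatClosed(p, 0.5 * th@phi0, theory = th)
  expect_equal(as.numeric(sub), 0)
  expect_true(any(attr(sub, "subsaturating")))

  ## one natural-log unit above Phi0 the saturation lasts exactly tau_E*
  expect_equal(tsatClosed(p, exp(1) * th@phi0, theory = th), th@tauE,
               tolerance = 1e-12, ignore_attr = TRUE)
  ## constant slope tau_E* in ln phi
  phis <- th@phi0 * exp(c(1, 2, 3))
  expect_equal(diff(tsatClosed(p, phis, theory = th)), rep(th@tauE, 2),
               tolerance = 1e-10)
})

test_that("two-exponential crossing matches the approximation when R* is fast", {
  p <- wtParams   # tau_R* = 1/60 s << tau_E* = 0.381 s
  th <- phiNaught(p)
  for (phi in th@phi0 * c(20, 200, 2000)) {
    exact <- tsatTwoExp(p, phi, theory = th)
    approx <- tsatClosed(p, phi, theory = th)
    expect_equal(exact, approx, tolerance = 0.02, ignore_attr = TRUE)
  }
  sub <- tsatTwoExp(p, 0.1 * th@phi0, theory = th)
  expect_true(isTRUE(attr(sub, "subsaturating")))
})

test_that("closed-form lines over varying tau_E* share the point (LnPhi0, 0)", {
  p <- wtParams
  th <- phiNaught(p)
  ## scaling RGS9 changes tau_E* but not Phi0; every line crosses zero at Phi0
  for (s in c(0.5, 2, 4)) {
    ps <- applyPreset(p, list(scale = list(RGS9_0 = s)))
    ths <- phiNaught(ps)
    expect_false(isTRUE(all.equal(ths@tauE, th@tauE)))
    expect_equal(ths@phi0, th@phi0, tolerance = 1e-10)
    expect_equal(tsatClosed(ps, th@phi0, theory = ths), 0, ignore_attr = TRUE)
  }
})

test_that("the analytic report is complete and serializable", {
  p <- wtParams
  f <- tempfile(fileext = ".json")
  analyticReport(p, path = f)
  js <- jsonlite::read_json(f)
  expect_setequal(names(js), c("cg_sat", "ca_sat", "e_char", "phi0", "ln_phi0",
                               "c_const_s", "tau_e_star_s", "eps"))
  expect_equal(js$eps, 0.02)
  expect_equal(js$ln_phi0, log(js$phi0), tolerance = 1e-10)
})
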