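test_that("saturation time matches the analytic crossing of a constructed trace", {
  ## J/J_dark = 0 for t <= T, then 1 - exp(-(t-T)/tau): the criterion c is
  ## crossed at exactly T + tau * ln(1/(1-c))
  T0 <- 1.25; tau <- 0.4
  tt <- seq(0, 10, by = 0.002)
  frac <- ifelse(tt <= T0, 0, 1 - exp(-(tt - T0) / tau))
  resp <- syntheticResponse(tt, frac)
  for (cr in c(0.02, 0.10, 0.20)) {
    expect_equal(measureTsat(resp, cr), T0 + tau * log(1 / (1 - cr)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  ## a higher criterion is always crossed later on a monotone recovery
  expect_gt(measureTsat(resp, 0.20), measureTsat(resp, 0.02))
})

test_that("non-saturating and truncated responses are handled explicitly", {
  tt <- seq(0, 5, by = 0.01)
  ## dips only to 40% of dark: no crossing of a 20% criterion
  shallow <- syntheticResponse(tt, 0.4 + 0.6 * (1 - exp(-pmax(tt - 0.5, 0))))
  out <- measureTsat(shallow, 0.20)
  expect_true(is.na(out))
  expect_equal(attr(out, "min_frac"), 0.4, tolerance = 1e-6)
  ## trace that ends while still below the criterion
  short <- syntheticResponse(seq(0, 1, by = 0.01),
                             rep(c(0.5, 0.001), c(10, 91)))
  expect_error(measureTsat(short, 0.20), "extend t_max")
  expect_error(measureTsat(shallow, 1.2), "criterion")
})

test_that("Pepperberg curves are monotone and record non-saturating flashes", {
  p <- wtParams
  cv <- cached("wt_small_curve", {
    ## spans sub-saturating through saturating flashes at 10% recovery
    pepperbergCurve(p, exp(c(2.5, 5, 6, 7)), criterion = 0.10, tMax = 20)
  })
  pts <- curvePoints(cv)
  expect_true(all(diff(pts$ln_phi) > 0))
  expect_true(all(diff(pts$t_sat) > 0))        # brighter flash, longer Tsat
  expect_equal(nrow(cv@dropped), 1)            # the ln 2.5 flash never saturates
  expect_lt(cv@dropped$ln_phi[1], 3)
  expect_equal(cv@criterion, 0.10)

  ## an empty flash list yields an empty curve, not an error
  empty <- pepperbergCurve(p, numeric(0), criterion = 0.10)
  expect_equal(nrow(curvePoints(empty)), 0)
  expect_error(pepperbergCurve(p, c(10, 5), criterion = 0.1), "sorted")
})

test_that("ordinary least squares recovers exact collinear Pepperberg data", {
  ln <- seq(5, 8, by = 0.5)
  cv <- syntheticCurve(ln, 0.25 * ln - 1.1)
  fit <- fitLinear(cv, window = c(4.9, 8.1))
  expect_equal(fit@tauD, 0.25, tolerance = 1e-12)
  expect_equal(fit@lnPhi0, 1.1 / 0.25, tolerance = 1e-12)
  expect_equal(fit@r2, 1)
  expect_equal(max(abs(fit@residuals)), 0, tolerance = 1e-12)

  expect_error(fitLinear(cv, window = c(5, 5.6)), ">= 3 points")
  down <- syntheticCurve(ln, 2 - 0.1 * ln)
  expect_error(fitLinear(down, window = c(4.9, 8.1)), "degenerate")
})

test_that("curve shape analysis flags bend and plateau only when present", {
  ## perfectly linear curve: no bend, no plateau
  ln <- seq(5, 16, by = 0.5)
  lin <- syntheticCurve(ln, 0.4 * ln - 1)
  sh <- curveShape(lin, tauD = 0.4)
  expect_true(is.na(sh$bend_onset_ln_phi))
  expect_true(is.na(sh$plateau_onset_ln_phi))
  expect_true(is.na(sh$plateau_tsat_s))
  expect_equal(sh$max_local_slope_s, 0.4, tolerance = 1e-12)

  ## linear segment, upward bend, then saturation to a flat plateau
  ts <- ifelse(ln < 10, 0.4 * ln - 1,
               0.4 * 10 - 1 + 3 * (1 - exp(-(ln - 10))))
  bent <- syntheticCurve(ln, cummax(ts))
  sh2 <- curveShape(bent, tauD = 0.4)
  expect_false(is.na(sh2$bend_onset_ln_phi))
  expect_gt(sh2$bend_onset_ln_phi, 9)
  expect_gte(sh2$max_local_slope_s, 0.4)       # convexity: local slope >= tau_D
  expect_false(is.na(sh2$plateau_onset_ln_phi))
  expect_equal(sh2$plateau_tsat_s, max(bent@points$t_sat))

  ## thresholds are configurable: an extreme bend factor suppresses detection
  sh3 <- curveShape(bent, tauD = 0.4, bendFactor = 50)
  expect_true(is.na(sh3$bend_onset_ln_phi))
})

test_that("curve export carries criterion and origin metadata", {
  cv <- syntheticCurve(seq(5, 7, 0.5), seq(1, 2, length.out = 5))
  f <- tempfile(fileext = ".csv")
  writeCurve(cv, f)
  expect_match(readLines(f, n = 1), "criterion: 0.1")
  df <- utils::read.csv(f, comment.char = "#")
  expect_equal(df$t_sat, cv@points$t_sat)
  fit <- fitLinear(cv, window = c(4.9, 7.1))
  fj <- tempfile(fileext = ".json")
  writeFit(fit, cv, fj)
  js <- jsonlite::read_json(fj)
  expect_equal(js$tau_d_s, fit@tauD, tolerance = 1e-12)
  expect_equal(js$origin, "mid_flash")
})
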