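## Shared fixtures: the packaged wild-type parameter set and a cross-file
## cache so expensive simulations (Pepperberg curves for the acceptance
## checks) are computed once per test run.

wtParams <- defaultParams()

.testCache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.testCache[[key]])) .testCache[[key]] <- force(expr)
  .testCache[[key]]
}

## Pepperberg curve + linear fit under a named protocol, cached.
curveAndFit <- function(key, p, lnGrid, criterion, window, tMax = 40,
                        origin = "mid_flash", model = "full") {
  cached(key, {
    cv <- pepperbergCurve(p, exp(lnGrid), criterion = criterion,
                          origin = origin, tMax = tMax, model = model)
    list(curve = cv, fit = fitLinear(cv, window = window))
  })
}

## Builds a synthetic FlashResponse with a prescribed J(t)/J_dark trace.
syntheticResponse <- function(time, frac, jDark = 15) {
  J <- frac * jDark
  new("FlashResponse", time = time,
      state = matrix(0, length(time), 1, dimnames = list(NULL, "cg")),
      currents = cbind(J_cG = J, J_ex = 0 * J, J = J),
      phi = 1000, jDark = jDark, dark = c(cg = 0),
      params = wtParams, solver = list(model = "full"))
}

## Builds a synthetic PepperbergCurve from (ln_phi, t_sat) points.
syntheticCurve <- function(ln_phi, t_sat, criterion = 0.1) {
  new("PepperbergCurve",
      points = data.frame(phi = exp(ln_phi), ln_phi = ln_phi, t_sat = t_sat),
      dropped = data.frame(phi = numeric(), ln_phi = numeric(),
                           min_frac = numeric()),
      criterion = criterion, origin = "mid_flash", paramsHash = "synthetic")
}
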