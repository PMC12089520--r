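# Shared fixtures.  Heavy objects (the fully calibrated reference design)
# are computed once per session and cached.

.fixtures <- new.env(parent = emptyenv())

refHyper <- function() dlmHyper(probit(0.2))

# small, fast design used by most unit tests (not calibrated; cutoffs are
# plausible hand-picked values)
smallDesign <- function(model = "dlm") {
  designParams(n = 10, m1 = 5, a1 = 0.05, a2 = 0.7, c1 = 0.3, c2 = 0.7,
               delta1 = 0.05, delta2 = 0.2, p0 = 0.2, pA = 0.4,
               model = model)
}

smallGrids <- function(model = "dlm") {
  key <- paste0("grids_", model)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- todesign:::.designGrids(smallDesign(model), refHyper())
  .fixtures[[key]]
}

# the reference configuration, calibrated once (used by the acceptance
# tests): p0 = 0.2, pA = 0.4, alpha1 = 10%, beta1 = 95%, alpha2 = 20%,
# alpha3 = 15%, wl = 0.40
refCalibrated <- function() {
  if (is.null(.fixtures$refdes)) {
    tg <- calibrationTargets(n_range = 20:40)
    d1 <- step1Search(tg, p0 = 0.2, pA = 0.4, refHyper())
    .fixtures$refdes <- step2Search(d1, tg, refHyper())
  }
  .fixtures$refdes
}

refCalibratedGrids <- function() {
  if (is.null(.fixtures$refgrids))
    .fixtures$refgrids <- todesign:::.designGrids(refCalibrated(), refHyper())
  .fixtures$refgrids
}

# independent single-dose probit posterior oracle: 1-D trapezoid over a
# fine mu grid, mu ~ N(theta, sigma1^2), y ~ Bin(n, pnorm(mu))
probitOracle <- function(y, n, theta, sigma1, p0) {
  mu <- seq(min(-12, theta - 6 * sigma1), max(12, theta + 6 * sigma1),
            by = 0.002)
  w <- dnorm(mu, theta, sigma1) * dbinom(y, n, pnorm(mu))
  c(pr = sum(w[mu > qnorm(p0)]) / sum(w),
    pm = sum(w * pnorm(mu)) / sum(w))
}
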