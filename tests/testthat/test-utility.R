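jointFixture <- function(rho = 0.67) {
  des <- designParams(n = 10, m1 = 5, a1 = 0.05, a2 = 0.7, c1 = 0.3,
                      c2 = 0.7, p0 = 0.25, pA = 0.4)
  jointDesign(des, utilityParams(rho, q0 = 0.4, qA = 0.2))
}

test_that("utility scores reproduce the benchmark scenario table", {
  expect_equal(round(utilityScore(0.20, 0.40, 0.67), 2), -0.07)
  expect_equal(utilityScore(0.5, 0, 0.9), 0.5)
  # scenario with reversed risk-benefit: large negative difference
  expect_equal(round(utilityScore(0.40, 0.45, 0.67) -
                       utilityScore(0.50, 0.20, 0.67), 2), -0.27)
  tb <- read.csv(system.file("extdata", "scenarios_table2.csv",
                             package = "todesign"))
  u1 <- round(utilityScore(tb$p1, tb$q1, 0.67), 2)
  u2 <- round(utilityScore(tb$p2, tb$q2, 0.67), 2)
  expect_length(u1, 15L)
  expect_true(all(is.finite(u1)) && all(is.finite(u2)))
  # the two global-null-style scenarios have equal (negative) utilities
  expect_equal(u1[1], u2[1])
  expect_lt(u1[1], 0)
})

test_that("joint monitoring drops a dose that is toxic or futile", {
  expect_identical(jointMonitor(1.0, 0.0, 0.1), "drop")   # futile though safe
  expect_identical(jointMonitor(0.0, 1.0, 0.1), "drop")   # toxic though effective
  expect_identical(jointMonitor(1.0, 1.0, 0.99), "pass")
  expect_identical(jointMonitor(c(0.05, 0.5), c(0.5, 0.05), 0.1),
                   c("drop", "drop"))
})

test_that("rho = 0 reduces the utility PP to the efficacy-only PP_NI", {
  h <- refHyper()
  e <- trialData(c(4, 6), c(10, 10))
  t <- trialData(c(2, 3), c(10, 10))
  pp0 <- ppUtilityNI(e, t, h, dlmHyper(probit(0.4)), delta1 = 0.05,
                     rho = 0, p0 = 0.2, q0 = 0.4)
  ref <- dlmPosterior(e, h, 0.2, 0.05, check = FALSE)$pp_ni
  expect_equal(pp0, ref, tolerance = 1e-12)
})

test_that("symmetric data on both arms favour utility noninferiority", {
  h <- refHyper(); ht <- dlmHyper(probit(0.4))
  e <- trialData(c(5, 5), c(12, 12))
  t <- trialData(c(3, 3), c(12, 12))
  pp <- ppUtilityNI(e, t, h, ht, delta1 = 0.05, rho = 0.67,
                    p0 = 0.2, q0 = 0.4)
  expect_gt(pp, 0.5)
  # and the PP grows with the margin
  pp2 <- ppUtilityNI(e, t, h, ht, delta1 = 0.15, rho = 0.67,
                     p0 = 0.2, q0 = 0.4)
  expect_gt(pp2, pp)
})

test_that("with rho = 0 and all-safe toxicity the joint design reproduces the efficacy-only decisions", {
  jd <- jointFixture(rho = 0)
  des <- jd$design
  g <- todesign:::.jointGrids(jd, diff = FALSE)
  ppu <- todesign:::.ppuMatrix(g$eff$fin, g$tox$fin, des$delta1, 0)
  n <- des$n
  Deff <- todesign:::.finalDecisionMatrix(g$eff$fin, des)
  # pick an all-safe toxicity path: zero toxicities throughout
  ct <- 0L * (n + 1L) + 0L + 1L
  tox_ok <- (1 - g$tox$fin$pr1[1L, 1L]) >= des$a2 &&
            (1 - g$tox$fin$pr2[1L, 1L]) >= des$a2
  expect_true(tox_ok)
  for (y1 in 0:n) for (y2 in 0:n) {
    f1 <- g$eff$fin$pr1[y1 + 1L, y2 + 1L] >= des$a2
    f2 <- g$eff$fin$pr2[y1 + 1L, y2 + 1L] >= des$a2
    if (!(f1 && f2)) next
    pp <- ppu[y1 * (n + 1L) + y2 + 1L, ct]
    dec <- if (pp <= des$c1) 2L else if (pp > des$c2) 1L else 3L
    expect_identical(dec, Deff[y1 + 1L, y2 + 1L])
  }
})

test_that("exact joint OC matches its Monte Carlo twin", {
  jd <- jointFixture()
  g <- todesign:::.jointGrids(jd)
  ppu <- todesign:::.ppuMatrix(g$eff$fin, g$tox$fin, jd$design$delta1,
                               jd$up$rho)
  reps <- 20000L
  for (scn in list(scenario(0.25, 0.25, 0.4, 0.4, label = "null-ish"),
                   scenario(0.4, 0.45, 0.2, 0.2, label = "active"))) {
    ex <- exactJointOC(scn, jd, grids = g, ppu = ppu)
    mc <- simulateJointOC(scn, jd, reps = reps, seed = 31, grids = g,
                          ppu = ppu)
    expect_equal(sum(ex$decision_prob), 1, tolerance = 1e-10)
    for (k in seq_along(ex$decision_prob)) {
      se <- sqrt(ex$decision_prob[k] * (1 - ex$decision_prob[k]) / reps)
      expect_lt(abs(ex$decision_prob[k] - mc$decision_prob[k]), 3 * se + 1e-9)
    }
    expect_lt(abs(ex$go[1] - mc$go[1]), 3 * 0.5 / sqrt(reps) + 1e-9)
    expect_lt(abs(ex$ass[2] - mc$ass[2]),
              3 * jd$design$m2 * 0.5 / sqrt(reps) + 0.05)
  }
})

test_that("joint calibration rejects a vacuous toxicity alternative", {
  tg <- calibrationTargets(n_range = 6:8, lambda_grid = 1,
                           a2_grid = c(0.6, 0.8))
  res <- calibrateJoint(tg, 0.25, 0.5, q0 = 0.4, qA = 0.4, rho = 0.67)
  expect_s3_class(res, "calibrationFailure")
  expect_match(res$message, "infeasible")
})

test_that("joint calibration returns a complete design on a small problem", {
  tg <- calibrationTargets(alpha1 = 0.15, beta1 = 0.80, alpha2 = 0.35,
                           alpha3 = 0.30, n_range = 8:12,
                           lambda_grid = c(0.5, 1),
                           a2_grid = seq(0.5, 0.9, by = 0.1),
                           c_grid = seq(0.1, 0.9, by = 0.1))
  jd <- calibrateJoint(tg, p0 = 0.25, pA = 0.5, q0 = 0.4, qA = 0.2,
                       rho = 0.67)
  expect_s3_class(jd, "jointDesign")
  expect_lte(jd$design$a1, jd$design$a2)
  expect_lte(jd$design$c1, jd$design$c2)
  # FWER constraint holds under the joint global null by exact enumeration
  oc0 <- exactJointOC(scenario(0.25, 0.25, 0.4, 0.4), jd)
  expect_lte(oc0$p_event, 0.15 + 1e-9)
})
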