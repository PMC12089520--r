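test_that("degenerate scenarios behave deterministically", {
  des <- smallDesign(); g <- smallGrids()
  r0 <- simulateTrial(scenario(0, 0), des, refHyper(), seed = 3, grids = g)
  expect_identical(r0$decision, "none")
  expect_identical(r0$enrolled, c(des$m1, des$m1))   # stop at interim
  oc1 <- exactOC(scenario(1, 1), des, refHyper(), grids = g)
  expect_equal(unname(oc1$decision_prob[["none"]]), 0, tolerance = 1e-12)
  expect_equal(oc1$go, c(1, 1), tolerance = 1e-12)
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  des <- smallDesign(); g <- smallGrids()
  scn <- scenario(0.3, 0.5)
  a <- simulateOC(scn, des, refHyper(), reps = 500, seed = 42, grids = g)
  b <- simulateOC(scn, des, refHyper(), reps = 500, seed = 42, grids = g)
  expect_identical(a$decision_prob, b$decision_prob)
  expect_identical(a$est_mean, b$est_mean)
  r1 <- simulateTrial(scn, des, refHyper(), seed = 9, grids = g)
  r2 <- simulateTrial(scn, des, refHyper(), seed = 9, grids = g)
  expect_identical(r1, r2)
})

test_that("exact decision probabilities form a probability distribution", {
  des <- smallDesign(); g <- smallGrids()
  for (scn in list(scenario(0.2, 0.2), scenario(0.4, 0.6), scenario(0.7, 0.3))) {
    oc <- exactOC(scn, des, refHyper(), grids = g)
    expect_equal(sum(oc$decision_prob), 1, tolerance = 1e-10)
    expect_true(all(oc$decision_prob >= 0))
    expect_equal(unname(oc$p_event),
                 unname(1 - oc$decision_prob[["none"]]), tolerance = 1e-12)
  }
})

test_that("Monte Carlo OC agrees with exact enumeration within 3 SEs", {
  des <- smallDesign(); g <- smallGrids()
  reps <- 10000L
  for (scn in list(scenario(0.2, 0.2), scenario(0.4, 0.45))) {
    ex <- exactOC(scn, des, refHyper(), grids = g)
    mc <- simulateOC(scn, des, refHyper(), reps = reps, seed = 17, grids = g)
    for (k in seq_along(ex$decision_prob)) {
      se <- sqrt(ex$decision_prob[k] * (1 - ex$decision_prob[k]) / reps)
      expect_lt(abs(ex$decision_prob[k] - mc$decision_prob[k]),
                3 * se + 1e-9)
    }
    expect_lt(abs(ex$ass[1] - mc$ass[1]), 3 * des$m2 * 0.5 / sqrt(reps) + 0.05)
  }
})

test_that("a single replication yields 0/1 operating characteristics", {
  oc <- simulateOC(scenario(0.4, 0.4), smallDesign(), refHyper(),
                   reps = 1, seed = 5, grids = smallGrids())
  expect_true(all(oc$decision_prob %in% c(0, 1)))
  expect_true(all(oc$ass >= smallDesign()$m1 & oc$ass <= smallDesign()$n))
})

test_that("ASS decomposes as m1 + m2 * P(pass interim)", {
  des <- smallDesign(); g <- smallGrids()
  scn <- scenario(0.25, 0.35)
  oc <- exactOC(scn, des, refHyper(), grids = g)
  w1 <- dbinom(0:des$m1, des$m1, scn$p[1])
  w2 <- dbinom(0:des$m1, des$m1, scn$p[2])
  W <- outer(w1, w2)
  p1 <- sum(W[g$int$pr1 >= des$a1])
  p2 <- sum(W[g$int$pr2 >= des$a1])
  expect_equal(oc$ass, des$m1 + des$m2 * c(p1, p2), tolerance = 1e-12)
})

test_that("raising a dose's true rate never lowers its Go probability", {
  des <- smallDesign(); g <- smallGrids()
  go1 <- vapply(c(0.2, 0.3, 0.4, 0.5), function(p)
    exactOC(scenario(p, 0.3), des, refHyper(), grids = g)$go[1], numeric(1))
  expect_true(all(diff(go1) > 0))
  go2 <- vapply(c(0.2, 0.35, 0.5), function(p)
    exactOC(scenario(0.3, p), des, refHyper(), grids = g)$go[2], numeric(1))
  expect_true(all(diff(go2) > 0))
})

test_that("trial data invariants are enforced", {
  expect_error(trialData(c(3, 11), c(10, 10)), "0 <= y <= n")
  expect_error(trialData(c(-1, 0), c(10, 10)), "0 <= y <= n")
  expect_error(trialData(c(1, 1), c(10, 10), t = c(11, 0)), "0 <= t <= n")
  d <- trialData(c(3, 5), c(10, 10), t = c(1, 2), stage = 2)
  expect_identical(d$stage, 2L)
})
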