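# calibration unit tests run on deliberately small configurations; the
# reference-scale calibration is exercised in test-acceptance.R

test_that("a degenerate unconstrained search returns the smallest n", {
  tg <- calibrationTargets(alpha1 = 1, beta1 = 0.5, n_range = 5:8,
                           lambda_grid = 1, a2_grid = 0)
  des <- step1Search(tg, 0.2, 0.4, refHyper())
  expect_s3_class(des, "designParams")
  expect_identical(des$n, 5L)            # a_k = 0 never drops: OMP = 1
  expect_identical(des$a2, 0)
})

test_that("step-1 designs respect the cutoff regularization a1 <= a2", {
  tg <- calibrationTargets(alpha1 = 0.2, beta1 = 0.6, n_range = 8:12,
                           lambda_grid = c(0.3, 1),
                           a2_grid = seq(0.5, 0.9, by = 0.1))
  des <- step1Search(tg, 0.2, 0.4, refHyper())
  expect_s3_class(des, "designParams")
  expect_lte(des$a1, des$a2)
  expect_equal(des$a1, des$a2 * (des$m1 / des$n)^des$lambda, tolerance = 1e-12)
})

test_that("relaxing the FWER cap never increases the minimal n", {
  base <- list(beta1 = 0.75, n_range = 6:16, lambda_grid = c(0.5, 1),
               a2_grid = seq(0.5, 0.95, by = 0.05))
  d_tight <- do.call(calibrationTargets, c(base, alpha1 = 0.08))
  d_loose <- do.call(calibrationTargets, c(base, alpha1 = 0.30))
  n_tight <- step1Search(d_tight, 0.2, 0.4, refHyper())$n
  n_loose <- step1Search(d_loose, 0.2, 0.4, refHyper())$n
  expect_lte(n_loose, n_tight)
})

test_that("an unattainable power target yields an explicit infeasibility report", {
  tg <- calibrationTargets(alpha1 = 0.3, beta1 = 0.999, n_range = 5:7,
                           lambda_grid = 1, a2_grid = c(0.6, 0.8))
  res <- step1Search(tg, 0.2, 0.4, refHyper())
  expect_s3_class(res, "calibrationFailure")
  expect_match(res$message, "best achieved")
  expect_true(res$best$omp < 0.999)
})

test_that("wl = 1 closes the inconclusive zone and alpha3 = 0 forces SIR = 0", {
  des <- smallDesign()
  tg1 <- calibrationTargets(alpha2 = 0.5, alpha3 = 0.5, wl = 1,
                            c_grid = seq(0.1, 0.9, by = 0.1))
  d1 <- step2Search(des, tg1, refHyper())
  expect_identical(d1$c1, d1$c2)
  tg0 <- calibrationTargets(alpha2 = 0.5, alpha3 = 0, wl = 0.4,
                            c_grid = seq(0.1, 0.9, by = 0.1))
  d0 <- step2Search(des, tg0, refHyper())
  expect_identical(d0$c1, d0$c2)
  oc <- exactOC(scenario(des$pA, des$pA + des$delta1), d0, refHyper())
  expect_equal(unname(oc$decision_prob[["inconclusive"]]), 0,
               tolerance = 1e-12)
})

test_that("step-2 optima satisfy their hard constraints by construction", {
  tg <- calibrationTargets(alpha2 = 0.2, alpha3 = 0.15,
                           c_grid = seq(0.05, 0.95, by = 0.05))
  des <- step2Search(smallDesign(), tg, refHyper())
  s2 <- attr(des, "step2")
  expect_lte(s2$mrid, 0.2 + 1e-12)
  expect_lte(s2$sir, 0.15 + 1e-12)
  # exact OC under HA+ reproduces the recorded MRID
  ocp <- exactOC(scenario(des$pA, des$pA + des$delta2), des, refHyper())
  expect_equal(unname(ocp$decision_prob[["select_d1"]]), s2$mrid,
               tolerance = 1e-10)
})

test_that("Simon search output satisfies its exact error constraints", {
  s <- simonTwoStage(0.3, 0.55, alpha = 0.1, power = 0.8, nmax = 40)
  # independent exact-binomial recomputation
  xs <- (s$r1 + 1):s$n1
  a <- sum(dbinom(xs, s$n1, 0.3) * (1 - pbinom(s$r - xs, s$n - s$n1, 0.3)))
  pw <- sum(dbinom(xs, s$n1, 0.55) * (1 - pbinom(s$r - xs, s$n - s$n1, 0.55)))
  expect_equal(a, s$alpha, tolerance = 1e-12)
  expect_lte(a, 0.1)
  expect_equal(pw, s$power, tolerance = 1e-12)
  expect_gte(pw, 0.8)
  expect_equal(s$EN0, s$n1 + (1 - pbinom(s$r1, s$n1, 0.3)) * (s$n - s$n1),
               tolerance = 1e-12)
  # unconstrained limit: the trivial minimal design
  s0 <- simonTwoStage(0.2, 0.4, alpha = 1, power = 1e-6, nmax = 10)
  expect_identical(s0$n1, 1L)
  expect_error(simonTwoStage(0.2, 0.4, alpha = 1e-8, power = 0.999,
                             nmax = 15), "no feasible")
})

test_that("the two-outcome comparator calibration honours its constraints", {
  des <- calibrateDreamm2(12, 6, 0.2, 0.4)
  # interim: early stopping rate under pA at most 5%
  s1 <- 1 - pbeta(0.2, 0.2 + 0:6, 0.8 + 6 - 0:6)
  stop_rate <- sum(dbinom(0:6, 6, 0.4)[s1 < des$a1])
  expect_lte(stop_rate, 0.05)
  # FWER under the global null at most 10%, by exact enumeration
  oc <- exactOC(scenario(0.2, 0.2), des, refHyper())
  expect_lte(oc$p_event, 0.10 + 1e-12)
  # even with a zero stopping-rate target a cutoff exists (cutting at the
  # smallest attainable statistic stops nothing, since the rule is strict)
  des0 <- calibrateDreamm2(12, 6, 0.2, 0.4, stop_rate = 0)
  s1f <- 1 - pbeta(0.2, 0.2 + 0:6, 0.8 + 6 - 0:6)
  expect_equal(sum(dbinom(0:6, 6, 0.4)[s1f < des0$a1]), 0)
  # comparison boundary: Pr(p2 > p1) = c' exactly selects d2 (>=, not >)
  ps <- structure(list(pp_ni = 0.5, pr_greater = 0.6),
                  class = "posteriorSummary")
  expect_identical(finalDecision(c(TRUE, TRUE), ps, des)$decision,
                   "select_d2")
  # no inconclusive outcome exists under this rule
  tb <- decisionTable(des, refHyper())
  expect_false(any(tb$final_both$decision == "inconclusive"))
})
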