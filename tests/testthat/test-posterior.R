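test_that("probit transform round-trips and rejects invalid input", {
  expect_identical(probit(0.5), 0)
  expect_identical(probitInv(0), 0.5)
  expect_equal(probit(0.2), -0.8416, tolerance = 1e-4)
  for (p in c(0.01, 0.2, 0.5, 0.93))
    expect_equal(probitInv(probit(p)), p, tolerance = 1e-12)
  expect_error(probit(0), "strictly inside")
  expect_error(probit(1.2), "strictly inside")
})

test_that("with no data the posterior returns the prior", {
  # theta = probit(p0) makes the prior exceedance probability exactly 1/2
  # for dose 1, and 1/2 for dose 2 by symmetry of the borrowing kernel
  h <- refHyper()
  ps <- dlmPosterior(trialData(c(0, 0), c(0, 0)), h, p0 = 0.2,
                     delta1 = 0.05, check = FALSE)
  expect_equal(ps$pr_exceed, c(0.5, 0.5), tolerance = 2e-3)
})

test_that("tau -> 0 collapses the DLM to a pooled probit model", {
  h <- dlmHyper(probit(0.2), sigma1 = 3, tau = 1e-5)
  ps <- dlmPosterior(trialData(c(3, 7), c(10, 10)), h, p0 = 0.2,
                     delta1 = 0.05, check = FALSE)
  # pooled oracle: single mu with both binomial likelihoods attached
  mu <- seq(-12, 12, by = 0.002)
  w <- dnorm(mu, h$theta, h$sigma1) * dbinom(3, 10, pnorm(mu)) *
    dbinom(7, 10, pnorm(mu))
  pr <- sum(w[mu > qnorm(0.2)]) / sum(w)
  pm <- sum(w * pnorm(mu)) / sum(w)
  expect_equal(ps$pr_exceed[1], pr, tolerance = 2e-3)
  expect_equal(ps$pr_exceed[2], pr, tolerance = 2e-3)
  expect_equal(ps$post_mean, c(pm, pm), tolerance = 2e-3)
  expect_equal(ps$pp_ni, 1, tolerance = 1e-6)   # p2 - p1 collapses to 0
})

test_that("large tau and sigma1 approach independent single-dose models", {
  # With a half-Cauchy borrowing prior the approach to independence is
  # slow: consistent outcomes keep a small posterior weight on strong
  # borrowing, so the deviation at tau = 50 can reach ~0.02, shrinking as
  # tau grows.
  h50 <- dlmHyper(0, sigma1 = 50, tau = 50)
  ps50 <- dlmPosterior(trialData(c(4, 6), c(10, 10)), h50, p0 = 0.2,
                       delta1 = 0.05, check = FALSE)
  or1 <- probitOracle(4, 10, 0, 50, 0.2)
  or2 <- probitOracle(6, 10, 0, 50, 0.2)
  expect_equal(ps50$pr_exceed[1], unname(or1["pr"]), tolerance = 0.02)
  expect_equal(ps50$pr_exceed[2], unname(or2["pr"]), tolerance = 0.02)
  expect_equal(ps50$post_mean, unname(c(or1["pm"], or2["pm"])),
               tolerance = 0.05)
  h1k <- dlmHyper(0, sigma1 = 50, tau = 1000)
  ps1k <- dlmPosterior(trialData(c(4, 6), c(10, 10)), h1k, p0 = 0.2,
                       delta1 = 0.05, check = FALSE)
  expect_lt(abs(ps1k$pr_exceed[1] - or1["pr"]),
            abs(ps50$pr_exceed[1] - or1["pr"]))
})

test_that("quadrature matches a long MCMC run on the reference table", {
  h <- refHyper()
  d <- trialData(c(8, 8), c(10, 10))
  q <- dlmPosterior(d, h, p0 = 0.2, delta1 = 0.05)
  m <- dlmPosterior(d, h, p0 = 0.2, delta1 = 0.05, method = "mcmc",
                    iter = 2e6, seed = 7)
  expect_lt(abs(q$pr_exceed[1] - m$pr_exceed[1]), 3 * m$mcse[["pr1"]] + 1e-4)
  expect_lt(abs(q$pp_ni - m$pp_ni), 3 * m$mcse[["ppni"]] + 1e-4)
  expect_lt(abs(q$post_mean[2] - m$post_mean[2]), 3 * m$mcse[["pm2"]] + 1e-4)
})

test_that("exceedance probability is monotone in the responder count", {
  g <- todesign:::.dlmGrid(10, 10, refHyper(), 0.2, 0.05)
  # raising y1 (y2 fixed) never lowers Pr(p1 > p0); same for dose 2
  expect_true(all(diff(g$pr1) >= -1e-9))        # columnwise in y1
  expect_true(all(apply(g$pr2, 1, diff) >= -1e-9))
  # note: monotonicity in the *other* dose's count is not asserted: with a
  # hierarchical borrowing scale, discordant data legitimately weaken the
  # pooling and the cross effect need not be monotone
})

test_that("PP_NI is a CDF in delta1 and sums with its complement to one", {
  h <- refHyper()
  d <- trialData(c(4, 7), c(12, 12))
  pp <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4),
               function(dl) dlmPosterior(d, h, 0.2, dl, check = FALSE)$pp_ni,
               numeric(1))
  expect_true(all(diff(pp) >= 0))
  expect_true(all(pp >= 0 & pp <= 1))
})

test_that("refinement check reports the achieved tolerance", {
  ps <- dlmPosterior(trialData(c(5, 6), c(10, 10)), refHyper(), 0.2, 0.05,
                     check = TRUE)
  expect_lt(ps$tol, 1e-3)
})

test_that("beta-binomial posterior matches the conjugate closed form", {
  p0 <- 0.2
  ps <- bbPosterior(4, 10, p0)
  expect_equal(ps$shape1, p0 + 4)
  expect_equal(ps$shape2, 1 - p0 + 6)
  expect_equal(ps$pr_exceed, 1 - pbeta(p0, p0 + 4, 1 - p0 + 6),
               tolerance = 1e-15)
  # y = n: posterior mean (p0 + n)/(1 + n), strictly increasing in n
  pm <- vapply(1:8, function(n) bbPosterior(n, n, p0)$post_mean, numeric(1))
  expect_equal(pm, (p0 + 1:8) / (1 + 1:8), tolerance = 1e-12)
  expect_true(all(diff(pm) > 0))
})

test_that("beta-binomial between-dose probabilities match a sampling oracle", {
  set.seed(11)
  ps <- bbPosterior(c(4, 6), c(10, 10), p0 = 0.2, delta1 = 0.05)
  r1 <- rbeta(4e5, ps$shape1[1], ps$shape2[1])
  r2 <- rbeta(4e5, ps$shape1[2], ps$shape2[2])
  se <- 0.5 / sqrt(4e5)
  expect_lt(abs(ps$pp_ni - mean(r2 - r1 < 0.05)), 4 * se)
  expect_lt(abs(ps$pr_greater - mean(r2 > r1)), 4 * se)
})

test_that("prior effective sample size moment-matching is exact for the uniform", {
  # Phi(N(0,1)) is exactly Uniform(0,1) = Beta(1,1): PESS = 2
  pess <- priorPESS(dlmHyper(0, sigma1 = 1), dose = 1)
  expect_equal(as.numeric(pess), 2, tolerance = 1e-6)
  expect_equal(attr(pess, "mean"), 0.5, tolerance = 1e-6)
  # dose-2 marginal has heavier tails than dose 1: smaller PESS
  h <- refHyper()
  expect_lt(as.numeric(priorPESS(h, 2)), as.numeric(priorPESS(h, 1)))
  expect_lt(as.numeric(priorPESS(h, 2)), 1)
})
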