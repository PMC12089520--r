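test_that("built-in scenario sets carry the published rates", {
  s1 <- scenarioTable1()
  expect_length(s1, 9L)
  expect_equal(s1[[1]]$p, c(0.20, 0.20))      # global null
  expect_identical(s1[[1]]$role, "global_null")
  expect_equal(s1[[2]]$p, c(0.40, 0.40))
  expect_equal(s1[[9]]$p, c(0.60, 0.40))      # decreasing dose-efficacy
  s2 <- scenarioTable2()
  expect_length(s2, 15L)
  expect_equal(s2[[1]]$q, c(0.40, 0.40))
  expect_equal(s2[[14]]$p, c(0.50, 0.40))
  expect_error(scenarioSet("table9"), "unknown scenario set")
})

test_that("an empty scenario set yields an empty report", {
  rep <- runScenarios(smallDesign(), list(), refHyper())
  expect_s3_class(rep, "ocReport")
  expect_identical(nrow(rep), 0L)
})

test_that("scenario reports carry one row per design and scenario", {
  scns <- list(scenario(0.2, 0.2, label = "null"),
               scenario(0.4, 0.4, label = "alt"))
  rep <- runScenarios(list(A = smallDesign(), B = smallDesign("bb")),
                      scns, refHyper())
  expect_identical(nrow(rep), 4L)
  expect_true(all(c("sel_d1", "sir", "wl", "ass_d1", "fwer_omp") %in%
                    names(rep)))
  expect_true(all(rep$sel_d1 >= 0 & rep$sel_d1 <= 100))
  # decisions partition: selections + SIR + none = 100
  none <- 100 - rep$sel_d1 - rep$sel_d2 - rep$sir
  expect_true(all(none > -1e-9 & none <= 100))
})

test_that("the wl sweep closes the inconclusive gap as wl grows", {
  tg <- calibrationTargets(alpha2 = 0.5, alpha3 = 0.5,
                           c_grid = seq(0.1, 0.9, by = 0.1))
  sw <- wlSweep(smallDesign(), tg, refHyper(), wl_grid = c(0, 0.4, 1),
                scenarios = list(scenario(0.4, 0.45, label = "HAstar")))
  expect_identical(nrow(sw), 3L)
  gap <- sw$c2 - sw$c1
  expect_true(all(diff(gap) <= 1e-12))           # non-increasing in wl
  expect_identical(sw$c1[3], sw$c2[3])           # wl = 1: identical cutoffs
  expect_true(all(sw$wloss[1] <= sw$wloss))      # wl = 0 minimizes IDR only
  expect_true("sel_correct_HAstar" %in% names(sw))
})

test_that("single-dataset analysis applies the stage rules", {
  des <- smallDesign()
  res1 <- analyzeTrial(trialData(c(0, 0), c(5, 5), stage = 1), des,
                       refHyper())
  expect_identical(unname(res1$monitor), c("drop", "drop"))
  expect_null(res1$decision)
  res2 <- analyzeTrial(trialData(c(6, 7), c(10, 10), stage = 2), des,
                       refHyper())
  expect_identical(unname(res2$monitor), c("pass", "pass"))
  expect_s3_class(res2$decision, "trialDecision")
})

test_that("run configurations validate and round-trip with a manifest", {
  cfg_file <- file.path(withr::local_tempdir(), "run.yaml")
  writeLines(c("design:",
               "  p0: 0.2", "  pA: 0.4",
               "  delta1: 0.05", "  delta2: 0.2",
               "  alpha1: 0.1", "  beta1: 0.95",
               "execution:", "  backend: exact", "  seed: 11"),
             cfg_file)
  cfg <- readRunConfig(cfg_file)
  expect_s3_class(cfg, "runConfig")
  expect_identical(cfg$execution$seed, 11L)
  expect_identical(cfg$execution$backend, "exact")
  mpath <- file.path(dirname(cfg_file), "manifest.json")
  m1 <- writeManifest(cfg, mpath, seed = 11)
  m2 <- writeManifest(cfg, file.path(dirname(cfg_file), "m2.json"), seed = 11)
  expect_identical(m1$config_hash, m2$config_hash)   # reproducible hash
  expect_true(file.exists(mpath))
  # validation errors
  bad <- file.path(dirname(cfg_file), "bad.yaml")
  writeLines(c("design:", "  p0: 0.2", "  pA: 0.4"), bad)
  expect_error(readRunConfig(bad), "missing fields")
  writeLines(c("design:", "  p0: 0.2", "  pA: 0.4", "  delta1: 0.05",
               "  delta2: 0.2", "execution:", "  backend: magic"), bad)
  expect_error(readRunConfig(bad), "backend")
})
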