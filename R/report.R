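## Scenario fixtures, batch reports, the wl sensitivity sweep, single-trial
## analysis, and run configuration handling.

#' Built-in scenario sets
#'
#' `scenarioTable1()` returns the nine efficacy-only two-dose scenarios
#' (scenario 1.1 is the global null `(0.20, 0.20)`, 1.2 the global
#' alternative `(0.40, 0.40)`, and so on); `scenarioTable2()` the fifteen
#' joint toxicity-efficacy scenarios.
#'
#' @return A list of [scenario()] objects.
#' @examples
#' length(scenarioTable1())   # 9
#' @export
scenarioTable1 <- function() {
  tb <- utils::read.csv(system.file("extdata", "scenarios_table1.csv",
                                    package = "todesign"),
                        colClasses = c("character", "numeric", "numeric",
                                       "character"))
  lapply(seq_len(nrow(tb)), function(i)
    scenario(tb$p1[i], tb$p2[i], label = tb$label[i], role = tb$role[i]))
}

#' @rdname scenarioTable1
#' @export
scenarioTable2 <- function() {
  tb <- utils::read.csv(system.file("extdata", "scenarios_table2.csv",
                                    package = "todesign"),
                        colClasses = c("character", rep("numeric", 4)))
  lapply(seq_len(nrow(tb)), function(i)
    scenario(tb$p1[i], tb$p2[i], q1 = tb$q1[i], q2 = tb$q2[i],
             label = tb$label[i]))
}

#' Look up a built-in scenario set by name
#'
#' @param name `"table1"` or `"table2"`.
#' @return A list of [scenario()] objects.
#' @export
scenarioSet <- function(name) {
  switch(name,
         table1 = scenarioTable1(),
         table2 = scenarioTable2(),
         stop(sprintf("unknown scenario set '%s'", name)))
}

#' Operating-characteristic report across scenarios and designs
#'
#' One row per scenario and design, with the columns reported in design
#' comparisons: selection percentages, SIR, IDR, WL, ASS, Go percentages
#' and FWER/OMP.  Percentages are stored unrounded; rounding is left to
#' presentation.
#'
#' @param designs a named list of [designParams()] (or a single one).
#' @param scenarios a list of [scenario()] objects (possibly empty).
#' @param hyper a [dlmHyper()] shared by the `"dlm"` designs.
#' @param backend `"exact"` (enumeration) or `"mc"` (Monte Carlo).
#' @param reps,seed Monte Carlo replications and seed.
#' @param settings a [dlmSettings()].
#' @return A data frame of class `"ocReport"`.
#' @export
runScenarios <- function(designs, scenarios, hyper,
                         backend = c("exact", "mc"),
                         reps = 10000L, seed = 1L,
                         settings = dlmSettings()) {
  backend <- match.arg(backend)
  if (inherits(designs, "designParams")) designs <- list(design = designs)
  stopifnot(is.list(designs), length(names(designs)) == length(designs))
  rows <- list()
  for (dn in names(designs)) {
    des <- designs[[dn]]
    grids <- .designGrids(des, hyper, settings)
    for (scn in scenarios) {
      oc <- if (backend == "exact")
        exactOC(scn, des, hyper, settings, grids = grids)
      else
        simulateOC(scn, des, hyper, reps = reps, seed = seed,
                   settings = settings, grids = grids)
      m <- ocMetrics(oc)
      rows[[length(rows) + 1L]] <- data.frame(
        design = dn, scenario = scn$label %||% "",
        p1 = scn$p[1], p2 = scn$p[2], t(m), row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(design = character(0), scenario = character(0))
  class(out) <- c("ocReport", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sensitivity sweep over the inconclusive discount wl
#'
#' Re-runs the step-2 cutoff calibration for each value of `wl`, keeping
#' the step-1 design fixed, and reports the calibrated cutoffs together
#' with correct-selection percentages and weighted loss for the supplied
#' scenarios.
#'
#' @param design a step-1 calibrated [designParams()].
#' @param targets a [calibrationTargets()] (its `wl` is overridden).
#' @param hyper a [dlmHyper()].
#' @param wl_grid values of `wl` to sweep.
#' @param scenarios optional list of scenarios to evaluate under each
#'   calibrated design (exact backend).
#' @param settings a [dlmSettings()].
#' @return A data frame with one row per `wl` (cutoffs, SIR/MRID/IDR/WL
#'   at calibration), plus `sel_correct_<label>` and `wl_<label>` columns
#'   per scenario.
#' @export
wlSweep <- function(design, targets, hyper, wl_grid = seq(0, 1, by = 0.1),
                    scenarios = NULL, settings = dlmSettings()) {
  rows <- list()
  grids <- .designGrids(design, hyper, settings)
  for (w in wl_grid) {
    tg <- targets
    tg$wl <- w
    des <- design
    des$wl <- w
    des <- step2Search(des, tg, hyper, settings)
    if (inherits(des, "calibrationFailure")) {
      rows[[length(rows) + 1L]] <- data.frame(wl = w, c1 = NA, c2 = NA)
      next
    }
    s2 <- attr(des, "step2")
    row <- data.frame(wl = w, c1 = des$c1, c2 = des$c2,
                      sir = s2$sir, mrid = s2$mrid, idr = s2$idr,
                      wloss = s2$wl)
    for (scn in scenarios %||% list()) {
      oc <- exactOC(scn, des, hyper, settings, grids = grids)
      m <- ocMetrics(oc)
      opt <- classifyScenario(scn, des$p0, des$delta1, des$delta2)
      sel <- switch(opt, select_d1 = m[["sel_d1"]],
                    select_d2 = m[["sel_d2"]],
                    none = 100 - m[["fwer_omp"]], NA_real_)
      row[[paste0("sel_correct_", scn$label)]] <- sel
      row[[paste0("wl_", scn$label)]] <- m[["wl"]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze one observed trial dataset
#'
#' Computes the posterior summary for observed counts and applies the
#' design's monitoring and comparison rules at the appropriate stage.
#'
#' @param data a [trialData()]; its `stage` selects the interim
#'   (`a1`) or final (`a2`) monitoring cutoff.
#' @param design a [designParams()].
#' @param hyper a [dlmHyper()].
#' @param settings a [dlmSettings()].
#' @return A list with the `posterior`, per-dose `monitor` outcomes, and
#'   (at the final stage) the `decision`.
#' @export
analyzeTrial <- function(data, design, hyper, settings = dlmSettings()) {
  stopifnot(inherits(data, "trialData"))
  post <- if (design$model == "dlm")
    dlmPosterior(data, hyper, design$p0, design$delta1, settings,
                 check = FALSE)
  else
    bbPosterior(data$y, data$n, design$p0, design$delta1)
  ak <- if (data$stage >= 2L) design$a2 else design$a1
  mon <- monitorDose(post$pr_exceed, ak)
  out <- list(posterior = post, monitor = setNames(mon, c("d1", "d2")),
              stage = data$stage)
  if (data$stage >= 2L)
    out$decision <- finalDecision(mon == "pass", post, design)
  out
}

## ---- run configuration -----------------------------------------------------

.requiredConfig <- c("p0", "pA", "delta1", "delta2")

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON with a `design` block (rates, margins,
#' constraints, hyperparameters, optional grids), an optional `execution`
#' block (`backend`, `reps`, `seed`), and an optional `output` block.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A validated list of class `"runConfig"`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (is.null(cfg$design)) stop("config must contain a 'design' block")
  miss <- setdiff(.requiredConfig, names(cfg$design))
  if (length(miss))
    stop("config design block missing fields: ", paste(miss, collapse = ", "))
  d <- cfg$design
  stopifnot(d$p0 > 0, d$p0 < 1, d$pA > d$p0, d$pA < 1,
            d$delta1 > 0, d$delta2 > d$delta1)
  cfg$execution <- modifyList(list(backend = "exact", reps = 10000L,
                                   seed = 1L), cfg$execution %||% list())
  if (!cfg$execution$backend %in% c("exact", "mc"))
    stop("execution backend must be 'exact' or 'mc'")
  cfg$output <- modifyList(list(dir = ".", formats = "csv"),
                           cfg$output %||% list())
  class(cfg) <- "runConfig"
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration hash, seed and package version so that any
#' report can be reproduced exactly from its manifest.
#'
#' @param config a `"runConfig"` (or any list).
#' @param path output JSON path.
#' @param seed the seed used for the run.
#' @return Invisibly, the manifest list.
#' @export
writeManifest <- function(config, path, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   seed = seed,
                   package = "todesign",
                   version = as.character(utils::packageVersion("todesign")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(manifest)
}
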