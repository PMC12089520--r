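## Per-dose monitoring, the triple-outcome between-dose comparison, the
## combined four-way trial decision, and exhaustive decision tables.

.DECISIONS <- c("none", "select_d1", "select_d2", "inconclusive")

#' Design parameters of the two-stage two-dose trial
#'
#' @param n maximum per-dose sample size.
#' @param m1 stage-1 per-dose sample size (`m2 = n - m1`).
#' @param a1,a2 per-dose monitoring cutoffs for the interim and final
#'   analysis: dose j is dropped at analysis k iff
#'   `Pr(p_j > p0 | D_k) < a_k` (strict).
#' @param c1,c2 triple-outcome comparison cutoffs, `c1 <= c2`; `c1 == c2`
#'   collapses the rule to a conventional two-outcome comparison.
#' @param delta1,delta2 noninferiority and inferiority margins,
#'   `0 < delta1 < delta2`.
#' @param p0 historical control response rate.
#' @param pA promising response rate used in calibration.
#' @param wl discount weight of an inconclusive outcome in the weighted
#'   loss, in `[0, 1]`.
#' @param lambda regularization exponent linking the cutoffs,
#'   `a1 = a2 (m1/n)^lambda` (recorded for provenance; `a1` is stored
#'   explicitly).
#' @param model posterior model driving the monitoring and comparison:
#'   `"dlm"` (dynamic linear model) or `"bb"` (independent beta-binomial).
#' @param rule `"triple"` (default) or `"dreamm2"` (two-outcome comparison
#'   selecting d2 iff `Pr(p2 > p1 | D) >= cprime`).
#' @param cprime comparison cutoff of the `"dreamm2"` rule.
#' @return An object of class `"designParams"`.
#' @export
designParams <- function(n, m1, a1, a2, c1 = NA, c2 = NA,
                         delta1 = 0.05, delta2 = 0.2, p0, pA = NA,
                         wl = 0.40, lambda = NA,
                         model = c("dlm", "bb"), rule = c("triple", "dreamm2"),
                         cprime = 0.6) {
  model <- match.arg(model); rule <- match.arg(rule)
  stopifnot(n >= 2, m1 >= 1, m1 < n, a1 >= 0, a1 <= 1, a2 >= 0, a2 <= 1,
            delta1 > 0, delta2 > delta1, p0 > 0, p0 < 1, wl >= 0, wl <= 1)
  if (rule == "triple") {
    if (is.na(c1) || is.na(c2)) stop("triple-outcome rule requires c1 and c2")
    if (c1 > c2) stop("comparison cutoffs must satisfy c1 <= c2")
  }
  structure(list(n = as.integer(n), m1 = as.integer(m1),
                 m2 = as.integer(n - m1), a1 = a1, a2 = a2,
                 c1 = c1, c2 = c2, delta1 = delta1, delta2 = delta2,
                 p0 = p0, pA = pA, wl = wl, lambda = lambda,
                 model = model, rule = rule, cprime = cprime),
            class = "designParams")
}

#' @export
print.designParams <- function(x, ...) {
  cat(sprintf("Two-dose %s design (%s model): n = %d, m1 = %d\n",
              ifelse(x$rule == "triple", "triple-outcome", "two-outcome"),
              x$model, x$n, x$m1))
  cat(sprintf("  monitoring: drop if Pr(p > %.2f | D) < a_k; a1 = %.4f, a2 = %.4f\n",
              x$p0, x$a1, x$a2))
  if (x$rule == "triple")
    cat(sprintf("  comparison: c1 = %.3f, c2 = %.3f; margins delta1 = %.2f, delta2 = %.2f; wl = %.2f\n",
                x$c1, x$c2, x$delta1, x$delta2, x$wl))
  else
    cat(sprintf("  comparison: select d2 iff Pr(p2 > p1 | D) >= %.2f\n", x$cprime))
  invisible(x)
}

#' Per-dose futility monitoring rule
#'
#' A dose is dropped at analysis k iff its posterior exceedance
#' probability falls strictly below the cutoff: `pr_exceed < a_k`.
#'
#' @param pr_exceed posterior probability Pr(p_j > p0 | D_k).
#' @param a_k monitoring cutoff for the analysis.
#' @return `"pass"` or `"drop"` (vectorized over `pr_exceed`).
#' @examples
#' monitorDose(c(0, 0.1, 1), a_k = 0.1)   # drop, pass, pass
#' @export
monitorDose <- function(pr_exceed, a_k) {
  stopifnot(all(pr_exceed >= 0 & pr_exceed <= 1), a_k >= 0, a_k <= 1)
  ifelse(pr_exceed < a_k, "drop", "pass")
}

#' Triple-outcome between-dose comparison
#'
#' Applied when both doses pass the final monitoring: select the higher
#' dose d2 iff `pp_ni <= c1`, select the lower dose d1 iff `pp_ni > c2`,
#' otherwise the comparison is inconclusive.
#'
#' @param pp_ni posterior noninferiority probability
#'   Pr(p2 - p1 < delta1 | D).
#' @param c1,c2 comparison cutoffs with `c1 <= c2`.
#' @return One of `"select_d2"`, `"select_d1"`, `"inconclusive"`
#'   (vectorized over `pp_ni`).
#' @examples
#' tripleOutcome(c(0.3, 0.5, 0.9), c1 = 0.3, c2 = 0.8)
#' @export
tripleOutcome <- function(pp_ni, c1, c2) {
  if (c1 > c2) stop("comparison cutoffs must satisfy c1 <= c2")
  stopifnot(all(pp_ni >= 0 & pp_ni <= 1))
  ifelse(pp_ni <= c1, "select_d2",
         ifelse(pp_ni > c2, "select_d1", "inconclusive"))
}

#' Final four-way trial decision
#'
#' Combines the final per-dose monitoring flags with the between-dose
#' comparison: if both doses fail, no dose is selected; if exactly one
#' dose passes it is selected automatically; if both pass, the
#' triple-outcome comparison decides.  A dose dropped at the interim is
#' never re-admitted.
#'
#' @param pass_flags logical length-2 vector: does dose j pass the final
#'   monitoring (a dose dropped at interim is `FALSE`).
#' @param posterior a `"posteriorSummary"` (its `pp_ni` is used), or a
#'   bare numeric `pp_ni`.
#' @param design a [designParams()] object.
#' @return An object of class `"trialDecision"` with elements `decision`
#'   (one of `"none"`, `"select_d1"`, `"select_d2"`, `"inconclusive"`)
#'   and `pass_flags`.
#' @export
finalDecision <- function(pass_flags, posterior, design) {
  stopifnot(length(pass_flags) == 2L, is.logical(pass_flags))
  dec <- if (!any(pass_flags)) "none"
  else if (pass_flags[1] && !pass_flags[2]) "select_d1"
  else if (!pass_flags[1] && pass_flags[2]) "select_d2"
  else {
    pp <- if (inherits(posterior, "posteriorSummary")) posterior$pp_ni
          else as.numeric(posterior)
    if (design$rule == "dreamm2") {
      prgt <- if (inherits(posterior, "posteriorSummary")) posterior$pr_greater
              else as.numeric(posterior)
      if (prgt >= design$cprime) "select_d2" else "select_d1"
    } else tripleOutcome(pp, design$c1, design$c2)
  }
  structure(list(decision = dec, pass_flags = pass_flags),
            class = "trialDecision")
}

#' @export
print.trialDecision <- function(x, ...) {
  cat("Trial decision:", x$decision, "\n")
  invisible(x)
}

## ---- posterior grid dispatch ----------------------------------------------

# posterior summary tables over the full outcome grid for sizes (n1, n2),
# under the design's posterior model
.postGrid <- function(design, hyper, n1, n2, settings, diff = FALSE) {
  if (design$model == "dlm")
    .dlmGrid(n1, n2, hyper, design$p0, design$delta1, settings, diff = diff)
  else
    .bbGrid(n1, n2, design$p0, design$delta1)
}

# all four grids a two-stage trial can terminate with
.designGrids <- function(design, hyper, settings = dlmSettings(), diff = FALSE) {
  list(int = .postGrid(design, hyper, design$m1, design$m1, settings),
       fin = .postGrid(design, hyper, design$n, design$n, settings, diff = diff),
       d1only = .postGrid(design, hyper, design$n, design$m1, settings),
       d2only = .postGrid(design, hyper, design$m1, design$n, settings))
}

# decision label matrix (values 0:3 indexing .DECISIONS) over the final
# (n+1) x (n+1) outcome grid, assuming both doses passed the interim
.finalDecisionMatrix <- function(fin, design) {
  pass1 <- fin$pr1 >= design$a2
  pass2 <- fin$pr2 >= design$a2
  D <- matrix(0L, design$n + 1L, design$n + 1L)
  D[pass1 & !pass2] <- 1L
  D[!pass1 & pass2] <- 2L
  both <- pass1 & pass2
  if (design$rule == "dreamm2") {
    D[both] <- ifelse(fin$prgt[both] >= design$cprime, 2L, 1L)
  } else {
    D[both] <- ifelse(fin$ppni[both] <= design$c1, 2L,
                      ifelse(fin$ppni[both] > design$c2, 1L, 3L))
  }
  D
}

## ---- exhaustive decision tables -------------------------------------------

#' Exhaustive decision tables over all outcome combinations
#'
#' Enumerates every possible responder-count combination and applies the
#' model and decision rules, yielding the interim continue/drop table and
#' the final decision tables for each interim-survival configuration.
#' These tables can be generated before enrollment and used directly
#' during trial conduct.
#'
#' @param design a [designParams()] object (calibrated cutoffs included).
#' @param hyper a [dlmHyper()] object (ignored for the `"bb"` model).
#' @param settings a [dlmSettings()] object.
#' @return An object of class `"decisionTables"`: list of data frames
#'   `interim` (`y1`, `y2`, `d1`, `d2` continue flags), `final_both`,
#'   `final_d1only`, `final_d2only` (`y1`, `y2`, `decision`).
#' @export
decisionTable <- function(design, hyper = dlmHyper(probit(design$p0)),
                          settings = dlmSettings()) {
  g <- .designGrids(design, hyper, settings)
  m1 <- design$m1; n <- design$n
  yi <- expand.grid(y1 = 0:m1, y2 = 0:m1)
  interim <- data.frame(yi,
    d1 = ifelse(g$int$pr1[as.matrix(yi) + 1L] >= design$a1, "continue", "drop"),
    d2 = ifelse(g$int$pr2[as.matrix(yi) + 1L] >= design$a1, "continue", "drop"))
  D <- .finalDecisionMatrix(g$fin, design)
  yf <- expand.grid(y1 = 0:n, y2 = 0:n)
  final_both <- data.frame(yf, decision = .DECISIONS[D[as.matrix(yf) + 1L] + 1L])
  y1o <- expand.grid(y1 = 0:n, y2 = 0:m1)
  final_d1 <- data.frame(y1o, decision = ifelse(
    g$d1only$pr1[as.matrix(y1o) + 1L] >= design$a2, "select_d1", "none"))
  y2o <- expand.grid(y1 = 0:m1, y2 = 0:n)
  final_d2 <- data.frame(y2o, decision = ifelse(
    g$d2only$pr2[as.matrix(y2o) + 1L] >= design$a2, "select_d2", "none"))
  structure(list(interim = interim, final_both = final_both,
                 final_d1only = final_d1, final_d2only = final_d2,
                 design = design),
            class = "decisionTables")
}

#' @export
print.decisionTables <- function(x, ...) {
  cat(sprintf("Decision tables for n = %d, m1 = %d (%s model)\n",
              x$design$n, x$design$m1, x$design$model))
  cat("  interim continue (d1, d2):",
      sum(x$interim$d1 == "continue"), ",", sum(x$interim$d2 == "continue"),
      "of", nrow(x$interim), "cells\n")
  tb <- table(factor(x$final_both$decision, levels = .DECISIONS))
  cat("  final (both active):",
      paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Export decision tables as CSV files
#'
#' @param tables a [decisionTable()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeDecisionTables <- function(tables, dir) {
  stopifnot(inherits(tables, "decisionTables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("interim", "final_both", "final_d1only", "final_d2only")) {
    p <- file.path(dir, paste0("decision_", nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Plot a final-analysis decision table
#'
#' Color-coded map of the four-way decision over the final responder
#' counts, assuming both doses passed the interim monitoring.
#'
#' @param tables a [decisionTable()] result.
#' @param which which table to draw (`"final_both"`, `"interim"`).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plotDecisionTable <- function(tables, which = "final_both", ...) {
  stopifnot(inherits(tables, "decisionTables"))
  tb <- tables[[which]]
  if (which == "interim") {
    lv <- c("drop/drop", "continue/drop", "drop/continue", "continue/continue")
    z <- (tb$d1 == "continue") + 2L * (tb$d2 == "continue")
    cols <- c("grey70", "steelblue", "orange", "forestgreen")
  } else {
    lv <- .DECISIONS
    z <- match(tb$decision, .DECISIONS) - 1L
    cols <- c("grey70", "steelblue", "orange", "goldenrod1")
  }
  n1 <- max(tb$y1); n2 <- max(tb$y2)
  zm <- matrix(z, n1 + 1L, n2 + 1L)
  graphics::image(0:n1, 0:n2, zm, col = cols[sort(unique(z)) + 1L],
                  xlab = "responders at d1", ylab = "responders at d2",
                  main = sprintf("Decision table (%s)", which), ...)
  graphics::legend("topleft", legend = lv[sort(unique(z)) + 1L],
                   fill = cols[sort(unique(z)) + 1L], bg = "white", cex = 0.8)
  invisible(NULL)
}
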