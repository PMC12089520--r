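## Design performance summaries: FWER/OMP, per-dose monitoring power and
## its analytic bound, SIR, IDR, MRID, weighted loss, ASS, bias and MSE.

.checkFreq <- function(freq) {
  if (is.null(names(freq)) || !all(.DECISIONS %in% names(freq)))
    stop("decision frequencies must be named: ",
         paste(.DECISIONS, collapse = ", "))
  if (any(freq < 0) || abs(sum(freq[.DECISIONS]) - 1) > 1e-6)
    stop("decision frequencies must be non-negative and sum to 1")
  freq[.DECISIONS]
}

#' Incorrect decision rate (IDR)
#'
#' Average probability of a definitively wrong trial decision under the
#' two calibration alternatives: selecting the higher dose or no dose
#' when the lower dose is truly noninferior (HA*), and selecting the
#' lower dose or no dose when the higher dose is truly superior (HA+).
#' Inconclusive outcomes are not counted.
#'
#' @param freq_HAstar,freq_HAplus named decision-frequency vectors (names
#'   `none`, `select_d1`, `select_d2`, `inconclusive`) summing to 1.
#' @param weights weights of the two alternatives (default 0.5/0.5).
#' @return The incorrect decision rate, a probability.
#' @examples
#' idr(c(none = 0.1, select_d1 = 0.7, select_d2 = 0.2, inconclusive = 0),
#'     c(none = 0, select_d1 = 0.3, select_d2 = 0.7, inconclusive = 0))
#' @export
idr <- function(freq_HAstar, freq_HAplus, weights = c(0.5, 0.5)) {
  fs <- .checkFreq(freq_HAstar); fp <- .checkFreq(freq_HAplus)
  stopifnot(length(weights) == 2, all(weights >= 0))
  weights <- weights / sum(weights)
  unname(weights[1] * (fs["select_d2"] + fs["none"]) +
         weights[2] * (fp["select_d1"] + fp["none"]))
}

#' Maximum rate of selecting an inadequate dose (MRID)
#'
#' Probability of selecting the lower, truly inferior dose under HA+.
#'
#' @param freq_HAplus named decision-frequency vector under HA+.
#' @return A probability.
#' @export
mrid <- function(freq_HAplus) {
  unname(.checkFreq(freq_HAplus)["select_d1"])
}

#' Weighted loss
#'
#' `WL = IDR + wl * SIR`: the calibration objective, discounting the size
#' of the inconclusive region (SIR) relative to outright incorrect
#' decisions by the factor `wl`.
#'
#' @param idr incorrect decision rate.
#' @param sir size of the inconclusive region.
#' @param wl discount weight in `[0, 1]`.
#' @return The weighted loss, on the same scale as the inputs.
#' @examples
#' weightedLoss(26.8, 5.6, 0.40)   # percent scale
#' @export
weightedLoss <- function(idr, sir, wl) {
  stopifnot(wl >= 0, wl <= 1)
  idr + wl * sir
}

#' Analytic per-dose monitoring power bound
#'
#' When the two doses are monitored independently with identical
#' operating characteristics, an overall monitoring power OMP implies a
#' per-dose power of exactly `1 - sqrt(1 - OMP)`; information borrowing
#' across doses can only improve on this bound.
#'
#' @param omp overall monitoring power in `[0, 1]`.
#' @return The per-dose power bound.
#' @examples
#' powerBound(0.95)   # 0.776
#' @export
powerBound <- function(omp) {
  stopifnot(all(omp >= 0 & omp <= 1))
  1 - sqrt(1 - omp)
}

#' Average bias and MSE of the posterior-mean estimates
#'
#' Replication-wise estimation errors, averaged first over replications
#' and then over the two doses: the bias is the dose-averaged mean of
#' `(estimate - truth)`, the MSE the dose-averaged mean of
#' `(estimate - truth)^2`.
#'
#' @param estimates numeric matrix (replications x 2) of posterior-mean
#'   estimates, one column per dose.
#' @param truths length-2 vector of true response rates.
#' @return Named vector `c(avg_bias, avg_mse)`.
#' @export
biasMSE <- function(estimates, truths) {
  estimates <- as.matrix(estimates)
  stopifnot(ncol(estimates) == 2L, length(truths) == 2L)
  err <- sweep(estimates, 2L, truths)
  c(avg_bias = mean(colMeans(err)), avg_mse = mean(colMeans(err^2)))
}

#' Truth-level categorization of a scenario
#'
#' Classifies the true rates into the four-way optimal decision: the
#' lower dose is optimal when it is non-futile and noninferior (or the
#' higher dose is futile); the higher dose is optimal when it is
#' non-futile and substantially better (or the lower dose is futile); no
#' dose when both are futile; otherwise the truth lies in the
#' inconclusive band `p2 - p1 in (delta1, delta2)`.
#'
#' @param scn a [scenario()].
#' @param p0 historical control rate.
#' @param delta1,delta2 noninferiority and inferiority margins.
#' @return One of `"none"`, `"select_d1"`, `"select_d2"`,
#'   `"inconclusive"`.
#' @export
classifyScenario <- function(scn, p0, delta1, delta2) {
  eps <- 1e-9                       # guard exact-boundary rate differences
  p1 <- scn$p[1]; p2 <- scn$p[2]
  if (p1 > p0 && (p2 - p1 <= delta1 + eps || p2 <= p0)) return("select_d1")
  if (p2 > p0 && (p2 - p1 >= delta2 - eps || p1 <= p0)) return("select_d2")
  if (p1 <= p0 && p2 <= p0) return("none")
  "inconclusive"
}

#' Derived operating-characteristic summaries
#'
#' Turns the raw decision probabilities of [exactOC()] or [simulateOC()]
#' into the reported metrics: selection percentages, SIR, per-scenario
#' IDR (relative to the truth-level optimal decision), weighted loss,
#' Go percentages, FWER/OMP and ASS.
#'
#' @param oc a `"trialOC"` object.
#' @return Named numeric vector (percent scale for rates).
#' @export
ocMetrics <- function(oc) {
  stopifnot(inherits(oc, "trialOC"))
  d <- oc$design
  dp <- oc$decision_prob
  opt <- classifyScenario(oc$scenario, d$p0, d$delta1, d$delta2)
  sir <- dp[["inconclusive"]]
  idr_s <- switch(opt,
    none = dp[["select_d1"]] + dp[["select_d2"]] + dp[["inconclusive"]],
    select_d1 = dp[["select_d2"]] + dp[["none"]],
    select_d2 = dp[["select_d1"]] + dp[["none"]],
    inconclusive = dp[["none"]])
  c(sel_d1 = 100 * dp[["select_d1"]], sel_d2 = 100 * dp[["select_d2"]],
    sir = 100 * sir, idr = 100 * idr_s,
    wl = 100 * weightedLoss(idr_s, sir, d$wl),
    ass_d1 = oc$ass[1], ass_d2 = oc$ass[2],
    go_d1 = 100 * oc$go[1], go_d2 = 100 * oc$go[2],
    fwer_omp = 100 * oc$p_event,
    avg_bias = mean(oc$est_mean - oc$scenario$p),
    avg_mse = mean(oc$est_mse))
}
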