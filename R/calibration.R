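## Two-step grid-search calibration of (n, m1, a1, a2) and (c1, c2), plus
## comparator calibrations: the unoptimized two-outcome comparator and
## Simon's optimal two-stage design.

#' Calibration targets and search grids
#'
#' @param alpha1 family-wise type I error cap (FWER under the global
#'   null), e.g. 0.10.
#' @param beta1 target overall monitoring power (OMP under the global
#'   alternative), e.g. 0.95.
#' @param alpha2 cap on the maximum rate of selecting an inadequate dose
#'   (MRID under HA+).
#' @param alpha3 cap on the size of the inconclusive region (SIR averaged
#'   across HA* and HA+).
#' @param wl inconclusive discount in the weighted loss.
#' @param n_range candidate maximum per-dose sample sizes, searched in
#'   increasing order.
#' @param m1_grid candidate stage-1 sizes; `NULL` uses
#'   `ceiling(n/3):floor(2n/3)` for each `n`.
#' @param lambda_grid grid of regularization exponents in `a1 = a2
#'   (m1/n)^lambda`.
#' @param a2_grid grid of final monitoring cutoffs.
#' @param c_grid grid of comparison cutoffs (all pairs `c1 <= c2` are
#'   searched).
#' @return An object of class `"calibrationTargets"`.
#' @export
calibrationTargets <- function(alpha1 = 0.10, beta1 = 0.95,
                               alpha2 = 0.20, alpha3 = 0.15, wl = 0.40,
                               n_range = 15:40, m1_grid = NULL,
                               lambda_grid = seq(0.1, 1, by = 0.1),
                               a2_grid = seq(0.50, 0.99, by = 0.01),
                               c_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(alpha1 > 0, alpha1 <= 1, beta1 >= 0, beta1 <= 1,
            alpha2 >= 0, alpha2 <= 1, alpha3 >= 0, alpha3 <= 1,
            wl >= 0, wl <= 1, length(n_range) >= 1,
            length(lambda_grid) >= 1, length(a2_grid) >= 1,
            length(c_grid) >= 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 alpha3 = alpha3, wl = wl, n_range = sort(n_range),
                 m1_grid = m1_grid, lambda_grid = lambda_grid,
                 a2_grid = a2_grid, c_grid = sort(c_grid)),
            class = "calibrationTargets")
}

# monitoring-only exact OC for one (a1, a2): returns P(E), ASS1, ASS2.
# `pre` holds scenario-specific precomputations shared across cutoffs.
.monitorOC <- function(pre, a1, a2) {
  I1 <- pre$int1 >= a1
  I2 <- pre$int2 >= a1
  Sboth <- I1 & I2; S1 <- I1 & !I2; S2 <- !I1 & I2
  W <- pre$W
  pnone <- sum(W[!I1 & !I2])
  if (any(Sboth)) {
    Gff <- pre$Q1 %*% ((pre$fin1 < a2) * (pre$fin2 < a2)) %*% t(pre$Q2)
    pnone <- pnone + sum(W[Sboth] * Gff[Sboth])
  }
  if (any(S1)) {
    Gf <- pre$Q1 %*% (pre$d1o < a2)
    pnone <- pnone + sum(W[S1] * Gf[S1])
  }
  if (any(S2)) {
    Gf <- (pre$d2o < a2) %*% t(pre$Q2)
    pnone <- pnone + sum(W[S2] * Gf[S2])
  }
  c(pE = 1 - pnone,
    ass1 = pre$m1 + pre$m2 * sum(W[I1]),
    ass2 = pre$m1 + pre$m2 * sum(W[I2]))
}

.monitorPre <- function(grids, design, p) {
  m1 <- design$m1; m2 <- design$m2
  list(m1 = m1, m2 = m2,
       W = outer(dbinom(0:m1, m1, p[1]), dbinom(0:m1, m1, p[2])),
       Q1 = .shiftBinom(m1, m2, p[1]), Q2 = .shiftBinom(m1, m2, p[2]),
       int1 = grids$int$pr1, int2 = grids$int$pr2,
       fin1 = grids$fin$pr1, fin2 = grids$fin$pr2,
       d1o = grids$d1only$pr1, d2o = grids$d2only$pr2)
}

#' Step 1: calibrate (n, m1, a1, a2)
#'
#' For each candidate `n` (in increasing order) and every grid point
#' `(m1, lambda, a2)` with `a1 = a2 (m1/n)^lambda`, computes the exact
#' FWER under the global null `(p0, p0)`, the OMP under the global
#' alternative `(pA, pA)`, and the global-null average sample size.
#' Among FWER-admissible combinations whose OMP is within one percentage
#' point of the maximum admissible OMP, the one minimizing the
#' global-null ASS is retained (ties: higher OMP, then smaller m1, then
#' smaller a2, then smaller lambda).  The search returns the smallest `n`
#' whose optimum attains `OMP >= beta1`.
#'
#' @param targets a [calibrationTargets()].
#' @param p0,pA null and promising response rates.
#' @param hyper a [dlmHyper()].
#' @param model `"dlm"` or `"bb"`.
#' @param delta1,delta2 margins recorded into the returned design.
#' @param settings a [dlmSettings()].
#' @param verbose print per-n progress.
#' @return A [designParams()] with calibrated `n, m1, a1, a2, lambda`
#'   (comparison cutoffs not yet set), with the search trace in
#'   `attr(, "trace")`.  If no `n` in range attains `beta1`, an object of
#'   class `"calibrationFailure"` reporting the best achieved OMP.
#' @export
step1Search <- function(targets, p0, pA, hyper, model = "dlm",
                        delta1 = 0.05, delta2 = 0.2,
                        settings = dlmSettings(), verbose = FALSE) {
  stopifnot(inherits(targets, "calibrationTargets"))
  trace <- list()
  best_overall <- NULL
  for (n in targets$n_range) {
    m1s <- if (is.null(targets$m1_grid))
      seq.int(ceiling(n / 3), floor(2 * n / 3)) else
      targets$m1_grid[targets$m1_grid < n]
    best <- NULL
    for (m1 in m1s) {
      des <- designParams(n, m1, 0, 0, 0, 1, delta1, delta2, p0, pA,
                          targets$wl, model = model)
      grids <- .designGrids(des, hyper, settings)
      pre0 <- .monitorPre(grids, des, c(p0, p0))
      preA <- .monitorPre(grids, des, c(pA, pA))
      for (lam in targets$lambda_grid) for (a2 in targets$a2_grid) {
        a1 <- a2 * (m1 / n)^lam
        oc0 <- .monitorOC(pre0, a1, a2)
        if (oc0["pE"] > targets$alpha1 + 1e-12) next
        ocA <- .monitorOC(preA, a1, a2)
        cand <- list(n = n, m1 = m1, lambda = lam, a1 = a1, a2 = a2,
                     fwer = unname(oc0["pE"]), omp = unname(ocA["pE"]),
                     ass_null = unname(oc0["ass1"] + oc0["ass2"]) / 2)
        best[[length(best) + 1L]] <- cand
      }
    }
    if (length(best) == 0L) next
    tb <- do.call(rbind, lapply(best, as.data.frame))
    omp_max <- max(tb$omp)
    adm <- tb[tb$omp >= omp_max - 0.01, ]
    adm <- adm[order(adm$ass_null, -adm$omp, adm$m1, adm$a2, adm$lambda), ]
    opt <- adm[1L, ]
    trace[[length(trace) + 1L]] <- cbind(opt, omp_max = omp_max)
    if (verbose)
      message(sprintf("n = %d: best OMP %.3f (max %.3f), FWER %.3f, ASS %.1f",
                      n, opt$omp, omp_max, opt$fwer, opt$ass_null))
    if (is.null(best_overall) || opt$omp > best_overall$omp)
      best_overall <- opt
    if (opt$omp >= targets$beta1) {
      des <- designParams(opt$n, opt$m1, opt$a1, opt$a2, 0, 1,
                          delta1, delta2, p0, pA, targets$wl,
                          lambda = opt$lambda, model = model)
      attr(des, "trace") <- do.call(rbind, trace)
      attr(des, "step1") <- opt
      return(des)
    }
  }
  structure(list(feasible = FALSE,
                 message = sprintf(
                   "no n in [%d, %d] attains OMP >= %.3f; best achieved %.3f (n = %d)",
                   min(targets$n_range), max(targets$n_range), targets$beta1,
                   if (is.null(best_overall)) NA else best_overall$omp,
                   if (is.null(best_overall)) NA else best_overall$n),
                 best = best_overall, trace = do.call(rbind, trace)),
            class = "calibrationFailure")
}

#' @export
print.calibrationFailure <- function(x, ...) {
  cat("Calibration infeasible:", x$message, "\n")
  invisible(x)
}

# terminal distribution needed by step 2 under one scenario: decision
# masses that do not depend on (c1, c2), plus the probability mass
# attached to each attainable PP value on the final both-active grid
.step2Dist <- function(design, grids, p) {
  m1 <- design$m1; m2 <- design$m2
  W <- outer(dbinom(0:m1, m1, p[1]), dbinom(0:m1, m1, p[2]))
  Q1 <- .shiftBinom(m1, m2, p[1]); Q2 <- .shiftBinom(m1, m2, p[2])
  I1 <- grids$int$pr1 >= design$a1
  I2 <- grids$int$pr2 >= design$a1
  Sboth <- I1 & I2; S1 <- I1 & !I2; S2 <- !I1 & I2
  f1 <- grids$fin$pr1 >= design$a2
  f2 <- grids$fin$pr2 >= design$a2

  d1_forced <- 0; d2_forced <- 0
  if (any(S1)) {
    G <- Q1 %*% (grids$d1only$pr1 >= design$a2)
    d1_forced <- d1_forced + sum(W[S1] * G[S1])
  }
  if (any(S2)) {
    G <- (grids$d2only$pr2 >= design$a2) %*% t(Q2)
    d2_forced <- d2_forced + sum(W[S2] * G[S2])
  }
  ppmass <- numeric(0); ppval <- numeric(0)
  if (any(Sboth)) {
    G <- Q1 %*% (f1 & !f2) %*% t(Q2)
    d1_forced <- d1_forced + sum(W[Sboth] * G[Sboth])
    G <- Q1 %*% (!f1 & f2) %*% t(Q2)
    d2_forced <- d2_forced + sum(W[Sboth] * G[Sboth])
    WS <- W; WS[!Sboth] <- 0
    Mfin <- t(Q1) %*% WS %*% Q2          # mass reaching each final cell
    keep <- f1 & f2
    ppmass <- Mfin[keep]; ppval <- grids$fin$ppni[keep]
  }
  pnone <- 1 - d1_forced - d2_forced - sum(ppmass)
  list(d1_forced = d1_forced, d2_forced = d2_forced, pnone = pnone,
       ppval = ppval, ppmass = ppmass)
}

.step2Eval <- function(dist, c1, c2) {
  p_d2 <- dist$d2_forced + sum(dist$ppmass[dist$ppval <= c1])
  p_d1 <- dist$d1_forced + sum(dist$ppmass[dist$ppval > c2])
  sir <- sum(dist$ppmass[dist$ppval > c1 & dist$ppval <= c2])
  c(none = dist$pnone, select_d1 = p_d1, select_d2 = p_d2,
    inconclusive = sir)
}

#' Step 2: calibrate the comparison cutoffs (c1, c2)
#'
#' Given the step-1 design, grid-searches all pairs `c1 <= c2` and
#' returns the pair minimizing the weighted loss `WL = IDR + wl * SIR`
#' under the hard constraints `MRID <= alpha2` (under HA+) and
#' `SIR <= alpha3` (averaged across HA* and HA+), where
#' `HA* = (pA, pA + delta1)` and `HA+ = (pA, pA + delta2)`.
#'
#' @param design a step-1 calibrated [designParams()].
#' @param targets a [calibrationTargets()].
#' @param hyper a [dlmHyper()].
#' @param settings a [dlmSettings()].
#' @return The design with `c1`, `c2` filled in and the feasible-search
#'   trace in `attr(, "step2")`.  If no pair is feasible, a
#'   `"calibrationFailure"` listing the minimum achievable MRID and SIR.
#' @export
step2Search <- function(design, targets, hyper, settings = dlmSettings()) {
  stopifnot(inherits(design, "designParams"),
            inherits(targets, "calibrationTargets"))
  pA <- design$pA
  grids <- .designGrids(design, hyper, settings)
  dist_star <- .step2Dist(design, grids, c(pA, pA + design$delta1))
  dist_plus <- .step2Dist(design, grids, c(pA, pA + design$delta2))
  cg <- targets$c_grid
  rows <- list()
  for (i in seq_along(cg)) for (j in i:length(cg)) {
    c1 <- cg[i]; c2 <- cg[j]
    fs <- .step2Eval(dist_star, c1, c2)
    fp <- .step2Eval(dist_plus, c1, c2)
    sir <- (fs[["inconclusive"]] + fp[["inconclusive"]]) / 2
    mrid_v <- fp[["select_d1"]]
    idr_v <- 0.5 * (fs[["select_d2"]] + fs[["none"]]) +
             0.5 * (fp[["select_d1"]] + fp[["none"]])
    rows[[length(rows) + 1L]] <- data.frame(
      c1 = c1, c2 = c2, sir = sir, mrid = mrid_v, idr = idr_v,
      wl = idr_v + targets$wl * sir,
      feasible = mrid_v <= targets$alpha2 + 1e-12 &
                 sir <= targets$alpha3 + 1e-12)
  }
  tb <- do.call(rbind, rows)
  feas <- tb[tb$feasible, ]
  if (nrow(feas) == 0L) {
    return(structure(list(feasible = FALSE,
                          message = sprintf(
                            "no (c1, c2) pair meets MRID <= %.2f and SIR <= %.2f; min MRID %.3f, min SIR %.3f",
                            targets$alpha2, targets$alpha3,
                            min(tb$mrid), min(tb$sir)),
                          trace = tb),
                     class = "calibrationFailure"))
  }
  feas <- feas[order(feas$wl, feas$sir, feas$c2 - feas$c1, feas$c1), ]
  opt <- feas[1L, ]
  design$c1 <- opt$c1; design$c2 <- opt$c2
  attr(design, "step2") <- opt
  attr(design, "step2_trace") <- tb
  design
}

#' Full two-step design calibration
#'
#' Runs [step1Search()] then [step2Search()] and returns the fully
#' calibrated design.
#'
#' @inheritParams step1Search
#' @param targets a [calibrationTargets()].
#' @return A calibrated [designParams()] (or a `"calibrationFailure"`).
#' @examples
#' \donttest{
#' tg <- calibrationTargets(n_range = 15:35)
#' des <- calibrateDesign(tg, p0 = 0.2, pA = 0.4, hyper = dlmHyper(probit(0.2)))
#' }
#' @export
calibrateDesign <- function(targets, p0, pA, hyper, model = "dlm",
                            delta1 = 0.05, delta2 = 0.2,
                            settings = dlmSettings(), verbose = FALSE) {
  d1 <- step1Search(targets, p0, pA, hyper, model, delta1, delta2,
                    settings, verbose)
  if (inherits(d1, "calibrationFailure")) return(d1)
  step2Search(d1, targets, hyper, settings)
}

## ---- comparator calibrations ----------------------------------------------

#' Calibrate the unoptimized two-outcome comparator design
#'
#' Beta-binomial design with heuristically chosen cutoffs: the interim
#' futility cutoff is the largest value keeping the per-dose early
#' stopping rate under the promising rate `pA` at or below `stop_rate`;
#' the final futility cutoff is the largest value keeping the FWER under
#' the global null at or below `alpha1`.  The dose comparison selects the
#' higher dose iff `Pr(p2 > p1 | D) >= cprime` (no inconclusive
#' outcome).
#'
#' @param n,m1 maximum and stage-1 per-dose sample sizes.
#' @param p0,pA null and promising response rates.
#' @param alpha1 FWER cap (default 0.10).
#' @param stop_rate target interim early-stopping rate under `pA`
#'   (default 0.05).
#' @param cprime comparison cutoff (default 0.6).
#' @param delta1,delta2 margins recorded into the design (used only for
#'   truth-level classification in reports).
#' @return A [designParams()] with `model = "bb"`, `rule = "dreamm2"`.
#' @export
calibrateDreamm2 <- function(n, m1, p0, pA, alpha1 = 0.10,
                             stop_rate = 0.05, cprime = 0.6,
                             delta1 = 0.05, delta2 = 0.2) {
  m2 <- n - m1
  s1 <- 1 - pbeta(p0, p0 + 0:m1, 1 - p0 + m1 - 0:m1)   # interim statistic
  w <- dbinom(0:m1, m1, pA)
  cand <- sort(unique(c(0, s1)))
  a1 <- 0
  for (v in cand) {
    if (sum(w[s1 < v]) <= stop_rate + 1e-12) a1 <- v else break
  }
  # final cutoff: FWER decreases as the cutoff rises, so controlling the
  # FWER at alpha1 means the smallest (least conservative) feasible cutoff
  s2 <- 1 - pbeta(p0, p0 + 0:n, 1 - p0 + n - 0:n)
  w0 <- dbinom(0:m1, m1, p0)
  wz <- dbinom(0:m2, m2, p0)
  gpass <- function(a2) {        # per-dose P(pass both stages | p0)
    sum(vapply(which(s1 >= a1), function(i)
      w0[i] * sum(wz[s2[(i - 1L) + 0:m2 + 1L] >= a2]), numeric(1)))
  }
  cand2 <- sort(unique(c(0, s2)))
  feas <- vapply(cand2, function(v) 1 - (1 - gpass(v))^2 <= alpha1 + 1e-12,
                 logical(1))
  a2 <- if (any(feas)) min(cand2[feas]) else 1
  designParams(n, m1, a1, a2, delta1 = delta1, delta2 = delta2,
               p0 = p0, pA = pA, model = "bb", rule = "dreamm2",
               cprime = cprime)
}

#' Simon's optimal two-stage design
#'
#' Exhaustive exact-binomial search for the two-stage single-arm design
#' `(r1/n1, r/n)` minimizing the expected sample size under the null
#' while meeting the type I error and power constraints.  Stage 1 stops
#' for futility if `y1 <= r1`; the treatment is declared promising at the
#' end iff `y1 + y2 > r`.
#'
#' @param p0 null response rate.
#' @param pA alternative response rate (`pA > p0`).
#' @param alpha maximum type I error rate.
#' @param power minimum power at `pA`.
#' @param nmax largest total sample size searched.
#' @return List with `r1`, `n1`, `r`, `n`, `EN0` (expected size under
#'   the null), `PET0` (early-termination probability), and the attained
#'   `alpha`/`power`, of class `"simonDesign"`.
#' @examples
#' \donttest{simonTwoStage(0.2, 0.4, alpha = 0.0519, power = 0.87)}
#' @export
simonTwoStage <- function(p0, pA, alpha, power, nmax = 100L) {
  stopifnot(p0 > 0, p0 < pA, pA < 1, alpha > 0, power > 0, power < 1)
  best <- NULL
  for (n in 2:nmax) {
    for (n1 in 1:(n - 1)) {
      n2 <- n - n1
      d1_0 <- dbinom(0:n1, n1, p0); d1_A <- dbinom(0:n1, n1, pA)
      # upper tail beyond r - x for stage 2, as a function of r
      for (r1 in 0:(n1 - 1)) {
        pet0 <- pbinom(r1, n1, p0)
        en0 <- n1 + (1 - pet0) * n2
        if (!is.null(best) && en0 >= best$EN0) next   # cannot improve
        xs <- (r1 + 1):n1
        # find smallest r with type I error <= alpha
        for (r in r1:n) {
          a <- sum(d1_0[xs + 1L] * (1 - pbinom(r - xs, n2, p0)))
          if (a <= alpha) {
            pw <- sum(d1_A[xs + 1L] * (1 - pbinom(r - xs, n2, pA)))
            if (pw >= power)
              best <- list(r1 = r1, n1 = n1, r = r, n = n, EN0 = en0,
                           PET0 = pet0, alpha = a, power = pw)
            break
          }
        }
      }
    }
  }
  if (is.null(best))
    stop(sprintf("no feasible Simon design with n <= %d", nmax))
  structure(best, class = "simonDesign")
}

#' @export
print.simonDesign <- function(x, ...) {
  cat(sprintf("Simon optimal two-stage design: r1/n1 = %d/%d, r/n = %d/%d\n",
              x$r1, x$n1, x$r, x$n))
  cat(sprintf("  EN(p0) = %.2f, PET(p0) = %.3f, alpha = %.4f, power = %.4f\n",
              x$EN0, x$PET0, x$alpha, x$power))
  invisible(x)
}
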