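## Utility-based joint toxicity-efficacy extension: monitoring on both
## endpoints, comparison on the risk-benefit utility u_j = p_j - rho q_j,
## and the corresponding calibration.
##
## Toxicity is modeled by an independent DLM of the same form as the
## efficacy model (with the toxicity limit q0 playing the anchor role);
## within a patient, efficacy and toxicity outcomes are independent.
## Because of that independence, the exact operating characteristics
## factor into efficacy-side and toxicity-side terms once the interim
## continuation pattern is fixed, which is how `exactJointOC()` avoids
## enumerating the full four-dimensional outcome space.

#' Risk-benefit utility score
#'
#' `u = p - rho * q`: response rate discounted by `rho` per unit of
#' toxicity rate.
#'
#' @param p response probability (or rate).
#' @param q toxicity probability.
#' @param rho toxicity penalty weight (> 0).
#' @return The utility, vectorized.
#' @examples
#' utilityScore(0.20, 0.40, 0.67)   # -0.07
#' @export
utilityScore <- function(p, q, rho) {
  stopifnot(all(p >= 0 & p <= 1), all(q >= 0 & q <= 1), rho >= 0)
  p - rho * q
}

#' Parameters of the utility extension
#'
#' @param rho toxicity penalty weight (> 0).
#' @param q0 toxicity upper limit (monitoring threshold).
#' @param qA acceptable toxicity rate used in calibration
#'   (`0 < qA < q0 < 1`).
#' @return An object of class `"utilityParams"`.
#' @export
utilityParams <- function(rho, q0, qA) {
  stopifnot(rho >= 0, qA > 0, qA < q0, q0 < 1)
  structure(list(rho = rho, q0 = q0, qA = qA), class = "utilityParams")
}

#' Joint admissibility monitoring
#'
#' A dose is dropped at analysis k if it is either overly toxic or
#' futile: `Pr(q_j < q0 | D_k) < a_k` or `Pr(p_j > p0 | D_k) < a_k`.
#'
#' @param pr_safe posterior probability Pr(q_j < q0 | D_k).
#' @param pr_effective posterior probability Pr(p_j > p0 | D_k).
#' @param a_k monitoring cutoff.
#' @return `"pass"` or `"drop"` (vectorized).
#' @examples
#' jointMonitor(1.0, 0.0, 0.1)   # futile though safe: drop
#' @export
jointMonitor <- function(pr_safe, pr_effective, a_k) {
  stopifnot(all(pr_safe >= 0 & pr_safe <= 1),
            all(pr_effective >= 0 & pr_effective <= 1))
  ifelse(pr_safe < a_k | pr_effective < a_k, "drop", "pass")
}

#' Joint design for utility-based dose optimization
#'
#' Bundles the efficacy design (margins interpreted on the utility
#' scale), the utility parameters, and the two DLM hyperparameter sets.
#'
#' @param design a [designParams()] (model `"dlm"`).
#' @param up a [utilityParams()].
#' @param hyper_eff efficacy [dlmHyper()]; default anchors at
#'   `probit(p0)`.
#' @param hyper_tox toxicity [dlmHyper()]; default anchors at
#'   `probit(q0)`, following the same construction rule as the efficacy
#'   model.
#' @return An object of class `"jointDesign"`.
#' @export
jointDesign <- function(design, up,
                        hyper_eff = dlmHyper(probit(design$p0)),
                        hyper_tox = dlmHyper(probit(up$q0))) {
  stopifnot(inherits(design, "designParams"), inherits(up, "utilityParams"))
  structure(list(design = design, up = up,
                 hyper_eff = hyper_eff, hyper_tox = hyper_tox),
            class = "jointDesign")
}

#' @export
print.jointDesign <- function(x, ...) {
  print(x$design)
  cat(sprintf("  utility: u = p - %.2f q; toxicity limit q0 = %.2f, qA = %.2f\n",
              x$up$rho, x$up$q0, x$up$qA))
  invisible(x)
}

## ---- posterior probability on the utility scale ---------------------------

# F_{De}(x) with De = p2 - p1 from a binned pmf matrix (cells x bins)
.diffCDF <- function(pmf, breaks, x) {
  nb <- ncol(pmf)
  C <- cbind(0, t(apply(pmf, 1L, cumsum)))
  i <- pmin(pmax(findInterval(x, breaks), 1L), nb)
  frac <- (x - breaks[i]) / (breaks[i + 1L] - breaks[i])
  frac <- pmin(pmax(frac, 0), 1)
  out <- C[, i, drop = FALSE] +
    pmf[, i, drop = FALSE] * rep(frac, each = nrow(pmf))
  out[, x <= breaks[1L]] <- 0
  out[, x >= breaks[nb + 1L]] <- 1
  out
}

# PP matrix Pr(u2 - u1 < delta1) over (efficacy cell) x (toxicity cell);
# rho = 0 reduces exactly to the efficacy-only PP_NI
.ppuMatrix <- function(effFin, toxFin, delta1, rho) {
  ppe <- as.vector(t(effFin$ppni))
  if (rho == 0)
    return(matrix(ppe, length(ppe), (toxFin$n1 + 1L) * (toxFin$n2 + 1L)))
  mt <- (toxFin$dgrid[-1L] + toxFin$dgrid[-length(toxFin$dgrid)]) / 2
  A <- .diffCDF(effFin$dpmf, effFin$dgrid, delta1 + rho * mt)
  A %*% t(toxFin$dpmf)
}

#' Posterior probability of utility noninferiority
#'
#' `PP = Pr(u2 - u1 < delta1 | D)` with `u_j = p_j - rho q_j`, the
#' efficacy and toxicity posteriors being independent DLMs.  With
#' `rho = 0` this reduces exactly to the efficacy-only noninferiority
#' probability.
#'
#' @param eff_data,tox_data [trialData()] objects with the efficacy and
#'   toxicity counts (`tox_data$y` holds toxicity events).
#' @param hyper_eff,hyper_tox [dlmHyper()] objects.
#' @param delta1 noninferiority margin on the utility scale.
#' @param rho toxicity penalty weight.
#' @param p0,q0 response threshold and toxicity limit (anchor rates).
#' @param settings a [dlmSettings()].
#' @return The posterior probability, a single number.
#' @export
ppUtilityNI <- function(eff_data, tox_data, hyper_eff, hyper_tox,
                        delta1, rho, p0 = 0.2, q0 = 0.4,
                        settings = dlmSettings()) {
  stopifnot(inherits(eff_data, "trialData"), inherits(tox_data, "trialData"))
  ge <- .dlmGrid(eff_data$n[1], eff_data$n[2], hyper_eff, p0, delta1,
                 settings, diff = rho > 0)
  if (rho == 0)
    return(ge$ppni[eff_data$y[1] + 1L, eff_data$y[2] + 1L])
  gt <- .dlmGrid(tox_data$n[1], tox_data$n[2], hyper_tox, q0, delta1,
                 settings, diff = TRUE)
  ce <- eff_data$y[1] * (eff_data$n[2] + 1L) + eff_data$y[2] + 1L
  ct <- tox_data$y[1] * (tox_data$n[2] + 1L) + tox_data$y[2] + 1L
  mt <- (gt$dgrid[-1L] + gt$dgrid[-length(gt$dgrid)]) / 2
  A <- .diffCDF(ge$dpmf[ce, , drop = FALSE], ge$dgrid, delta1 + rho * mt)
  drop(A %*% gt$dpmf[ct, ])
}

## ---- exact joint operating characteristics --------------------------------

# grids for both endpoint models; the toxicity grids use q0 as threshold
.jointGrids <- function(jdes, settings = dlmSettings(), diff = TRUE) {
  d <- jdes$design
  dtox <- d; dtox$p0 <- jdes$up$q0
  list(eff = .designGrids(d, jdes$hyper_eff, settings, diff = diff),
       tox = .designGrids(dtox, jdes$hyper_tox, settings, diff = diff))
}

# per-endpoint path statistics; `safe = TRUE` flips the exceedance
# probabilities into safety probabilities Pr(q < q0) = 1 - Pr(q > q0).
# Pattern/flag encoding: integer 0..3 = 2*dose1 + dose2.
.sideStats <- function(grids, m1, m2, rates, a1, a2, safe = FALSE) {
  tr <- function(x) if (safe) 1 - x else x
  n <- m1 + m2
  W <- outer(dbinom(0:m1, m1, rates[1]), dbinom(0:m1, m1, rates[2]))
  Q1 <- .shiftBinom(m1, m2, rates[1]); Q2 <- .shiftBinom(m1, m2, rates[2])
  I1 <- tr(grids$int$pr1) >= a1
  I2 <- tr(grids$int$pr2) >= a1
  pat <- 2L * I1 + I2
  M <- vapply(0:3, function(k) sum(W[pat == k]), numeric(1))

  # config "dose 1 only": P(pattern A and dose-1 final pass at (n, m1))
  H1 <- Q1 %*% (tr(grids$d1only$pr1) >= a2)
  h1 <- c(A2 = sum(W[pat == 2L] * H1[pat == 2L]),
          A3 = sum(W[pat == 3L] * H1[pat == 3L]))
  H2 <- (tr(grids$d2only$pr2) >= a2) %*% t(Q2)
  h2 <- c(A1 = sum(W[pat == 1L] * H2[pat == 1L]),
          A3 = sum(W[pat == 3L] * H2[pat == 3L]))

  # config "both": mass reaching each final cell, with both interim pass
  WS <- W; WS[pat != 3L] <- 0
  Mfin <- t(Q1) %*% WS %*% Q2
  f1 <- tr(grids$fin$pr1) >= a2
  f2 <- tr(grids$fin$pr2) >= a2
  fpat <- 2L * f1 + f2
  T11 <- vapply(0:3, function(k) sum(Mfin[fpat == k]), numeric(1))
  list(M = M, h1 = h1, h2 = h2, T11 = T11,
       Mfin = Mfin, fboth = f1 & f2,
       pI1 = M[3] + M[4], pI2 = M[2] + M[4])   # M is 0-indexed by +1
}

# combine the two endpoint sides into exact joint decision probabilities;
# monitor_only skips the comparison split (both-final-pass mass is then
# booked under select_d1 — any non-none label gives the same P(E)/ASS)
.jointAssemble <- function(se, st, ppu, c1, c2, monitor_only = FALSE) {
  pnone <- 0; p_d1 <- 0; p_d2 <- 0; go1 <- 0; go2 <- 0
  for (Ae in 0:3) for (At in 0:3) {
    C <- bitwAnd(Ae, At)
    mm <- se$M[Ae + 1L] * st$M[At + 1L]
    if (mm == 0 && C != 3L) next
    if (C == 0L) { pnone <- pnone + mm; next }
    if (C == 2L) {                       # only dose 1 continues
      he <- se$h1[[if (Ae == 3L) "A3" else "A2"]]
      ht <- st$h1[[if (At == 3L) "A3" else "A2"]]
      p_d1 <- p_d1 + he * ht
      go1 <- go1 + he * ht
      pnone <- pnone + mm - he * ht
    } else if (C == 1L) {                # only dose 2 continues
      he <- se$h2[[if (Ae == 3L) "A3" else "A1"]]
      ht <- st$h2[[if (At == 3L) "A3" else "A1"]]
      p_d2 <- p_d2 + he * ht
      go2 <- go2 + he * ht
      pnone <- pnone + mm - he * ht
    } else {                             # both continue to the final
      Te <- se$T11; Tt <- st$T11
      Fj <- matrix(0, 4, 4)
      for (ef in 0:3) for (tf in 0:3)
        Fj[bitwAnd(ef, tf) + 1L, 1L] <- Fj[bitwAnd(ef, tf) + 1L, 1L] +
          Te[ef + 1L] * Tt[tf + 1L]
      pnone <- pnone + Fj[1L, 1L]
      p_d1 <- p_d1 + Fj[3L, 1L]          # joint flags (1, 0)
      p_d2 <- p_d2 + Fj[2L, 1L]          # joint flags (0, 1)
      go1 <- go1 + Fj[3L, 1L] + Fj[4L, 1L]
      go2 <- go2 + Fj[2L, 1L] + Fj[4L, 1L]
    }
  }
  # both-final-pass branch: product measure over final cells
  pe <- as.vector(t(se$Mfin * se$fboth))
  pt <- as.vector(t(st$Mfin * st$fboth))
  sir <- 0
  if (monitor_only) {
    p_d1 <- p_d1 + sum(pe) * sum(pt)
  } else {
    ie <- which(pe > 0); it <- which(pt > 0)
    if (length(ie) && length(it)) {
      Wv <- outer(pe[ie], pt[it])
      V <- ppu[ie, it, drop = FALSE]
      p_d2 <- p_d2 + sum(Wv[V <= c1])
      p_d1 <- p_d1 + sum(Wv[V > c2])
      sir <- sum(Wv[V > c1 & V <= c2])
    }
  }
  c(none = pnone, select_d1 = p_d1, select_d2 = p_d2, inconclusive = sir,
    go1 = go1, go2 = go2)
}

#' Exact operating characteristics of the joint design
#'
#' Computes the decision probabilities, Go percentages, FWER/OMP and ASS
#' of the utility-based joint design by exact enumeration, exploiting the
#' independence of the efficacy and toxicity outcome paths given the
#' continuation configuration.
#'
#' @param scn a [scenario()] carrying toxicity rates `q1`, `q2`.
#' @param jdes a [jointDesign()].
#' @param settings a [dlmSettings()].
#' @param grids optional precomputed `.jointGrids()` output.
#' @param ppu optional precomputed utility-PP matrix.
#' @return A `"trialOC"` object (estimation summaries are provided by the
#'   Monte Carlo backend [simulateJointOC()], not here).
#' @export
exactJointOC <- function(scn, jdes, settings = dlmSettings(),
                         grids = NULL, ppu = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(jdes, "jointDesign"))
  if (is.null(scn$q)) stop("joint OC requires toxicity rates in the scenario")
  d <- jdes$design
  if (is.null(grids)) grids <- .jointGrids(jdes, settings)
  if (is.null(ppu))
    ppu <- .ppuMatrix(grids$eff$fin, grids$tox$fin, d$delta1, jdes$up$rho)
  se <- .sideStats(grids$eff, d$m1, d$m2, scn$p, d$a1, d$a2, safe = FALSE)
  st <- .sideStats(grids$tox, d$m1, d$m2, scn$q, d$a1, d$a2, safe = TRUE)
  r <- .jointAssemble(se, st, ppu, d$c1, d$c2)
  dec <- r[c("none", "select_d1", "select_d2", "inconclusive")]
  structure(list(scenario = scn, design = d, backend = "exact",
                 decision_prob = setNames(as.numeric(dec), .DECISIONS),
                 go = unname(r[c("go1", "go2")]),
                 p_event = unname(1 - r[["none"]]),
                 ass = d$m1 + d$m2 * c(se$pI1 * st$pI1, se$pI2 * st$pI2),
                 est_mean = rep(NA_real_, 2), est_mse = rep(NA_real_, 2),
                 reps = NA_integer_, se = NULL),
            class = "trialOC")
}

#' Monte Carlo operating characteristics of the joint design
#'
#' Simulates `reps` trials with independent efficacy and toxicity
#' outcomes and summarizes decisions, enrollment, and efficacy-rate
#' estimation (posterior means at trial end, all replications included).
#'
#' @inheritParams exactJointOC
#' @param reps number of replications.
#' @param seed integer seed.
#' @return A `"trialOC"` object with Monte Carlo standard errors.
#' @export
simulateJointOC <- function(scn, jdes, reps = 10000L, seed = 1L,
                            settings = dlmSettings(), grids = NULL,
                            ppu = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(jdes, "jointDesign"))
  if (is.null(scn$q)) stop("joint OC requires toxicity rates in the scenario")
  d <- jdes$design
  if (is.null(grids)) grids <- .jointGrids(jdes, settings)
  if (is.null(ppu))
    ppu <- .ppuMatrix(grids$eff$fin, grids$tox$fin, d$delta1, jdes$up$rho)
  m1 <- d$m1; m2 <- d$m2; n <- d$n
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  xe1 <- rbinom(reps, m1, scn$p[1]); xe2 <- rbinom(reps, m1, scn$p[2])
  xt1 <- rbinom(reps, m1, scn$q[1]); xt2 <- rbinom(reps, m1, scn$q[2])
  ze1 <- rbinom(reps, m2, scn$p[1]); ze2 <- rbinom(reps, m2, scn$p[2])
  zt1 <- rbinom(reps, m2, scn$q[1]); zt2 <- rbinom(reps, m2, scn$q[2])

  ie <- cbind(xe1 + 1L, xe2 + 1L); it <- cbind(xt1 + 1L, xt2 + 1L)
  i1 <- grids$eff$int$pr1[ie] >= d$a1 & (1 - grids$tox$int$pr1[it]) >= d$a1
  i2 <- grids$eff$int$pr2[ie] >= d$a1 & (1 - grids$tox$int$pr2[it]) >= d$a1
  ye1 <- xe1 + ifelse(i1, ze1, 0L); ye2 <- xe2 + ifelse(i2, ze2, 0L)
  yt1 <- xt1 + ifelse(i1, zt1, 0L); yt2 <- xt2 + ifelse(i2, zt2, 0L)

  dec <- integer(reps); f1 <- logical(reps); f2 <- logical(reps)
  pm1 <- pm2 <- numeric(reps)
  b <- i1 & i2
  if (any(b)) {
    ixe <- cbind(ye1[b] + 1L, ye2[b] + 1L)
    ixt <- cbind(yt1[b] + 1L, yt2[b] + 1L)
    f1[b] <- grids$eff$fin$pr1[ixe] >= d$a2 &
             (1 - grids$tox$fin$pr1[ixt]) >= d$a2
    f2[b] <- grids$eff$fin$pr2[ixe] >= d$a2 &
             (1 - grids$tox$fin$pr2[ixt]) >= d$a2
    ce <- ye1[b] * (n + 1L) + ye2[b] + 1L
    ct <- yt1[b] * (n + 1L) + yt2[b] + 1L
    pp <- ppu[cbind(ce, ct)]
    dec[b] <- ifelse(!f1[b] & !f2[b], 0L,
               ifelse(f1[b] & !f2[b], 1L,
                ifelse(!f1[b] & f2[b], 2L,
                 ifelse(pp <= d$c1, 2L, ifelse(pp > d$c2, 1L, 3L)))))
    pm1[b] <- grids$eff$fin$pm1[ixe]; pm2[b] <- grids$eff$fin$pm2[ixe]
  }
  o1 <- i1 & !i2
  if (any(o1)) {
    ixe <- cbind(ye1[o1] + 1L, xe2[o1] + 1L)
    ixt <- cbind(yt1[o1] + 1L, xt2[o1] + 1L)
    f1[o1] <- grids$eff$d1only$pr1[ixe] >= d$a2 &
              (1 - grids$tox$d1only$pr1[ixt]) >= d$a2
    dec[o1] <- ifelse(f1[o1], 1L, 0L)
    pm1[o1] <- grids$eff$d1only$pm1[ixe]; pm2[o1] <- grids$eff$d1only$pm2[ixe]
  }
  o2 <- !i1 & i2
  if (any(o2)) {
    ixe <- cbind(xe1[o2] + 1L, ye2[o2] + 1L)
    ixt <- cbind(xt1[o2] + 1L, yt2[o2] + 1L)
    f2[o2] <- grids$eff$d2only$pr2[ixe] >= d$a2 &
              (1 - grids$tox$d2only$pr2[ixt]) >= d$a2
    dec[o2] <- ifelse(f2[o2], 2L, 0L)
    pm1[o2] <- grids$eff$d2only$pm1[ixe]; pm2[o2] <- grids$eff$d2only$pm2[ixe]
  }
  s0 <- !i1 & !i2
  if (any(s0)) {
    ixe <- cbind(xe1[s0] + 1L, xe2[s0] + 1L)
    pm1[s0] <- grids$eff$int$pm1[ixe]; pm2[s0] <- grids$eff$int$pm2[ixe]
  }
  dp <- vapply(0:3, function(k) mean(dec == k), numeric(1))
  structure(list(scenario = scn, design = d, backend = "mc",
                 decision_prob = setNames(dp, .DECISIONS),
                 go = c(mean(i1 & f1), mean(i2 & f2)),
                 p_event = mean(dec != 0L),
                 ass = c(mean(ifelse(i1, n, m1)), mean(ifelse(i2, n, m1))),
                 est_mean = c(mean(pm1), mean(pm2)),
                 est_mse = c(mean((pm1 - scn$p[1])^2),
                             mean((pm2 - scn$p[2])^2)),
                 reps = as.integer(reps),
                 se = setNames(sqrt(dp * (1 - dp) / reps), .DECISIONS)),
            class = "trialOC")
}

## ---- joint calibration -----------------------------------------------------

#' Calibrate the joint toxicity-efficacy design
#'
#' Runs the two-step calibration with the operating characteristics
#' computed under the joint hypotheses: the global null has all doses
#' futile and overly toxic (`p = p0`, `q = q0`), the global alternative
#' all doses promising and safe (`p = pA`, `q = qA`); the comparison
#' cutoffs are calibrated under the utility alternatives
#' `(pA, pA + delta1)` and `(pA, pA + delta2)` with toxicity fixed at
#' `qA`.
#'
#' @param targets a [calibrationTargets()].
#' @param p0,pA null and promising response rates.
#' @param q0,qA toxicity limit and acceptable toxicity rate.
#' @param rho toxicity penalty weight.
#' @param delta1,delta2 margins on the utility scale.
#' @param hyper_eff,hyper_tox optional [dlmHyper()] overrides.
#' @param settings a [dlmSettings()].
#' @param verbose print per-n progress.
#' @return A calibrated [jointDesign()] (or `"calibrationFailure"`).
#' @export
calibrateJoint <- function(targets, p0, pA, q0, qA, rho,
                           delta1 = 0.05, delta2 = 0.2,
                           hyper_eff = dlmHyper(probit(p0)),
                           hyper_tox = dlmHyper(probit(q0)),
                           settings = dlmSettings(), verbose = FALSE) {
  stopifnot(inherits(targets, "calibrationTargets"))
  if (qA >= q0)
    return(structure(list(feasible = FALSE,
                          message = "qA >= q0: the toxicity alternative coincides with (or exceeds) the null; calibration is infeasible",
                          best = NULL, trace = NULL),
                     class = "calibrationFailure"))
  up <- utilityParams(rho, q0, qA)
  trace <- list(); best_overall <- NULL
  for (n in targets$n_range) {
    m1s <- if (is.null(targets$m1_grid))
      seq.int(ceiling(n / 3), floor(2 * n / 3)) else
      targets$m1_grid[targets$m1_grid < n]
    best <- NULL
    for (m1 in m1s) {
      des <- designParams(n, m1, 0, 0, 0, 1, delta1, delta2, p0, pA,
                          targets$wl, model = "dlm")
      jd <- jointDesign(des, up, hyper_eff, hyper_tox)
      g <- .jointGrids(jd, settings, diff = FALSE)
      for (lam in targets$lambda_grid) for (a2 in targets$a2_grid) {
        a1 <- a2 * (m1 / n)^lam
        se0 <- .sideStats(g$eff, m1, n - m1, c(p0, p0), a1, a2)
        st0 <- .sideStats(g$tox, m1, n - m1, c(q0, q0), a1, a2, safe = TRUE)
        r0 <- .jointAssemble(se0, st0, NULL, 0, 1, monitor_only = TRUE)
        fwer <- 1 - r0[["none"]]
        if (fwer > targets$alpha1 + 1e-12) next
        seA <- .sideStats(g$eff, m1, n - m1, c(pA, pA), a1, a2)
        stA <- .sideStats(g$tox, m1, n - m1, c(qA, qA), a1, a2, safe = TRUE)
        rA <- .jointAssemble(seA, stA, NULL, 0, 1, monitor_only = TRUE)
        omp <- 1 - rA[["none"]]
        best[[length(best) + 1L]] <- list(
          n = n, m1 = m1, lambda = lam, a1 = a1, a2 = a2, fwer = fwer,
          omp = omp,
          ass_null = m1 + (n - m1) *
            (se0$pI1 * st0$pI1 + se0$pI2 * st0$pI2) / 2)
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
      message(sprintf("n = %d: best OMP %.3f, FWER %.3f", n, opt$omp, opt$fwer))
    if (is.null(best_overall) || opt$omp > best_overall$omp)
      best_overall <- opt
    if (opt$omp >= targets$beta1) {
      des <- designParams(opt$n, opt$m1, opt$a1, opt$a2, 0, 1,
                          delta1, delta2, p0, pA, targets$wl,
                          lambda = opt$lambda, model = "dlm")
      jd <- jointDesign(des, up, hyper_eff, hyper_tox)
      jd <- .jointStep2(jd, targets, settings)
      attr(jd, "trace") <- do.call(rbind, trace)
      return(jd)
    }
  }
  structure(list(feasible = FALSE,
                 message = sprintf(
                   "no n in [%d, %d] attains joint OMP >= %.3f; best achieved %.3f",
                   min(targets$n_range), max(targets$n_range), targets$beta1,
                   if (is.null(best_overall)) NA else best_overall$omp),
                 best = best_overall, trace = do.call(rbind, trace)),
            class = "calibrationFailure")
}

# step 2 on the utility scale: grid search (c1, c2) under the utility
# alternatives with toxicity fixed at qA
.jointStep2 <- function(jdes, targets, settings) {
  d <- jdes$design; up <- jdes$up
  g <- .jointGrids(jdes, settings, diff = TRUE)
  ppu <- .ppuMatrix(g$eff$fin, g$tox$fin, d$delta1, up$rho)
  scn_star <- scenario(d$pA, d$pA + d$delta1, up$qA, up$qA, role = "HA_star")
  scn_plus <- scenario(d$pA, d$pA + d$delta2, up$qA, up$qA, role = "HA_plus")
  sides <- lapply(list(scn_star, scn_plus), function(s) list(
    e = .sideStats(g$eff, d$m1, d$m2, s$p, d$a1, d$a2),
    t = .sideStats(g$tox, d$m1, d$m2, s$q, d$a1, d$a2, safe = TRUE)))
  cg <- targets$c_grid
  rows <- list()
  for (i in seq_along(cg)) for (j in i:length(cg)) {
    c1 <- cg[i]; c2 <- cg[j]
    fs <- .jointAssemble(sides[[1]]$e, sides[[1]]$t, ppu, c1, c2)
    fp <- .jointAssemble(sides[[2]]$e, sides[[2]]$t, ppu, c1, c2)
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
  if (nrow(feas) == 0L)
    return(structure(list(feasible = FALSE,
                          message = sprintf("no feasible (c1, c2); min MRID %.3f, min SIR %.3f",
                                            min(tb$mrid), min(tb$sir)),
                          trace = tb),
                     class = "calibrationFailure"))
  feas <- feas[order(feas$wl, feas$sir, feas$c2 - feas$c1, feas$c1), ]
  jdes$design$c1 <- feas$c1[1L]; jdes$design$c2 <- feas$c2[1L]
  attr(jdes, "step2") <- feas[1L, ]
  jdes
}
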