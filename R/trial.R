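## Trial simulation and exact operating characteristics by enumeration of
## the binomial outcome space.

#' True-rate scenario for a two-dose trial
#'
#' @param p1,p2 true response rates of the lower and higher dose.
#' @param q1,q2 optional true toxicity rates (joint toxicity-efficacy
#'   extension).
#' @param label scenario label (e.g. `"1.2"`).
#' @param role hypothesis role tag: one of `"global_null"`,
#'   `"global_alternative"`, `"HA_star"`, `"HA_plus"`, `"other"`.
#' @return An object of class `"scenario"`.
#' @examples
#' scenario(0.4, 0.4, label = "1.2")
#' @export
scenario <- function(p1, p2, q1 = NULL, q2 = NULL, label = NULL,
                     role = c("other", "global_null", "global_alternative",
                              "HA_star", "HA_plus")) {
  role <- match.arg(role)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (!is.null(q1)) stopifnot(q1 >= 0, q1 <= 1, q2 >= 0, q2 <= 1)
  structure(list(p = c(p1, p2),
                 q = if (is.null(q1)) NULL else c(q1, q2),
                 label = label, role = role),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: (p1, p2) = (%.2f, %.2f)",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$p[1], x$p[2]))
  if (!is.null(x$q)) cat(sprintf(", (q1, q2) = (%.2f, %.2f)", x$q[1], x$q[2]))
  cat("\n")
  invisible(x)
}

# shifted-binomial transition matrix: row x1 (0..m1) holds the pmf of the
# stage-2 total y = x1 + Bin(m2, p) over 0..n
.shiftBinom <- function(m1, m2, p) {
  n <- m1 + m2
  t(vapply(0:m1, function(x) dbinom(0:n - x, m2, p), numeric(n + 1L)))
}

## ---- single-trial simulation ----------------------------------------------

#' Simulate one two-stage trial
#'
#' Draws stage-1 responder counts, applies the interim monitoring, draws
#' stage-2 counts for surviving doses, and applies the final monitoring
#' and between-dose comparison.  Deterministic given `seed`.
#'
#' @param scn a [scenario()].
#' @param design a [designParams()].
#' @param hyper a [dlmHyper()].
#' @param seed integer seed.
#' @param settings a [dlmSettings()].
#' @param grids optional precomputed `.designGrids()` output (reused
#'   across many simulations).
#' @return An object of class `"trialResult"`: `decision`, per-dose
#'   `enrolled`, per-dose posterior-mean `estimates`, and the stage
#'   pass flags.
#' @export
simulateTrial <- function(scn, design, hyper, seed = 1L,
                          settings = dlmSettings(), grids = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(design, "designParams"))
  if (is.null(grids)) grids <- .designGrids(design, hyper, settings)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r <- .simulateVec(scn, design, grids, reps = 1L)
  structure(list(decision = .DECISIONS[r$dec + 1L],
                 enrolled = c(r$en1, r$en2),
                 estimates = c(r$pm1, r$pm2),
                 interim_pass = c(r$i1, r$i2),
                 final_pass = c(r$f1, r$f2)),
            class = "trialResult")
}

#' @export
print.trialResult <- function(x, ...) {
  cat(sprintf("Trial result: %s; enrolled (%d, %d); estimates (%.3f, %.3f)\n",
              x$decision, x$enrolled[1], x$enrolled[2],
              x$estimates[1], x$estimates[2]))
  invisible(x)
}

# vectorized simulation core; returns per-replication vectors
.simulateVec <- function(scn, design, grids, reps) {
  m1 <- design$m1; m2 <- design$m2; n <- design$n
  p1 <- scn$p[1]; p2 <- scn$p[2]
  x1 <- rbinom(reps, m1, p1); x2 <- rbinom(reps, m1, p2)
  z1 <- rbinom(reps, m2, p1); z2 <- rbinom(reps, m2, p2)
  i1 <- grids$int$pr1[cbind(x1 + 1L, x2 + 1L)] >= design$a1
  i2 <- grids$int$pr2[cbind(x1 + 1L, x2 + 1L)] >= design$a1
  y1 <- x1 + ifelse(i1, z1, 0L); y2 <- x2 + ifelse(i2, z2, 0L)
  dec <- integer(reps)
  f1 <- logical(reps); f2 <- logical(reps)
  pm1 <- pm2 <- numeric(reps)

  b <- i1 & i2
  if (any(b)) {
    D <- .finalDecisionMatrix(grids$fin, design)
    ix <- cbind(y1[b] + 1L, y2[b] + 1L)
    dec[b] <- D[ix]
    f1[b] <- grids$fin$pr1[ix] >= design$a2
    f2[b] <- grids$fin$pr2[ix] >= design$a2
    pm1[b] <- grids$fin$pm1[ix]; pm2[b] <- grids$fin$pm2[ix]
  }
  o1 <- i1 & !i2
  if (any(o1)) {
    ix <- cbind(y1[o1] + 1L, x2[o1] + 1L)
    f1[o1] <- grids$d1only$pr1[ix] >= design$a2
    dec[o1] <- ifelse(f1[o1], 1L, 0L)
    pm1[o1] <- grids$d1only$pm1[ix]; pm2[o1] <- grids$d1only$pm2[ix]
  }
  o2 <- !i1 & i2
  if (any(o2)) {
    ix <- cbind(x1[o2] + 1L, y2[o2] + 1L)
    f2[o2] <- grids$d2only$pr2[ix] >= design$a2
    dec[o2] <- ifelse(f2[o2], 2L, 0L)
    pm1[o2] <- grids$d2only$pm1[ix]; pm2[o2] <- grids$d2only$pm2[ix]
  }
  s0 <- !i1 & !i2
  if (any(s0)) {
    ix <- cbind(x1[s0] + 1L, x2[s0] + 1L)
    pm1[s0] <- grids$int$pm1[ix]; pm2[s0] <- grids$int$pm2[ix]
  }
  list(dec = dec, i1 = i1, i2 = i2, f1 = f1, f2 = f2,
       en1 = ifelse(i1, n, m1), en2 = ifelse(i2, n, m1),
       pm1 = pm1, pm2 = pm2)
}

## ---- operating characteristics --------------------------------------------

#' Exact operating characteristics by outcome enumeration
#'
#' Sums binomial probability mass over the full outcome tree (interim
#' cells times conditional stage-2 cells), so all probabilities are exact
#' (no Monte Carlo error).  The exact twin of [simulateOC()].
#'
#' @param scn a [scenario()].
#' @param design a [designParams()].
#' @param hyper a [dlmHyper()].
#' @param settings a [dlmSettings()].
#' @param grids optional precomputed `.designGrids()` output.
#' @return An object of class `"trialOC"`; see [ocMetrics()] for the
#'   derived summaries.
#' @export
exactOC <- function(scn, design, hyper, settings = dlmSettings(),
                    grids = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(design, "designParams"))
  if (is.null(grids)) grids <- .designGrids(design, hyper, settings)
  m1 <- design$m1; m2 <- design$m2; n <- design$n
  p1 <- scn$p[1]; p2 <- scn$p[2]

  w1 <- dbinom(0:m1, m1, p1); w2 <- dbinom(0:m1, m1, p2)
  W <- outer(w1, w2)
  I1 <- grids$int$pr1 >= design$a1
  I2 <- grids$int$pr2 >= design$a1
  Q1 <- .shiftBinom(m1, m2, p1); Q2 <- .shiftBinom(m1, m2, p2)

  dec <- numeric(4L)           # none, d1, d2, inconclusive
  go <- numeric(2L)
  epm <- numeric(2L); emse <- numeric(2L)

  Sboth <- I1 & I2
  if (any(Sboth)) {
    D <- .finalDecisionMatrix(grids$fin, design)
    for (d in 0:3) {
      G <- Q1 %*% (D == d) %*% t(Q2)
      dec[d + 1L] <- dec[d + 1L] + sum(W[Sboth] * G[Sboth])
    }
    Gp1 <- Q1 %*% (grids$fin$pr1 >= design$a2) %*% t(Q2)
    Gp2 <- Q1 %*% (grids$fin$pr2 >= design$a2) %*% t(Q2)
    go[1] <- go[1] + sum(W[Sboth] * Gp1[Sboth])
    go[2] <- go[2] + sum(W[Sboth] * Gp2[Sboth])
    for (j in 1:2) {
      pm <- grids$fin[[paste0("pm", j)]]
      Gm <- Q1 %*% pm %*% t(Q2)
      Gs <- Q1 %*% (pm - scn$p[j])^2 %*% t(Q2)
      epm[j] <- epm[j] + sum(W[Sboth] * Gm[Sboth])
      emse[j] <- emse[j] + sum(W[Sboth] * Gs[Sboth])
    }
  }
  S1 <- I1 & !I2
  if (any(S1)) {
    A <- grids$d1only
    Gsel <- Q1 %*% (A$pr1 >= design$a2)       # (m1+1) x (m1+1)
    psel <- sum(W[S1] * Gsel[S1])
    dec[2] <- dec[2] + psel
    dec[1] <- dec[1] + sum(W[S1]) - psel
    go[1] <- go[1] + psel
    for (j in 1:2) {
      pm <- A[[paste0("pm", j)]]
      epm[j] <- epm[j] + sum(W[S1] * (Q1 %*% pm)[S1])
      emse[j] <- emse[j] + sum(W[S1] * (Q1 %*% (pm - scn$p[j])^2)[S1])
    }
  }
  S2 <- !I1 & I2
  if (any(S2)) {
    B <- grids$d2only
    Gsel <- (B$pr2 >= design$a2) %*% t(Q2)
    psel <- sum(W[S2] * Gsel[S2])
    dec[3] <- dec[3] + psel
    dec[1] <- dec[1] + sum(W[S2]) - psel
    go[2] <- go[2] + psel
    for (j in 1:2) {
      pm <- B[[paste0("pm", j)]]
      epm[j] <- epm[j] + sum(W[S2] * (pm %*% t(Q2))[S2])
      emse[j] <- emse[j] + sum(W[S2] * ((pm - scn$p[j])^2 %*% t(Q2))[S2])
    }
  }
  S0 <- !I1 & !I2
  if (any(S0)) {
    dec[1] <- dec[1] + sum(W[S0])
    for (j in 1:2) {
      pm <- grids$int[[paste0("pm", j)]]
      epm[j] <- epm[j] + sum(W[S0] * pm[S0])
      emse[j] <- emse[j] + sum(W[S0] * ((pm - scn$p[j])^2)[S0])
    }
  }

  pint <- c(sum(W[I1]), sum(W[I2]))
  structure(list(scenario = scn, design = design, backend = "exact",
                 decision_prob = setNames(dec, .DECISIONS),
                 go = go, p_event = sum(dec[2:4]),
                 ass = m1 + m2 * pint,
                 est_mean = epm, est_mse = emse,
                 reps = NA_integer_, se = NULL),
            class = "trialOC")
}

#' Monte Carlo operating characteristics
#'
#' Simulates `reps` independent trials (deterministic given `seed`) and
#' summarizes the decision frequencies with their Monte Carlo standard
#' errors.  Mirrors the reporting convention of simulation studies with
#' 10,000 replications per scenario.
#'
#' @inheritParams exactOC
#' @param reps number of trial replications (>= 1).
#' @param seed integer seed.
#' @return An object of class `"trialOC"` with Monte Carlo standard
#'   errors in `se`.
#' @export
simulateOC <- function(scn, design, hyper, reps = 10000L, seed = 1L,
                       settings = dlmSettings(), grids = NULL) {
  stopifnot(reps >= 1)
  if (is.null(grids)) grids <- .designGrids(design, hyper, settings)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r <- .simulateVec(scn, design, grids, reps)
  dec <- vapply(0:3, function(d) mean(r$dec == d), numeric(1))
  structure(list(scenario = scn, design = design, backend = "mc",
                 decision_prob = setNames(dec, .DECISIONS),
                 go = c(mean(r$i1 & r$f1), mean(r$i2 & r$f2)),
                 p_event = mean(r$dec != 0L),
                 ass = c(mean(r$en1), mean(r$en2)),
                 est_mean = c(mean(r$pm1), mean(r$pm2)),
                 est_mse = c(mean((r$pm1 - scn$p[1])^2),
                             mean((r$pm2 - scn$p[2])^2)),
                 reps = as.integer(reps),
                 se = setNames(sqrt(dec * (1 - dec) / reps), .DECISIONS)),
            class = "trialOC")
}

#' @export
print.trialOC <- function(x, ...) {
  cat(sprintf("Operating characteristics (%s backend%s)\n", x$backend,
              if (x$backend == "mc") sprintf(", %d reps", x$reps) else ""))
  print(x$scenario)
  dp <- x$decision_prob * 100
  cat(sprintf("  decisions %%: none %.1f | d1 %.1f | d2 %.1f | inconclusive %.1f\n",
              dp[1], dp[2], dp[3], dp[4]))
  cat(sprintf("  Go %%: d1 %.1f, d2 %.1f;  P(E) = %.1f%%;  ASS (%.1f, %.1f)\n",
              100 * x$go[1], 100 * x$go[2], 100 * x$p_event,
              x$ass[1], x$ass[2]))
  invisible(x)
}
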