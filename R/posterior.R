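## Posterior engine for the two-dose Bayesian dynamic linear model (DLM)
##
##   y_j | p_j        ~ Bin(n_j, p_j)               j = 1, 2
##   mu_j             = probit(p_j)
##   mu_1             ~ N(theta, sigma1^2)
##   mu_2 | mu_1, s2  ~ N(mu_1, s2^2)
##   s2               ~ half-Cauchy(xi, tau)        (support s2 > xi)
##
## The default backend is a deterministic quadrature on a shared lattice in
## mu with spacing h: the half-Cauchy scale is integrated out on a
## stratified grid, giving a cell-averaged "borrowing kernel" for
## d = mu2 - mu1, and all posterior summaries reduce to weighted sums over
## a 2-D table.  Mass beyond the lattice (the Cauchy tails, where Phi(mu)
## saturates at 0 or 1) is collected in absorbing edge cells so that
## normalization is exact on the probability scale.

#' Probit and inverse-probit transforms
#'
#' `probit()` maps a response probability to the latent normal scale,
#' `probitInv()` maps back.
#'
#' @param p probability strictly inside (0, 1).
#' @param x real number.
#' @return `probit()` returns a real number; `probitInv()` a probability.
#' @examples
#' probit(0.5)          # 0
#' probitInv(probit(0.2))
#' @export
probit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probit() requires probabilities strictly inside (0, 1)")
  qnorm(p)
}

#' @rdname probit
#' @export
probitInv <- function(x) pnorm(x)

#' Hyperparameters of the dynamic linear model
#'
#' @param theta prior mean of the probit response rate at the lowest dose;
#'   conventionally `probit(p0)` for historical control rate `p0`.
#' @param sigma1 prior SD of `mu1` (> 0); large values give a
#'   noninformative prior.
#' @param xi location of the half-Cauchy prior on the borrowing scale
#'   (default 0).
#' @param tau scale of the half-Cauchy prior (> 0, default 1).
#' @return An object of class `"dlmHyper"`.
#' @examples
#' dlmHyper(probit(0.2))
#' @export
dlmHyper <- function(theta, sigma1 = 3, xi = 0, tau = 1) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (!is.numeric(sigma1) || sigma1 <= 0) stop("sigma1 must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  structure(list(theta = theta, sigma1 = sigma1, xi = xi, tau = tau),
            class = "dlmHyper")
}

#' @export
print.dlmHyper <- function(x, ...) {
  cat(sprintf("DLM hyperparameters: theta = %.4f, sigma1 = %g, HC(xi = %g, tau = %g)\n",
              x$theta, x$sigma1, x$xi, x$tau))
  invisible(x)
}

#' Numerical settings of the quadrature backend
#'
#' @param h lattice spacing on the probit scale.
#' @param sigma_nodes number of stratified nodes used to integrate out the
#'   half-Cauchy borrowing scale.
#' @param tol target absolute tolerance for posterior probabilities when
#'   `dlmPosterior()` is asked to verify convergence by grid refinement.
#' @param max_refine maximum number of h-halving refinements attempted.
#' @param soft absorbing-edge location: beyond `|mu| = soft` the response
#'   probability is numerically saturated and mass is collected in edge
#'   cells at p = 0 or 1.
#' @param spread half-width, in approximate likelihood SDs, of the lattice
#'   window kept around the data.
#' @return An object of class `"dlmSettings"`.
#' @export
dlmSettings <- function(h = 0.05, sigma_nodes = 64, tol = 1e-3,
                        max_refine = 2, soft = 8.6, spread = 8) {
  stopifnot(h > 0, sigma_nodes >= 8, tol > 0, soft > 4, spread >= 4)
  structure(list(h = h, sigma_nodes = sigma_nodes, tol = tol,
                 max_refine = max_refine, soft = soft, spread = spread),
            class = "dlmSettings")
}

#' Accumulated two-dose trial data
#'
#' Container for the per-dose responder counts at an analysis; optionally
#' carries toxicity counts for the joint toxicity-efficacy extension.
#'
#' @param y length-2 integer vector of responders per dose.
#' @param n length-2 integer vector of evaluable patients per dose.
#' @param t optional length-2 integer vector of toxicity events per dose.
#' @param stage analysis stage index (1 = interim, 2 = final).
#' @return An object of class `"trialData"`.
#' @examples
#' trialData(y = c(3, 5), n = c(10, 10))
#' @export
trialData <- function(y, n, t = NULL, stage = 1L) {
  y <- as.integer(y); n <- as.integer(n)
  stopifnot(length(y) == 2L, length(n) == 2L, all(n >= 0))
  if (any(y < 0) || any(y > n)) stop("counts must satisfy 0 <= y <= n")
  if (!is.null(t)) {
    t <- as.integer(t)
    stopifnot(length(t) == 2L)
    if (any(t < 0) || any(t > n)) stop("counts must satisfy 0 <= t <= n")
  }
  structure(list(y = y, n = n, t = t, stage = as.integer(stage)),
            class = "trialData")
}

#' @export
print.trialData <- function(x, ...) {
  cat(sprintf("Two-dose trial data (stage %d): d1 %d/%d, d2 %d/%d responders\n",
              x$stage, x$y[1], x$n[1], x$y[2], x$n[2]))
  if (!is.null(x$t))
    cat(sprintf("  toxicity: d1 %d/%d, d2 %d/%d\n",
                x$t[1], x$n[1], x$t[2], x$n[2]))
  invisible(x)
}

## ---- internal quadrature pieces -------------------------------------------

# stratified nodes for the half-Cauchy scale: s = xi + tau * tan(pi u / 2)
# with u = v^3 on a midpoint grid in v, so small scales (strong borrowing)
# are well resolved for any tau
.hcNodes <- function(K, xi, tau) {
  v <- (seq_len(K) - 0.5) / K
  list(s = xi + tau * tan(pi * v^3 / 2), w = 3 * v^2 / K)
}

# cell-averaged marginal kernel of d = mu2 - mu1 over cells of width h
.hcKernel <- function(d, h, nodes) {
  a <- outer(d + h / 2, nodes$s, function(x, s) pnorm(x / s))
  b <- outer(d - h / 2, nodes$s, function(x, s) pnorm(x / s))
  drop((a - b) %*% nodes$w) / h
}

# P(d < x) marginal over the half-Cauchy scale
.hcTail <- function(x, nodes) {
  drop(outer(x, nodes$s, function(z, s) pnorm(z / s)) %*% nodes$w)
}

# lattice window for one dose: prior/likelihood-informed [lo, hi]
.doseRange <- function(y, n, prior_lo, prior_hi, soft, spread) {
  if (n > 0) {
    ph <- (y + 0.5) / (n + 1)
    zh <- qnorm(ph)
    s <- sqrt(ph * (1 - ph) / n) / dnorm(zh)
    like_lo <- if (y > 0) zh - spread * s else -Inf
    like_hi <- if (y < n) zh + spread * s else Inf
  } else {
    like_lo <- -Inf
    like_hi <- Inf
  }
  c(max(like_lo, prior_lo, -soft), min(like_hi, prior_hi, soft))
}

# fraction of a lattice cell centered at mu lying above threshold z
.fracAbove <- function(mu, z, h) pmin(pmax((mu - z) / h + 0.5, 0), 1)

## Full posterior table over all outcome pairs (y1, y2) for sample sizes
## (n1, n2).  Returns (n1+1) x (n2+1) matrices pr1, pr2, ppni, pm1, pm2 and,
## if diff = TRUE, the binned posterior pmf of p2 - p1 per outcome pair.
.dlmGrid <- function(n1, n2, hyper, p0, delta1, settings = dlmSettings(),
                     diff = FALSE, dgrid = NULL) {
  h <- settings$h
  theta <- hyper$theta; sigma1 <- hyper$sigma1
  nodes <- .hcNodes(settings$sigma_nodes, hyper$xi, hyper$tau)
  prior_lo <- theta - 6.5 * sigma1
  prior_hi <- theta + 6.5 * sigma1

  r1all <- vapply(0:n1, function(y)
    .doseRange(y, n1, prior_lo, prior_hi, settings$soft, settings$spread),
    numeric(2))
  r2all <- vapply(0:n2, function(y)
    .doseRange(y, n2, -Inf, Inf, settings$soft, settings$spread),
    numeric(2))
  k1 <- seq(floor(min(r1all[1, ]) / h), ceiling(max(r1all[2, ]) / h))
  k2 <- seq(floor(min(r2all[1, ]) / h), ceiling(max(r2all[2, ]) / h))
  mu1 <- k1 * h; mu2 <- k2 * h
  m <- length(mu1); p <- length(mu2)
  P1 <- pnorm(mu1); P2 <- pnorm(mu2)

  off <- (min(k2) - max(k1)):(max(k2) - min(k1))
  kern <- .hcKernel(off * h, h, nodes)
  K <- matrix(kern[outer(k1, k2, function(a, b) b - a) - min(off) + 1L], m, p)
  TL <- .hcTail(mu2[1] - h / 2 - mu1, nodes)      # mass below the mu2 lattice
  TR <- .hcTail(mu1 - (mu2[p] + h / 2), nodes)    # mass above it

  z0 <- qnorm(p0)
  fa1 <- .fracAbove(mu1, z0, h)
  fa2 <- .fracAbove(mu2, z0, h)
  # fractional indicator of {p2 - p1 < delta1}, exact per lattice cell
  t1 <- ifelse(P1 + delta1 >= 1, Inf, qnorm(pmin(P1 + delta1, 1 - 1e-15)))
  Fm <- pmin(pmax((rep(t1, p) - rep(mu2, each = m)) / h + 0.5, 0), 1)
  dim(Fm) <- c(m, p)
  KF <- K * Fm

  prior1 <- dnorm(mu1, theta, sigma1)
  L1mat <- matrix(dbinom(rep(0:n1, each = m), n1, P1), m, n1 + 1L)
  L2mat <- matrix(dbinom(rep(0:n2, each = p), n2, P2), p, n2 + 1L)

  A00 <- pnorm((mu1[1] - h / 2 - theta) / sigma1)   # joint saturation atoms
  A11 <- pnorm((theta - mu1[m] - h / 2) / sigma1)

  nm <- c("tot", "pr1", "pm1", "ppni")
  out <- lapply(c(nm, "pr2", "pm2"), function(.) matrix(0, n1 + 1L, n2 + 1L))
  names(out) <- c(nm, "pr2", "pm2")
  edgeR_ppni <- as.numeric(P1 > 1 - delta1)

  if (diff) {
    if (is.null(dgrid)) dgrid <- seq(-1, 1, by = 0.005)
    nb <- length(dgrid) - 1L
    Dpmf <- matrix(0, (n1 + 1L) * (n2 + 1L), nb)
    Bin <- matrix(findInterval(rep(P2, each = m) - rep(P1, p), dgrid,
                               all.inside = TRUE), m, p)
    binL <- findInterval(-P1, dgrid, all.inside = TRUE)  # p2 = 0 edge
    binR <- findInterval(1 - P1, dgrid, all.inside = TRUE)
    bin0 <- findInterval(0, dgrid, all.inside = TRUE)
    lsig <- apply(L1mat, 2, function(l) range(which(l > max(l) * 1e-13)))
    lsig2 <- apply(L2mat, 2, function(l) range(which(l > max(l) * 1e-13)))
  }

  for (iy in 0:n1) {
    r <- prior1 * L1mat[, iy + 1L]
    stack <- rbind(r, r * fa1, r * P1) %*% K        # 3 x p
    nppni <- drop(crossprod(r, KF))                 # length p
    base <- rbind(stack, nppni) %*% L2mat           # 4 x (n2+1), grid part
    out$tot[iy + 1L, ]  <- base[1, ] * h * h
    out$pr1[iy + 1L, ]  <- base[2, ] * h * h
    out$pm1[iy + 1L, ]  <- base[3, ] * h * h
    out$ppni[iy + 1L, ] <- base[4, ] * h * h
    out$pr2[iy + 1L, ]  <- drop((stack[1, ] * fa2) %*% L2mat) * h * h
    out$pm2[iy + 1L, ]  <- drop((stack[1, ] * P2) %*% L2mat) * h * h
    # absorbing mu2 edges: only the saturated likelihood values survive
    eL <- sum(r * TL) * h; eLr <- sum(r * fa1 * TL) * h
    eLp <- sum(r * P1 * TL) * h
    eR <- sum(r * TR) * h; eRr <- sum(r * fa1 * TR) * h
    eRp <- sum(r * P1 * TR) * h; eRni <- sum(r * TR * edgeR_ppni) * h
    out$tot[iy + 1L, 1L] <- out$tot[iy + 1L, 1L] + eL
    out$pr1[iy + 1L, 1L] <- out$pr1[iy + 1L, 1L] + eLr
    out$pm1[iy + 1L, 1L] <- out$pm1[iy + 1L, 1L] + eLp
    out$ppni[iy + 1L, 1L] <- out$ppni[iy + 1L, 1L] + eL    # d = -p1 < delta1
    out$tot[iy + 1L, n2 + 1L] <- out$tot[iy + 1L, n2 + 1L] + eR
    out$pr1[iy + 1L, n2 + 1L] <- out$pr1[iy + 1L, n2 + 1L] + eRr
    out$pr2[iy + 1L, n2 + 1L] <- out$pr2[iy + 1L, n2 + 1L] + eR
    out$pm1[iy + 1L, n2 + 1L] <- out$pm1[iy + 1L, n2 + 1L] + eRp
    out$pm2[iy + 1L, n2 + 1L] <- out$pm2[iy + 1L, n2 + 1L] + eR
    out$ppni[iy + 1L, n2 + 1L] <- out$ppni[iy + 1L, n2 + 1L] + eRni

    if (diff) {
      ii <- lsig[1, iy + 1L]:lsig[2, iy + 1L]
      for (jy in 0:n2) {
        jj <- lsig2[1, jy + 1L]:lsig2[2, jy + 1L]
        Wsub <- (r[ii] * K[ii, jj, drop = FALSE]) *
          rep(L2mat[jj, jy + 1L], each = length(ii))
        acc <- rowsum(as.vector(Wsub) * h * h, as.vector(Bin[ii, jj, drop = FALSE]))
        row <- numeric(nb)
        row[as.integer(rownames(acc))] <- acc[, 1]
        if (jy == 0L) {
          accL <- rowsum(r[ii] * TL[ii] * h, binL[ii])
          row[as.integer(rownames(accL))] <-
            row[as.integer(rownames(accL))] + accL[, 1]
        }
        if (jy == n2) {
          accR <- rowsum(r[ii] * TR[ii] * h, binR[ii])
          row[as.integer(rownames(accR))] <-
            row[as.integer(rownames(accR))] + accR[, 1]
        }
        if (iy == 0L && jy == 0L) row[bin0] <- row[bin0] + A00
        if (iy == n1 && jy == n2) row[bin0] <- row[bin0] + A11
        Dpmf[iy * (n2 + 1L) + jy + 1L, ] <- row
      }
    }
  }

  # saturation atoms: all counts at their extreme values
  out$tot[1L, 1L] <- out$tot[1L, 1L] + A00
  out$ppni[1L, 1L] <- out$ppni[1L, 1L] + A00
  ix <- cbind(n1 + 1L, n2 + 1L)
  for (f in c("tot", "pr1", "pr2", "pm1", "pm2", "ppni"))
    out[[f]][ix] <- out[[f]][ix] + A11

  res <- list(pr1 = out$pr1 / out$tot, pr2 = out$pr2 / out$tot,
              ppni = out$ppni / out$tot,
              pm1 = out$pm1 / out$tot, pm2 = out$pm2 / out$tot,
              n1 = n1, n2 = n2)
  if (diff) {
    res$dpmf <- Dpmf / as.vector(out$tot)
    res$dgrid <- dgrid
  }
  res
}

# single-table convenience wrapper around .dlmGrid (evaluates one column)
.dlmCell <- function(y1, n1, y2, n2, hyper, p0, delta1, settings) {
  g <- .dlmGrid(n1, n2, hyper, p0, delta1, settings)
  i <- y1 + 1L; j <- y2 + 1L
  c(pr1 = g$pr1[i, j], pr2 = g$pr2[i, j], ppni = g$ppni[i, j],
    pm1 = g$pm1[i, j], pm2 = g$pm2[i, j])
}

## ---- user-facing posterior computation ------------------------------------

#' Posterior summaries under the dynamic linear model
#'
#' Computes, for accumulated two-dose data, the per-dose posterior
#' exceedance probabilities Pr(p_j > p0 | D), the posterior noninferiority
#' probability PP_NI = Pr(p2 - p1 < delta1 | D), and the posterior mean
#' response rates.  The default backend is a deterministic quadrature with
#' optional grid-refinement verification; a seeded random-walk MCMC backend
#' (compiled) is available as an independent cross-check.
#'
#' Data from a dose dropped at an interim analysis still enter the joint
#' posterior: borrowing across doses is the point of the model.
#'
#' @param data a [trialData()] object.
#' @param hyper a [dlmHyper()] object.
#' @param p0 historical control response rate.
#' @param delta1 noninferiority margin on the response-rate scale.
#' @param settings a [dlmSettings()] object (quadrature backend).
#' @param method `"quadrature"` (deterministic, default) or `"mcmc"`.
#' @param check if `TRUE` (default for `"quadrature"`), verify convergence
#'   by refining the lattice until successive summaries agree to
#'   `settings$tol`; an explicit error is raised if the tolerance is not
#'   met after `settings$max_refine` refinements.
#' @param iter,burn MCMC iterations and burn-in (method `"mcmc"`).
#' @param seed integer seed for the MCMC backend.
#' @return An object of class `"posteriorSummary"`: list with elements
#'   `pr_exceed` (length 2), `pp_ni`, `post_mean` (length 2), `method`,
#'   and `tol` (tolerance achieved, quadrature) or `mcse` (MCMC).
#' @examples
#' d <- trialData(y = c(8, 8), n = c(10, 10))
#' dlmPosterior(d, dlmHyper(probit(0.2)), p0 = 0.2, delta1 = 0.05)
#' @export
dlmPosterior <- function(data, hyper, p0, delta1,
                         settings = dlmSettings(),
                         method = c("quadrature", "mcmc"),
                         check = TRUE, iter = 2e6, burn = 2e4, seed = 1L) {
  stopifnot(inherits(data, "trialData"), inherits(hyper, "dlmHyper"),
            p0 > 0, p0 < 1, delta1 > 0)
  method <- match.arg(method)
  y <- data$y; n <- data$n

  if (method == "mcmc") {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    r <- dlm_mcmc_cpp(y[1], n[1], y[2], n[2], hyper$theta, hyper$sigma1,
                      hyper$xi, hyper$tau, p0, delta1,
                      as.double(iter), as.double(burn))
    return(structure(list(
      pr_exceed = c(r$est[1], r$est[2]), pp_ni = r$est[3],
      post_mean = c(r$est[4], r$est[5]), method = "mcmc",
      mcse = setNames(r$mcse, c("pr1", "pr2", "ppni", "pm1", "pm2")),
      accept = r$accept), class = "posteriorSummary"))
  }

  s <- settings
  cur <- .dlmCell(y[1], n[1], y[2], n[2], hyper, p0, delta1, s)
  tol_achieved <- NA_real_
  if (check) {
    for (k in seq_len(s$max_refine + 1L)) {
      s2 <- s
      s2$h <- s$h / 2
      s2$sigma_nodes <- s$sigma_nodes * 2L
      nxt <- .dlmCell(y[1], n[1], y[2], n[2], hyper, p0, delta1, s2)
      tol_achieved <- max(abs(nxt - cur))
      cur <- nxt
      s <- s2
      if (tol_achieved <= settings$tol) break
      if (k == s$max_refine + 1L)
        stop(sprintf(paste0("dlmPosterior: quadrature did not reach tolerance",
                            " %.1e after %d refinements (achieved %.1e)"),
                     settings$tol, settings$max_refine, tol_achieved))
    }
  }
  structure(list(pr_exceed = unname(cur[c("pr1", "pr2")]),
                 pp_ni = unname(cur["ppni"]),
                 post_mean = unname(cur[c("pm1", "pm2")]),
                 method = "quadrature", tol = tol_achieved),
            class = "posteriorSummary")
}

#' @export
print.posteriorSummary <- function(x, ...) {
  cat("Posterior summary (", x$method, " backend)\n", sep = "")
  cat(sprintf("  Pr(p1 > p0 | D) = %.4f   Pr(p2 > p0 | D) = %.4f\n",
              x$pr_exceed[1], x$pr_exceed[2]))
  cat(sprintf("  PP_NI = Pr(p2 - p1 < delta1 | D) = %.4f\n", x$pp_ni))
  cat(sprintf("  posterior means: %.4f, %.4f\n",
              x$post_mean[1], x$post_mean[2]))
  invisible(x)
}

## ---- conjugate beta-binomial model (comparator designs) -------------------

#' Beta-binomial posterior summaries
#'
#' Conjugate posterior under independent per-dose modeling with a
#' `Beta(p0, 1 - p0)` prior (prior mean `p0`, prior effective sample
#' size 1), as used by the unoptimized comparator and the beta-binomial
#' variant of the design.  With length-2 inputs the between-dose
#' probabilities are computed by quadrature over the two independent Beta
#' posteriors.
#'
#' @param y responders (length 1 or 2).
#' @param n evaluable patients (same length as `y`).
#' @param p0 historical control rate; also sets the prior `Beta(p0, 1-p0)`.
#' @param delta1 noninferiority margin (used when `y` has length 2).
#' @return A `"posteriorSummary"` object; for a single dose `pp_ni` is `NA`.
#'   For two doses the element `pr_greater` holds Pr(p2 > p1 | D).
#' @examples
#' bbPosterior(4, 10, p0 = 0.2)
#' bbPosterior(c(4, 6), c(10, 10), p0 = 0.2, delta1 = 0.05)
#' @export
bbPosterior <- function(y, n, p0, delta1 = 0.05) {
  stopifnot(length(y) == length(n), length(y) %in% 1:2,
            all(y >= 0), all(y <= n), p0 > 0, p0 < 1)
  a <- p0 + y; b <- 1 - p0 + n - y
  pr <- 1 - pbeta(p0, a, b)
  pm <- a / (a + b)
  if (length(y) == 1L) {
    return(structure(list(pr_exceed = pr, pp_ni = NA_real_, post_mean = pm,
                          shape1 = a, shape2 = b, method = "conjugate"),
                     class = "posteriorSummary"))
  }
  u <- (seq_len(2048) - 0.5) / 2048            # quantile-scale quadrature
  q1 <- qbeta(u, a[1], b[1])
  ppni <- mean(pbeta(pmin(q1 + delta1, 1), a[2], b[2]))
  prgt <- 1 - mean(pbeta(q1, a[2], b[2]))
  structure(list(pr_exceed = pr, pp_ni = ppni, pr_greater = prgt,
                 post_mean = pm, shape1 = a, shape2 = b,
                 method = "conjugate"),
            class = "posteriorSummary")
}

# beta-binomial analogue of .dlmGrid, same return shape
.bbGrid <- function(n1, n2, p0, delta1, nq = 2048) {
  a1 <- p0 + 0:n1; b1 <- 1 - p0 + n1 - 0:n1
  a2 <- p0 + 0:n2; b2 <- 1 - p0 + n2 - 0:n2
  pr1v <- 1 - pbeta(p0, a1, b1)
  pr2v <- 1 - pbeta(p0, a2, b2)
  pm1v <- a1 / (a1 + b1)
  pm2v <- a2 / (a2 + b2)
  u <- (seq_len(nq) - 0.5) / nq
  Q1 <- vapply(seq_along(a1), function(i) qbeta(u, a1[i], b1[i]), numeric(nq))
  ppni <- matrix(0, n1 + 1L, n2 + 1L)
  prgt <- matrix(0, n1 + 1L, n2 + 1L)
  for (j in seq_along(a2)) {
    Fq <- matrix(pbeta(pmin(Q1 + delta1, 1), a2[j], b2[j]), nq)
    Gq <- matrix(pbeta(Q1, a2[j], b2[j]), nq)
    ppni[, j] <- colMeans(Fq)
    prgt[, j] <- 1 - colMeans(Gq)
  }
  list(pr1 = matrix(pr1v, n1 + 1L, n2 + 1L),
       pr2 = matrix(pr2v, n1 + 1L, n2 + 1L, byrow = TRUE),
       ppni = ppni, prgt = prgt,
       pm1 = matrix(pm1v, n1 + 1L, n2 + 1L),
       pm2 = matrix(pm2v, n1 + 1L, n2 + 1L, byrow = TRUE),
       n1 = n1, n2 = n2)
}

## ---- prior effective sample size ------------------------------------------

#' Prior effective sample size of the DLM dose priors
#'
#' The prior marginal of `p_j` implied by the dynamic linear model is
#' moment-matched to a `Beta(a, b)` distribution
#' (`a + b = m(1 - m)/v - 1` for prior mean `m` and variance `v`), and the
#' implied prior effective sample size PESS = a + b is returned.  A design
#' prior is considered suitably vague when the PESS lies in roughly
#' (0.01, 4).
#'
#' @param hyper a [dlmHyper()] object.
#' @param dose 1 (lowest dose) or 2.
#' @return PESS as a single number, with the matched moments attached as
#'   attributes `mean`, `var`, `shape1`, `shape2`.  A degenerate prior
#'   variance (`v >= m(1-m)`) yields PESS 0 with a warning.
#' @examples
#' priorPESS(dlmHyper(0, sigma1 = 1))   # uniform prior marginal: PESS = 2
#' @export
priorPESS <- function(hyper, dose = 1L) {
  stopifnot(inherits(hyper, "dlmHyper"), dose %in% 1:2)
  th <- hyper$theta; s1 <- hyper$sigma1
  if (dose == 1L) {
    V <- s1^2
    m <- pnorm(th / sqrt(1 + V))
    Ep2 <- .ephisq(th, V)
  } else {
    nodes <- .hcNodes(512L, hyper$xi, hyper$tau)
    V <- s1^2 + nodes$s^2
    m <- drop(pnorm(th / sqrt(1 + V)) %*% nodes$w)
    Ep2 <- drop(vapply(V, .ephisq, numeric(1), theta = th) %*% nodes$w)
  }
  v <- Ep2 - m^2
  if (v >= m * (1 - m)) {
    warning("degenerate prior variance: v >= m(1 - m); PESS reported as 0")
    pess <- 0
    a <- b <- NA_real_
  } else {
    pess <- m * (1 - m) / v - 1
    a <- m * pess; b <- (1 - m) * pess
  }
  structure(round(pess, 2), mean = m, var = v, shape1 = a, shape2 = b)
}

# E[Phi(X)^2] for X ~ N(theta, V), by trapezoid over a wide standard grid
.ephisq <- function(theta, V) {
  z <- seq(-8, 8, length.out = 2001L)
  w <- dnorm(z); w <- w / sum(w)
  sum(w * pnorm(theta + sqrt(V) * z)^2)
}

#' Serialize a posterior outcome table as CSV
#'
#' Writes the posterior summaries for every outcome pair `(y1, y2)` at
#' sample sizes `(n1, n2)` — the cache that drives enumeration and
#' simulation — in long format with columns `y1, n1, y2, n2,
#' pr_exceed_1, pr_exceed_2, pp_ni, post_mean_1, post_mean_2`.
#'
#' @param n1,n2 per-dose sample sizes.
#' @param hyper a [dlmHyper()].
#' @param p0 historical control rate.
#' @param delta1 noninferiority margin.
#' @param path output CSV path.
#' @param settings a [dlmSettings()].
#' @return Invisibly, the data frame written.
#' @export
writePosteriorGrid <- function(n1, n2, hyper, p0, delta1, path,
                               settings = dlmSettings()) {
  g <- .dlmGrid(n1, n2, hyper, p0, delta1, settings)
  yy <- expand.grid(y1 = 0:n1, y2 = 0:n2)
  ix <- as.matrix(yy) + 1L
  df <- data.frame(y1 = yy$y1, n1 = n1, y2 = yy$y2, n2 = n2,
                   pr_exceed_1 = g$pr1[ix], pr_exceed_2 = g$pr2[ix],
                   pp_ni = g$ppni[ix],
                   post_mean_1 = g$pm1[ix], post_mean_2 = g$pm2[ix])
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
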