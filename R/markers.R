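# Per-gene negative-binomial dispersion by adjusted method of moments,
# shrunk toward a lowess mean-dispersion trend. Fitted means come from
# the design groups (cluster x batch cells), so systematic differences
# are not absorbed into the dispersion, and the residual sum is scaled
# by n/(n - #groups) to offset fitting losses. `off` is the
# multiplicative offset (effective library size).
estimate_dispersions <- function(y, off, groups = NULL, prior_weight = 20) {
  G <- nrow(y)
  n <- ncol(y)
  if (is.null(groups)) groups <- rep(1L, n)
  groups <- as.integer(factor(groups))
  ngrp <- max(groups)
  rate <- rowSums(y) / sum(off)
  grp_y <- t(rowsum(t(y), groups))          # gene x group sums
  grp_off <- as.numeric(rowsum(off, groups))
  grp_rate <- sweep(grp_y, 2, grp_off, "/") # gene x group rates
  mu <- grp_rate[, groups, drop = FALSE] *
    rep(off, each = G)
  adj <- n / max(1, n - ngrp)
  raw <- vapply(seq_len(G), function(g) {
    m <- mu[g, ]
    num <- adj * sum((y[g, ] - m)^2 - m)
    den <- sum(m^2)
    if (den == 0) return(NA_real_)
    max(num / den, 1e-4)
  }, numeric(1))
  ok <- !is.na(raw) & rate > 0
  if (sum(ok) >= 10) {
    lm <- log(rate[ok]); ld <- log(raw[ok])
    tr <- lowess(lm, ld, f = 0.5)
    trend <- exp(approx(tr$x, tr$y, xout = log(pmax(rate, min(rate[ok]))),
                        rule = 2, ties = mean)$y)
  } else {
    trend <- rep(exp(mean(log(raw[ok])) %||% log(0.1)), G)
  }
  n <- ncol(y)
  w <- n / (n + prior_weight)
  disp <- exp(w * log(pmax(raw, 1e-4)) + (1 - w) * log(trend))
  disp[is.na(disp)] <- trend[is.na(disp)]
  pmax(disp, 1e-4)
}

nb_fit_dev <- function(X, y, off_log, disp) {
  fam <- MASS::negative.binomial(theta = 1 / disp)
  fit <- suppressWarnings(glm.fit(X, y, family = fam, offset = off_log))
  fit
}

#' Cluster marker testing by negative-binomial likelihood-ratio tests
#'
#' For each cluster, each gene is modeled as NB counts with a log-linear
#' predictor `~ in_cluster + batch` and offset `log(theta_c * nbar)`
#' (size factor times the mean library size). Gene-wise dispersions are
#' method-of-moments estimates shrunk toward a lowess mean-dispersion
#' trend; significance of the cluster term comes from the deviance
#' likelihood-ratio test (1 df), with Benjamini-Hochberg correction per
#' cluster. Clusters with fewer than three cells are skipped with a
#' warning; all-zero genes report `p = 1` and zero fold change.
#'
#' @param counts genes x cells count matrix.
#' @param assignment named cluster ids per cell.
#' @param batch named batch (sample-of-origin) labels per cell.
#' @param theta named size factors per cell.
#' @param clusters clusters to test (default all).
#' @return data.frame with gene, cluster, log2_fold_change, p_value, fdr.
#' @export
test_cluster_markers <- function(counts, assignment, batch = NULL,
                                 theta = NULL, clusters = NULL) {
  bcs <- colnames(counts)
  assignment <- assignment[bcs]
  if (anyNA(assignment)) stop("assignment must cover every cell")
  if (length(unique(assignment)) < 2L) stop("need at least two clusters")
  if (is.null(theta)) theta <- setNames(rep(1, length(bcs)), bcs)
  off <- theta[bcs] * mean(col_totals(counts))
  off_log <- log(off)
  y <- as.matrix(counts)
  disp_groups <- if (is.null(batch)) assignment else {
    paste(assignment, batch[bcs])
  }
  disp <- estimate_dispersions(y, off, groups = disp_groups)
  clusters <- clusters %||% sort(unique(assignment))
  batch_f <- if (!is.null(batch) && length(unique(batch[bcs])) > 1L) {
    factor(batch[bcs])
  } else NULL
  out <- list()
  for (k in clusters) {
    in_k <- as.numeric(assignment == k)
    if (sum(in_k) < 3) {
      warning("cluster ", k, " has fewer than 3 cells; skipped")
      next
    }
    X_null <- if (is.null(batch_f)) {
      matrix(1, length(bcs), 1)
    } else {
      stats::model.matrix(~batch_f)
    }
    X_full <- cbind(X_null, in_k = in_k)
    G <- nrow(y)
    lfc <- numeric(G); pv <- rep(1, G)
    for (g in seq_len(G)) {
      yy <- y[g, ]
      if (all(yy == 0)) next
      f1 <- nb_fit_dev(X_full, yy, off_log, disp[g])
      f0 <- nb_fit_dev(X_null, yy, off_log, disp[g])
      stat <- max(0, f0$deviance - f1$deviance)
      pv[g] <- pchisq(stat, df = 1, lower.tail = FALSE)
      lfc[g] <- f1$coefficients[["in_k"]] / log(2)
    }
    out[[as.character(k)]] <- data.frame(gene = rownames(y),
                                         cluster = k,
                                         log2_fold_change = lfc,
                                         p_value = pv,
                                         fdr = p.adjust(pv, "BH"))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Select genes enriched in at least one cluster
#'
#' A gene passes when its highest cluster-aggregated expression is at
#' least `fold_min` times the mean of the remaining clusters (with a
#' 1-UPM pseudocount in the denominator) and reaches `min_expr`.
#'
#' @param profile genes x clusters UPM matrix.
#' @param fold_min minimum fold enrichment (default 4).
#' @param min_expr minimum peak expression in UPM.
#' @return character vector of enriched genes.
#' @export
select_enriched_genes <- function(profile, fold_min = 4, min_expr = 0) {
  if (ncol(profile) < 2L) stop("need at least two clusters")
  sel <- apply(profile, 1, function(v) {
    i <- which.max(v)
    v[i] >= fold_min * (mean(v[-i]) + 1) && v[i] >= min_expr
  })
  rownames(profile)[sel]
}

#' Region-enrichment filter for bulk abundance tables
#'
#' Keeps genes whose peak regional abundance is at least `2^lfc_min`
#' times the per-gene median over regions (0.1-ppm pseudocount on both)
#' and at least `min_ppm` in the peak region.
#'
#' @param bulk_ppm genes x regions abundance matrix in parts per million.
#' @param lfc_min minimum log2 fold change versus the median (default 2).
#' @param min_ppm minimum peak abundance (default 20 ppm).
#' @param pseudo pseudocount in ppm.
#' @return character vector of region-enriched genes.
#' @export
select_region_enriched_bulk <- function(bulk_ppm, lfc_min = 2,
                                        min_ppm = 20, pseudo = 0.1) {
  mx <- apply(bulk_ppm, 1, max)
  md <- apply(bulk_ppm, 1, median)
  lfc <- log2((mx + pseudo) / (md + pseudo))
  rownames(bulk_ppm)[lfc >= lfc_min & mx >= min_ppm]
}

nb_loglik_weighted <- function(x, w, mu, size) {
  sum(w * dnbinom(x, size = size, mu = mu, log = TRUE))
}

#' Fit a zero-inflated negative binomial by expectation-maximization
#'
#' Models a gene's counts in a cluster as a mixture of structural zeros
#' (weight `pi`) and NB(mu, size) sampling, `P(x) = pi * 1[x=0] +
#' (1 - pi) * NB(x; mu, size)`. The E-step computes each zero's posterior
#' probability of being structural; the M-step updates `pi` as the mean
#' posterior and re-fits the NB on posterior weights (closed-form mean,
#' 1-D likelihood optimization for the size). Iteration stops when the
#' log-likelihood improves by less than `tol` or after `max_iter` rounds;
#' the log-likelihood is non-decreasing throughout. The expressing
#' fraction is `1 - pi`; `mean_positive` is the mean over cells whose
#' posterior-majority component is the NB and whose count is positive.
#'
#' @param x nonnegative integer counts (>= 20 observations advised).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return a `zinb_fit` list: `pi_zero`, `mu`, `size`, `frac_expressing`,
#'   `mean_positive`, `loglik` (trace), `converged`, `all_zero`.
#' @export
fit_zinb <- function(x, tol = 1e-8, max_iter = 500L) {
  stopifnot(all(x >= 0))
  n <- length(x)
  if (all(x == 0)) {
    return(structure(list(pi_zero = 1, mu = 0, size = 1,
                          frac_expressing = 0, mean_positive = 0,
                          loglik = numeric(0), converged = TRUE,
                          all_zero = TRUE),
                     class = "zinb_fit"))
  }
  zero <- x == 0
  pi0 <- max(min(mean(zero) * 0.5, 0.95), 1e-4)
  mu <- mean(x[!zero])
  v <- var(x[!zero]) %||% mu
  size <- if (!is.na(v) && v > mu) mu^2 / (v - mu) else 10
  size <- min(max(size, 1e-3), 1e4)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  z <- numeric(n)
  for (it in seq_len(max_iter)) {
    p0 <- dnbinom(0, size = size, mu = mu)
    z[] <- 0
    z[zero] <- pi0 / (pi0 + (1 - pi0) * p0)
    pi0 <- max(mean(z), 1e-10)
    w <- 1 - z
    mu <- sum(w * x) / sum(w)
    opt <- optimize(function(ls) nb_loglik_weighted(x, w, mu, exp(ls)),
                    interval = c(log(1e-3), log(1e4)), maximum = TRUE)
    size <- exp(opt$maximum)
    dens <- (1 - pi0) * dnbinom(x, size = size, mu = mu)
    dens[zero] <- dens[zero] + pi0
    ll <- sum(log(pmax(dens, 1e-300)))
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol && it > 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  nb_member <- z < 0.5
  mp <- if (any(nb_member & x > 0)) mean(x[nb_member & x > 0]) else 0
  structure(list(pi_zero = pi0, mu = mu, size = size,
                 frac_expressing = 1 - pi0, mean_positive = mp,
                 loglik = ll_trace, converged = converged,
                 all_zero = FALSE),
            class = "zinb_fit")
}
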