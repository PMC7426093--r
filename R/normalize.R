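# Ring ordering used for pooling: cells sorted by library size, odd ranks
# walked forward and even ranks walked back, so any window of the ring
# mixes small and large libraries.
ring_order <- function(totals) {
  n <- length(totals)
  ord <- order(totals)
  c(ord[seq(1, n, by = 2)], rev(ord[seq.int(2, length.out = n %/% 2, by = 2)]))
}

# Build and solve the pooled-deconvolution linear system for one group.
solve_group_factors <- function(sub, ref, pool_sizes, anchor_weight) {
  n <- ncol(sub)
  totals <- colSums(sub)
  ring <- ring_order(totals)
  sizes <- unique(pmin(pool_sizes, n))
  rows_i <- list(); rows_j <- list(); rhs <- numeric(0)
  use <- ref > 0
  eq <- 0L
  for (s in sizes) {
    for (start in seq_len(n)) {
      members <- ring[((start - 1L + 0:(s - 1L)) %% n) + 1L]
      v <- rowSums(sub[, members, drop = FALSE])
      m_pool <- median(v[use] / ref[use])
      eq <- eq + 1L
      rows_i[[eq]] <- rep.int(eq, s)
      rows_j[[eq]] <- members
      rhs <- c(rhs, m_pool)
    }
  }
  # low-weight anchor equations theta_c ~ lib_c / mean(lib) fix the scale
  anchor <- totals / mean(totals)
  A <- Matrix::sparseMatrix(i = c(unlist(rows_i), eq + seq_len(n)),
                            j = c(unlist(rows_j), seq_len(n)),
                            x = c(rep(1, sum(lengths(rows_j))),
                                  rep(anchor_weight, n)),
                            dims = c(eq + n, n))
  b <- c(rhs, anchor_weight * anchor)
  th <- as.numeric(Matrix::solve(Matrix::crossprod(A),
                                 Matrix::crossprod(A, b)))
  if (any(th <= 0)) {
    smallest <- if (any(th > 0)) min(th[th > 0]) else 1
    warning("non-positive deconvolved size factors clamped")
    th[th <= 0] <- smallest * 1e-3
  }
  th
}

#' Pooled-deconvolution size factors within broad populations
#'
#' Size factors are estimated by pooling and deconvolution, separately
#' within each broad cell population so composition differences between
#' populations do not bias the estimates. Only the top `top_expr_fraction`
#' of genes by mean count across all cells enter the estimation. Within a
#' population, cells are arranged on a ring ordered by library size;
#' overlapping windows of several sizes form pools, and each pool's summed
#' profile is compared with the population average profile (median ratio
#' over the retained genes) to yield one linear equation in the member
#' cells' factors. The overdetermined system, plus low-weight anchor
#' equations tying each factor to the cell's relative library size, is
#' solved by least squares. Finally each population's factors are rescaled
#' so its mean factor equals the ratio of its mean library size to the
#' global mean, making factors comparable across populations. Populations
#' with fewer than `min_group_size` cells fall back to library-size
#' factors with a warning.
#'
#' @param counts genes x barcodes count matrix.
#' @param broad_labels named character vector, population per barcode.
#' @param top_expr_fraction fraction of genes (by mean expression) used.
#' @param pool_sizes window sizes for pooling (capped at the group size).
#' @param anchor_weight weight of the library-size anchor equations.
#' @param min_group_size below this, a population uses library-size factors.
#' @return named numeric vector of positive size factors, one per cell.
#' @export
compute_pooled_size_factors <- function(counts, broad_labels,
                                        top_expr_fraction = 0.2,
                                        pool_sizes = c(21, 41, 61, 81, 101),
                                        anchor_weight = 0.1,
                                        min_group_size = 20L) {
  stopifnot(top_expr_fraction > 0, top_expr_fraction <= 1)
  bcs <- colnames(counts)
  broad_labels <- broad_labels[bcs]
  if (anyNA(broad_labels)) stop("broad_labels must cover every barcode")
  gm <- row_means(counts)
  ntop <- max(1L, ceiling(top_expr_fraction * nrow(counts)))
  top <- order(gm, decreasing = TRUE)[seq_len(ntop)]
  totals <- col_totals(counts)
  theta <- setNames(numeric(length(bcs)), bcs)
  for (g in unique(broad_labels)) {
    cells <- bcs[broad_labels == g]
    sub <- as.matrix(counts[top, cells, drop = FALSE])
    if (length(cells) < min_group_size) {
      warning("population '", g, "' has fewer than ", min_group_size,
              " cells; using library-size factors")
      th <- totals[cells] / mean(totals[cells])
    } else {
      ref <- rowMeans(sub)
      th <- solve_group_factors(sub, ref, pool_sizes, anchor_weight)
    }
    th <- th / mean(th) * (mean(totals[cells]) / mean(totals))
    theta[cells] <- th
  }
  theta
}

#' Order-of-magnitude size-factor band filter
#'
#' Keeps cells whose size factor differs from the mean factor by less
#' than one order of magnitude: `0.1 * mean(theta) < theta_c <
#' 10 * mean(theta)`, strict at both bounds. The mean is taken over all
#' input cells and the filter is applied once, not iterated.
#'
#' @param theta named numeric size factors.
#' @return character vector of retained cell barcodes.
#' @export
filter_by_size_factor <- function(theta) {
  m <- mean(theta)
  names(theta)[theta > 0.1 * m & theta < 10 * m]
}

#' Convert normalized counts to per-cell gene fractions
#'
#' Each cell's counts are divided by its size factor and then rescaled to
#' sum to one: `x_gc = (counts_gc / theta_c) / sum_g(counts_gc / theta_c)`.
#' Note the factor cancels algebraically in the fraction itself; it is
#' retained in the interface because the same factors drive the band
#' filter and model offsets elsewhere.
#'
#' @param counts genes x barcodes count matrix (retained cells only).
#' @param theta named size factors covering the columns.
#' @return dense or sparse matrix of gene fractions; columns sum to 1.
#' @export
to_gene_fractions <- function(counts, theta) {
  bcs <- colnames(counts)
  th <- theta[bcs]
  if (anyNA(th)) stop("size factors missing for some cells")
  norm <- sweep_cols(counts, 1 / th)
  tot <- col_totals(norm)
  if (any(tot == 0)) stop("zero-total cell encountered; filter cells first")
  sweep_cols(norm, 1 / tot)
}

sweep_cols <- function(m, f) {
  if (inherits(m, "Matrix")) {
    out <- m %*% Matrix::Diagonal(x = f, names = FALSE)
    dimnames(out) <- dimnames(m)
    out
  } else {
    sweep(m, 2, f, "*")
  }
}
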