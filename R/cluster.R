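#' Select highly variable genes by coefficient of variation
#'
#' Genes are ranked by CV = sd/mean over cells, computed on the supplied
#' matrix (raw counts for the first clustering round, gene fractions for
#' the second). Zero-mean genes are excluded; the top
#' `ceiling(top_fraction * G)` genes are returned (fewer if not enough
#' genes have nonzero mean).
#'
#' @param mat genes x cells matrix.
#' @param top_fraction fraction of the gene universe to keep, in (0, 1].
#' @return character vector of selected gene identifiers.
#' @export
select_variable_genes <- function(mat, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  m <- row_means(mat)
  dense <- as.matrix(mat)
  sds <- apply(dense, 1, sd)
  cv <- ifelse(m > 0, sds / m, -Inf)
  ntop <- min(ceiling(top_fraction * nrow(mat)), sum(m > 0))
  rownames(mat)[order(-cv, seq_along(cv))[seq_len(ntop)]]
}

#' PCA keeping the minimal components that explain a variance share
#'
#' Cells are observations and (variable) genes are centered features. The
#' smallest number of leading principal components whose cumulative share
#' of variance strictly exceeds `variance_threshold` is retained.
#'
#' @param mat genes x cells matrix (typically the variable-gene submatrix).
#' @param variance_threshold share of variance to exceed, in [0, 1).
#' @return cells x PCs score matrix; attribute `explained` holds the
#'   per-component variance shares.
#' @export
run_pca <- function(mat, variance_threshold = 0.85) {
  stopifnot(variance_threshold >= 0, variance_threshold < 1)
  x <- t(as.matrix(mat))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  npc <- which(cumsum(shares) > variance_threshold)[1]
  if (is.na(npc)) npc <- length(shares)
  npc <- max(1L, npc)
  out <- pc$x[, seq_len(npc), drop = FALSE]
  attr(out, "explained") <- shares
  out
}

#' Deterministic t-SNE embedding of PCA scores
#'
#' Two-dimensional Barnes-Hut t-SNE with a fixed seed; duplicates are
#' permitted and no internal PCA is applied, matching a pipeline where
#' dimensionality was already reduced.
#'
#' @param pcs cells x PCs matrix.
#' @param perplexity t-SNE perplexity (the run needs at least
#'   `3 * perplexity + 1` cells).
#' @param seed RNG seed; fixed seed gives reproducible coordinates.
#' @param ... passed to [Rtsne::Rtsne()].
#' @return cells x 2 coordinate matrix.
#' @export
run_tsne <- function(pcs, perplexity = 30, seed = 1L, ...) {
  n <- nrow(pcs)
  if (n - 1 < 3 * perplexity) {
    stop("too few cells (", n, ") for perplexity ", perplexity,
         "; use a smaller perplexity")
  }
  emb <- with_seed(seed, {
    Rtsne::Rtsne(as.matrix(pcs), dims = 2, perplexity = perplexity,
                 pca = FALSE, check_duplicates = FALSE, ...)$Y
  })
  rownames(emb) <- rownames(pcs)
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

#' Density-peak clustering on a 2-D embedding
#'
#' Implements cluster detection by fast search of density peaks. Local
#' density uses a Gaussian kernel, `rho_i = sum_j exp(-(d_ij/d_c)^2)`,
#' with the cutoff `d_c` set to the `dc_quantile` quantile of all
#' pairwise distances (2% by default, the rule of thumb of the
#' algorithm's authors). `delta_i` is the distance to the nearest point
#' of higher density (for the global density maximum, the largest
#' distance to any point). Centers are the `k` points with the largest
#' `gamma = rho * delta`; every other point joins the cluster of its
#' nearest higher-density neighbor, assignments propagating in order of
#' decreasing density. Density ties are broken by point index.
#'
#' @param embedding cells x 2 coordinate matrix.
#' @param k number of cluster centers to select.
#' @param dc_quantile quantile of pairwise distances defining `d_c`.
#' @return a `cluster_result` list with `rho`, `delta`, `gamma`,
#'   `centers`, `assignment`, `embedding`, `neighbor`.
#' @export
density_peak_cluster <- function(embedding, k, dc_quantile = 0.02) {
  n <- nrow(embedding)
  if (k < 1 || k > n) stop("k must lie in 1..number of cells")
  d <- as.matrix(stats::dist(embedding))
  dc <- quantile(d[upper.tri(d)], dc_quantile, names = FALSE)
  if (dc <= 0) dc <- min(d[d > 0], 1)
  rho <- rowSums(exp(-(d / dc)^2)) - 1  # exclude self term
  # density order with index tie-break: earlier index ranks denser on ties
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  neighbor <- integer(n)
  delta[ord[1]] <- max(d[ord[1], ])
  neighbor[ord[1]] <- NA_integer_
  for (r in seq_len(n)[-1]) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    neighbor[i] <- j
  }
  gamma <- rho * delta
  centers <- order(-gamma, seq_len(n))[seq_len(k)]
  assignment <- integer(n)
  # label centers by decreasing gamma so cluster 1 is the strongest peak
  assignment[centers] <- seq_len(k)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (assignment[i] == 0L) assignment[i] <- assignment[neighbor[i]]
  }
  nm <- rownames(embedding)
  if (!is.null(nm)) {
    names(rho) <- names(delta) <- names(gamma) <- names(assignment) <- nm
  }
  structure(list(rho = rho, delta = delta, gamma = gamma,
                 centers = if (is.null(nm)) centers else nm[centers],
                 assignment = assignment,
                 embedding = embedding,
                 neighbor = neighbor),
            class = "cluster_result")
}

#' Run the reduction-and-clustering chain on a cell subset
#'
#' Applies variable-gene selection, PCA, t-SNE and density-peak
#' clustering to the given cells only, with subset-specific parameters.
#' Used both for the global rounds and for independent re-clustering of
#' each broad population.
#'
#' @param mat genes x cells expression matrix (counts or gene fractions).
#' @param cells barcodes of the subset (default: all columns).
#' @param top_fraction variable-gene fraction.
#' @param variance_threshold PCA cumulative-variance cutoff.
#' @param k number of density-peak centers.
#' @param perplexity t-SNE perplexity.
#' @param seed RNG seed for the embedding.
#' @return a `cluster_result` (see [density_peak_cluster()]).
#' @export
recluster_subset <- function(mat, cells = colnames(mat),
                             top_fraction = 0.15,
                             variance_threshold = 0.95,
                             k = 6L, perplexity = 30, seed = 1L) {
  if (length(cells) < 2L) stop("cell subset too small to cluster")
  sub <- mat[, cells, drop = FALSE]
  genes <- select_variable_genes(sub, top_fraction)
  pcs <- run_pca(sub[genes, , drop = FALSE], variance_threshold)
  emb <- run_tsne(pcs, perplexity = perplexity, seed = seed)
  density_peak_cluster(emb, k)
}

#' Aggregate cluster expression as UMIs per million
#'
#' Per cluster, gene counts are summed over member cells and divided by
#' the cluster's total UMIs, times 1e6, so each column sums to one
#' million.
#'
#' @param counts genes x cells count matrix.
#' @param assignment named cluster ids covering the columns.
#' @return genes x clusters UPM matrix; attribute `n_cells` gives cluster
#'   sizes.
#' @export
aggregate_cluster_expression <- function(counts, assignment) {
  bcs <- colnames(counts)
  assignment <- assignment[bcs]
  if (anyNA(assignment)) stop("assignment must cover every cell")
  ks <- sort(unique(assignment))
  upm <- vapply(ks, function(k) {
    sub <- counts[, bcs[assignment == k], drop = FALSE]
    s <- row_sums(sub)
    tot <- sum(s)
    if (tot == 0) stop("cluster ", k, " has no counts")
    1e6 * as.numeric(s) / tot
  }, numeric(nrow(counts)))
  dimnames(upm) <- list(rownames(counts), as.character(ks))
  attr(upm, "n_cells") <- table(assignment)[as.character(ks)]
  upm
}
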