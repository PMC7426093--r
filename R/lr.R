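#' Read a ligand-receptor pair table
#'
#' Two-column CSV with header `ligand,receptor`; duplicate pairs are
#' dropped.
#'
#' @param path CSV file path.
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    stop_format("ligand-receptor table needs 'ligand' and 'receptor' columns")
  }
  unique(df[, c("ligand", "receptor")])
}

#' Filter ligand-receptor genes by population expression breadth
#'
#' A ligand or receptor is retained when at least `min_fraction` of the
#' cells of at least one population have a nonzero count for it
#' (inclusive threshold); a pair is retained when both ends survive.
#'
#' @param lr_pairs data.frame with `ligand`, `receptor` columns.
#' @param counts genes x cells count matrix.
#' @param assignment named population labels per cell.
#' @param min_fraction expression-breadth threshold (default 0.2).
#' @return list with `ligands`, `receptors` (retained gene vectors) and
#'   `pairs` (retained pair table).
#' @export
filter_lr_genes <- function(lr_pairs, counts, assignment,
                            min_fraction = 0.2) {
  bcs <- colnames(counts)
  assignment <- assignment[bcs]
  genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  genes <- intersect(genes, rownames(counts))
  pops <- sort(unique(assignment))
  frac <- vapply(pops, function(p) {
    sub <- counts[genes, bcs[assignment == p], drop = FALSE]
    row_sums(sub > 0) / sum(assignment == p)
  }, numeric(length(genes)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = length(genes))
  expressed <- genes[apply(frac, 1, max) >= min_fraction]
  pairs <- lr_pairs[lr_pairs$ligand %in% expressed &
                      lr_pairs$receptor %in% expressed, , drop = FALSE]
  list(ligands = intersect(unique(lr_pairs$ligand), expressed),
       receptors = intersect(unique(lr_pairs$receptor), expressed),
       pairs = pairs)
}

#' Group ligand (or receptor) expression profiles by k-means
#'
#' Genes' per-population aggregated profiles are row-normalized to sum to
#' one and clustered by k-means (multi-restart, best within-cluster sum
#' of squares, fixed seed). Each k-means cluster is labeled by the
#' population where its centroid peaks (ties to the earlier population
#' column); clusters sharing a label are merged, so the final groups are
#' named by population and there may be fewer than `k`.
#'
#' @param upm genes x populations aggregated expression matrix.
#' @param k number of k-means clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return named character vector: population-label group per gene.
#' @export
group_lr_profiles <- function(upm, k, seed = 1L, nstart = 50L) {
  if (k > nrow(upm)) stop("k exceeds the number of genes")
  rs <- rowSums(upm)
  prof <- upm
  prof[rs > 0, ] <- upm[rs > 0, , drop = FALSE] / rs[rs > 0]
  km <- with_seed(seed, kmeans(prof, centers = k, nstart = nstart,
                               iter.max = 100L))
  lab <- colnames(upm)[apply(km$centers, 1, which.max)]
  setNames(lab[km$cluster], rownames(upm))
}

#' Count ligand-receptor connections between gene groups
#'
#' Entry (A, B) is the number of retained pairs whose ligand belongs to
#' group A and whose receptor belongs to group B; the total over the
#' matrix equals the number of retained pairs.
#'
#' @param groups_l named group labels for every retained ligand.
#' @param groups_r named group labels for every retained receptor.
#' @param pairs retained pair table.
#' @return ligand-group x receptor-group integer matrix.
#' @export
count_connections <- function(groups_l, groups_r, pairs) {
  un_l <- setdiff(pairs$ligand, names(groups_l))
  un_r <- setdiff(pairs$receptor, names(groups_r))
  if (length(un_l) || length(un_r)) {
    stop("unassigned gene(s): ", paste(c(un_l, un_r), collapse = ", "))
  }
  la <- sort(unique(groups_l))
  ra <- sort(unique(groups_r))
  m <- matrix(0L, length(la), length(ra), dimnames = list(la, ra))
  if (nrow(pairs)) {
    tab <- table(factor(groups_l[pairs$ligand], levels = la),
                 factor(groups_r[pairs$receptor], levels = ra))
    m[] <- as.integer(tab)
  }
  m
}

#' Hypergeometric enrichment of ligand-receptor connections
#'
#' For every (ligand group A, receptor group B) cell of the connection
#' matrix, the observed pair count is compared with the count expected by
#' chance given the margins: drawing `n` pairs (column total of B) from a
#' population of `N` pairs (matrix total) containing `K` successes (row
#' total of A), upper-tail hypergeometric. Significance is called at raw
#' `p < alpha`; optional Benjamini-Hochberg correction is off by default,
#' matching the convention of reporting raw p-values.
#'
#' @param connections ligand-group x receptor-group count matrix.
#' @param alpha significance level (default 0.01).
#' @param adjust apply BH correction before calling significance.
#' @return data.frame: ligand_group, receptor_group, observed_pairs,
#'   expected_pairs, p_value, significant.
#' @export
test_interactions <- function(connections, alpha = 0.01, adjust = FALSE) {
  N <- sum(connections)
  rows <- rownames(connections) %||% as.character(seq_len(nrow(connections)))
  cols <- colnames(connections) %||% as.character(seq_len(ncol(connections)))
  rt <- rowSums(connections)
  ct <- colSums(connections)
  out <- expand.grid(ligand_group = rows, receptor_group = cols,
                     stringsAsFactors = FALSE)
  out$observed_pairs <- as.vector(connections)
  if (N == 0) {
    out$expected_pairs <- 0
    out$p_value <- 1
  } else {
    K <- rt[out$ligand_group]
    n <- ct[out$receptor_group]
    out$expected_pairs <- as.numeric(K * n / N)
    out$p_value <- phyper(out$observed_pairs - 1, K, N - K, n,
                          lower.tail = FALSE)
  }
  pv <- if (adjust) p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- pv < alpha
  out
}

#' Hypergeometric test for cell-type enrichment in samples
#'
#' Tests over-representation of each cell type in each sample: from all
#' cells (`N`), of which `K` are of the type, a sample of size `n` is
#' drawn; the upper-tail probability of observing at least the actual
#' overlap is reported.
#'
#' @param assignment named cell-type labels per cell.
#' @param sample_labels named sample labels over the same cells.
#' @return data.frame: cell_type, sample, observed, expected, p_value.
#' @export
test_composition_enrichment <- function(assignment, sample_labels) {
  cells <- names(assignment)
  sample_labels <- sample_labels[cells]
  if (anyNA(sample_labels)) stop("sample labels must cover every cell")
  N <- length(cells)
  out <- expand.grid(cell_type = sort(unique(assignment)),
                     sample = sort(unique(sample_labels)),
                     stringsAsFactors = FALSE)
  out$observed <- mapply(function(tt, s) {
    sum(assignment == tt & sample_labels == s)
  }, out$cell_type, out$sample)
  K <- vapply(out$cell_type, function(tt) sum(assignment == tt), numeric(1))
  n <- vapply(out$sample, function(s) sum(sample_labels == s), numeric(1))
  out$expected <- K * n / N
  out$p_value <- phyper(out$observed - 1, K, N - K, n, lower.tail = FALSE)
  out
}

#' End-to-end ligand-receptor interaction inference
#'
#' Runs the full chain: expression-breadth filter, per-population
#' aggregation of the retained genes, separate k-means grouping of
#' ligands and receptors (defaults k = 13 and k = 14), connection
#' counting and hypergeometric testing.
#'
#' @param lr_pairs pair table.
#' @param counts genes x cells count matrix.
#' @param assignment named population labels.
#' @param k_ligand,k_receptor k-means sizes for the two gene classes.
#' @param min_fraction expression-breadth threshold.
#' @param alpha significance level.
#' @param seed RNG seed for k-means.
#' @return list with `filtered`, `groups_ligand`, `groups_receptor`,
#'   `connections`, `interactions`.
#' @export
infer_lr_network <- function(lr_pairs, counts, assignment,
                             k_ligand = 13L, k_receptor = 14L,
                             min_fraction = 0.2, alpha = 0.01, seed = 1L) {
  flt <- filter_lr_genes(lr_pairs, counts, assignment, min_fraction)
  if (nrow(flt$pairs) == 0L) stop("no ligand-receptor pairs survive the filter")
  upm <- aggregate_cluster_expression(counts, assignment)
  gl <- group_lr_profiles(upm[flt$ligands, , drop = FALSE],
                          k = min(k_ligand, length(flt$ligands)), seed = seed)
  gr <- group_lr_profiles(upm[flt$receptors, , drop = FALSE],
                          k = min(k_receptor, length(flt$receptors)),
                          seed = seed + 1L)
  conn <- count_connections(gl, gr, flt$pairs)
  list(filtered = flt, groups_ligand = gl, groups_receptor = gr,
       connections = conn,
       interactions = test_interactions(conn, alpha = alpha))
}
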