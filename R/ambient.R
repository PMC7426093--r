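#' Call valid cells by total UMI thresholds
#'
#' A barcode is a valid cell when its total UMI count over known genes
#' lies between `min_umis` and `max_umis`, bounds inclusive.
#'
#' @param counts genes x barcodes count matrix.
#' @param min_umis,max_umis inclusive bounds (defaults 350 and 15,000).
#' @return character vector of valid-cell barcodes.
#' @export
call_cells <- function(counts, min_umis = 350, max_umis = 15000) {
  tot <- col_totals(counts)
  colnames(counts)[tot >= min_umis & tot <= max_umis]
}

#' Select empty droplets per sample by total-UMI range
#'
#' Empty droplets carry ambient RNA only; they are picked per sample as
#' barcodes whose totals fall inside a sample-specific inclusive range
#' (e.g. caput 20--175, vas deferens 20--115).
#'
#' @param counts genes x barcodes count matrix.
#' @param sample_of named character vector, sample label per barcode.
#' @param range_per_sample named list of `c(lo, hi)` per sample.
#' @return character vector of empty-droplet barcodes.
#' @export
select_empty_droplets <- function(counts, sample_of, range_per_sample) {
  bcs <- colnames(counts)
  missing <- setdiff(unique(sample_of[bcs]), names(range_per_sample))
  if (length(missing)) {
    stop_config("no empty-droplet range configured for sample(s): %s",
                paste(missing, collapse = ", "))
  }
  tot <- col_totals(counts)
  keep <- vapply(bcs, function(b) {
    r <- range_per_sample[[sample_of[b]]]
    tot[b] >= r[1] && tot[b] <= r[2]
  }, logical(1))
  bcs[keep]
}

#' Estimate the ambient ("soup") expression profile
#'
#' The soup profile is the pooled gene-fraction vector of the selected
#' empty droplets: summed counts per gene divided by the pooled total.
#'
#' @param counts genes x barcodes count matrix.
#' @param empty barcodes of the empty droplets (nonempty).
#' @return per-gene fraction vector summing to 1.
#' @export
estimate_soup_profile <- function(counts, empty) {
  if (length(empty) == 0L) stop("empty-droplet set is empty")
  sub <- counts[, empty, drop = FALSE]
  s <- row_sums(sub)
  tot <- sum(s)
  if (tot == 0) stop("empty droplets contain no counts")
  p <- as.numeric(s) / tot
  names(p) <- rownames(counts)
  p
}

# Mode of an integer histogram. The raw histogram of empty-droplet
# totals is noisy, so the argmax is taken on a short running-mean
# smoothing of the binned totals (window `smooth`); exact ties on the
# smoothed counts fall back to the raw counts, then to the smaller value
# (conservative removal downstream), with a warning.
integer_mode <- function(x, smooth = 5L) {
  vals <- seq(min(x), max(x))
  cnt <- tabulate(x - min(x) + 1L, nbins = length(vals))
  half <- smooth %/% 2L
  sm <- as.numeric(stats::filter(c(rep(0, half), cnt, rep(0, half)),
                                 rep(1 / smooth, smooth), sides = 2))
  sm <- sm[half + seq_along(cnt)]
  top <- which(sm >= max(sm) - 1e-12)
  if (length(top) > 1L) {
    raw_top <- top[cnt[top] == max(cnt[top])]
    if (length(raw_top) > 1L) {
      warning("multimodal empty-droplet UMI histogram; using smallest mode")
    }
    top <- raw_top
  }
  as.integer(vals[top[1]])
}

#' Estimate per-sample soup models and per-cell contamination fractions
#'
#' The contamination level of every droplet in a sample is taken to be a
#' fixed budget of `m` ambient UMIs, where `m` is the most frequent
#' total-UMI count among that sample's empty droplets. A valid cell with
#' `n_c` total UMIs then has contamination fraction
#' `rho_c = min(1, m / n_c)` -- the same absolute contamination expected
#' in cell-containing droplets.
#'
#' @param counts genes x barcodes count matrix.
#' @param sample_of named character vector, sample label per barcode.
#' @param empty empty-droplet barcodes.
#' @param valid valid-cell barcodes.
#' @return a `soup_model`: per-sample `soup_profile` (list of fraction
#'   vectors), `modal_empty_umis` (named integer), and `rho_per_cell`
#'   (named numeric over `valid`).
#' @export
estimate_rho <- function(counts, sample_of, empty, valid) {
  if (length(empty) == 0L || length(valid) == 0L) {
    stop("need nonempty empty-droplet and valid-cell sets")
  }
  samples <- sort(unique(sample_of[c(empty, valid)]))
  tot <- col_totals(counts)
  profiles <- list()
  modes <- integer(0)
  for (s in samples) {
    es <- empty[sample_of[empty] == s]
    if (length(es) == 0L) stop("sample ", s, " has no empty droplets")
    profiles[[s]] <- estimate_soup_profile(counts, es)
    modes[s] <- integer_mode(as.integer(round(tot[es])))
  }
  rho <- pmin(1, modes[sample_of[valid]] / tot[valid])
  names(rho) <- valid
  structure(list(soup_profile = profiles,
                 modal_empty_umis = modes,
                 rho_per_cell = rho),
            class = "soup_model")
}

# Greedy ambient removal for one cell: clamped expected subtraction, then
# one-at-a-time removal from the largest soup-excess ratio.
adjust_cell <- function(y, soup, rho) {
  n <- sum(y)
  target <- round(rho * n)
  if (target <= 0) return(y)
  e <- rho * n * soup
  rem <- pmin(y, round(e))
  removed <- sum(rem)
  y2 <- y - rem
  # residual expected soup drives the one-at-a-time phase: a gene stops
  # being attractive once its removals have consumed its expected soup
  while (removed < target && sum(y2) > 0) {
    ratio <- (e - (y - y2)) / (y2 + 1)
    ratio[y2 == 0] <- -Inf
    g <- which.max(ratio)
    y2[g] <- y2[g] - 1
    removed <- removed + 1
  }
  y2
}

#' Remove ambient counts from valid cells
#'
#' For each cell `c` with contamination fraction `rho_c` and total `n_c`,
#' a removal target `T_c = round(rho_c * n_c)` is set; the expected soup
#' count of gene `g` is `e_gc = rho_c * n_c * soup_g`. First
#' `min(count, round(e_gc))` is subtracted per gene; any remaining budget
#' is then removed one count at a time from the gene with the largest
#' soup-excess ratio `e_gc / (remaining count + 1)`, until the target is
#' met or nothing removable is left. Output counts are integral and never
#' below zero nor above the raw counts.
#'
#' @param counts genes x barcodes count matrix.
#' @param soup a `soup_model` from [estimate_rho()].
#' @param sample_of named character vector, sample label per barcode.
#' @return adjusted count matrix over the cells in the soup model.
#' @export
adjust_counts <- function(counts, soup, sample_of) {
  stopifnot(inherits(soup, "soup_model"))
  cells <- names(soup$rho_per_cell)
  out <- as.matrix(counts[, cells, drop = FALSE])
  for (i in seq_along(cells)) {
    b <- cells[i]
    prof <- soup$soup_profile[[sample_of[b]]]
    out[, i] <- adjust_cell(out[, i], prof, soup$rho_per_cell[b])
  }
  as_sparse(out)
}
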