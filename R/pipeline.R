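#' Read a Matrix-Market count triplet directory
#'
#' Expects `matrix.mtx` (coordinate format, genes x barcodes),
#' `barcodes.tsv` and `features.tsv` in `dir`. Dimensions announced in
#' the matrix header must match the sidecar files; a truncated or
#' malformed matrix raises a format error naming the offending line.
#'
#' @param dir directory containing the triplet.
#' @return sparse genes x barcodes count matrix with dimnames.
#' @export
read_mtx_triplet <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bcf <- file.path(dir, "barcodes.tsv")
  ftf <- file.path(dir, "features.tsv")
  for (f in c(mtx, bcf, ftf)) {
    if (!file.exists(f)) stop_format("missing file: %s", f)
  }
  lines <- readLines(mtx)
  body <- which(!startsWith(lines, "%"))
  if (length(body) < 1L) stop_format("%s: no size line found", mtx)
  hdr <- scan(text = lines[body[1]], quiet = TRUE)
  if (length(hdr) != 3L) {
    stop_format("%s: malformed size line at line %d", mtx, body[1])
  }
  nnz <- hdr[3]
  if (length(body) - 1L != nnz) {
    stop_format("%s: expected %d entries but found %d (file ends at line %d)",
                mtx, nnz, length(body) - 1L, length(lines))
  }
  m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    stop_format("%s: %s", mtx, conditionMessage(e))
  })
  bcs <- readLines(bcf)
  fts <- read.delim(ftf, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) != nrow(fts) || ncol(m) != length(bcs)) {
    stop_format("matrix is %d x %d but features.tsv has %d rows and barcodes.tsv %d",
                nrow(m), ncol(m), nrow(fts), length(bcs))
  }
  m <- methods::as(m, "generalMatrix")
  dimnames(m) <- list(fts[[1]], bcs)
  as_sparse(m)
}

#' @rdname read_mtx_triplet
#' @param counts genes x barcodes matrix to write.
#' @export
write_mtx_triplet <- function(counts, dir) {
  assert_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(as_sparse(counts), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(rownames(counts), rownames(counts)),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Default pipeline configuration
#'
#' Returns the full parameter block of [run_pipeline()] with the
#' pipeline's defaults: UMI-based cell calling at 350--15,000, per-sample
#' empty-droplet ranges, two clustering rounds (20% CV genes / 85%
#' variance, then 15% / 95%), pooled size factors on the top 20% genes
#' within broad populations, and the ligand-receptor stage parameters.
#'
#' @param ... overrides for any top-level field.
#' @return a named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cell_min_umis = 350, cell_max_umis = 15000,
    empty_ranges = list(),          # per-sample c(lo, hi)
    collapse_reads = TRUE,
    top_fraction_round1 = 0.2, variance_threshold_round1 = 0.85,
    top_fraction_round2 = 0.15, variance_threshold_round2 = 0.95,
    k_broad = 6L, k_fine = 6L, perplexity = 30,
    size_factor_top_fraction = 0.2,
    lr_k_ligand = 13L, lr_k_receptor = 14L,
    lr_min_fraction = 0.2, lr_alpha = 0.01,
    run_markers = FALSE,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_config("unknown pipeline config field(s): %s",
                paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, overrides)
}

file_md5 <- function(path) unname(tools::md5sum(path))

object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  file_md5(f)
}

#' Run the end-to-end decomposition pipeline
#'
#' Executes, in order: optional UMI collapse of a read-level table, cell
#' calling, per-sample empty-droplet selection and soup modeling, ambient
#' count adjustment per sample, merging, a first clustering round on the
#' clean raw matrix yielding broad populations, pooled size factors and
#' the order-of-magnitude band filter, gene-fraction conversion, a second
#' clustering round, per-cluster UPM aggregation, optional marker testing
#' and optional ligand-receptor inference. Every stage is a pure function
#' of its inputs, parameters and the recorded seed; the returned manifest
#' carries checksums of all stage outputs so reruns can be compared.
#'
#' @param counts genes x barcodes raw count matrix (cells and empties),
#'   or NULL when `reads` is given.
#' @param sample_of named sample label per barcode.
#' @param config list from [pipeline_config()].
#' @param reads optional read-level table; collapsed and counted when
#'   `config$collapse_reads` is TRUE.
#' @param lr_pairs optional ligand-receptor pair table; enables the
#'   interaction stage.
#' @param outdir optional directory for stage outputs (CSV/MTX/JSON).
#' @return list of stage results plus `manifest`.
#' @export
run_pipeline <- function(counts = NULL, sample_of, config = pipeline_config(),
                         reads = NULL, lr_pairs = NULL, outdir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  if (!is.null(reads) && isTRUE(config$collapse_reads)) {
    res$reads_collapsed <- stage("collapse", {
      collapse_umis(drop_n_umis(reads))
    })
    counts <- stage("count", reads_to_counts(
      res$reads_collapsed,
      genes = if (is.null(counts)) NULL else rownames(counts),
      barcodes = if (is.null(counts)) NULL else colnames(counts)))
  }
  if (is.null(counts)) stop_config("run_pipeline needs counts or reads")
  assert_count_matrix(counts)
  valid <- stage("call_cells", call_cells(counts, config$cell_min_umis,
                                          config$cell_max_umis))
  if (length(config$empty_ranges) == 0L) {
    stop_config("config$empty_ranges must map every sample to c(lo, hi)")
  }
  empty <- stage("empty_droplets", select_empty_droplets(
    counts, sample_of, config$empty_ranges))
  soup <- stage("soup_model", estimate_rho(counts, sample_of, empty, valid))
  adjusted <- stage("adjust_counts", adjust_counts(counts, soup, sample_of))
  res$valid_cells <- valid
  res$empty_droplets <- empty
  res$soup_model <- soup
  res$adjusted_counts <- adjusted

  round1 <- stage("cluster_round1", recluster_subset(
    adjusted, top_fraction = config$top_fraction_round1,
    variance_threshold = config$variance_threshold_round1,
    k = config$k_broad, perplexity = config$perplexity,
    seed = config$seed))
  broad <- setNames(as.character(round1$assignment), colnames(adjusted))
  res$round1 <- round1
  res$broad_labels <- broad

  theta <- stage("size_factors", compute_pooled_size_factors(
    adjusted, broad, top_expr_fraction = config$size_factor_top_fraction))
  kept <- stage("band_filter", filter_by_size_factor(theta))
  fractions <- stage("gene_fractions", to_gene_fractions(
    adjusted[, kept, drop = FALSE], theta))
  res$size_factors <- theta
  res$kept_cells <- kept
  res$gene_fractions <- fractions

  round2 <- stage("cluster_round2", recluster_subset(
    fractions, top_fraction = config$top_fraction_round2,
    variance_threshold = config$variance_threshold_round2,
    k = config$k_fine, perplexity = config$perplexity,
    seed = config$seed + 1L))
  res$round2 <- round2
  assignment <- setNames(round2$assignment, kept)
  res$assignment <- assignment
  res$upm <- stage("upm", aggregate_cluster_expression(
    adjusted[, kept, drop = FALSE], assignment))

  if (isTRUE(config$run_markers)) {
    res$markers <- stage("markers", test_cluster_markers(
      adjusted[, kept, drop = FALSE], assignment,
      batch = sample_of[kept], theta = theta[kept]))
  }
  if (!is.null(lr_pairs)) {
    res$lr <- stage("lr_network", infer_lr_network(
      lr_pairs, adjusted[, kept, drop = FALSE], assignment,
      k_ligand = config$lr_k_ligand, k_receptor = config$lr_k_receptor,
      min_fraction = config$lr_min_fraction, alpha = config$lr_alpha,
      seed = config$seed + 2L))
  }

  checks <- vapply(c("valid_cells", "empty_droplets", "size_factors",
                     "kept_cells", "assignment"),
                   function(nm) object_checksum(res[[nm]]), character(1))
  manifest <- list(stages = names(res),
                   seed = config$seed,
                   config_checksum = object_checksum(config),
                   output_checksums = as.list(checks),
                   started = format(t0, usetz = TRUE),
                   finished = format(Sys.time(), usetz = TRUE))
  res$manifest <- manifest
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_mtx_triplet(adjusted, file.path(outdir, "adjusted"))
    write.table(data.frame(barcode = names(assignment),
                           cluster = assignment),
                file.path(outdir, "clusters.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    write.table(data.frame(barcode = names(theta), theta = theta),
                file.path(outdir, "size_factors.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [pipeline_config()].
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$empty_ranges)) {
    raw$empty_ranges <- lapply(raw$empty_ranges, function(r) {
      as.numeric(unlist(r))
    })
  }
  do.call(pipeline_config, raw)
}
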