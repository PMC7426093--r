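#' Simulation configuration for synthetic droplet data
#'
#' Builds and validates the parameter set for the synthetic droplet
#' generator. Defaults describe a small but realistic ductal-tissue
#' experiment: six discrete cell types with disjoint marker programs,
#' log-normal library sizes, a shared ambient ("soup") profile mixed into
#' every cell at a known fraction, empty droplets drawn from the soup, and
#' UMI reads carrying rare single-base sequencing errors.
#'
#' @param n_cell_types number of discrete cell types.
#' @param cells_per_type cells simulated per type (scalar, or one count
#'   per type for uneven compositions).
#' @param program_seed optional seed for the expression programs alone;
#'   samples sharing a `program_seed` share gene programs and marker sets
#'   while drawing their own cells (defaults to `seed`).
#' @param n_genes size of the gene universe.
#' @param markers_per_type marker genes per type; marker sets are disjoint.
#' @param marker_fold expected fold elevation of a marker in its own type
#'   relative to all other types (must exceed 1).
#' @param library_size_log_mean,library_size_log_sd parameters of the
#'   log-normal per-cell library-size distribution (natural log scale).
#' @param soup_fraction true per-cell contamination fraction in `[0, 1)`
#'   (ignored when `soup_budget` is set).
#' @param soup_budget optional fixed ambient budget in UMIs per droplet:
#'   every droplet receives about this many soup UMIs regardless of its
#'   size, so a cell's contamination fraction is `soup_budget / library
#'   size` and empty-droplet totals are Poisson around the budget. This
#'   is the contamination model the modal-UMI rho estimator assumes.
#' @param marker_exclusive make markers essentially private to their own
#'   type (background weight scaled by 1e-3), so foreign-marker counts in
#'   other types arise from the soup alone.
#' @param n_empty_droplets number of cell-free droplets.
#' @param empty_umi_mean Poisson mean of empty-droplet total UMIs
#'   (fraction mode; budget mode uses `soup_budget`).
#' @param umi_length UMI length in bases (2--15).
#' @param per_base_error_rate per-base sequencing error probability.
#' @param reads_per_umi_mean mean reads covering each molecule (>= 1).
#' @param sample_name label attached to every barcode of this batch.
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cell_types = 6L,
                       cells_per_type = 100L,
                       n_genes = 1000L,
                       markers_per_type = 20L,
                       marker_fold = 8,
                       library_size_log_mean = log(2500),
                       library_size_log_sd = 0.35,
                       soup_fraction = 0.10,
                       soup_budget = NULL,
                       marker_exclusive = FALSE,
                       n_empty_droplets = 20000L,
                       empty_umi_mean = 100,
                       umi_length = 10L,
                       per_base_error_rate = 0.001,
                       reads_per_umi_mean = 4,
                       sample_name = "sample1",
                       program_seed = NULL,
                       seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              program_seed = if (is.null(program_seed)) NULL
                             else as.integer(program_seed),
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              marker_fold = marker_fold,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              soup_fraction = soup_fraction,
              soup_budget = soup_budget,
              marker_exclusive = isTRUE(marker_exclusive),
              n_empty_droplets = as.integer(n_empty_droplets),
              empty_umi_mean = empty_umi_mean,
              umi_length = as.integer(umi_length),
              per_base_error_rate = per_base_error_rate,
              reads_per_umi_mean = reads_per_umi_mean,
              sample_name = as.character(sample_name),
              seed = as.integer(seed))
  for (f in c("n_cell_types", "cells_per_type", "n_genes",
              "markers_per_type", "n_empty_droplets")) {
    if (anyNA(cfg[[f]]) || any(cfg[[f]] < 1L)) {
      stop_config("sim_config field '%s' must be a count >= 1", f)
    }
  }
  if (length(cfg$cells_per_type) != 1L &&
      length(cfg$cells_per_type) != cfg$n_cell_types) {
    stop_config("sim_config field 'cells_per_type' must be scalar or one per type")
  }
  if (cfg$marker_fold <= 1) {
    stop_config("sim_config field 'marker_fold' must exceed 1")
  }
  for (f in c("soup_fraction", "per_base_error_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop_config("sim_config field '%s' must lie in [0, 1)", f)
    }
  }
  if (cfg$umi_length < 2L || cfg$umi_length > 15L) {
    stop_config("sim_config field 'umi_length' must be in 2..15")
  }
  if (cfg$reads_per_umi_mean < 1) {
    stop_config("sim_config field 'reads_per_umi_mean' must be >= 1")
  }
  if (cfg$markers_per_type * cfg$n_cell_types > cfg$n_genes) {
    stop_config("sim_config: markers_per_type x n_cell_types exceeds n_genes")
  }
  if (cfg$library_size_log_sd < 0) {
    stop_config("sim_config field 'library_size_log_sd' must be >= 0")
  }
  if (!is.null(cfg$soup_budget) && cfg$soup_budget <= 0) {
    stop_config("sim_config field 'soup_budget' must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate ground truth for a synthetic droplet experiment
#'
#' Draws per-type expression programs and per-cell endogenous counts.
#' Gene baseline rates are gamma distributed; each type's markers are the
#' baseline multiplied by `marker_fold`, and marker sets are disjoint
#' across types so the planted fold is identifiable. The ambient soup
#' profile is the abundance-weighted mixture of the (normalized) type
#' profiles, emulating ambient RNA released by lysed cells of all types.
#' Per-cell counts are multinomial draws from the type profile at a
#' log-normal library size, so per-cell totals are controlled exactly.
#'
#' @param config a [sim_config()].
#' @return a `sim_truth` list: `cell_type_labels`, `sample_labels`,
#'   `library_sizes`, `endogenous_counts` (genes x cells, sparse),
#'   `type_profiles` (genes x types, unnormalized weights),
#'   `soup_profile_true`, `soup_fraction_true`, `marker_sets`,
#'   `lr_programs` (empty until [plant_lr_programs()]).
#' @export
generate_truth <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  G <- config$n_genes
  Tn <- config$n_cell_types
  genes <- sprintf("g%04d", seq_len(G))
  types <- sprintf("type%d", seq_len(Tn))
  # expression programs are drawn under program_seed so several samples
  # of the same tissue can share programs while drawing their own cells
  profiles <- with_seed(config$program_seed %||% config$seed, {
    baseline <- stats::rgamma(G, shape = 2, rate = 1) + 1e-4
    pr <- matrix(baseline, nrow = G, ncol = Tn,
                 dimnames = list(genes, types))
    for (t in seq_len(Tn)) {
      pr[genes[((t - 1L) * config$markers_per_type + 1L):
                 (t * config$markers_per_type)], t] <-
        pr[genes[((t - 1L) * config$markers_per_type + 1L):
                   (t * config$markers_per_type)], t] * config$marker_fold
    }
    pr
  })
  marker_sets <- lapply(seq_len(Tn), function(t) {
    genes[((t - 1L) * config$markers_per_type + 1L):
            (t * config$markers_per_type)]
  })
  names(marker_sets) <- types
  if (config$marker_exclusive) {
    for (t in seq_len(Tn)) {
      profiles[marker_sets[[t]], -t] <- profiles[marker_sets[[t]], -t] * 1e-3
    }
  }
  with_seed(config$seed, {
    per_type <- rep_len(config$cells_per_type, Tn)
    n_cells <- sum(per_type)
    labels <- rep(types, times = per_type)
    lib <- pmax(1, round(rlnorm(n_cells, config$library_size_log_mean,
                                config$library_size_log_sd)))
    counts <- matrix(0L, nrow = G, ncol = n_cells)
    for (t in seq_len(Tn)) {
      idx <- which(labels == types[t])
      p <- profiles[, t] / sum(profiles[, t])
      counts[, idx] <- vapply(idx, function(c) {
        rmultinom(1, lib[c], p)[, 1]
      }, integer(G))
    }
    barcodes <- sprintf("cell%05d", seq_len(n_cells))
    dimnames(counts) <- list(genes, barcodes)
    norm_prof <- sweep(profiles, 2, colSums(profiles), "/")
    soup <- as.vector(norm_prof %*% (table(labels)[types] / n_cells))
    soup <- soup / sum(soup)
    names(soup) <- genes
    truth <- list(cell_type_labels = setNames(labels, barcodes),
                  sample_labels = setNames(rep(config$sample_name, n_cells),
                                           barcodes),
                  library_sizes = setNames(lib, barcodes),
                  endogenous_counts = as_sparse(counts),
                  type_profiles = profiles,
                  soup_profile_true = soup,
                  soup_fraction_true = setNames(
                    if (is.null(config$soup_budget)) {
                      rep(config$soup_fraction, n_cells)
                    } else {
                      pmin(0.9, config$soup_budget / lib)
                    }, barcodes),
                  marker_sets = marker_sets,
                  lr_programs = list(),
                  config = config)
    class(truth) <- "sim_truth"
    truth
  })
}

# Integer <-> DNA encoding for UMIs: base-4 digits mapped to A,C,G,T.
umi_int_to_seq <- function(x, L) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(x), ncol = L)
  v <- x
  for (p in L:1) {
    out[, p] <- bases[(v %% 4) + 1]
    v <- v %/% 4
  }
  apply(out, 1, paste0, collapse = "")
}

# Mutate one read's UMI integer at `k` random positions (hamming-k result).
mutate_umi_int <- function(u, L) {
  pos <- sample.int(L, 1L)
  place <- 4^(pos - 1)
  digit <- (u %/% place) %% 4
  newdigit <- sample((0:3)[-(digit + 1)], 1L)
  u + (newdigit - digit) * place
}

#' Generate observed droplets and read-level data from a simulated truth
#'
#' Observed per-cell counts are multinomial draws at the cell's library
#' size from the mixture `(1 - s) * type profile + s * soup`, where `s` is
#' the true contamination fraction; empty droplets draw Poisson totals
#' from the soup profile alone. Optionally, each molecule is expanded into
#' sequencing reads (1 + Poisson), and each read's UMI suffers independent
#' per-base substitution errors; reads with an error land on a mutated
#' (usually hamming-distance-1) UMI, creating the singleton artifacts the
#' UMI-collapse stage removes. When reads are generated, the returned
#' count matrix is the naive distinct-UMI count of the read table, so
#' collapse is the exact inverse of the injected error process.
#'
#' @param truth a `sim_truth` from [generate_truth()].
#' @param config the same [sim_config()]; defaults to `truth$config`.
#' @param make_reads generate the read-level table (can be skipped for
#'   large runs that start from counts).
#' @param seed RNG seed for the droplet stage (default derived from the
#'   config seed so truth and droplets use distinct streams).
#' @return list with `reads` (data.frame barcode/gene/umi/reads or NULL),
#'   `counts` (genes x barcodes sparse matrix over cells and empties),
#'   `molecule_counts` (true molecule counts, same shape), `is_cell`
#'   (named logical), `sample_of` (named character).
#' @export
generate_droplets <- function(truth, config = truth$config,
                              make_reads = TRUE, seed = config$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(seed, {
    G <- config$n_genes
    genes <- rownames(truth$endogenous_counts)
    labels <- truth$cell_type_labels
    n_cells <- length(labels)
    lib <- truth$library_sizes
    s <- truth$soup_fraction_true
    soup <- truth$soup_profile_true
    norm_prof <- sweep(truth$type_profiles, 2,
                       colSums(truth$type_profiles), "/")
    cell_counts <- matrix(0L, nrow = G, ncol = n_cells)
    for (i in seq_len(n_cells)) {
      p <- (1 - s[i]) * norm_prof[, labels[i]] + s[i] * soup
      cell_counts[, i] <- rmultinom(1, lib[i], p)[, 1]
    }
    n_empty <- config$n_empty_droplets
    empty_tot <- rpois(n_empty, config$soup_budget %||% config$empty_umi_mean)
    empty_counts <- matrix(0L, nrow = G, ncol = n_empty)
    for (i in seq_len(n_empty)) {
      if (empty_tot[i] > 0) {
        empty_counts[, i] <- rmultinom(1, empty_tot[i], soup)[, 1]
      }
    }
    bc_cells <- names(labels)
    bc_empty <- sprintf("empty%05d", seq_len(n_empty))
    mol <- cbind(cell_counts, empty_counts)
    dimnames(mol) <- list(genes, c(bc_cells, bc_empty))
    is_cell <- setNames(c(rep(TRUE, n_cells), rep(FALSE, n_empty)),
                        colnames(mol))
    sample_of <- setNames(rep(config$sample_name, ncol(mol)), colnames(mol))

    reads <- NULL
    counts <- mol
    if (make_reads) {
      L <- config$umi_length
      nz <- which(mol > 0, arr.ind = TRUE)
      k <- mol[nz]
      mol_bc <- rep(colnames(mol)[nz[, 2]], k)
      mol_gene <- rep(genes[nz[, 1]], k)
      n_mol <- length(mol_bc)
      # distinct UMI per molecule within each (barcode, gene) group;
      # collisions are redrawn so molecule counts stay exact
      umi <- floor(runif(n_mol) * 4^L)
      repeat {
        dup <- duplicated(data.table::data.table(mol_bc, mol_gene, umi))
        if (!any(dup)) break
        umi[dup] <- floor(runif(sum(dup)) * 4^L)
      }
      reads_per <- 1L + rpois(n_mol, config$reads_per_umi_mean - 1)
      p_any <- 1 - (1 - config$per_base_error_rate)^L
      n_err <- rbinom(n_mol, reads_per, p_any)
      ok_reads <- reads_per - n_err
      err_idx <- rep.int(seq_len(n_mol), n_err)
      err_umi <- if (length(err_idx)) {
        vapply(umi[err_idx], mutate_umi_int, numeric(1), L = L)
      } else numeric(0)
      dt <- data.table::data.table(
        barcode = c(mol_bc[ok_reads > 0], mol_bc[err_idx]),
        gene = c(mol_gene[ok_reads > 0], mol_gene[err_idx]),
        umi_int = c(umi[ok_reads > 0], err_umi),
        reads = c(ok_reads[ok_reads > 0], rep(1L, length(err_idx))))
      dt <- dt[, list(reads = sum(reads)), by = c("barcode", "gene", "umi_int")]
      dt[, "umi" := umi_int_to_seq(dt$umi_int, L)]
      reads <- as.data.frame(dt[, c("barcode", "gene", "umi", "reads")])
      counts <- reads_to_counts(reads, genes = genes,
                                barcodes = colnames(mol))
    }
    list(reads = reads,
         counts = as_sparse(counts),
         molecule_counts = as_sparse(mol),
         is_cell = is_cell,
         sample_of = sample_of)
  })
}

#' Plant complementary ligand-receptor programs into a simulated truth
#'
#' Elevates chosen ligand genes in a sender type and the matched receptor
#' genes in a receiver type so that downstream interaction inference has a
#' known positive. Each planted gene's profile weight in the target type
#' is raised until its expected per-cell count is `strength` UMIs (at the
#' median library size), which puts it comfortably above the
#' 20%-of-cells expression filter; other genes' weights are untouched.
#' Endogenous counts are re-drawn under the truth's own seed so the
#' returned object is internally consistent.
#'
#' @param truth a `sim_truth`.
#' @param lr_pairs data.frame with columns `ligand`, `receptor`.
#' @param programs list of lists with fields `sender`, `receiver`,
#'   `pairs` (indices into `lr_pairs`, or a data.frame of pairs), and
#'   optional `strength` (expected UMIs per cell in the planted type,
#'   default 2) and `dominance` (minimum ratio of the planted weight to
#'   the gene's weight in any other type, default 5).
#' @return a new `sim_truth` with updated profiles, counts and
#'   `lr_programs` records.
#' @export
plant_lr_programs <- function(truth, lr_pairs, programs) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(programs) == 0L) return(truth)
  genes <- rownames(truth$type_profiles)
  cfg <- truth$config
  profiles <- truth$type_profiles
  med_lib <- median(truth$library_sizes)
  recs <- list()
  for (pr in programs) {
    pairs <- if (is.data.frame(pr$pairs)) pr$pairs else lr_pairs[pr$pairs, ]
    strength <- pr$strength %||% 2
    bad <- setdiff(unique(c(pairs$ligand, pairs$receptor)), genes)
    if (length(bad)) {
      stop("unknown gene(s) in ligand-receptor program: ",
           paste(bad, collapse = ", "))
    }
    if (!all(c(pr$sender, pr$receiver) %in% colnames(profiles))) {
      stop("unknown cell type in ligand-receptor program")
    }
    dominance <- pr$dominance %||% 5
    for (side in c("ligand", "receptor")) {
      tt <- if (side == "ligand") pr$sender else pr$receiver
      gs <- unique(pairs[[side]])
      tot <- sum(profiles[, tt])
      # weight giving ~`strength` expected UMIs/cell at the median
      # library size, and at least `dominance` times the gene's weight
      # in any other type so the planted population is its clear peak
      w <- strength * tot / (med_lib - strength * length(gs))
      rowmax <- apply(profiles[gs, , drop = FALSE], 1, max)
      profiles[gs, tt] <- pmax(profiles[gs, tt], w, dominance * rowmax)
    }
    recs[[length(recs) + 1L]] <- list(sender = pr$sender,
                                      receiver = pr$receiver,
                                      ligands = unique(pairs$ligand),
                                      receptors = unique(pairs$receptor),
                                      strength = strength)
  }
  out <- truth
  out$type_profiles <- profiles
  out$lr_programs <- c(truth$lr_programs, recs)
  norm_prof <- sweep(profiles, 2, colSums(profiles), "/")
  tab <- table(truth$cell_type_labels)[colnames(profiles)]
  soup <- as.vector(norm_prof %*% (tab / sum(tab)))
  out$soup_profile_true <- setNames(soup / sum(soup), genes)
  with_seed(cfg$seed + 17L, {
    labels <- truth$cell_type_labels
    counts <- matrix(0L, nrow = length(genes), ncol = length(labels),
                     dimnames = list(genes, names(labels)))
    for (tt in colnames(profiles)) {
      idx <- which(labels == tt)
      for (c in idx) {
        counts[, c] <- rmultinom(1, truth$library_sizes[c],
                                 norm_prof[, tt])[, 1]
      }
    }
    out$endogenous_counts <- as_sparse(counts)
  })
  out
}

#' Simulate and merge several samples with distinct soups
#'
#' Generates one batch per config (each a logical sample with its own
#' seed, abundances and therefore its own ambient profile) and merges the
#' count matrices over the shared gene universe, prefixing barcodes with
#' the sample name.
#'
#' @param configs list of [sim_config()] objects (same `n_genes`).
#' @param make_reads passed to [generate_droplets()].
#' @return list with `counts`, `sample_of`, `is_cell`, `truths`,
#'   `droplets` (per-sample generator outputs).
#' @export
simulate_samples <- function(configs, make_reads = FALSE) {
  truths <- lapply(configs, generate_truth)
  drops <- lapply(truths, generate_droplets, make_reads = make_reads)
  mats <- list(); samp <- character(0); is_cell <- logical(0)
  for (i in seq_along(drops)) {
    m <- drops[[i]]$counts
    nm <- paste0(configs[[i]]$sample_name, ":", colnames(m))
    colnames(m) <- nm
    mats[[i]] <- m
    samp <- c(samp, setNames(rep(configs[[i]]$sample_name, ncol(m)), nm))
    is_cell <- c(is_cell, setNames(unname(drops[[i]]$is_cell), nm))
  }
  list(counts = do.call(cbind, mats), sample_of = samp,
       is_cell = is_cell, truths = truths, droplets = drops)
}
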