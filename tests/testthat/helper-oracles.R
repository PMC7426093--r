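# Independent reference implementations used as oracles. These are kept
# deliberately naive (O(n^2) scans, explicit enumeration) and separate
# from the package's own code paths.

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Exhaustive all-pairs reference for the singleton-merge rule: within one
# (barcode, gene) group, each reads==1 UMI looks at every reads>=2 UMI,
# merges into the one at hamming distance exactly 1 with the most reads
# (ties: lexicographically smallest), all decisions taken on the initial
# state of the group.
collapse_group_oracle <- function(umis, reads) {
  recipients <- which(reads >= 2)
  singles <- which(reads == 1)
  out_reads <- reads
  drop <- logical(length(umis))
  for (s in singles) {
    cand <- recipients[vapply(recipients, function(r) {
      hamming(umis[s], umis[r]) == 1
    }, logical(1))]
    if (length(cand) == 0) next
    best <- cand[order(-reads[cand], umis[cand])][1]
    out_reads[best] <- out_reads[best] + reads[s]
    drop[s] <- TRUE
  }
  data.frame(umi = umis[!drop], reads = out_reads[!drop])
}

random_umi_group <- function(n, L = 6) {
  umis <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                           replace = TRUE), collapse = "")))
  data.frame(umi = umis,
             reads = sample(c(1L, 1L, 1L, 2L, 3L, 5L), length(umis),
                            replace = TRUE))
}

# Upper-tail hypergeometric by explicit combinatorial sum (no phyper).
hyper_upper_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Explicit least-squares solution of the pooled-deconvolution system for
# one group, rebuilt from the documented contract.
pooled_factors_oracle <- function(sub, pool_sizes, anchor_weight = 0.1) {
  n <- ncol(sub)
  totals <- colSums(sub)
  ord <- order(totals)
  ring <- c(ord[seq(1, n, by = 2)],
            rev(ord[seq.int(2, length.out = n %/% 2, by = 2)]))
  ref <- rowMeans(sub)
  A <- NULL; b <- numeric(0)
  for (s in unique(pmin(pool_sizes, n))) {
    for (start in seq_len(n)) {
      members <- ring[((start - 1 + 0:(s - 1)) %% n) + 1]
      row <- numeric(n); row[members] <- 1
      v <- rowSums(sub[, members, drop = FALSE])
      A <- rbind(A, row)
      b <- c(b, median(v[ref > 0] / ref[ref > 0]))
    }
  }
  A <- rbind(A, diag(anchor_weight, n))
  b <- c(b, anchor_weight * totals / mean(totals))
  qr.solve(A, b)
}

# Small standard simulation reused across tests.
small_sim <- function(seed = 3, ...) {
  cfg <- sim_config(n_cell_types = 3, cells_per_type = 40, n_genes = 300,
                    n_empty_droplets = 400, seed = seed, ...)
  tr <- generate_truth(cfg)
  list(config = cfg, truth = tr,
       droplets = generate_droplets(tr, make_reads = FALSE))
}

make_read_table <- function(barcode, gene, umi, reads) {
  data.frame(barcode = barcode, gene = gene, umi = umi, reads = as.integer(reads),
             stringsAsFactors = FALSE)
}
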