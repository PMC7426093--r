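toy_counts <- function(totals, genes = 3) {
  n <- length(totals)
  m <- vapply(totals, function(tt) {
    stats::rmultinom(1, tt, rep(1 / genes, genes))[, 1]
  }, integer(genes))
  dimnames(m) <- list(paste0("g", seq_len(genes)),
                      names(totals) %||% paste0("b", seq_len(n)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cell calling bounds are inclusive at 350 and 15,000", {
  set.seed(1)
  totals <- c(b1 = 349, b2 = 350, b3 = 15000, b4 = 15001, b5 = 2000)
  m <- toy_counts(totals)
  expect_setequal(call_cells(m), c("b2", "b3", "b5"))
  # random fixture equals a brute-force scan
  tot <- sample(100:20000, 300, replace = TRUE)
  names(tot) <- paste0("c", seq_along(tot))
  m2 <- toy_counts(tot)
  expect_setequal(call_cells(m2),
                  names(tot)[tot >= 350 & tot <= 15000])
})

test_that("empty-droplet selection follows per-sample inclusive ranges", {
  set.seed(2)
  totals <- c(a1 = 19, a2 = 20, a3 = 175, a4 = 176, v1 = 115, v2 = 116)
  m <- toy_counts(totals)
  sample_of <- c(a1 = "caput", a2 = "caput", a3 = "caput", a4 = "caput",
                 v1 = "vas", v2 = "vas")
  ranges <- list(caput = c(20, 175), vas = c(20, 115))
  expect_setequal(select_empty_droplets(m, sample_of, ranges),
                  c("a2", "a3", "v1"))
  expect_error(select_empty_droplets(m, sample_of, list(caput = c(20, 175))),
               class = "ductalsc_config_error")
  tot <- sample(5:300, 200, replace = TRUE)
  names(tot) <- paste0("d", seq_along(tot))
  m2 <- toy_counts(tot)
  so <- setNames(rep(c("caput", "vas"), 100), names(tot))
  got <- select_empty_droplets(m2, so, ranges)
  want <- names(tot)[ifelse(so == "caput", tot >= 20 & tot <= 175,
                            tot >= 20 & tot <= 115)]
  expect_setequal(got, want)
})

test_that("soup profile is the pooled empty-droplet gene fraction", {
  m <- matrix(c(2, 2), nrow = 2, dimnames = list(c("g1", "g2"), "e1"))
  expect_equal(unname(estimate_soup_profile(m, "e1")), c(0.5, 0.5))
  m2 <- matrix(c(5, 0, 3, 0), nrow = 2,
               dimnames = list(c("g1", "g2"), c("e1", "e2")))
  expect_equal(unname(estimate_soup_profile(m2, c("e1", "e2"))), c(1, 0))
  expect_error(estimate_soup_profile(m2, character(0)), "empty")
  sim <- small_sim(seed = 21)
  dr <- sim$droplets
  empties <- names(dr$is_cell)[!dr$is_cell]
  est <- estimate_soup_profile(dr$counts, empties)
  tv <- 0.5 * sum(abs(est - sim$truth$soup_profile_true))
  expect_gt(sum(dr$counts[, empties]), 1e4)
  expect_lt(tv, 0.05)
})

test_that("modal empty count and per-cell rho follow the budget rule", {
  genes <- paste0("g", 1:3)
  m <- cbind(toy_counts(setNames(rep(100, 40), paste0("e", 1:40))),
             toy_counts(c(cell1 = 1000)))
  sample_of <- setNames(rep("s", 41), colnames(m))
  sm <- estimate_rho(m, sample_of, paste0("e", 1:40), "cell1")
  expect_equal(unname(sm$modal_empty_umis), 100)
  expect_equal(unname(sm$rho_per_cell["cell1"]), 0.1)
  expect_s3_class(sm, "soup_model")
})

test_that("mode and rho are recovered on budget-mode simulations", {
  cfg <- sim_config(n_cell_types = 3, cells_per_type = 60, n_genes = 300,
                    soup_budget = 114, n_empty_droplets = 10000, seed = 22)
  tr <- generate_truth(cfg)
  dr <- generate_droplets(tr, make_reads = FALSE)
  valid <- call_cells(dr$counts)
  sm <- estimate_rho(dr$counts, dr$sample_of,
                     names(dr$is_cell)[!dr$is_cell], valid)
  expect_lte(abs(sm$modal_empty_umis - 114), 2)
  planted <- mean(tr$soup_fraction_true[valid])
  expect_lt(abs(mean(sm$rho_per_cell) / planted - 1), 0.2)
})

test_that("count adjustment follows the clamped-then-greedy contract", {
  # no contamination: unchanged
  m <- toy_counts(c(c1 = 500))
  so <- setNames("s", "c1")
  sm <- structure(list(soup_profile = list(s = setNames(rep(1 / 3, 3),
                                                        rownames(m))),
                       modal_empty_umis = c(s = 0L),
                       rho_per_cell = c(c1 = 0)),
                  class = "soup_model")
  expect_equal(as.matrix(adjust_counts(m, sm, so)), unname(as.matrix(m)),
               ignore_attr = TRUE)
  # cell profile identical to soup, rho 1: everything removed
  m2 <- matrix(c(6, 3, 1), ncol = 1,
               dimnames = list(paste0("g", 1:3), "c1"))
  sm2 <- structure(list(soup_profile = list(s = setNames(c(.6, .3, .1),
                                                         rownames(m2))),
                        modal_empty_umis = c(s = 10L),
                        rho_per_cell = c(c1 = 1)),
                   class = "soup_model")
  expect_equal(sum(adjust_counts(m2, sm2, so)), 0)
  # 3-gene hand-executed case: counts 10/5/0, soup .5/.3/.2, rho .2, n 15
  # T = 3; e = (1.5, .9, .6); first pass removes min(counts, round(e)) =
  # (2, 1, 0) = 3 = T; adjusted = (8, 4, 0)
  m3 <- matrix(c(10, 5, 0), ncol = 1,
               dimnames = list(paste0("g", 1:3), "c1"))
  sm3 <- structure(list(soup_profile = list(s = setNames(c(.5, .3, .2),
                                                         rownames(m3))),
                        modal_empty_umis = c(s = 3L),
                        rho_per_cell = c(c1 = 0.2)),
                   class = "soup_model")
  expect_equal(as.numeric(adjust_counts(m3, sm3, so)), c(8, 4, 0))
})

test_that("adjustment is bounded, meets its target, and helps profiles", {
  cfg <- sim_config(n_cell_types = 3, cells_per_type = 80, n_genes = 300,
                    soup_budget = 100, marker_exclusive = TRUE,
                    n_empty_droplets = 6000, seed = 23)
  tr <- generate_truth(cfg)
  dr <- generate_droplets(tr, make_reads = FALSE)
  valid <- call_cells(dr$counts)
  sm <- estimate_rho(dr$counts, dr$sample_of,
                     names(dr$is_cell)[!dr$is_cell], valid)
  adj <- adjust_counts(dr$counts, sm, dr$sample_of)
  raw <- as.matrix(dr$counts[, valid])
  am <- as.matrix(adj[, valid])
  expect_true(all(am >= 0 & am <= raw))
  removed <- colSums(raw) - colSums(am)
  target <- round(sm$rho_per_cell * colSums(raw))
  expect_true(all(removed == pmin(target, colSums(raw))))
  lab <- tr$cell_type_labels[valid]
  for (t in names(tr$marker_sets)) {
    q <- tr$type_profiles[, t] / sum(tr$type_profiles[, t])
    pr <- rowMeans(raw[, lab == t]); pr <- pr / sum(pr)
    pa <- rowMeans(am[, lab == t]); pa <- pa / sum(pa)
    expect_lt(0.5 * sum(abs(pa - q)), 0.5 * sum(abs(pr - q)))
    oth <- unlist(tr$marker_sets[setdiff(names(tr$marker_sets), t)])
    expect_lt(mean(am[oth, lab == t]), mean(raw[oth, lab == t]))
  }
})
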