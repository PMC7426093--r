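lr_toy <- function() {
  # 3 populations x 9 cells; g1 expressed by >=20% of pop A only,
  # g2 nowhere, g3 everywhere
  m <- matrix(0, nrow = 4, ncol = 9,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:9)))
  assign <- setNames(rep(c("A", "B", "C"), each = 3), colnames(m))
  m["g1", 1] <- 5           # 1/3 of A
  m["g3", ] <- 2
  m["g4", 4:9] <- 1
  list(m = m, assign = assign)
}

test_that("expression-breadth filter is inclusive at 20%", {
  toy <- lr_toy()
  pairs <- data.frame(ligand = c("g1", "g2", "g3"),
                      receptor = c("g3", "g4", "g4"))
  flt <- filter_lr_genes(pairs, toy$m, toy$assign)
  expect_setequal(flt$ligands, c("g1", "g3"))
  expect_false("g2" %in% flt$ligands)
  expect_equal(nrow(flt$pairs), 2)  # (g1,g3) and (g3,g4) survive
  # exact 20% boundary: 1 of 5 cells
  m2 <- matrix(0, nrow = 1, ncol = 5,
               dimnames = list("lig", paste0("c", 1:5)))
  m2[1, 1] <- 3
  a2 <- setNames(rep("P", 5), colnames(m2))
  flt2 <- filter_lr_genes(data.frame(ligand = "lig", receptor = "lig"),
                          m2, a2)
  expect_equal(flt2$ligands, "lig")
  # brute-force fraction filter on a random fixture
  set.seed(61)
  m3 <- matrix(stats::rbinom(30 * 40, 1, 0.2) * stats::rpois(30 * 40, 3),
               nrow = 30, dimnames = list(paste0("g", 1:30),
                                          paste0("c", 1:40)))
  a3 <- setNames(rep(c("A", "B"), each = 20), colnames(m3))
  p3 <- data.frame(ligand = paste0("g", 1:15),
                   receptor = paste0("g", 16:30))
  flt3 <- filter_lr_genes(p3, m3, a3)
  ok <- vapply(rownames(m3), function(g) {
    max(mean(m3[g, 1:20] > 0), mean(m3[g, 21:40] > 0)) >= 0.2
  }, logical(1))
  expect_setequal(flt3$ligands, intersect(p3$ligand, names(ok)[ok]))
  expect_setequal(flt3$receptors, intersect(p3$receptor, names(ok)[ok]))
})

test_that("profile grouping labels by peak population and merges", {
  upm <- rbind(a1 = c(100, 0, 0), a2 = c(90, 10, 0),
               b1 = c(0, 100, 0), b2 = c(5, 95, 0))
  colnames(upm) <- c("A", "B", "C")
  grp <- group_lr_profiles(upm, k = 2, seed = 1)
  expect_setequal(unique(grp), c("A", "B"))
  expect_equal(unname(grp[c("a1", "a2")]), c("A", "A"))
  # three k-means clusters, two sharing a peak population: merged to 2
  upm2 <- rbind(a1 = c(100, 1, 0), a2 = c(100, 2, 0),
                a3 = c(60, 40, 0), a4 = c(61, 39, 0),
                b1 = c(0, 100, 0), b2 = c(1, 99, 0))
  colnames(upm2) <- c("A", "B", "C")
  grp2 <- group_lr_profiles(upm2, k = 3, seed = 2)
  expect_length(unique(grp2), 2)
  expect_equal(unname(grp2["a3"]), "A")
  expect_error(group_lr_profiles(upm2, k = 10), "exceeds")
})

test_that("connection counts enumerate retained pairs exactly", {
  gl <- c(l1 = "A", l2 = "A", l3 = "B")
  gr <- c(r1 = "X", r2 = "Y")
  pairs <- data.frame(ligand = c("l1", "l2", "l3", "l1"),
                      receptor = c("r1", "r1", "r2", "r2"))
  m <- count_connections(gl, gr, pairs)
  expect_equal(m["A", "X"], 2)
  expect_equal(m["A", "Y"], 1)
  expect_equal(m["B", "Y"], 1)
  expect_equal(sum(m), nrow(pairs))
  expect_error(count_connections(gl[1], gr, pairs), "unassigned")
  z <- count_connections(gl, gr, pairs[0, ])
  expect_equal(sum(z), 0)
  set.seed(62)
  big <- data.frame(ligand = sample(names(gl), 12, replace = TRUE),
                    receptor = sample(names(gr), 12, replace = TRUE))
  m2 <- count_connections(gl, gr, big)
  for (a in rownames(m2)) for (b in colnames(m2)) {
    expect_equal(m2[a, b], sum(gl[big$ligand] == a & gr[big$receptor] == b))
  }
})

test_that("interaction p-values equal combinatorial enumeration", {
  set.seed(63)
  for (i in 1:30) {
    n_l <- sample(2:3, 1); n_r <- sample(2:3, 1)
    conn <- matrix(stats::rpois(n_l * n_r, 1.2), n_l, n_r,
                   dimnames = list(paste0("L", 1:n_l), paste0("R", 1:n_r)))
    if (sum(conn) == 0 || sum(conn) > 12) next
    res <- test_interactions(conn)
    N <- sum(conn)
    for (j in seq_len(nrow(res))) {
      K <- sum(conn[res$ligand_group[j], ])
      n <- sum(conn[, res$receptor_group[j]])
      want <- hyper_upper_oracle(res$observed_pairs[j], K, N, n)
      expect_equal(res$p_value[j], want, tolerance = 1e-12)
      expect_equal(res$expected_pairs[j], K * n / N)
    }
  }
  # zero-margin group: p = 1
  conn0 <- matrix(c(0, 0, 3, 2), 2, 2,
                  dimnames = list(c("L1", "L2"), c("R1", "R2")))
  res0 <- test_interactions(conn0)
  expect_true(all(res0$p_value[res0$ligand_group == "L1"] == 1))
  # empty matrix: all p = 1
  resz <- test_interactions(matrix(0, 2, 2))
  expect_true(all(resz$p_value == 1))
})

test_that("p-values are monotone in the observed count at fixed margins", {
  N <- 100; K <- 30; n <- 25
  ps <- vapply(0:25, function(k) {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("composition enrichment matches enumeration and flags bias", {
  # 20 cells, 5 of type T; sample S holds 4 cells, all T
  assign <- setNames(c(rep("T", 5), rep("U", 15)), paste0("c", 1:20))
  samp <- setNames(c(rep("S", 4), rep("O", 16)), paste0("c", 1:20))
  res <- test_composition_enrichment(assign, samp)
  row <- res[res$cell_type == "T" & res$sample == "S", ]
  expect_equal(row$observed, 4)
  expect_equal(row$p_value, hyper_upper_oracle(4, 5, 20, 4),
               tolerance = 1e-12)
  # proportional composition: no signal
  a2 <- setNames(rep(c("T", "U"), each = 10), paste0("c", 1:20))
  s2 <- setNames(rep(c("S", "O"), 10), paste0("c", 1:20))
  r2 <- test_composition_enrichment(a2, s2)
  expect_true(all(r2$p_value >= 0.5))
  # planted 5x excess of one type in one sample at scale
  set.seed(64)
  n_cells <- 4000
  samp3 <- sample(c("vas", "caput", "corpus", "cauda"), n_cells,
                  replace = TRUE)
  type3 <- ifelse(samp3 == "vas",
                  sample(c("macrophage", "other"), n_cells, replace = TRUE,
                         prob = c(0.25, 0.75)),
                  sample(c("macrophage", "other"), n_cells, replace = TRUE,
                         prob = c(0.05, 0.95)))
  names(samp3) <- names(type3) <- paste0("c", seq_len(n_cells))
  r3 <- test_composition_enrichment(type3, samp3)
  expect_lt(r3$p_value[r3$cell_type == "macrophage" & r3$sample == "vas"],
            1e-7)
})

test_that("randomized pairings are calibrated and planted programs found", {
  cfg <- sim_config(seed = 71, n_cell_types = 10, cells_per_type = 40,
                    n_genes = 800, n_empty_droplets = 200)
  tr <- generate_truth(cfg)
  nonmark <- setdiff(rownames(tr$endogenous_counts),
                     unlist(tr$marker_sets))
  set.seed(71)
  gs <- sample(nonmark, 220)
  lrp <- data.frame(ligand = gs[1:110], receptor = gs[111:220])
  progs <- lapply(11:110, function(i) {
    list(sender = sample(colnames(tr$type_profiles), 1),
         receiver = sample(colnames(tr$type_profiles), 1),
         pairs = lrp[i, ])
  })
  progs <- c(list(list(sender = "type1", receiver = "type2",
                       pairs = lrp[1:10, ])), progs)
  tr2 <- plant_lr_programs(tr, lrp, progs)
  dr <- generate_droplets(tr2, make_reads = FALSE)
  valid <- call_cells(dr$counts)
  net <- infer_lr_network(lrp, dr$counts[, valid],
                          tr2$cell_type_labels[valid],
                          k_ligand = 13, k_receptor = 14, seed = 71)
  row <- net$interactions[net$interactions$ligand_group == "type1" &
                            net$interactions$receptor_group == "type2", ]
  expect_true(row$significant)
  # null: shuffle the pairing many times, count significant entries
  set.seed(72)
  fracs <- replicate(40, {
    shuf <- data.frame(ligand = sample(net$filtered$pairs$ligand),
                       receptor = net$filtered$pairs$receptor)
    conn <- count_connections(net$groups_ligand, net$groups_receptor, shuf)
    res <- test_interactions(conn)
    mean(res$significant)
  })
  expect_lt(mean(fracs), 0.01 + 1.96 * sqrt(0.01 * 0.99 / (40 * 110)))
})
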