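# ductalsc

Droplet single-cell decomposition pipeline for ductal tissue atlases.

Single-cell atlases of ductal organs such as the epididymis and vas
deferens are built from droplet scRNA-seq data that must first be cleaned
of sequencing artifacts and ambient contamination before cell types can
be resolved. `ductalsc` packages that analysis chain as tested, reusable
R functions, together with a synthetic droplet generator with complete
ground truth, so every stage can be verified without downloading any
dataset. It is aimed at analysts who want a transparent, fully specified
implementation of each step rather than a monolithic black box.

The stages, in pipeline order:

* **UMI error collapse** — reads whose UMI contains `N` are discarded;
  within each (barcode, gene), a UMI seen once at hamming distance 1
  from a UMI seen ≥ 2 times is merged into it.
* **Cell calling** — barcodes with 350 ≤ total UMIs ≤ 15,000 are cells;
  per-sample total-UMI ranges select empty droplets.
* **Ambient ("soup") correction** — the soup profile is the pooled gene
  fraction of empty droplets; the modal empty-droplet total *m* is read
  as a fixed ambient budget, so a cell with *n<sub>c</sub>* UMIs has
  contamination fraction ρ<sub>c</sub> = *m*/*n<sub>c</sub>*, and
  round(ρ<sub>c</sub>·*n<sub>c</sub>*) counts are removed by clamped
  subtraction of the expected soup followed by residual-greedy removal.
* **Normalization** — pooled-deconvolution size factors θ within broad
  populations on the top 20% expressed genes; cells outside the band
  0.1·mean(θ) < θ < 10·mean(θ) are dropped; counts become per-cell gene
  fractions.
* **Clustering** — top-CV gene selection, PCA to a cumulative
  variance-explained threshold, 2-D t-SNE (perplexity 30), then
  density-peak clustering: γ = ρ·δ (local density × distance to the
  nearest denser point), top-k γ as centers, assignment along
  density-increasing links. Two rounds (20%/85%, then 15%/95% on gene
  fractions), plus per-population re-clustering.
* **Markers** — per-cluster NB log-linear model `count ~ in_cluster +
  batch` with size-factor offsets, trended-dispersion shrinkage, 1-df
  LRT, BH per cluster; fourfold UPM enrichment and bulk region
  (log2FC ≥ 2, ≥ 20 ppm) filters; zero-inflated NB expressing fractions
  by EM.
* **Ligand-receptor networks** — pairs kept when both genes are
  expressed by ≥ 20% of cells of some population; k-means grouping of
  expression profiles (k = 13/14) merged by peak population; connection
  counts tested with an upper-tail hypergeometric on the matrix margins
  at p < 0.01; plus a compositional enrichment test of cell types within
  samples.

## Worked example

Simulate one sample with a known ambient budget and run the pipeline:

```r
library(ductalsc)

cfg <- sim_config(n_cell_types = 4, cells_per_type = 80, n_genes = 600,
                  soup_budget = 100, n_empty_droplets = 10000, seed = 42)
truth <- generate_truth(cfg)
drops <- generate_droplets(truth, make_reads = FALSE)

pcfg <- pipeline_config(empty_ranges = list(sample1 = c(20, 220)),
                        k_broad = 4, k_fine = 4, seed = 1)
res <- run_pipeline(drops$counts, drops$sample_of, pcfg)
```

Printing the key quantities:

```
valid cells:          320
modal empty UMIs:     100
mean rho per cell:    0.043
cells after band:     320
clusters (sizes):     80 80 80 80
cluster vs truth agreement: 1
fourfold-enriched genes: 80
```

All 320 simulated cells pass calling; the modal empty-droplet total
recovers the planted ambient budget of 100 UMIs exactly, giving a mean
contamination fraction of ~4% at this depth; the band filter drops no
one (factors are homogeneous here); the second clustering round returns
four clusters of 80 cells that agree perfectly with the planted types;
and the fourfold-enrichment filter on the cluster UPM profiles returns
exactly the 4 × 20 planted marker genes.

`run_pipeline()` also accepts a read-level table (collapsed on the fly),
multiple samples via `simulate_samples()` or merged matrices with a
`sample_of` label vector, and an optional ligand-receptor pair table to
enable the interaction stage. Matrix-Market triplets are read and
written with `read_mtx_triplet()` / `write_mtx_triplet()`.

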