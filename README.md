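# coregut

Genus-level analysis of the **core gut microbiota** in mouse 16S rRNA
surveys, packaged as a tested, reusable pipeline.

Healthy hosts of different ages, sexes and strains share a set of
prevalent gut bacterial genera. `coregut` identifies that set, describes
its internal ecology and relates it to host phenotype:

* **Core identification** — a genus is *core* when detected in at least
  50% of healthy samples (prevalence `P(g) = #{s : x_gs > 0} / n`, core =
  `P(g) ≥ 0.5`, inclusive).
* **Co-abundance groups (CAGs)** — Spearman correlation `ρ` over the core
  genera across healthy samples, Benjamini–Yekutieli FDR over all
  `k(k−1)/2` pairs; significant edges need `|ρ| > 0.5` and `q < 0.001`;
  the core set is partitioned by average-linkage clustering on `1 − ρ`
  cut at 0.5 (mean within-group `ρ ≥ 0.5`).
* **Ordination + MANOVA** — PCA of core-genus relative abundances
  (centered, unscaled) and one-way MANOVA on the leading PC scores:
  Wilks' `Λ = det(W)/det(W+B)`, Bartlett's `χ² = −(n−1−(k+g)/2) ln Λ` on
  `k(g−1)` df.
* **LEfSe-style differential abundance** — per-genus Kruskal–Wallis
  screen (`p < 0.05`), then a bootstrapped regularized LDA effect size on
  per-million abundances, selected at `log10(1 + effect) > 2.0`.
* **Phenotype screen** — Spearman correlation of PC scores vs. host
  parameters, Benjamini–Hochberg FDR, significant at `q < 0.1`.
* **Phylogeny** — p-distances (pairwise deletion), classic neighbor
  joining (implemented in full) and Felsenstein bootstrap supports from
  1,000 column resamples, written as Newick.
* **Synthetic communities** — a generator that plants a known core set,
  co-abundance blocks, class effects and phenotype couplings, and emits a
  machine-readable truth record, so every stage can be validated by
  recovery.

Inputs are plain TSV (OTU or genus counts, RDP-style taxonomy, sample
metadata, host parameters), BIOM v1, and aligned FASTA; outputs are TSV
tables, Newick trees, YAML manifests and recovery reports.

## Worked example

```r
library(coregut)

fx  <- make_fixture("study", seed = 1)   # 205 samples, 3 cohorts, 120 genera
res <- run_pipeline(fx$config)

head(res$core, 3)
#>   genus prevalence  mean_abund
#> 1  g001   1.000000 0.004441584
#> 2  g004   1.000000 0.003366733
#> 3  g003   0.990099 0.055631089

round(res$summary$per_dataset, 4)
#>    CUG    FMT    PRO
#> 0.7115 0.7387 0.7288

res$contrasts[["health_healthy_vs_HFD"]]$manova
#> One-way MANOVA on 2 PC scores (64 samples, 2 classes)
#>   Wilks' lambda = 0.8782, chi2 = 7.922 on 2 df, p = 0.01904

head(as.data.frame(res$contrasts[["health_healthy_vs_HFD"]]$lefse), 2)
#>   genus        H           p passed_screen lda_score enriched selected
#> 1  g023 6.749854 0.009375536          TRUE  4.716688  healthy     TRUE
#> 2  g024 4.115260 0.042497999          TRUE  4.700642  healthy     TRUE
```

Reading the output: the core table lists each core genus with its
prevalence across the 101 healthy samples and mean relative abundance;
`per_dataset` gives the fraction of each cohort's reads held by core
genera (here ~72–74%); the MANOVA line says the healthy and high-fat-diet
communities separate in the 2-D PC score space (`p ≈ 0.019`); and the
LEfSe rows show the two genera whose depletion under the diet drives that
separation (`lda_score > 2`, enriched in the healthy class — both are
planted disease effects of this fixture, which the run's
`recovery.yaml` confirms with a core-set Jaccard of 1.0).

Every run directory also contains `run.log` (all thresholds actually
applied), `manifest.yaml` (checksums of every artifact; reruns with the
same config are bit-identical) and, when ground truth is supplied,
`recovery.yaml`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/coregut.R simulate --size study --seed 1 --dir fixture/
Rscript inst/cli/coregut.R run-all --config fixture/config.yaml
```

## Package layout

| Area | Files |
| --- | --- |
| Synthetic communities | `R/synthetic.R`, `R/fixtures.R` |
| Ingest / filters / collapse | `R/ingest.R` |
| Core identification | `R/core.R` |
| Co-abundance groups | `R/coabundance.R` |
| PCA + MANOVA | `R/ordination.R` |
| Differential abundance | `R/lefse.R` |
| Phenotype correlations | `R/phenotype.R` |
| Neighbor joining + bootstrap | `R/phylogeny.R` |
| Orchestration | `R/pipeline.R`, `inst/cli/coregut.R` |

Methodological details, default parameters and their rationale, and known
limitations are documented in
`vignettes/core-microbiota-methods.Rmd`.
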