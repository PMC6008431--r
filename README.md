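# idseqr

Processing and statistics for **immuno-detection by sequencing (ID-seq)**
experiments, in which antibodies carry double-stranded DNA tags with a
10-nt antibody-dedicated barcode and a 15-nt unique molecular identifier
(UMI), wells receive a second PCR-added barcode, and protein levels are
read out as distinct-UMI counts per antibody and well. The package is
aimed at groups running plate-based multiplexed antibody screens — from
raw FASTQ to kinase-level enrichment calls — and at anyone who needs a
fully simulatable reference implementation of that pipeline.

## What it does

1. **Demultiplexing and UMI counting** (`parse_reads()`, `count_umis()`):
   fixed-position parsing against a configurable read layout
   (`UMI(15) – ANCHOR – BC1(10) – BC2(10)` by default), error-tolerant
   barcode matching (unique match within Hamming distance *t*, ties
   rejected; panels validated for min pairwise distance ≥ 2*t* + 1), and
   duplicate removal on the corrected (well, antibody, UMI) triple.
2. **Normalization** (`size_factors()`): median-of-ratios size factors
   rescaled to geometric mean 1, used as model offsets.
3. **Differential model** (`fit_nb()`, `lrt()`, `differential_table()`):
   per-antibody negative-binomial regression with log link,

   `y_aw ~ NB(mu_aw, alpha_a),  log mu_aw = log s_w + x_w' beta_a`,

   with treatment plus replicate/batch blocking covariates, Cox–Reid
   adjusted per-antibody dispersion, a likelihood-ratio test for the
   treatment term (small-sample F reference by default at plate scale),
   BH q-values, and the signed p-value score
   `sign(beta) * (-log10 p)` per antibody.
4. **Screen analytics** (`screen_pca()`, `annotate_pcs()`,
   `decile_contrast()`, `assign_probe_sets()`, `gsea()`,
   `kinase_profiles()`, `profile_cluster_compare()`): PCA over the probes ×
   phenotypes signed-p matrix, phenotype–PC annotation, top-vs-bottom
   decile contrasts, robust-z (median/MAD) probe-set assignment from a
   %-inhibition matrix, weighted Kolmogorov–Smirnov set enrichment with
   permutation NES/FDR, and probe-set molecular profiles.
5. **Simulators** (`simulate_fastq()`, `simulate_counts()`,
   `simulate_screen()`): ground-truthed generators for every stage —
   triple-barcoded reads with geometric PCR duplication and substitution
   errors, NB count matrices with planted fold changes, and screen
   matrices with planted phenotype axes and kinase probe sets.
6. **Pipeline** (`run_pipeline()` and `inst/cli/idseq.R`): one YAML config
   drives demux → normalize → diff → screen with a provenance manifest;
   reruns are byte-identical given the same seeds.

## Worked example

```r
library(idseqr)

panel  <- simulate_panel(12, seed = 3)
plate  <- simulate_plate(24, seed = 4)
layout <- read_layout()

sim <- simulate_fastq(panel, plate, layout, truth_counts = 40,
                      duplication_rate = 0.3, barcode_error_rate = 0.005,
                      seed = 5)
m <- count_umis(sim$reads, layout, panel, plate)
m
#> UMI count matrix: 12 antibodies x 24 wells
#>   reads: 16371 total, 16336 assigned (99.8%), 4836 duplicates removed (29.60% duplicate rate)
#>   total distinct UMIs: 11500

counts <- simulate_counts(plate, n_antibodies = 12,
                          effects = c(log(2), rep(0, 11)),
                          dispersion = 0.2, seed = 6)$counts
tab <- differential_table(counts, model_spec(plate), size_factors(counts))
head(as.data.frame(tab)[order(tab$p_value),
                        c("antibody_id", "estimate", "p_value", "signed_logp")], 3)
#>   antibody_id   estimate      p_value signed_logp
#> 1        ab01  0.7637760 0.0001064448   3.9728756
#> 9        ab09 -0.2858903 0.1334116356  -0.8748063
#> 7        ab07  0.2262371 0.2142275092   0.6691248
```

The simulated duplicate rate matches the planted duplication probability
(`0.3`), and the antibody with the planted two-fold effect (`ab01`) is
recovered with an estimate near `ln 2 = 0.693` and dominates the ranking;
the remaining antibodies are null. A full screen-shaped run (probes ×
phenotypes signed-p matrix → PCA → probe sets → enrichment) is shown in the
methods vignette, `vignettes/idseq-methods.Rmd`.

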