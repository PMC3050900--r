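# butolscreen

Computational pipeline for pooled genomic-library enrichment screens of
solvent tolerance in bacteria, built around the n-butanol tolerance screen
design in *E. coli*: a plasmid library of random 2–3 kb genomic inserts
(~14,000 clones, about seven-fold genome coverage) is serially transferred
through increasing n-butanol concentrations, plasmid pools from each step
are read out against the starting library on two-channel arrays
(array-CGH), and candidate genes are re-tested individually by growth
kinetics. The package is aimed at people analysing such screens — or
studying their statistical behaviour — without access to wet-lab data:
every stage is paired with a synthetic generator with recorded ground
truth.

## What it computes

* **Array-CGH stage** — LOWESS normalization of two-channel scans
  (M = log2 S/R against A = ½·log2 SR), per-gene enrichment profiles
  across challenge steps (median over probes), one-sample Student's
  t-calling of enriched/depleted genes at raw p < 0.05, and subtraction of
  genes also enriched in the solvent-free control arm.
* **CAST clustering** — Cluster Affinity Search Technique over shifted
  Pearson affinities s = (r+1)/2, grouping genes with similar enrichment
  profiles.
* **GO enrichment** — per term, counts (k, n, K, N), log odds-ratio
  log2((k/n)/(K/N)), one-sided hypergeometric p with BH correction, with
  ancestor propagation.
* **Growth kinetics** — maximum specific growth rate µ_max (peak slope of
  ln OD over sliding windows on a noise-weighted smoothed curve), the
  tolerance ratio T = µ(0.5% butanol)/µ(0%), and the tolerance statistics

      IIE  = (T_clone / T_wt − 1) · 100 %
      RSGR = (µ_clone,0% / µ_wt,0% − 1) · 100 %

  with a two-sample t-test over 4 paired biological replicates.
* **Synthetic data** — genomes, clone libraries, serial-selection array
  scans (multiplicative clone selection, intensity-dependent dye bias,
  log2 noise), and lagged-logistic plate-reader curves, all deterministic
  under a seed.

See `vignettes/tolerance-screen-methods.Rmd` for the models, defaults and
caveats.

## Worked example

An end-to-end synthetic run (12 clones under positive selection among
2000, four challenge steps plus control arm, then a 4-replicate kinetics
screen of the candidates):

```r
library(butolscreen)
cfg <- screen_config(seed = 7)
rep <- run_screen(cfg)
print(rep)
#> Genomic library enrichment screen (synthetic run)
#>   seed 7, config 5b3f8403ee7e
#>   genes: 300 | enriched candidates: 11 | depleted: 6
#>   clusters: 4 | kinetics-significant genes: 4
```

11 genes pass the array stage as enriched candidates (6 depleted); CAST
groups their profiles into 4 clusters; 4 candidates survive the kinetics
re-test at alpha 0.05. The per-gene tables behind those counts:

```r
head(rep$tolerance[, c("gene_id","iie","iie_sd","rsgr","p_value")], 3)
#>  gene_id   iie iie_sd   rsgr  p_value
#>    g0005 40.90   6.80  7.960 0.000148
#>    g0016  2.28   4.51 -3.608 0.478466
#>    g0026  6.23  11.56 -0.517 0.230912
```

`g0005` is a true positive (genes covered by selected clones carry a true
IIE of 49.1% in this scenario): its recovered IIE of 40.9 ± 6.8 % with
p = 1.5e-4 is a significant tolerance improvement; `g0016` and `g0026` are
array-stage false positives that the kinetics re-test correctly rejects.

Calibration of the kinetics stage against known truth:

```r
set.seed(42)
rr <- recover_iie(49.1, n_screens = 30)
#> mean 48.84, sd 7.94, median p 0.0006
```

A single 4-replicate screen scatters with sd ≈ 8 points; the mean over
independent screens recovers the encoded 49.1 % effect closely.

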