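# zombiefish

Image cytometry and statistics for quantifying pelagiphage-infected and
"zombie" SAR11 cells in multi-channel FISH microscopy.

SAR11 (*Pelagibacterales*) dominates marine bacterioplankton, and its
phages are among the most abundant biological entities in the ocean.
Triple labelling — DAPI for DNA, 16S rRNA CARD-FISH for ribosome content,
and direct-geneFISH probes against phage genome regions — resolves four
cell populations per field of view:

| population | DNA | 16S rRNA | phage |
|---|---|---|---|
| total (DAPI) cells | + | any | any |
| SAR11 | + | + | − |
| phage-infected SAR11 | + | + | + |
| zombie cells | + | − | + |

Zombie cells are phage-infected cells with no detectable ribosomal RNA —
consistent with phage-driven recycling of host RNA into nucleotides.
Free phage particles and vesicles are excluded from all cell counts by a
size gate (default 0.05 µm²), since they are far smaller than any intact
cell. A cell with exactly two local DNA maxima counts as dividing, giving
the frequency of dividing cells (FDC), a proxy for division rate.

The package provides, as plain R functions:

* **synthetic imaging** — `scene_spec()`, `render_field()`,
  `render_negative_control()`, `render_timeseries()`: ground-truthed
  multi-channel fields (ellipse cells, Gaussian PSF, additive noise) for
  every population above, so the whole chain is testable without any
  microscopy download;
* **cytometry** — `segment_objects()`, `classify_objects()`,
  `count_dna_maxima()`, `tabulate_counts()`, `run_cytometry()`:
  thresholding, connected components, the gating partition, dividing-cell
  detection, and pooled per-sample ratios
  (infected/SAR11, zombie/total, SAR11/total, FDC);
* **probe design** — `enumerate_candidates()`, `screen_offtargets()`,
  `select_probes()`, `design_probes()`: 10–13 probes per phage genome,
  156–318 bp, GC in the 22.0–43.2% band, ≥90% ungapped identity to all
  references, off-target exclusion;
* **abundance** — `mag_rpkm()`, `phage_relative_rpkm()`,
  `compute_abundance_table()`: RPKM against library size for SAR11 MAGs
  and 16S genes, and phage abundance relative to the SAR11 community,
  `reads_phage · 10⁶ / (Σ reads_SAR11-MAGs · length_phage,kb)`;
* **statistics** — `welch_t()`, `rm_anova()`, `transform_zero()`,
  `simulate_beta_data()`, `fit_beta_regression()`,
  `posterior_tail_fraction()`: Welch's t from summaries or samples,
  one-within-factor repeated-measures ANOVA, and logit-link Bayesian
  beta regression `y ~ Beta(µφ, (1−µ)φ)`, `logit(µ) = β₀ + β₁x`, with
  flat coefficient priors, sampled by adaptive random-walk Metropolis
  (4 chains × 2000 retained after 2000 warmup = 8000 draws).

The numbered scripts under `analysis/` run the whole study chain on
synthetic data (simulate → cytometry → probes → abundance → models) and
write their tables under `results/`.

## Worked example

```r
library(zombiefish)

# a field with known composition: 120 uninfected SAR11, 15 infected,
# 8 zombies, 60 other bacteria, 40 free phage particles
spec <- scene_spec(seed = 7)
rf   <- render_field(spec)
res  <- run_cytometry(list(rf))
res
#> cytometry_result: 203 cells (135 SAR11, 15 infected, 8 zombie, 8 dividing); 40 free phage/vesicle objects
#>   rel_infected=0.1111 rel_zombie=0.0394 rel_sar11=0.6650 fdc=0.0394
```

All 243 rendered objects are recovered and classified: 15/135 infected
SAR11 cells (11.1% — infected cells count toward the SAR11 denominator),
8/203 zombies (3.9% of total cells), and all 8 dividing cells found.

```r
# beta regression: infected fraction vs zombie fraction, study-sized data
d   <- simulate_beta_data(-3.72, 6.92, phi = 30, n = 148, seed = 11)
fit <- fit_beta_regression(d, y ~ x, seed = 42)
fit
#> Bayesian beta regression: y ~ x  (n = 148 )
#>    4 chains x 2000 retained after 2000 warmup; mean acceptance 0.28
#>   parameter   mean    sd ci_lower ci_upper  rhat
#> 1 intercept -3.722 0.143   -3.999   -3.447 1.002
#> 2     slope  7.356 1.603    4.345   10.513 1.003
#> 3       phi 32.131 4.018   24.630   40.173 1.005
#>   P(slope <= 0) = 0, P(slope >= 0) = 1 of 8000 draws
```

The posterior recovers the generating logit-scale slope (6.92) well
within one posterior SD, and no retained draw is negative — the evidence
pattern used throughout the analysis for directional claims.

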