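---
title: "Quantifying phage-infected and zombie SAR11 cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phage-infected and zombie SAR11 cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zombiefish)
```

## The problem

SAR11 (*Pelagibacterales*) is the most abundant clade of free-living
marine bacteria, and pelagiphages are among the most abundant viruses on
Earth. Triple-labelled FISH microscopy — a DNA stain (DAPI), a 16S rRNA
CARD-FISH probe, and direct-geneFISH probes against phage genome regions —
makes infection visible cell by cell and distinguishes four populations:

* **total cells**: any DNA-positive object of plausible cell size;
* **SAR11 cells**: DNA plus 16S rRNA signal;
* **phage-infected SAR11**: DNA, rRNA, and phage signal;
* **zombie cells**: DNA and phage signal but *no detectable rRNA* —
  phage-infected cells whose ribosome content has been depleted, most
  plausibly because the phage recycles host RNA into nucleotides for its
  own genome replication.

Small phage-positive particles are excluded by a size gate: free phage
capsids and vesicles are far below the size of an intact cell, while
zombie cells are not, and zombies always contain DNA.

`zombiefish` implements this quantification chain as testable code: a
ground-truthed synthetic image generator, the cytometry (segmentation,
gating, dividing-cell detection), probe design for the direct-geneFISH
stage, RPKM abundance formulas for the accompanying metagenomic
estimates, and the statistical models applied to the resulting fractions.
Because the original microscopy belongs to the source data repositories,
every downstream stage here is exercised against synthetic fields whose
ground truth is known exactly.

## The synthetic field generator

`scene_spec()` fixes everything about a field: per-class object counts,
cell sizes, per-class signal amplitudes in the three channels, optics and
noise, and a seed. `render_field()` draws geometry, paints each object as
an axis-aligned ellipse plateau, convolves with an isotropic Gaussian
point-spread function, and adds constant background plus Gaussian noise
clipped at zero.

Key parameters, units and defaults:

| parameter | default | why |
|---|---|---|
| `pixel_size` | 0.065 um/px | 63x objective with a standard CCD |
| `cell_diameter_range` | 0.4–0.8 um | SAR11 are among the smallest free-living cells |
| `free_phage_diameter` | 0.15 um | sub-resolution particle, well below any cell |
| `psf_sigma` | 0.1 um | widefield Gaussian approximation |
| `background_level`, `noise_sd` | 10, 3 (8-bit units) | dim, flat background with moderate camera noise |
| `dividing_fraction` | 0.05 | baseline division activity |
| `ribosome_continuum_fraction` | 0 | fraction of infected cells with partially depleted rRNA |

Class amplitudes implement the gating truth table (uninfected SAR11:
DNA+rRNA; infected: DNA+rRNA+phage; zombie: DNA+phage; other bacteria:
DNA only, or DNA+rRNA under `eub_mode` which emulates the general
bacterial EUB I-III probe; free phage: phage only).

Numerical choices worth knowing:

* **Placement** is rejection sampling of bounding disks padded by the PSF
  support, so rendered objects never merge; an `overlap_budget` can relax
  this. An explicit error reports infeasible packing.
* **Sub-resolution particles** (free phage) are painted with
  supersampled fractional pixel coverage; a hard binary raster would make
  a particle's rendered flux depend on where its centre falls within a
  pixel, and particles straddling pixel corners could drop below the
  detection threshold.
* **Dividing cells** are painted as an elongated envelope (factor 1.7, as
  pre-division cells elongate) holding a faint nucleoid plus two bright
  DNA foci separated by 0.6–0.9 of the cell length. The faint envelope
  keeps the object connected in the DNA channel; the foci guarantee two
  detectable local maxima.
* **Ribosome continuum**: infected cells flagged by
  `ribosome_continuum_fraction` draw their rRNA amplitude uniformly
  between zero and the detection-threshold equivalent, emulating the
  observed continuum of decreasing ribosomal content during infection.
  Fully depleted cells are, by construction, classified as zombies — that
  is the phenomenon, not an error.

What the generator does *not* emulate: vignetting, chromatic shift, stage
drift, hybridization chemistry, photobleaching, super-resolution optics,
or realistic cell-shape variation (rods, vibrios). Passing tests
therefore demonstrate that the *counting and gating logic* is correct and
unbiased under controlled optics — not that the thresholds would be
optimal on any particular microscope's output.

## Image cytometry

`segment_objects()` thresholds each channel, takes connected components
(8-connectivity by default) of the union mask, and measures per-object
areas, centroids and per-channel mean/max intensities.
`classify_objects()` applies the gating partition; `tabulate_counts()`
computes the survey's ratios with their printed denominators — infected
relative to SAR11 cells (infected cells *are* SAR11 cells, so they join
that denominator), zombies and SAR11 relative to total DAPI cells, and
the frequency of dividing cells (FDC) relative to total cells. Zero
denominators yield flagged `NA`s, never silent zeros.

The default threshold rule is `background + max(k * sigma_MAD, floor)`
with `k = 5` and `floor = 40` intensity units. The absolute floor is a
deliberate addition: in the noise-free limit the robust sigma collapses
to zero and a pure `k * sigma` rule would threshold at the background
itself, turning the whole field into one component through the FFT
convolution tails; under realistic noise, a low threshold also inflates
the point-spread halo of bright sub-resolution particles past the
free-phage size gate. The floor pins the masks near the objects' painted
support in both regimes. All of this sits in `gate_config()`.

The free-phage size gate defaults to 0.05 um^2 (equivalent diameter about
0.25 um): phage capsids are below 100 nm, SAR11 cells are 0.4 um and
larger, so the gate separates the two populations with a wide margin in
either direction. Objects at or below the gate are retained as
sub-cellular (free phage or vesicles) and excluded from all cell counts.

**Dividing cells.** A cell with exactly two local DNA maxima counts as
dividing. `count_dna_maxima()` smooths the DNA plane (sigma 0.03 um),
restricts it to the object mask and counts topographic peaks by
descending water-level accretion: a peak survives only if its prominence
(height above the saddle connecting it to a higher peak) reaches 20
intensity units, and equal-intensity plateaus merge into one maximum.
Cells with more than two maxima are treated as aggregates and excluded
from the FDC numerator.

## Probe design

The direct-geneFISH design rules are: 10–13 probes per phage, each
156–318 bp, GC inside the band of the target phage genomes (22.0–43.2%),
at least 90% ungapped nucleotide identity against every reference
sequence, and no ambiguous similarity to off-target sequences
(strict removal above 80% identity). `enumerate_candidates()` slides
windows (lengths 156/200/250/318, step 10 bp by default) and screens
them; `select_probes()` greedily maximizes a score combining gene-class
preference (terminase, polymerase and structural genes are weighted
double, as the most conserved), identity, and closeness to the genome GC,
subject to pairwise non-overlap and a soft even-spacing constraint, with
deterministic leftmost-start tie-breaks.

The identity screen is exact for its purpose: candidate alignment offsets
are anchored on shared 8-mers, and a window at >= 90% identity over at
most 318 bp *must* share an 8-mer with its reference at the true offset
(pigeonhole over match runs), so no qualifying window can be missed.
The off-target screen offers the exact quadratic scan (default; right for
the small curated off-target sets of a real design) and a linear-time
shared-12-mer mode for screening thousands of windows against large
sequence sets.

## Abundance formulas

Two normalizations, applied per sample: MAG and 16S-gene abundances as
reads per kilobase per million library reads,
`RPKM = mapped * 1e6 / (total_reads * length_kb)`, and — because the
assessed phages are SAR11-specific — phage abundance relative to the
SAR11 community, `phage_mapped * 1e6 / (sum SAR11 MAG mapped *
phage_length_kb)`. A sample with no SAR11 MAG reads flags its phage
records undefined rather than reporting zero: "no SAR11 detected" and "no
phage detected" are different statements. The package consumes count
tables; read mapping itself is out of scope (a toy exact-substring
mapper exists purely so end-to-end tests run without external tools).

## Statistical models

* `welch_t()` — unequal-variance t with Welch–Satterthwaite degrees of
  freedom, from raw samples or (n, mean, sd) summaries.
* `rm_anova()` — one-within-factor repeated-measures ANOVA
  (`F = MS_condition / MS_(condition x subject)`), used for the
  SAR11-specificity comparison of zombie counts under the SAR11 vs the
  general bacterial probe across dates; dates are the subjects because
  the time-series samples are not independent.
* `transform_zero()` — the response proportions are shifted by +0.001,
  uniformly across all values, before beta regression; the beta density
  is undefined at zero and observed infection fractions can be exactly
  zero. The uniform shift (rather than shifting only the zeros) keeps
  the transformation order-preserving and affine near zero.
* `fit_beta_regression()` — mean-precision beta likelihood with logit
  link: `y ~ Beta(mu * phi, (1 - mu) * phi)`,
  `logit(mu) = b0 + b1 x`. Priors are flat (improper) on the
  coefficients; the precision needs a proper prior and gets a weak
  half-normal(0, 50). The sampler is adaptive random-walk Metropolis on
  `(b0, b1, log phi)`: during the 2000-iteration warmup the proposal
  covariance is taken from the chain history (scaled 2.38^2/d) and a
  global step scale is tuned toward ~0.3 acceptance; the kernel is then
  frozen and 2000 iterations per chain are retained across 4 chains
  (8000 draws). A 3-parameter, unimodal posterior does not need gradient
  methods. Split R-hat above 1.05 flags the fit as non-converged —
  reported, never silent. Tail probabilities such as P(slope <= 0) are
  reported as raw fractions of retained draws together with the draw
  count (a fraction of 1/8000 is 0.000125, not 0.000125%).
* `simulate_beta_data()` — the matching generator. Defaults draw the
  covariate uniformly on [0, 0.15], the observed range of zombie
  fractions. For the zombie-vs-SAR11 model the analysis scripts use
  [0, 0.5] (SAR11 relative abundances reach roughly half of total
  cells), and for the FDC model the covariate stays on its percent
  scale, where the printed slope magnitude (about 0.04 per percentage
  point) lives. The third printed regression is implemented as
  infected ~ FDC: its reported slope and interval match the
  division-rate relationship, and FDC is the only covariate on that
  scale.

## Problem sizes and reproducibility

The test-suite and acceptance scales are chosen to make binomial and
posterior uncertainties small relative to the effects under test while
keeping a laptop run comfortable: negative-control audits pool ~5,000
cells over 25 fields of 768x768 px; the bloom-peak recovery uses ~1,100
SAR11 cells over 8 fields; ground-truth equivalence runs 100 independent
noise-free scenes; regression recovery uses the study's n = 148 with 20
independent seeds per model. Every stochastic step takes an explicit
seed, and identical seeds give bit-identical images, tables and draws.

## Known limitations

* Ellipse cells and Gaussian optics are idealizations; segmentation on
  real micrographs would additionally need illumination correction and
  cell-shape-aware splitting of touching cells, which the non-overlap
  placement deliberately sidesteps so that gating errors are measured in
  isolation.
* The channel thresholds are conventions exposed in `gate_config()`, not
  calibrations against any instrument; the original analysis tool's
  channel-specific settings are not public.
* The probe scorer automates what was originally manual curation; the
  count, length, GC and identity constraints are enforced exactly, but
  the gene-preference weights are a simple stand-in for expert choice.
* The Metropolis sampler is adequate for these 3-parameter posteriors;
  models with more covariates would warrant gradient-based samplers.
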