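---
title: "Quantifying cohesin clustering in imaging screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cohesin clustering in imaging screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesinscreen)
```

# The phenotype and the statistic

When cohesin unloading is blocked — for example by depleting the unloader
WAPL — cohesin accumulates into punctate, axial structures on chromatin
("vermicelli"). The degree of this clustering responds to the whole cohesin
life cycle: depleting the loader NIPBL suppresses it, depleting WAPL or the
unloading cofactors PDS5A/B enhances it. A high-content screen can therefore
read out cohesin regulation from immunofluorescence images of the RAD21
subunit alone, at a throughput no genomic method matches.

The clustering statistic is a **granularity spectrum**, a grayscale
granulometry. For a nucleus mask $M$ and marker raster $I$:

1. **Background subtraction.** The local background is the morphological
   opening of $I$ with a disc of radius $r$ (default 60 px); the non-negative
   residue $I' = \max(I - I \circ D_r,\, 0)$ retains structures smaller than
   the disc and cancels any additive offset.
2. **Erosion–reconstruction ladder.** Starting from $I'_0 = I'$, each scale
   $i = 1 \dots L$ erodes with a radius-1 disc (the 4-neighbourhood cross),
   $E_i = \varepsilon(E_{i-1})$ with $E_0 = I'$, then reconstructs under $I'$
   by geodesic dilation to its fixpoint, $R_i = \rho_{I'}(E_i)$.
3. **Spectrum.** With $m_i = \operatorname{mean}_M(R_i)$ and
   $m_0 = \operatorname{mean}_M(I')$, the spectrum element is
   $g_i = 100\,(m_{i-1} - m_i)/m_0$ — the percent of starting signal that
   lives at scale $i$.

Reconstruction means are non-increasing, so $g_i \ge 0$ and
$\sum_i g_i \le 100$ on any input; the spectrum is invariant to positive
rescaling (the normalization) and to additive offsets (the opening residue).
The **clustering score** is the second element of a length-5 spectrum:
punctate cohesin clusters a few pixels across lose most of their mass at the
second erosion scale, while diffuse nucleoplasmic signal does not survive
background subtraction at all.

Everything is evaluated **per nucleus** (mask = one segmented nucleus), with
pixels outside the mask set to zero for the erosion/reconstruction iteration.
Nuclei come from two-class Otsu thresholding of the DAPI channel followed by
8-connected component labeling, hole filling, a minimum-area filter (200 px)
and removal of border-touching components. Otsu is computed over a 256-bin
histogram of the observed intensity range with exact per-bin intensity sums,
so the returned threshold is identical to an exhaustive search over all bin
edges; ties break toward the smaller threshold.

# Screen statistics and hit calling

Per well, the median per-nucleus score is the well statistic; wells with
fewer than 200 segmented nuclei are dropped (the screen imaged >200 nuclei
per well; the exact retention rule of the original screen is not recorded,
so the threshold is a configurable default). Per plate and replicate,
$z = (\text{median} - \mu)/\sigma$ with the sample standard deviation, where
$\mu, \sigma$ come from the assay wells only: controls sit at fixed border
positions and would otherwise bias the plate statistics (they are still
scored against the same population).

Hit calling proceeds in narrowing rounds, all inequalities strict:

| Round | Rule |
|---|---|
| primary, suppressor (NIPBL-like) | $z < -2.1$ in both replicates, or $z < -2.45$ in any |
| primary, enhancer (WAPL/PDS5-like) | $z > 2.45$ in both replicates, or $z > 2.9$ in any |
| de-pooled, suppressor | best of 4 siRNA fold changes $< 0.80$ and second best $< 0.90$ |
| de-pooled, enhancer | best $> 1.30$ and second best $> 1.10$ |
| secondary, suppressor | any siRNA with KO fc $< 0.87$ **and** degron fc $< 0.90$ |
| secondary, enhancer | $\ge 2$ of 3 assays passed: KO ($>1.1$ \& degron $>1.1$), siWAPL ($>1.15$ \& $>1.1$), hit alone ($>1.15$ \& $>1.1$) |
| stratification | enhancer with CTCF fc $< 0.93$ is PDS5-like, else WAPL-like |

Fold changes are well medians over the same-plate nontargeting-control
median. Genes in the degron/proteasome machinery (SKP1, CUL1, RBX1, ...) are
force-excluded in the primary round, since their depletion rescues WAPL
rather than regulating cohesin. For the "hit alone" assay the gate is applied
to the hit-alone fold change paired with the degron fold change; the source
protocol's prose and figure annotations differ on this point and the
figure reading is implemented. Hit calls replace the significance tests shown
alongside the published figures: the calling rules themselves are effect-size
gates, and ANOVA/Dunnett testing never enters a call.

The control band diagnostic reports the fraction of nontargeting fold
changes within ±7% of the control median; for well-behaved controls with 3%
coefficient of variation the expected capture is
$\Phi(7/3) - \Phi(-7/3) \approx 98\%$.

# DNA-FISH distances

Inter-TAD interaction is read out as the center-to-center distance (CCD)
between two FISH-labeled adjacent domains on one allele. Spots are detected
per nucleus by **robust background** thresholding: discard the top and
bottom 5% of in-nucleus intensities, threshold at trimmed mean + 2 trimmed
SDs, label 8-connected components, filter by area, and take
intensity-weighted centroids. The minimum spot area is 9 px: a
diffraction-limited spot thresholded near its base covers at least a 3×3
pixel core at ~0.108 µm/px, while shot-noise excursions form smaller
components. Spots outside all nuclei are discarded.

Cross-channel spots are paired **destructively and greedily**: all A×B
distances within a nucleus are sorted ascending (ties broken by A then B
index) and consumed; a pair is accepted if both spots are free and the
distance is within the cutoff (default 2.0 µm — the cutoff is an empirical
parameter and is recorded in output metadata). An exhaustive
minimum-total-distance assignment is available behind `method = "optimal"`
for sensitivity analysis only; per-nucleus spot counts are small enough for
exact search. Distances are 2D (the assay analyzes maximum projections).

# The synthetic-data generators

All quantitative guarantees are exercised on synthetic data with known
ground truth, since the original screen's raw images are not deposited.

**Nuclear fields** (`simulate_field`): non-overlapping ellipses (semi-major
axis 18–28 px with mild eccentricity jitter, placed by rejection sampling),
a flat DAPI level inside nuclei, and a marker channel of diffuse
nucleoplasmic signal (500 counts) plus Gaussian-profile clusters
(σ = radius/2, default peak 1500 counts, 10 per nucleus). Noise is Poisson
shot noise on the expected intensity followed by additive Gaussian read
noise (SD 50); the two terms are independently switchable so degenerate
configurations can be tested exactly. Intensities are arbitrary camera
units on a 16-bit scale — no public intensity statistics exist for the
original RAD21 fields, so these are realistic but uncalibrated choices.

**FISH fields** (`simulate_fish_field`): 512×512 px fields of larger nuclei
(24–32 px semi-axis), two allele pairs per nucleus, one Gaussian spot
(σ = 1.5 px, peak 3000) per channel per allele, pair separation drawn from
a truncated normal in micrometres. Allele pair midpoints are kept far
enough apart that every cross-allele distance exceeds the true pair
distances, emulating separate chromosome territories; because an early
allele can land where no second allele fits, the whole allele set of a
nucleus is placed jointly and restarted on failure. Geometry rejects a
small fraction of large separations, so realized truth CCDs sit ~1–3%
below the nominal mean; the truth tables record the realized values and
recovery is judged against them.

**Screen tables** (`simulate_screen_tables`): 384-well plates with 104
border control wells and 280 assay wells (the original plate design), one
well per gene per replicate, baseline score 5 with multiplicative planted
effects (suppressors 0.5×, enhancers 1.5×, 2% each) and additive well noise
of 0.25 score units (5% of baseline) — the conditions under which
recovery is benchmarked. Under these conditions the expected
between-replicate correlation of z-scores is
$\sigma^2_{\text{effect}} / (\sigma^2_{\text{effect}} + \sigma^2_{\text{noise}})
\approx 0.80$, matching the replicate concordance the screening platform
was designed to achieve.

## What the generators do not emulate

Real chromatin texture, cell-cycle heterogeneity, mitotic and apoptotic
nuclei, touching nuclei, field illumination gradients, optical PSFs beyond
Gaussian spots, and 3D structure (fields are 2D; projections are taken as
given). Passing tests therefore demonstrate the correctness of the
*computations* — segmentation, granulometry, normalization, calling rules,
pairing — under a controlled imaging model, not robustness to every
pathology of real microscopy.

# Numerical choices and edge cases

* **Morphology engine.** Grayscale erosion/dilation run through EBImage,
  wrapped in an affine rescale to its [0, 1] domain (erosion and dilation
  commute with positive affine maps); border handling is min/max over
  in-bounds pixels. Geodesic reconstruction iterates
  $\min(\delta(\text{marker}), \text{mask})$ to its fixpoint.
* **Connectivity.** Foreground components are 8-connected everywhere, by
  in-package min-label propagation.
* **Degenerate inputs.** A constant DAPI raster yields an empty
  segmentation with a warning (plate processing continues); a constant
  marker region yields an all-zero spectrum flagged `zero_signal`; Otsu on
  a constant raster and granulometry on an empty mask are errors.
* **Score response range.** The clustering score is a percentage of
  background-subtracted signal. Below the noise floor (cluster peaks under
  a few hundred counts at read-noise SD 50) the spectrum is dominated by
  noise speckle and the score is *not* monotone in cluster amplitude; far
  above it, the percentage saturates toward the cluster-shape spectrum.
  Monotonicity holds, and is tested, across the response range
  (~300–5000 counts under the default noise model).
* **Subsampling.** The granulometry exposes `subsample_fraction` and
  `background_sample_fraction` (both default 1 = off) so conventions that
  downsample before granulometry (e.g. 0.25) can be reproduced; the
  background radius scales with both factors, with bilinear interpolation
  for rasters and nearest-neighbour for masks.
* **Determinism.** Every generator consumes one seed through an isolated
  RNG scope; identical configuration + seed reproduces outputs
  bit-for-bit, and `run_pipeline` writes an MD5-checksummed manifest.
* **Verification panel sizes.** The granulometry oracle panel uses 50
  randomized fields of 32–128 px with background radii 6–12 and a plain-R
  literal reference implementation; the structuring-element radius does not
  change the code path, and these sizes keep the reference loop exact and
  fast. Screen-recovery benchmarks use 1000 genes × 2 replicates × 10
  seeds; FISH benchmarks use 25-nucleus fields.

# Known limitations

* The granulometry agrees with the morphological definition to machine
  precision but is not a bit-for-bit reproduction of any specific
  CellProfiler release (whose sampling options for the original screen are
  not fully recorded).
* The well-retention criterion and the FISH pairing cutoff of the original
  screen are unknown; both ship as documented, configurable defaults.
* Greedy pairing is order-dependent by design (it reproduces the screen's
  destructive iteration); the optimal-assignment flag exists to quantify
  that choice, not to replace it.
* With two alleles per nucleus in cramped nuclei, greedy pairing can
  cross-pair alleles if territories overlap; the generator avoids this by
  construction, real data cannot be guaranteed to.
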