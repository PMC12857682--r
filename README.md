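# cohesinscreen

Analysis toolkit for high-content imaging screens that quantify **cohesin
clustering** in interphase nuclei. When cohesin unloading is impaired
(partial WAPL loss), cohesin — imaged through its RAD21 subunit —
accumulates into punctate structures whose intensity "granularity" reports
on the whole cohesin life cycle: depleting the loader NIPBL suppresses
clustering, depleting WAPL or PDS5A/B enhances it. Screening siRNA
libraries against this phenotype identifies regulators of genome folding
without any genomic assay.

The package is aimed at image-analysis and screening groups who want the
complete, testable analysis chain:

* **Synthetic data with ground truth** — nuclear fields with controllable
  punctate clustering, two-colour DNA-FISH fields with paired allele spots,
  and full plate-format screen tables with planted suppressor/enhancer
  effects (`simulate_field`, `simulate_fish_field`,
  `simulate_screen_tables`).
* **Segmentation** — two-class Otsu thresholding of DAPI plus 8-connected
  components (`otsu_threshold`, `segment_nuclei`).
* **The clustering statistic** — per-nucleus grayscale granulometry: after
  background subtraction by a radius-60 disc opening, the image is
  repeatedly eroded and reconstructed under itself, and the percent of
  signal removed at each scale forms the granularity spectrum
  `g_1..g_5`; the second element is the clustering score
  (`granularity_spectrum`, `clustering_score`, `score_field`).
* **Screen statistics** — per-well medians, plate-wise z-scores
  (`z = (well median − plate mean) / plate SD` over assay wells), and the
  multi-round hit-calling rules: primary z-gates (−2.1/−2.45 and
  2.45/2.9), de-pooled two-best-siRNA fold-change gates (0.80 & 0.90 down,
  1.30 & 1.10 up), secondary dual gates across orthogonal WAPL-depletion
  assays with a 2-of-3 overlap rule, and WAPL- vs PDS5-like stratification
  by CTCF clustering (`plate_zscores`, `call_primary_hits`,
  `prioritize_depooled`, `call_secondary`, `stratify_ctcf`).
* **DNA-FISH distances** — robust-background spot detection, destructive
  greedy allele pairing under a distance cutoff, and center-to-center
  distance (CCD) summaries with fold changes versus nontargeting controls
  (`detect_spots`, `pair_spots`, `summarize_ccd`).

## Worked example

Score a simulated field and call hits on a simulated 1000-gene screen:

```r
library(cohesinscreen)

## image level: simulate, segment, score
f   <- simulate_field(field_sim_config(seed = 1))
seg <- segment_nuclei(f$dapi)
scores <- score_field(f$marker, seg$labels)
head(scores[, c("label", "n_pixels", "g_1", "g_2", "g_3", "score")], 4)
#>   label n_pixels   g_1   g_2   g_3 score
#> 1     1     1446 1.966 3.723 3.906 3.723
#> 2     2     1184 1.765 3.427 7.299 3.427
#> 3     3      885 1.838 3.605 2.872 3.605
#> 4     4     1473 1.555 3.500 6.411 3.500
```

Each row is one nucleus: `g_1..g_5` is the percent of background-subtracted
RAD21 signal removed at each erosion scale, and `score` (= `g_2`) is the
clustering statistic — diffuse nuclei score near 2, clustered nuclei well
above.

```r
## screen level: simulate plates, z-score, call primary hits
res <- run_pipeline(screen_sim_config(n_genes = 1000L, seed = 1L))
res$confusion
#>                 called
#> truth            NIPBL-like none WAPL/PDS5-like
#>   NIPBL-like             20    0              0
#>   none                    0  960              0
#>   WAPL/PDS5-like          0    0             20

head(res$hits[res$hits$class != "none", c("gene", "class", "z_rep1", "z_rep2")], 4)
#>         gene          class    z_rep1    z_rep2
#> 37  GENE0037 WAPL/PDS5-like  6.514922  5.615219
#> 105 GENE0105 WAPL/PDS5-like  4.370601  5.513290
#> 111 GENE0111 WAPL/PDS5-like  6.020760  5.436652
#> 129 GENE0129     NIPBL-like -4.596362 -5.219107
```

Under the default study conditions (2% planted suppressors at 0.5×, 2%
enhancers at 1.5×, 5% well noise, two replicates) all 40 planted modifiers
are recovered in the correct direction with no false calls.

See the vignette (`vignettes/cohesin-clustering-screen.Rmd`) for the full
account of the statistic, the calling rules, the synthetic-data model and
its limits.

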