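# menquant

Single-cell quantification of mitotic exit network (MEN) signaling in
budding yeast, for microscopists and proteomics analysts studying how the
Dbf2-Mob1 kinase relays the mitotic-exit signal from the spindle pole
bodies (SPBs) to the nucleolus, where the phosphatase Cdc14 is held by its
inhibitor Cfi1/Net1.

The package implements, as tested reusable functions:

* **FRAP analysis** — double normalization
  *I*<sub>FRAP</sub>(t) = [*I*<sub>norm</sub>(t) − *I*<sub>norm</sub>(0)] /
  [*I*<sub>norm</sub>(pre) − *I*<sub>norm</sub>(0)] with
  *I*<sub>norm</sub> = *I*<sub>SPB</sub>/*I*<sub>cytosol</sub>, and
  least-squares fitting of the recovery
  *y* = *y*<sub>max</sub>(1 − e<sup>−ln2·t/t<sub>1/2</sub></sup>);
* **imaging** — FFT drift correction, Otsu marker segmentation, SPB
  detection, backward-overlap cell tracking, mother–bud assignment;
* **per-cell metrics** — SPB/nucleolar relative enrichment
  (*I*<sub>site</sub>/*I*<sub>cytosol</sub> − 1), reporter pixel CV
  (sd/mean), nucleolar *I*<sub>Cdc14</sub>/*I*<sub>Cfi1</sub> ratio and the
  relative-release statistic
  1 − r(t<sub>min</sub>)/r(t<sub>−20</sub>), anaphase onset (spindle
  length > 3 µm), bud entry, and the optogenetic recruitment slope
  (*I*<sub>PIF</sub> = α + β·*I*<sub>PhyB</sub>);
* **ensembles** — event-aligned averaging with 95% bands
  (μ ± 1.96·σ/√n) and the two-sided Wilcoxon rank sum test (exact for
  combined n ≤ 10);
* **omics** — TurboID enrichment ratios with the 10-SD hit threshold, and
  differential phosphoproteomics (R > 2 & BH-adjusted p < 0.05 plus two
  detection-rescue rules), single-phosphopeptide-priority site calls,
  CDC5-only set subtraction, residue zones and site-catalog merging;
* **synthetic data** — generators for movies, FRAP traces, peptide tables
  and TurboID counts with known ground truth, so the whole pipeline is
  testable without microscopy or MS data.

## Worked example

Simulate a FRAP trace with a known half-recovery time, then a dividing
cell with planted nucleolar enrichment, and quantify both:

```r
library(menquant)

tr  <- generate_frap_trace(t_half = 4.6, plateau = 0.8, noise_sd = 0.05,
                           seed = 7001)
fit <- fit_recovery(tr)
fit
#> Recovery fit: ymax = 0.788, t1/2 = 4.414 s (rss 0.0417, 31 points)

cfg <- movie_config(n_cells = 1, noise_sd = 0.05, seed = 21)
sim <- generate_movie(cfg)
sim$movie
#> Movie: 40 frames x 3 channels (spb, nucleolus, probe), 120 x 120 px,
#> 0.2 um/px, 3 min/frame

masks <- merge_mother_bud(sim$truth$cell_masks, sim$truth$events)
m     <- quantify_movie(sim$movie, masks)
s     <- sim$truth$spb
onset <- detect_anaphase_onset(
  as.matrix(s[s$role == "d", c("row", "col")]),
  as.matrix(s[s$role == "m", c("row", "col")]),
  cfg$pixel_size_um)
onset
#> [1] 15
```

The fitted half-time (4.41 s) recovers the planted 4.6 s within the noise,
and onset is detected at the scheduled frame 15. Aligning the nucleolar
enrichment trace on onset shows the planted anaphase enrichment of 2:

```r
nuc  <- m$value[m$metric == "nucleolar_enrichment"]
band <- mean_ci(align_traces(list(cell1 = nuc), onset, frame_interval = 3))
subset(band, rel_frame %in% c(-2, 0, 4, 10))[, c("time_min", "mean", "n")]
#>    time_min  mean n
#> 13       -6 0.009 1
#> 15        0 0.000 1
#> 19       12 2.009 1
#> 25       30 2.020 1
max_enrichment(nuc, c(onset, sim$truth$events$exit_frame))
#> [1] 2.057
```

Before onset the probe is cytosolic (enrichment ≈ 0); during anaphase the
nucleolar enrichment plateaus at the planted value of 2 (measured 2.01 to
2.06 under 5% noise). `run_pipeline()` chains these stages from a YAML
configuration and writes per-cell metrics, event tables, aligned ensemble
bands, omics hit tables and a machine-readable run log.

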