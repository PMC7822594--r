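---
title: "Methods: quantifying mitotic exit network signaling with menquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitotic exit network signaling with menquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menquant)
```

## What the package measures

In budding yeast, exit from mitosis is triggered when the mitotic exit
network (MEN) — a Hippo-like kinase cascade anchored at the spindle pole
bodies (SPBs) — liberates the phosphatase Cdc14 from its nucleolar
inhibitor Cfi1/Net1. menquant implements the quantitative toolkit with
which this signal propagation is measured in single cells and in bulk
phosphoproteomes:

* **FRAP turnover** of an SPB-localized kinase (double normalization +
  single-exponential recovery fit);
* **compartment enrichment** of a probe at SPBs and in the nucleolus over
  the cell cycle;
* **translocation** of a nuclear kinase-activity reporter (pixel CV);
* **Cdc14 release** from the nucleolus (per-pixel Cdc14/Cfi1 ratio and a
  relative-release summary);
* **optogenetic recruitment** (pixel-regression slope);
* **event-aligned ensemble averages** with 95% confidence bands and
  rank-sum comparisons;
* **hit calling** for TurboID proximity labeling and for
  kinase-dependence phosphoproteomics, down to per-site strong/weak
  labels, the CDC5-only subtraction, residue zones and catalog merging.

Every stage is exercised end to end on a synthetic-data module with known
ground truth, so no microscopy or mass-spectrometry data are required to
validate the code paths.

## FRAP: double normalization and recovery fitting

A FRAP trace consists of background-subtracted intensities at the bleached
SPB, $I_{SPB}(t)$, and in the cytosol of the same cell, $I_{cytosol}(t)$.
Acquisition photobleaching is corrected by the ratio
$I_{norm}(t) = I_{SPB}(t)/I_{cytosol}(t)$, and the trace is rescaled
between the first post-bleach frame (0) and the pre-bleach frame (1):

$$I_{FRAP}(t) = \frac{I_{norm}(t) - I_{norm}(0)}{I_{norm}(pre) - I_{norm}(0)}.$$

By construction the output is exactly 0 at the bleach frame and 1 at the
pre-bleach frame, and it is invariant to any positive per-frame gain
applied to both channels — the property that makes the statistic immune to
photobleaching. The normalized series is then fitted on the post-bleach
frames to

$$y = y_{max}\left(1 - e^{-\ln 2\, t / t_{1/2}}\right),$$

where $y_{max}$ is the recovered (mobile) fraction and $t_{1/2}$ the
half-recovery time; at $t = t_{1/2}$ the model value is $y_{max}/2$.
Fitting uses Levenberg–Marquardt least squares with starting values
$y_{max}$ = last observed value and $t_{1/2}$ = first half-crossing time;
both parameters are bounded positive. Non-convergence is reported via a
flag rather than an error. On noiseless model data the fit recovers the
generating parameters to better than $10^{-6}$ across
$t_{1/2} \in [1, 60]$ s (tested), provided the acquisition covers several
half-times.

When several pre-bleach images exist, the single frame immediately
preceding the bleach is the reference; averaging all pre-bleach frames is
available via `average_pre = TRUE`.

The FRAP generator plants a known $(t_{1/2}, y_{max})$, embeds the model
into raw SPB/cytosol series with an exponentially bleaching cytosolic
reference (0.01/frame) and a 75% bleach depth, and adds Gaussian noise
*on the normalized scale*, so `noise_sd` is directly the scatter of the
double-normalized values around the model. The two anchor frames (pre and
bleach) stay noise-free: perturbing them would rescale the whole trace
rather than scatter points about it.

## Imaging: drift, segmentation, SPB detection, tracking, buds

*Drift correction* estimates integer-pixel shifts by maximizing
frame-to-reference cross-correlation (computed by FFT, searched within a
±10 px window) and resamples all channels identically. The reference is
the last frame, which also anchors tracking. Use a spatially static
channel for alignment — the nucleolar marker works well; point-like SPB
markers move biologically between frames and can dominate the correlation
peak. Sub-pixel registration is deliberately omitted: all downstream
metrics are ratio- or median-based and insensitive to half-pixel errors.

*Marker segmentation* applies an Otsu threshold to background-subtracted
pixels and labels connected components, discarding objects under 4 px. A
blank image yields an empty labeling, not an error.

*SPB detection* finds up to two local maxima of the SPB-marker channel
inside a cell mask, requiring peaks to exceed the in-mask median by both
3 median absolute deviations and 25% of the median (so a uniform cell
yields no detections), with a 3 px minimum separation.

*Tracking* propagates identities backward from the last frame by maximal
mask overlap, with ties broken by larger overlap then lower id; unmatched
objects start or terminate tracks. On well-separated cells this equals
brute-force bipartite maximal-overlap matching (tested).

*Bud assignment* follows marker migration: a tracked cell in which the
cell-cycle marker first appears after the first frame is a bud, and its
mother is the cell that hosted the same (tracked) marker object in the
preceding frame. Ambiguous migrations leave the bud unassigned with a
warning. The daughter/mother SPB labels are only meaningful once bud entry
is detected; no attempt is made to disambiguate them earlier.

*Background* is the median intensity outside the union of cell masks; a
fully covered frame is an error instructing the caller to supply an
estimate.

## Per-cell metrics

All enrichment statistics operate on background-subtracted images and are
invariant to a global multiplicative gain (tested in both directions: gain
invariance holds, offset invariance deliberately does not).

* SPB enrichment: $\max(I_{probe}$ in a 2 px-dilated disk around the SPB
  point$) / \mathrm{median}(I_{probe}$ in cytosol$) - 1$. The 2 px
  dilation covers the diffraction-limited point-spread of the rendered
  spot. The cytosol is the cell mask minus the nucleolus and the dilated
  SPB disks.
* Nucleolar enrichment: median over the nucleolus mask in the numerator.
* Reporter CV: sd/mean of reporter pixels within the dividing cell
  (mother plus bud, since the reporter redistributes between the two);
  population (n) standard deviation, computed on background-subtracted
  pixels by default.
* Nucleolar Cdc14/Cfi1 ratio: mean of per-pixel ratios within the
  nucleolus; pixels whose denominator falls below 5% of the in-mask
  median are excluded to avoid ratio blow-up on dim pixels.
* Relative release: $1 - r(t_{min})/r(t_{-20})$ where $r$ is the
  nucleolar ratio trace, $t_{-20}$ the frame 20 min before bud entry of
  the daughter SPB and $t_{min}$ the minimal-ratio frame searched from
  $t_{-20}$ to the end of the trace (earliest frame on ties). Cells
  whose trace does not reach 20 min before bud entry are excluded with an
  explicit status. The statistic is 0 for constant traces, 1 for complete
  release, and never exceeds 1 for positive traces.
* Anaphase onset: first frame of at least two consecutive frames with
  inter-SPB distance above 3 µm; requiring two frames resists
  single-frame detection noise. Bud entry: first frame with the daughter
  SPB point inside the bud mask.
* Optogenetic recruitment: ordinary least squares of target (PIF) pixel
  intensities on anchor (PhyB) pixel intensities within the cell;
  the slope $\beta$ measures enrichment in the anchored region and is
  robust to target photobleaching and to the anchored region's geometry.

## Ensembles and comparisons

Single-cell traces are aligned on their event frame (anaphase onset or
dSPB bud entry), padded with missing values, and averaged pointwise. The
95% confidence band is $\mu \pm 1.96\,\sigma/\sqrt{n}$ with the sample
(n−1) standard deviation and the per-time non-missing count $n$; the
$\sigma/n$ form is available as a compatibility switch
(`se_mode = "sd_over_n"`) for reproducing legacy band definitions.

Group comparisons use the two-sided Wilcoxon rank sum test: exact
enumeration of the rank-sum null over all assignments for combined
$n \le 10$ (ties handled by midranks), and the tie-corrected,
continuity-corrected normal approximation otherwise. At combined
$n = 10$ the approximation is within 0.01 of the exact p throughout the
decision-relevant tail (exact $p \le 0.2$); its absolute deviation peaks
around 0.017 near $p \approx 0.4$, where no decision depends on it. Fully
tied data return $p = 1$.

## Omics hit calling

**TurboID.** Per-protein enrichment is
$(\mathrm{tagged} + 1)/(\mathrm{control} + 1)$ — the pseudocount keeps
proteins absent from the untagged control defined — and hits exceed the
mean ratio by 10 standard deviations. Note an arithmetic property of this
rule: among $n$ ratios, a single outlier's z-score is bounded by
$n/\sqrt{n+1}$, so the threshold is only operable on realistically sized
tables (hundreds of quantified proteins, as in an actual MS run); the
synthetic tables used in tests contain 300 background proteins.

**Differential phosphoproteomics.** For each peptide in a WT-versus-
inhibited (as1) contrast, with replicate intensities and missing values
treated as non-detections (never zero-imputed):

1. peptides detected in ≥2 replicates per condition get
   $R = \overline{WT}/\overline{as1}$ (detected intensities only) and a
   two-sided pooled-variance Student's t-test on log intensities,
   BH-adjusted across all tested peptides of the contrast; hits satisfy
   $R > 2$ and $p_{adj} < 0.05$;
2. peptides never detected in as1 but detected in
   $\ge \lceil\frac{5}{7} n_{WT}\rceil$ WT replicates are hits regardless
   of p (5 of 7 in the default design; 4 of 6 for a 6-replicate design);
3. peptides detected in exactly one as1 replicate, with the rule-2 WT
   minimum and $\overline{WT}/(\text{the single as1 value}) > 2$, are
   hits.

The ratio uses means (not medians) across detected replicates, and rule
3's denominator is the single as1 value — both choices where the source
description is silent, recorded here as the package's defaults. The
Welch test is available via `var_equal = FALSE`.

**Site calls.** Peptide hits map to sites with singly phosphorylated
peptides given priority: a site covered by single-phospho peptides is a
*strong* hit only if all of them are hits (one non-hit vetoes it); a site
seen only in multi-phospho peptides is a *weak* hit when at least one
covering peptide is a hit — a multi-phospho peptide cannot attribute its
loss to one specific site, hence the weaker label. The any-hit reading
for weak sites is one of two defensible interpretations of the rule; it
is the more permissive one and is fixed here as the package's definition.

**Set logic.** CDC5-only sites are the set difference of CDC5-dependent
minus CDC15-dependent sites — the sites attributable to direct Cdc5
phosphorylation rather than to loss of MEN activity. Zones z1 = 31–69,
z2 = 160–615, z3 = 676–840, z4 = 1017–1166 (inclusive bounds, matching
the residues-X–Y naming convention) label sites by region; catalog
merging is a distinct-set union over (protein, residue) pairs, residues
1-based throughout.

## The synthetic-data module

The generators define the conditions under which everything is tested;
they are first-class, tested code.

*Movies* (`movie_config()` + `generate_movie()`): 120×120 px at
0.2 µm/px, 40 frames at 3 min/frame, 1–3 cells — a desk-scale analog of
multi-hour acquisitions. Cells are disks (12 px mother radius) with a
nucleolar disk offset perpendicular to the spindle axis; a bud appears at
its scheduled frame and grows; the spindle elongates so that it crosses
3 µm exactly at the scheduled onset frame and pushes the daughter SPB
into the bud about two frames later (the recorded entry frame is derived
from the same geometry that is rendered, so truth and pixels agree).
SPBs are 2D Gaussians with σ = 1 px, reflecting that real SPBs are below
the diffraction limit. Probe enrichment at SPBs (default 4) and in the
nucleolus (default 2) switches on during anaphase; an optional Cdc14-like
channel dips in the nucleolus after bud entry with a configurable planted
release depth, and an optional reporter channel collapses from
nuclear-high to uniform at mitotic exit. Signal is scaled by a common
per-frame photobleaching factor, shifted by the (rounded) cumulative
drift, offset by a constant camera background, and degraded with
multiplicative Gaussian noise (sd proportional to signal) — a tractable
stand-in for shot noise, declared as such rather than a claim about any
instrument. Movies are generated and analyzed in 2D, faithful to the
maximum-projection representation on which the original quantification
operated.

What the movie generator does *not* emulate: bright-field images (cell
masks come from the generator — the published bright-field segmenter is
prior work and out of scope), irregular cell shapes, focus drift,
overlapping or colliding cells, and camera-specific noise. Passing tests
therefore demonstrate correctness of the measurement code under
idealized geometry, not robustness to real microscopy artifacts.

*Peptide tables*: log-normal intensities (per-peptide baseline spread
0.5 log units around 10^6), replicate CV via
$\sigma_{\log} = \sqrt{\log(1 + cv^2)}$ with the mean-preserving
$-\sigma^2/2$ offset, planted fold drops in the inhibited condition, and
missingness through a detection floor — values below the floor are
recorded as missing, the way an MS detection limit silently drops low
signals. *TurboID tables*: Poisson counts around log-normal per-protein
rates, background ratios scattered around 1, planted interactors enriched
by a configurable factor.

## Numerical choices and degenerate inputs

* Double normalization errors on zero bleach depth; cytosol intensities
  must be strictly positive.
* Recovery fits flag rather than fail on non-convergence and report
  starting values with a warning.
* Otsu segmentation of a constant image returns an empty labeling.
* Tracking ties: larger overlap, then lower cell id.
* Release statistic ties: earliest minimal frame.
* Rank-sum on fully tied data: p = 1. Exact/normal switch at combined
  n = 10.
* TurboID with zero ratio variance: warning, empty hit set.
* Pipeline runs are deterministic given the configuration and seed; the
  run log (JSON) records package version, seed and parameters.

## Problem sizes

The test suite and the acceptance script use the simulation sizes quoted
above (40-frame 120 px movies with up to 2 cells, 6 FRAP traces of ~33
frames, peptide tables of ~53 sites × 7 replicates × 2 conditions, 300-
protein TurboID tables, 20-seed null calibrations). These are the
package's chosen validation scales; all complete in well under a minute
apiece on a single CPU.
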