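---
title: "Methods: multimodal quantification of cardiomyocyte phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal quantification of cardiomyocyte phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiopheno)
```

`cardiopheno` quantifies functional differences between two cardiomyocyte
populations — in the motivating application, first-heart-field (FHF,
TBX5+/NKX2-5+) versus second-heart-field (SHF, TBX5−/NKX2-5+) hESC-derived
cardiomyocytes — across six measurement modalities. Each analysis stage is
paired with a seeded synthetic-data generator whose output carries exact
ground truth, so every estimator in the package is validated by recovery
rather than by assertion. This vignette explains the models, the defaults,
what the generators do and do not emulate, and the numerical choices a
maintainer would want spelled out.

## Optical-mapping action potentials

Voltage-dye fluorescence at 500 frames/s is an uncalibrated, possibly
inverted, drifting proxy for transmembrane voltage. `normalize_trace()`
first resolves optical polarity: the orientation in which the steeper
extreme first difference is the upstroke is taken as "up", so inverted dye
signals (fluorescence decreasing on depolarization) are handled without
configuration. The slow baseline is then estimated by a running
order-statistic filter — the 0.25 quantile over a window of twice the
longest expected cycle length (2000 ms default) — evaluated on a coarse
grid, smoothed by a local line fit, and linearly extrapolated at the trace
edges. A running *median* is the more common choice, but a cardiac AP can
occupy half of each cycle, in which case the median rides above the
diastolic level and distorts amplitudes; a low quantile stays pinned to
diastole while following photobleaching drift. Within two cycle lengths of
a recording edge the baseline is partly extrapolated and APD estimates may
move by ~1–2 ms under strong drift; interior beats stay within half a
frame.

`extract_ap_features()` segments beats at upward crossings of a threshold
(default half of the site's global amplitude) with a 100 ms refractory
minimum and a Schmitt-trigger re-arm (the signal must fall below half the
threshold before a new beat can trigger; this stops noise re-triggering on
the repolarization ramp). Activation time is the discrete dV/dt-max
analogue: the midpoint of the steepest first-difference segment, refined by
parabolic interpolation of the derivative peak, which is unbiased at the
upstroke midpoint for a symmetric upstroke. APDx is the time from
activation until the trace first falls below peak − (x/100)·amplitude, with
linear interpolation between samples; cycle length is the difference of
successive activation times, computed before truncated beats are dropped.
APD30 ≤ APD80 is asserted per beat; violations are dropped as detection
failures with a warning.

Two refinements, both off by default so the noise-free semantics stay
exact, make the estimator usable at realistic noise: `smooth_ms` (we use
20 ms) applies a centred moving average for detection and level
measurement, with diastolic and peak levels taken as medians of raw-sample
windows anchored at the activation (medians avoid the upward bias of
extremes; anchoring at activation rather than at the argmax avoids
selection bias); `refine_ms` (we use 24 ms) re-fits each repolarization
crossing by an ordinary least-squares line on the raw samples around the
detected crossing — the ramp is locally linear, so the line's
level-crossing is an unbiased sub-frame estimate, free of the early bias
that first-passage detection suffers under noise. With 5% amplitude noise
at 500 fps, the mean recovered APD30/APD80/cycle length are within 2 ms
(one frame) of truth over 100 beats; individual beats scatter with a
standard deviation of ~5 ms, which no per-sample interpolation scheme can
avoid at that noise level.

The synthetic AP template is piecewise analytic: a linear upstroke (2 ms
default), a plateau, and a two-segment linear repolarization pinned so the
30% and 80% crossings sit exactly `apd30_ms` and `apd80_ms` after the
upstroke midpoint (the activation convention above). It deliberately
contains no ionic-current dynamics: passing recovery tests shows the
measurement chain is correct, not that the package can segment arrhythmic
or alternans recordings. Group comparisons use the classic pooled-variance
unpaired two-tailed Student's t test, with percent increase defined as
100·(mean_A − mean_B)/mean_B.

## AFM nanoindentation (Hertz model)

For a spherical tip of radius R indenting an incompressible sample
(Poisson ratio ν = 0.5 by default), force and indentation obey
F = (4√R/3)·E/(1−ν²)·δ^{3/2}. The instrument records piezo position z and
cantilever deflection d; the geometry z = contact + d + δ splits piezo
travel into bending and indentation. `force_indentation()` converts with
F = k·(d − d₀), d₀ the mean pre-contact deflection (at least 5 samples
required), and `fit_hertz()` estimates E by least squares of F against
δ^{3/2} through the origin — a closed form with no convergence tuning —
restricted to the range from contact to the maximum-force point. Units are
audited end to end: k in nN/nm with d, δ, z in µm yields E in Pa.

The contact point is treated as a free parameter: `find_contact_and_fit()`
grid-searches candidate contacts at the sample spacing, scoring each by the
full-curve mean squared force residual (zero-force model before contact,
best-fit Hertz beyond), then refines by golden-section search to a tenth of
the spacing, keeping the best point evaluated anywhere. On noise-free
curves this recovers E to better than 1e-6 relative. Under 5% force noise
the joint contact+modulus estimator carries an intrinsic upward bias of
~2–3% in per-curve E: the contact point is identified only by the
low-force, low-SNR region near touch, and its error couples convexly into
the modulus (a 2-parameter nonlinear fit shows the same bias — it is a
property of the estimation problem, not of the solver). When the contact
point is known (or taken from the instrument), the closed-form fit is
unbiased to within 0.1% at that noise level. Defaults mirror a typical soft
probe protocol: k = 0.286 nN/nm, 10 µm tip diameter, 3 nN force cap, with
cell stiffness reported as the mean modulus of five sites per cell.
Adhesion on retract, viscoelastic relaxation and substrate-thickness
corrections are out of scope; retract curves are parsed but unused.

## Quantitative-phase dry-mass motion

Phase shift (optical path difference) is proportional to dry mass:
mass per pixel = OPD·pixel area/α, with the specific refractive increment
α = 0.18 µm³/pg, a common literature value exposed as a parameter. Negative
OPD is clipped with the clipped fraction recorded.

Segmentation is local adaptive Otsu: per-tile thresholds (64 px tiles)
bilinearly interpolated to a per-pixel threshold surface, with
background-only tiles (dynamic range under a quarter of the frame's)
falling back to the global Otsu cut. Because an Otsu threshold sits near
the half-maximum of a smooth cell profile — capturing only ~half of a
Gaussian blob's mass — the mask is dilated by a disc (`dilate_px`, default
2 px; 10–12 px in our full-mass tests) before connected-component
labelling and a 50 px minimum-area filter. With that dilation, segmented
mass is within 2% of rendered mass at a peak signal-to-noise ratio of 10.

Tracking is greedy nearest-neighbour linking on mass-weighted centroids,
gated at `max_link_um` (20 µm default), with distance ties broken by the
smallest relative mass difference; merges and splits are not modelled, so
tracks end where clusters fuse. Per interval, net positional displacement
is the Euclidean centroid distance, and percent mass fluctuation is
100·Σ|m₂(x−s) − m₁(x)|/M₁ over the union of the two aligned masks, where s
is the *integer-pixel* shift aligning the centroids and M₁ the cell mass in
the earlier frame. Integer alignment is deliberate: sub-pixel interpolation
manufactures phantom mass differences on sharp profiles, whereas integer
alignment makes a rigid translation contribute exactly zero fluctuation.
The cost is that genuinely sub-pixel drift leaks a small positive
fluctuation; for the motile cells this metric targets, programmed
redistribution dominates that leakage. Mass accumulation rate is the slope
of a straight-line fit of track mass against time.

The generator renders truncated-Gaussian blobs (static, constant-velocity
drift, or a two-lobe "pulsate" model that shuttles a fraction f of the mass
between lobes on alternate frames, mimicking internal mass redistribution)
and refuses layouts where supports approach within a safety margin —
segmentation ambiguity is intentionally out of fixture scope. Its
ground-truth percent fluctuation is computed by direct pixel differencing
of the two rendered states, the same oracle the tests use.

## Single-cell QC and marker detection

QC follows three rules with strict less-than semantics, cells first and
then genes on the surviving cells: cells expressing fewer than 200 detected
genes or fewer than 3,000 UMIs are removed, then genes detected in fewer
than 3 of the remaining cells. A cell with exactly 200 genes, or a gene in
exactly 3 cells, is retained. The order matters only marginally in
practice, but it is fixed and documented so the marker lists feeding the
enrichment stage are bit-reproducible.

Normalization is value = ln(1 + 10⁴·count/cell total). Marker detection
tests every gene detected in at least `min_pct` (0.3) of the cells of at
least one group, using a two-sided Wilcoxon rank-sum test on the normalized
values: exact by enumeration over group assignments when both groups have
≤ 25 cells and the assignment count is enumerable (ties handled exactly;
the two-sided p doubles the smaller inclusive tail — the fully separated
3-vs-3 case gives p = 2/20 = 0.1), otherwise the normal approximation with
tie correction and no continuity correction. Fold change is
log2((mean₁+ε)/(mean₂+ε)) on de-logged normalized expression with ε = 1e-9;
BH correction runs across tested genes; group-1 markers are rows with
positive fold change. Bulk counts are normalized as TPM (rate =
count/length, scaled to 10⁶) followed by log2(TPM+1).

The count generator draws negative binomial counts around lognormal gene
means with lognormal library-size factors, plants markers via a fold
change plus a per-cell detection gate, and engineers QC casualties
(low-gene cells, low-UMI cells, near-silent genes). It does not emulate
ambient RNA, doublets or batch effects, so passing tests validate the
filter and test logic, not robustness to those artefacts. Its QC ground
truth is obtained by applying the rule definitions to the realized matrix
with independent dense arithmetic, which is why the removal-equality test
can be exact.

## Promoter-occupancy enrichment

The question: do a transcription factor's binding peaks overlap the
promoters of a marker gene set more often than chance? Promoters are
TSS ± 2 kb by default (strand-aware, clipped at chromosome bounds; the
window is a parameter and all results should be reported with the window
used). A gene is bound when its promoter shares at least 1 bp with any
peak, in half-open coordinate semantics ([0,10) and [10,20) do not
overlap); intervals live in `GRanges` and overlap uses the standard
interval machinery, cross-checked in tests against a brute-force
quadratic oracle.

For each factor, one upper-tail hypergeometric test per gene set:
p = Σ_{i=k}^{min(n,K)} C(K,i)·C(N−K,n−i)/C(N,n), accumulated in log space.
The universe N is the set of genes possessing promoter coordinates — the
population in which "bound" is defined — K its bound subset, n the gene-set
size and k its bound count. Ten random control sets of 150 genes are drawn
without replacement from the universe excluding both marker sets, so each
factor contributes a family of twelve tests, and BH correction is applied
within that family. Ortholog mapping (e.g. human markers onto a murine
promoter table) is an input table, not a computation. The genome fixture
places genes on a spaced grid so promoters can never abut and each gene's
bound state equals its programmed Bernoulli draw exactly, which makes both
the degenerate placements and the type-I calibration testable; p_in =
p_out is the legitimate null configuration.

## Mitochondrial stress test

A four-phase OCR trace (basal, post-oligomycin, post-FCCP,
post-antimycin-A) is reduced to phase levels by the conventional
reductions — last basal measurement, post-oligomycin minimum, post-FCCP
maximum, post-antimycin minimum — with a mean-of-phase alternative
(`method = "mean"`) that is unbiased under noise where the order statistics
are not. Parameters follow the standard decomposition: non-mitochondrial =
L4, basal = L1 − L4, ATP-linked = L1 − L2, proton leak = L2 − L4, maximal =
L3 − L4, spare capacity = maximal − basal; basal ≡ ATP-linked + proton leak
holds exactly by construction, which also means a group difference in
ATP-linked respiration at fixed basal and non-mitochondrial OCR *must* be
mirrored in proton leak — there is no four-level configuration that moves
only one of the two. Normalization divides by cell count/1000
(per-1000-cells units keep magnitudes readable); raw values are always
retained. ECAR is carried through to phase summaries untransformed; no
derived ECAR parameters are defined.

## Pipeline and reproducibility

`run_pipeline()` executes requested stages in dependency order from a
config (R list or YAML), derives per-stage child seeds deterministically
from one global seed, and writes a manifest with parameters, seeds, output
paths and MD5 hashes; two runs from the same config and seed are
byte-identical, which the suite asserts. Unknown config keys are rejected
by name. All generator randomness flows through a private RNG stream that
never touches the caller's `.Random.seed`. File formats are plain text or
standard containers: wide CSV for traces, CSV + JSON sidecars for curves
and OCR, BED (0-based half-open) for intervals, Matrix-Market triplets for
counts, multi-page TIFF + JSON sidecar for phase stacks.

Problem sizes used in the validation suite — 100-beat trains, 100 force
curves, 96×96×50 phase stacks, 2,000-gene count matrices and genome
fixtures, 200 null and 100 enriched simulation replicates, 100 twelve-well
respirometry comparisons — were chosen as the smallest sizes at which the
Monte-Carlo error of each check is comfortably below its tolerance.

## Known limitations

- The AP analyzer assumes quasi-periodic monomorphic beats; conduction
  mapping, alternans and rotor analysis are out of scope.
- Free-contact Hertz fits are biased upward by a few percent under heavy
  force noise (see above); prefer instrument-provided contact points when
  available, or average many curves.
- The QPM tracker neither merges nor splits objects, and the fluctuation
  metric's integer alignment slightly overstates redistribution for
  sub-pixel drifts.
- The marker test's normal approximation omits the continuity correction;
  at the cell numbers where it is used (> 25 per group) the effect is
  negligible, and the exact path takes over below that.
- The enrichment stage requires external peak sets and ortholog maps to
  reproduce any real-data result; the package validates the machinery on
  synthetic fixtures with programmed occupancy only.
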