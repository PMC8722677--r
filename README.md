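# cardiopheno

Multimodal quantification of functional differences between stem-cell-derived
cardiomyocyte populations — for example first-heart-field (FHF,
TBX5+/NKX2-5+) versus second-heart-field (SHF, TBX5−/NKX2-5+) hESC-derived
cardiomyocytes. The package implements, as tested R code, the bespoke
quantifications such a comparison needs:

- **Optical mapping** — per-beat action potential durations from voltage-dye
  fluorescence: APDx is the time from activation (dV/dt-max) until the trace
  falls below peak − (x/100)·amplitude with sub-frame interpolation; cycle
  length is the spacing of activations; groups are compared by the unpaired
  two-tailed Student's t test.
- **AFM nanoindentation** — Young's modulus from approach curves via the
  spherical-tip Hertz model, F = (4√R/3)·E/(1−ν²)·δ^{3/2} with z = d + δ,
  fitted in closed form by origin-constrained regression of F on δ^{3/2},
  with the contact point found by residual minimization.
- **Quantitative phase imaging** — dry mass (OPD·pixel area/α), local
  adaptive Otsu segmentation, nearest-neighbour tracking, net positional
  displacement and percent mass fluctuation
  100·Σ|m₂(x−s) − m₁(x)|/M₁ after integer-pixel centroid alignment.
- **Single-cell RNA-seq** — QC filters (cells with < 200 detected genes or
  < 3,000 UMIs; genes in < 3 cells), log-normalization, and two-group
  Wilcoxon marker detection (min.pct 0.3, BH-corrected), plus TPM + log2
  normalization for bulk counts.
- **Promoter occupancy** — upper-tail hypergeometric enrichment of
  transcription-factor peaks at marker-gene promoters (TSS ± 2 kb), with ten
  random control sets of 150 genes and Benjamini-Hochberg correction within
  each factor's twelve tests.
- **Respirometry** — mitochondrial stress-test parameters from
  oligomycin/FCCP/antimycin-A OCR traces (non-mito, basal, ATP-linked,
  proton leak, maximal, spare capacity), normalized to cell count.

Every stage has a seeded synthetic-data generator (`sim_spec()` +
`gen_*()`) that carries exact ground truth, so each estimator is validated
by recovering programmed parameters. `run_pipeline()` orchestrates
simulate-and-analyze runs with one global seed and a hashed manifest for
byte-identical reproduction.

## Worked example

Simulate two populations whose true APD30 differs by 45% (290 ms vs
200 ms), extract per-beat features at 5% noise, and compare:

```r
library(cardiopheno)

fhf <- gen_ap_traces(sim_spec("ap", 11, list(
  n_sites = 4L, n_beats = 30L, noise_sd = 0.05,
  apd30_ms = 290, apd80_ms = 455, cycle_length_ms = 1000, group_label = "FHF")))
shf <- gen_ap_traces(sim_spec("ap", 12, list(
  n_sites = 4L, n_beats = 30L, noise_sd = 0.05,
  apd30_ms = 200, apd80_ms = 350, cycle_length_ms = 800, group_label = "SHF")))

f_fhf <- extract_ap_features(fhf$traces, baseline_window_ms = 2000,
                             smooth_ms = 20, refine_ms = 24)
f_shf <- extract_ap_features(shf$traces, baseline_window_ms = 1600,
                             smooth_ms = 20, refine_ms = 24)
head(as.data.frame(f_shf), 3)
#>      site beat activation_time_ms peak_time_ms apd30_ms apd80_ms cycle_length_ms amplitude
#> 1 site_01    1             1.0000            2 210.1279 370.3545        799.9903 1.0593018
#> 2 site_01    2           800.9903          826 191.0466 348.5134        800.0319 1.0130116
#> 3 site_01    3          1601.0222         1684 203.8217 357.0280        799.9708 0.9954616

compare_groups(f_fhf, f_shf, "apd30_ms", labels = c("FHF", "SHF"))
#> Group comparison of apd30_ms
#>  group   n     mean       sem
#>    FHF 120 286.1568 0.6179441
#>    SHF 120 199.4526 0.4729157
#> percent increase (FHF vs SHF): 43.47%
#> Student's t (unpaired, two-tailed): t = 111.425, p = 2.33e-207
```

The per-beat table lists activation time, peak time, APD30/APD80 (ms),
cycle length and amplitude per detected beat; the comparison recovers the
programmed 45% group difference to within the per-beat noise and reports
the pooled-variance t statistic.

Fitting stiffness from a synthetic approach curve:

```r
curve <- gen_force_curves(sim_spec("afm", 2, list(E_pa = 6500)))$curves[[1]]
fit <- find_contact_and_fit(curve)
sprintf("E = %.1f Pa, contact at z = %.3f um, fit on %d points",
        fit$E, fit$contact_point_z, fit$n_points_fit)
#> "E = 6500.0 Pa, contact at z = 2.000 um, fit on 12 points"
```

A full simulate-and-analyze run over all six modalities:

```r
run_pipeline(list(seed = 42, out_dir = "out", stages = list(
  ap = list(), afm = list(), qpm = list(),
  counts = list(), occupancy = list(), ocr = list())))
```

which writes per-stage CSV/BED/JSON artifacts and `out/manifest.json` with
content hashes; the same config and seed reproduce every byte. A thin
command-line wrapper for shell use lives at `inst/scripts/cfp.R`
(`run`, `simulate`, `ap`, `mito` subcommands).

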