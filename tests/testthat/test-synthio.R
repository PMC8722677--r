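test_that("identical SimSpec yields identical output for every modality", {
  specs <- list(
    sim_spec("ap", 3, list(n_sites = 2L, n_beats = 3L, noise_sd = 0.05)),
    sim_spec("afm", 3, list(noise_sd = 0.1), n_replicates = 2L),
    sim_spec("qpm", 3, list(n_frames = 3L, background_noise = 2)),
    sim_spec("counts", 3, list(n_genes = 200L, n_cells = c(30L, 30L),
                               n_markers = c(5L, 5L), mean_log_mu = 2.5)),
    sim_spec("genome", 3, list(n_genes = 100L)),
    sim_spec("ocr", 3, list(noise_sd = 2)))
  gens <- list(gen_ap_traces, gen_force_curves, gen_phase_stack, gen_counts,
               gen_genome_fixture, gen_ocr_trace)
  for (i in seq_along(specs)) {
    a <- gens[[i]](specs[[i]])
    b <- gens[[i]](specs[[i]])
    expect_identical(a, b, info = specs[[i]]$modality)
  }
})

test_that("generators do not disturb the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_ap_traces(sim_spec("ap", 1, list(noise_sd = 0.1))))
  expect_identical(.Random.seed, before)
})

test_that("AP template crossings sit at the programmed APDs", {
  sim <- gen_ap_traces(sim_spec("ap", 1, list(
    n_sites = 1L, n_beats = 3L, noise_sd = 0, apd30_ms = 200, apd80_ms = 350,
    cycle_length_ms = 800)))
  v <- sim$traces$samples[, 1]
  dt <- 1000 / sim$traces$frame_rate_hz
  # read crossing times directly from the first beat's samples, with linear
  # interpolation; activation is the upstroke midpoint (u/2 = 1 ms)
  cross_time <- function(level) {
    i <- which(v[-length(v)] >= level & v[-1] < level)[1]
    ((i - 1) + (v[i] - level) / (v[i] - v[i + 1])) * dt
  }
  expect_lt(abs(cross_time(0.7) - 1 - 200), dt / 2)
  expect_lt(abs(cross_time(0.2) - 1 - 350), dt / 2)
  # sampling arithmetic: 500 Hz means 2 ms frames, length = n_beats*CL/dt
  expect_identical(nrow(sim$traces$samples), as.integer(round(3 * 800 / 2)))
})

test_that("AP generator rejects impossible parameter combinations", {
  expect_error(gen_ap_traces(sim_spec("ap", 1, list(apd30_ms = 400, apd80_ms = 350))),
               "apd30")
  expect_error(gen_ap_traces(sim_spec("ap", 1, list(cycle_length_ms = 300))),
               "cycle_length")
  expect_error(gen_ap_traces(sim_spec("ap", 1, list(polarity = "sideways"))),
               "polarity")
  expect_error(sim_spec("ap", 1, list(noise_sd = NaN)), "finite")
  expect_error(gen_ap_traces(sim_spec("ap", 1, list(nonsense = 1))), "unknown")
})

test_that("generated force curves obey the Hertz closed form and geometry", {
  p <- list(E_pa = 4000, R_um = 5, k_nN_per_nm = 0.286, nu = 0.5,
            contact_z_um = 2, noise_sd = 0)
  sim <- gen_force_curves(sim_spec("afm", 1, p))
  cu <- sim$curves[[1]]
  post <- cu$z > p$contact_z_um
  F_nN <- cu$k * 1000 * cu$d
  delta <- (cu$z - p$contact_z_um) - cu$d
  # z = contact + d + delta and F = (4 sqrt(R)/3) E/(1-nu^2) delta^{3/2}
  expect_equal(F_nN[post], hertz_oracle_nN(delta[post], p$E_pa, p$R_um, p$nu),
               tolerance = 1e-9)
  expect_equal(F_nN[!post], rep(0, sum(!post)))
  # zero indentation at the contact point gives zero force
  expect_equal(hertz_oracle_nN(0, p$E_pa, p$R_um, p$nu), 0)
  # the protocol force cap is respected
  expect_lte(max(F_nN), 3 + 1e-9)
})

test_that("force-curve generator validates physical parameters", {
  expect_error(gen_force_curves(sim_spec("afm", 1, list(E_pa = -1))), "E_pa")
  expect_error(gen_force_curves(sim_spec("afm", 1, list(R_um = 0))), "R_um")
  expect_error(gen_force_curves(sim_spec("afm", 1, list(nu = 0.8))), "nu")
})

test_that("phase stack generator renders programmed scenes", {
  static <- gen_phase_stack(sim_spec("qpm", 1, list(n_frames = 4L)))
  for (f in 2:4)
    expect_identical(static$stack$frames[[f]], static$stack$frames[[1]])

  drift <- gen_phase_stack(sim_spec("qpm", 1, list(
    n_frames = 4L, pixel_size_um = 0.5,
    cells = list(list(x = 20, y = 40, sigma_px = 4, mass_pg = 250,
                      motion = list(type = "drift", v = c(3, 0)))))))
  gt <- drift$ground_truth$cells
  expect_equal(diff(gt$cx_px), rep(3, 3), tolerance = 1e-9)
  expect_equal(drift$ground_truth$true_drift_um_per_frame, 3 * 0.5)
  expect_equal(gt$mass_pg, rep(250, 4), tolerance = 1e-9)

  expect_error(gen_phase_stack(sim_spec("qpm", 1, list(
    cells = list(list(x = 40, y = 40, sigma_px = 5, mass_pg = 100,
                      motion = list(type = "static")),
                 list(x = 52, y = 40, sigma_px = 5, mass_pg = 100,
                      motion = list(type = "static")))))),
    "overlap")
})

test_that("count generator bookkeeping flags engineered QC casualties", {
  sim <- gen_counts(sim_spec("counts", 2, list(
    n_genes = 600L, n_cells = c(50L, 50L), n_markers = c(8L, 8L),
    mean_log_mu = 2.2, n_lowgene_cells = 3L, lowgene_genes = 150L,
    n_lowumi_cells = 2L, n_rare_genes = 4L)))
  gt <- sim$ground_truth
  x <- as.matrix(sim$matrix$counts)
  # every flagged cell really violates a rule; a 150-detected-gene cell is in
  expect_gte(length(gt$qc_fail_cells), 5L)
  det <- colSums(x > 0); umi <- colSums(x)
  expect_true(all(det[gt$qc_fail_cells] < 200 | umi[gt$qc_fail_cells] < 3000))
  expect_true(any(det[gt$qc_fail_cells] == 150))
  expect_gte(length(gt$qc_fail_genes), 4L)
  # markers carry high detection in their own group
  g1 <- sim$matrix$group == "FHF"
  pct_on <- rowMeans(x[gt$markers_group1, g1, drop = FALSE] > 0)
  pct_off <- rowMeans(x[gt$markers_group1, !g1, drop = FALSE] > 0)
  expect_gt(mean(pct_on), mean(pct_off))
  expect_error(gen_counts(sim_spec("counts", 1, list(marker_log2fc = 0))),
               "fold change")
})

test_that("genome fixture degenerate placement is exact and deterministic", {
  enriched <- sprintf("gene_%04d", 1:40)
  sim <- gen_genome_fixture(sim_spec("genome", 4, list(
    n_genes = 300L, enriched_set = enriched, p_in = 1, p_out = 0)))
  prom <- build_promoters(sim$tss)
  bound <- overlap_flags(prom, sim$peaks)
  expect_identical(unname(bound[enriched]), rep(TRUE, 40))
  expect_false(any(bound[setdiff(names(bound), enriched)]))
  expect_identical(bound, sim$ground_truth$bound)

  expect_error(gen_genome_fixture(sim_spec("genome", 1, list(
    enriched_set = enriched, p_in = 0.1, p_out = 0.5))), "p_in")

  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_bed(gen_genome_fixture(sim_spec("genome", 7, list(n_genes = 100L)))$peaks, f1)
  write_bed(gen_genome_fixture(sim_spec("genome", 7, list(n_genes = 100L)))$peaks, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("OCR ground truth follows the stress-test arithmetic", {
  sim <- gen_ocr_trace(sim_spec("ocr", 1, list(
    basal_raw = 100, post_oligo = 40, post_fccp = 150, post_antimycin = 10,
    noise_sd = 0)))
  gt <- sim$ground_truth
  expect_equal(unlist(gt), c(true_non_mito = 10, true_basal = 90,
                             true_atp_linked = 60, true_proton_leak = 30,
                             true_maximal = 140, true_spare = 50))
  flat <- gen_ocr_trace(sim_spec("ocr", 1, list(
    basal_raw = 50, post_oligo = 50, post_fccp = 50, post_antimycin = 50)))
  expect_equal(unlist(flat$ground_truth),
               c(true_non_mito = 50, true_basal = 0, true_atp_linked = 0,
                 true_proton_leak = 0, true_maximal = 0, true_spare = 0))
  expect_warning(gen_ocr_trace(sim_spec("ocr", 1, list(post_antimycin = 120))),
                 "odd")
})

test_that("noise-free generation plus analysis is the identity per modality", {
  # ap
  sim <- gen_ap_traces(sim_spec("ap", 5, list(n_sites = 1L, n_beats = 5L)))
  f <- extract_ap_features(sim$traces, baseline_window_ms = 1600)
  expect_lt(max(abs(f$apd30_ms - 200)), 1)
  expect_lt(max(abs(f$apd80_ms - 350)), 1)
  expect_equal(unique(f$cycle_length_ms[!is.na(f$cycle_length_ms)]), 800)
  # afm
  s2 <- gen_force_curves(sim_spec("afm", 5, list(E_pa = 7000)))
  expect_lt(abs(find_contact_and_fit(s2$curves[[1]])$E / 7000 - 1), 1e-6)
  # qpm
  s3 <- gen_phase_stack(sim_spec("qpm", 5, list(n_frames = 3L)))
  r <- qpm_pipeline(s3$stack, dilate_px = 12)
  expect_equal(r$tracks$mass_pg, rep(300, 3), tolerance = 1e-6)
  # ocr
  s4 <- gen_ocr_trace(sim_spec("ocr", 5))
  p <- stress_test(s4$trace, normalize = FALSE)
  expect_equal(p$atp_linked, s4$ground_truth$true_atp_linked)
})
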