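test_that("segmentation recovers simple rendered scenes", {
  one <- gen_phase_stack(sim_spec("qpm", 1, list(n_frames = 2L)))
  lab <- segment_frame(one$stack$frames[[1]])
  expect_identical(max(lab), 1L)
  expect_gt(sum(lab == 1), 50)

  two <- gen_phase_stack(sim_spec("qpm", 1, list(
    dim = c(96L, 96L), n_frames = 2L,
    cells = list(list(x = 25, y = 25, sigma_px = 4, mass_pg = 200,
                      motion = list(type = "static")),
                 list(x = 70, y = 70, sigma_px = 4, mass_pg = 300,
                      motion = list(type = "static"))))))
  lab2 <- segment_frame(two$stack$frames[[1]])
  expect_identical(max(lab2), 2L)

  expect_warning(lab0 <- segment_frame(matrix(0, 64, 64)), "empty")
  expect_true(all(lab0 == 0L))
})

test_that("segmented mass under SNR-10 noise is within 5% of rendered mass", {
  # blob peak OPD ~ 53 nm; background noise sd 5.3 nm
  sim <- gen_phase_stack(sim_spec("qpm", 6, list(
    dim = c(96L, 96L), n_frames = 2L, background_noise = 5.3,
    cells = list(list(x = 48, y = 48, sigma_px = 5, mass_pg = 300,
                      motion = list(type = "static"))))))
  m <- phase_to_mass(sim$stack$frames[[1]], 1, 0.18)
  lab <- segment_frame(m, dilate_px = 10)
  expect_lt(abs(sum(m[lab == 1]) / 300 - 1), 0.05)
})

test_that("phase-to-mass conversion follows the closed form and scale law", {
  frame <- matrix(0, 20, 20)
  frame[5:14, 5:14] <- 100  # uniform 100 nm OPD over a 10x10 patch
  m <- phase_to_mass(frame, pixel_size_um = 0.5, alpha = 0.2)
  expect_equal(sum(m), 0.1 * 0.25 / 0.2 * 100)  # OPD_um * area / alpha per px
  expect_equal(sum(phase_to_mass(frame, 0.5, 0.4)), sum(m) / 2)
  neg <- matrix(c(-1, 2, 3, 4), 2)
  mn <- phase_to_mass(neg, 1, 0.18)
  expect_equal(attr(mn, "clipped_fraction"), 0.25)
  expect_true(all(mn >= 0))
  expect_error(phase_to_mass(frame, 1, alpha = 0), "alpha")
})

test_that("a programmed cell mass of 300 pg is recovered through the pipeline", {
  sim <- gen_phase_stack(sim_spec("qpm", 2, list(n_frames = 3L,
                                                 background_noise = 2)))
  res <- qpm_pipeline(sim$stack, dilate_px = 12)
  expect_lt(max(abs(res$tracks$mass_pg / 300 - 1)), 0.02)
})

test_that("greedy linking respects the gate", {
  sim <- gen_phase_stack(sim_spec("qpm", 3, list(
    dim = c(96L, 96L), n_frames = 5L,
    cells = list(list(x = 20, y = 48, sigma_px = 4, mass_pg = 300,
                      motion = list(type = "drift", v = c(8, 0)))))))
  mass <- lapply(sim$stack$frames, phase_to_mass, pixel_size_um = 1, alpha = 0.18)
  masks <- lapply(mass, segment_frame)
  linked <- link_tracks(masks, mass, pixel_size_um = 1, max_link_um = 12)
  expect_identical(length(unique(linked$track)), 1L)   # drift below gate
  expect_warning(
    broken <- link_tracks(masks, mass, pixel_size_um = 1, max_link_um = 4),
    "gate")
  expect_identical(length(unique(broken$track)), 5L)   # every frame a new track
})

test_that("two passing cells are linked to the correct identities", {
  hits <- 0; total <- 0
  for (seed in 1:20) {
    jit <- (seed %% 5) - 2
    sim <- gen_phase_stack(sim_spec("qpm", seed, list(
      dim = c(120L, 120L), n_frames = 5L,
      cells = list(list(x = 20, y = 40 + jit, sigma_px = 3, mass_pg = 250,
                        motion = list(type = "drift", v = c(6, 0))),
                   list(x = 100, y = 80 - jit, sigma_px = 3, mass_pg = 350,
                        motion = list(type = "drift", v = c(-6, 0)))))))
    res <- qpm_pipeline(sim$stack, dilate_px = 4, max_link_um = 10)
    tr <- res$tracks
    for (id in unique(tr$track)) {
      tt <- tr[tr$track == id, ]
      total <- total + nrow(tt)
      # identity preserved if the track's mass stays near one programmed value
      hits <- hits + sum(abs(tt$mass_pg - tt$mass_pg[1]) < 50)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("static scenes give exactly zero displacement and fluctuation", {
  sim <- gen_phase_stack(sim_spec("qpm", 4, list(n_frames = 4L)))
  res <- qpm_pipeline(sim$stack, dilate_px = 8)
  expect_equal(res$metrics$net_displacement_um, rep(0, 3))
  expect_equal(res$metrics$pct_mass_fluctuation, rep(0, 3))
})

test_that("rigid integer-pixel translation: exact displacement, zero fluctuation", {
  sim <- gen_phase_stack(sim_spec("qpm", 4, list(
    dim = c(96L, 96L), n_frames = 5L, pixel_size_um = 0.7,
    cells = list(list(x = 20, y = 48, sigma_px = 4, mass_pg = 300,
                      motion = list(type = "drift", v = c(3, 0)))))))
  res <- qpm_pipeline(sim$stack, dilate_px = 8, max_link_um = 10)
  expect_equal(res$metrics$net_displacement_um, rep(3 * 0.7, 4), tolerance = 1e-9)
  expect_equal(res$metrics$pct_mass_fluctuation, rep(0, 4), tolerance = 1e-9)
})

test_that("pulsating-cell fluctuation equals the direct pixel-sum oracle", {
  sim <- gen_phase_stack(sim_spec("qpm", 5, list(
    n_frames = 4L,
    cells = list(list(x = 48, y = 48, sigma_px = 5, mass_pg = 300,
                      motion = list(type = "pulsate", frac = 0.1,
                                    lobe_offset_px = 10))))))
  mass <- lapply(sim$stack$frames, phase_to_mass, pixel_size_um = 1, alpha = 0.18)
  masks <- lapply(mass, function(m) matrix(as.integer(m > 0), nrow(m)))
  tracks <- link_tracks(masks, mass, pixel_size_um = 1, max_link_um = 10)
  met <- motion_metrics(tracks, masks, mass, 1, 10)
  # oracle: direct pixel differencing of the two rendered states, computed
  # here from the frames themselves after integer centroid alignment
  m1 <- mass[[1]]; m2 <- mass[[2]]
  cw <- function(m) c(sum(col(m) * m), sum(row(m) * m)) / sum(m)
  s <- round(cw(m2) - cw(m1))
  m2a <- matrix(0, nrow(m2), ncol(m2))
  m2a[(1 + max(0, -s[2])):(nrow(m2) - max(0, s[2])),
      (1 + max(0, -s[1])):(ncol(m2) - max(0, s[1]))] <-
    m2[(1 + max(0, s[2])):(nrow(m2) - max(0, -s[2])),
       (1 + max(0, s[1])):(ncol(m2) - max(0, -s[1]))]
  oracle <- 100 * sum(abs(m2a - m1)) / sum(m1)
  expect_equal(met$pct_mass_fluctuation[1], oracle, tolerance = 1e-6)
  expect_equal(met$pct_mass_fluctuation[1], sim$ground_truth$true_pct_fluct,
               tolerance = 1e-6)
})

test_that("metrics are invariant to 90-degree stack rotation and mass scaling", {
  sim <- gen_phase_stack(sim_spec("qpm", 8, list(
    dim = c(96L, 96L), n_frames = 4L,
    cells = list(list(x = 30, y = 50, sigma_px = 4, mass_pg = 300,
                      motion = list(type = "pulsate", frac = 0.15,
                                    lobe_offset_px = 8))))))
  run <- function(frames) {
    st <- phase_stack(frames, 1, 10)
    r <- qpm_pipeline(st, dilate_px = 8)
    r$metrics
  }
  m0 <- run(sim$stack$frames)
  rot <- lapply(sim$stack$frames, function(f) t(f[nrow(f):1, ]))
  m90 <- run(rot)
  expect_equal(m90$net_displacement_um, m0$net_displacement_um, tolerance = 1e-9)
  expect_equal(m90$pct_mass_fluctuation, m0$pct_mass_fluctuation, tolerance = 1e-9)
  m2 <- run(lapply(sim$stack$frames, function(f) f * 3))
  expect_equal(m2$pct_mass_fluctuation, m0$pct_mass_fluctuation, tolerance = 1e-9)
})

test_that("total segmented mass is conserved across a closed 50-frame scene", {
  sim <- gen_phase_stack(sim_spec("qpm", 9, list(
    n_frames = 50L, background_noise = 1,
    cells = list(list(x = 48, y = 48, sigma_px = 5, mass_pg = 300,
                      motion = list(type = "pulsate", frac = 0.1,
                                    lobe_offset_px = 10))))))
  res <- qpm_pipeline(sim$stack, dilate_px = 10)
  per_frame <- res$tracks$mass_pg
  expect_identical(length(per_frame), 50L)
  expect_lt(sd(per_frame) / mean(per_frame), 0.02)
})

test_that("mass accumulation rate is recovered from a growing track", {
  frames <- lapply(1:6, function(f) {
    m <- cardiopheno:::render_blob(c(64, 64), 32, 32, 4, 200 + 12 * (f - 1))
    m * 0.18 / 1 * 1000  # to OPD nm at 1 um pixels
  })
  st <- phase_stack(frames, 1, 30)  # 30 min between frames
  r <- qpm_pipeline(st, dilate_px = 10)
  # 12 pg per 0.5 h = 24 pg/h
  expect_equal(r$summary$mass_accumulation_rate_pg_per_h, 24, tolerance = 0.01)
})
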