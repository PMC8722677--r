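#' Simulation specification
#'
#' A `SimSpec` bundles the modality, seed and parameter map for one synthetic
#' dataset. The same `(modality, seed, params)` triple always reproduces the
#' same dataset, byte for byte; all randomness inside the generators flows
#' from this single seed and never touches the caller's RNG state.
#'
#' @param modality one of `"ap"`, `"afm"`, `"qpm"`, `"counts"`, `"genome"`,
#'   `"ocr"`.
#' @param seed integer seed for the generator's private RNG stream.
#' @param params named list of modality-specific parameters; unknown names
#'   are rejected, missing ones take the documented defaults.
#' @param n_replicates number of replicate datasets/curves/traces.
#' @return an object of class `SimSpec`.
#' @export
sim_spec <- function(modality, seed = 1L, params = list(), n_replicates = 1L) {
  modality <- match.arg(modality, c("ap", "afm", "qpm", "counts", "genome", "ocr"))
  if (length(seed) != 1L || !is.finite(seed)) stopf("seed must be a single finite integer")
  if (n_replicates < 1L) stopf("n_replicates must be positive")
  num <- unlist(Filter(is.numeric, params), use.names = FALSE)
  if (length(num) && !all(is.finite(num))) stopf("all numeric params must be finite")
  structure(list(modality = modality, seed = as.integer(seed),
                 params = params, n_replicates = as.integer(n_replicates)),
            class = "SimSpec")
}

# Merge user params into defaults, rejecting unknown keys.
resolve_params <- function(params, defaults) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  defaults
}

## ---------------------------------------------------------------------------
## Action potential traces

# Piecewise AP template at time tau (ms) after beat onset. Linear upstroke
# over `u` ms, plateau, then two linear repolarization segments pinned so
# the trace crosses 0.7*A at tau = u/2 + apd30 and 0.2*A at tau = u/2 +
# apd80; the second slope continues to baseline. Activation by the
# dV/dt-max convention sits at the upstroke midpoint u/2, so the true APDs
# measured from activation are exact by construction (and, with the default
# 2 ms upstroke, within half a frame of the times measured from onset).
ap_template <- function(tau, amplitude, apd30, apd80, upstroke, plateau_frac = 0.5) {
  a30 <- upstroke / 2 + apd30
  a80 <- upstroke / 2 + apd80
  t_p <- upstroke + plateau_frac * (a30 - upstroke)
  s2 <- (0.2 - 0.7) * amplitude / (a80 - a30)
  t_end <- a80 + 0.2 * amplitude / abs(s2)
  v <- numeric(length(tau))
  i <- tau >= 0 & tau <= upstroke
  v[i] <- amplitude * tau[i] / upstroke
  i <- tau > upstroke & tau <= t_p
  v[i] <- amplitude
  i <- tau > t_p & tau <= a30
  v[i] <- amplitude + (0.7 - 1) * amplitude * (tau[i] - t_p) / (a30 - t_p)
  i <- tau > a30 & tau <= t_end
  v[i] <- pmax(0, 0.7 * amplitude + s2 * (tau[i] - a30))
  v
}

#' Generate synthetic voltage-dye action potential traces
#'
#' Builds fluorescence traces from a piecewise-analytic AP template (linear
#' upstroke, plateau, two-segment linear repolarization) whose true 30% and
#' 80% repolarization times equal `apd30_ms` and `apd80_ms` exactly, repeated
#' every `cycle_length_ms`, with optional additive Gaussian noise, linear
#' baseline drift, and inverted optical polarity (fluorescence falling on
#' depolarization, as voltage dyes often show).
#'
#' Parameters (with defaults): `frame_rate_hz` (500), `n_sites` (4),
#' `n_beats` (5), `amplitude` (1), `apd30_ms` (200), `apd80_ms` (350),
#' `cycle_length_ms` (800), `upstroke_ms` (2), `noise_sd` (0), `polarity`
#' ("up"), `baseline_drift` (0, a.u./s), `plateau_frac` (0.5).
#'
#' @param spec a [sim_spec()] with `modality = "ap"`.
#' @return list with elements `traces` (a `VoltageTraceSet`) and
#'   `ground_truth` (per-site true APD30/APD80/cycle length in ms).
#' @export
gen_ap_traces <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"), spec$modality == "ap")
  p <- resolve_params(spec$params, list(
    frame_rate_hz = 500, n_sites = 4L, n_beats = 5L, amplitude = 1,
    apd30_ms = 200, apd80_ms = 350, cycle_length_ms = 800, upstroke_ms = 2,
    noise_sd = 0, polarity = "up", baseline_drift = 0, plateau_frac = 0.5,
    group_label = "group"))
  if (p$apd30_ms >= p$apd80_ms) stopf("apd30_ms must be < apd80_ms")
  if (p$cycle_length_ms <= p$apd80_ms) stopf("cycle_length_ms must exceed apd80_ms")
  if (!p$polarity %in% c("up", "down")) stopf("polarity must be 'up' or 'down'")

  dt <- 1000 / p$frame_rate_hz
  n_samp <- round(p$n_beats * p$cycle_length_ms / dt)
  t_ms <- (seq_len(n_samp) - 1) * dt
  tau <- t_ms %% p$cycle_length_ms
  clean <- ap_template(tau, p$amplitude, p$apd30_ms, p$apd80_ms,
                       p$upstroke_ms, p$plateau_frac)

  with_seed(spec$seed, {
    mat <- vapply(seq_len(p$n_sites), function(s) {
      v <- clean + rnorm(n_samp, 0, p$noise_sd) + p$baseline_drift * t_ms / 1000
      if (p$polarity == "down") -v else v
    }, numeric(n_samp))
  })
  colnames(mat) <- sprintf("site_%02d", seq_len(p$n_sites))
  traces <- voltage_trace_set(mat, p$frame_rate_hz, group_label = p$group_label)
  gt <- data.frame(site = colnames(mat),
                   true_apd30_ms = p$apd30_ms, true_apd80_ms = p$apd80_ms,
                   true_cycle_length_ms = p$cycle_length_ms,
                   n_beats = p$n_beats)
  list(traces = traces, ground_truth = gt)
}

## ---------------------------------------------------------------------------
## AFM force curves

# Hertz force (nN) for a spherical tip: F = (4*sqrt(R)/3) * E/(1-nu^2) * d^{3/2}
# with R in m, E in Pa, delta in m. With delta in um the same coefficient
# computed from R in m gives F in nN directly ((1e-6)^{3/2} * 1e9 = 1).
hertz_force_nN <- function(delta_um, E_pa, R_um, nu) {
  A <- 4 * sqrt(R_um * 1e-6) * E_pa / (3 * (1 - nu^2))
  A * pmax(delta_um, 0)^1.5
}

#' Generate synthetic AFM approach curves
#'
#' Synthesizes piezo-position/deflection approach records obeying the
#' spherical-tip Hertz relation beyond the contact point and zero force (plus
#' noise) before it, using the indentation geometry z = contact + d + delta
#' where d = F/k is cantilever deflection. Gaussian force noise of sd
#' `noise_sd` (nN) is added to the force before conversion to deflection.
#'
#' Parameters: `E_pa` (5000), `R_um` (5, a 10 um diameter spherical tip),
#' `k_nN_per_nm` (0.286), `nu` (0.5), `contact_z_um` (2), `z_step_um` (0.02),
#' `max_force_nN` (3), `noise_sd` (0), `pre_um` (1, approach travel before
#' contact).
#'
#' @param spec a [sim_spec()] with `modality = "afm"`; `n_replicates` curves
#'   are generated.
#' @return list with `curves` (list of `ForceCurve`) and `ground_truth`
#'   (per-curve `true_E_pa`, `true_contact_z_um`).
#' @export
gen_force_curves <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"), spec$modality == "afm")
  p <- resolve_params(spec$params, list(
    E_pa = 5000, R_um = 5, k_nN_per_nm = 0.286, nu = 0.5,
    contact_z_um = 2, z_step_um = 0.02, max_force_nN = 3,
    noise_sd = 0, pre_um = 1))
  if (p$E_pa <= 0) stopf("E_pa must be positive")
  if (p$R_um <= 0) stopf("R_um must be positive")
  if (p$nu < 0 || p$nu > 0.5) stopf("nu must lie in [0, 0.5]")

  A <- 4 * sqrt(p$R_um * 1e-6) * p$E_pa / (3 * (1 - p$nu^2))  # nN / um^1.5
  k_um <- p$k_nN_per_nm * 1000                                 # nN / um
  delta_max <- (p$max_force_nN / A)^(2 / 3)
  z_max <- p$contact_z_um + delta_max + p$max_force_nN / k_um
  z <- seq(p$contact_z_um - p$pre_um, z_max, by = p$z_step_um)

  # invert z - contact = delta + F(delta)/k for delta (Newton, monotone g)
  s <- pmax(z - p$contact_z_um, 0)
  delta <- s
  for (i in 1:60) {
    g <- delta + (A / k_um) * delta^1.5 - s
    gp <- 1 + 1.5 * (A / k_um) * sqrt(delta)
    delta <- pmax(delta - g / gp, 0)
  }
  F_true <- A * delta^1.5

  curves <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_replicates), function(r) {
      F_obs <- F_true + rnorm(length(z), 0, p$noise_sd)
      force_curve(z = z, d = F_obs / k_um, k = p$k_nN_per_nm,
                  R = p$R_um, nu = p$nu, direction = "approach")
    })
  })
  gt <- data.frame(curve = seq_len(spec$n_replicates),
                   true_E_pa = p$E_pa, true_contact_z_um = p$contact_z_um)
  list(curves = curves, ground_truth = gt)
}

## ---------------------------------------------------------------------------
## Quantitative phase stacks

# Render a truncated-Gaussian blob with exact total mass (pg) onto a matrix.
render_blob <- function(dim, cx, cy, sigma, mass) {
  xs <- seq_len(dim[2]); ys <- seq_len(dim[1])
  r2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  w <- exp(-r2 / (2 * sigma^2))
  w[r2 > (3 * sigma)^2] <- 0
  w * (mass / sum(w))
}

mass_to_opd_nm <- function(mass_img, pixel_size_um, alpha) {
  mass_img * alpha / pixel_size_um^2 * 1000
}

#' Generate a synthetic quantitative-phase time-lapse stack
#'
#' Renders each cell as a compact truncated-Gaussian dry-mass distribution on
#' a zero background and converts mass to optical path difference using the
#' specific refractive increment `alpha` (um^3/pg). Motion models per cell:
#' `static`, `drift` (constant px/frame velocity), or `pulsate` (a two-lobe
#' blob that shuttles a fraction `frac` of its mass between lobes on
#' alternate frames, emulating internal mass redistribution).
#'
#' Parameters: `dim` (c(96, 96)), `n_frames` (8), `frame_interval_min` (10),
#' `pixel_size_um` (1), `wavelength_nm` (660), `alpha` (0.18),
#' `background_noise` (0, nm sd), `min_margin_px` (5), and `cells`, a list of
#' per-cell lists with `x`, `y`, `sigma_px`, `mass_pg`, and `motion` (e.g.
#' `list(type = "drift", v = c(3, 0))` or
#' `list(type = "pulsate", frac = 0.1, lobe_offset_px = 8)`).
#'
#' @param spec a [sim_spec()] with `modality = "qpm"`.
#' @return list with `stack` (a `PhaseStack`, frames in nm OPD) and
#'   `ground_truth` (per cell/frame centroids and masses; for pulsating cells
#'   `true_pct_fluct`, the analytic percent mass fluctuation computed by
#'   direct pixel differencing of the two rendered states).
#' @export
gen_phase_stack <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"), spec$modality == "qpm")
  p <- resolve_params(spec$params, list(
    dim = c(96L, 96L), n_frames = 8L, frame_interval_min = 10,
    pixel_size_um = 1, wavelength_nm = 660, alpha = 0.18,
    background_noise = 0, min_margin_px = 5,
    cells = list(list(x = 48, y = 48, sigma_px = 5, mass_pg = 300,
                      motion = list(type = "static")))))

  dim <- as.integer(p$dim)
  # reject layouts where cell supports come too close (segmentation ambiguity)
  extent <- lapply(p$cells, function(cl) {
    v <- if (identical(cl$motion$type, "drift")) cl$motion$v else c(0, 0)
    off <- if (identical(cl$motion$type, "pulsate"))
      (cl$motion$lobe_offset_px %||% 8) / 2 else 0
    travel <- sqrt(sum(v^2)) * (p$n_frames - 1)
    list(x = cl$x + c(0, v[1] * (p$n_frames - 1)), y = cl$y + c(0, v[2] * (p$n_frames - 1)),
         r = 3 * cl$sigma_px + off, travel = travel)
  })
  if (length(p$cells) > 1) {
    for (i in seq_along(extent)) for (j in seq_along(extent)) if (i < j) {
      dmin <- min(sqrt(outer(extent[[i]]$x, extent[[j]]$x, `-`)^2 +
                       outer(extent[[i]]$y, extent[[j]]$y, `-`)^2))
      if (dmin < extent[[i]]$r + extent[[j]]$r + p$min_margin_px)
        stopf("cells %d and %d overlap within the safety margin", i, j)
    }
  }

  render_cell <- function(cl, f) {
    m <- cl$motion
    type <- m$type %||% "static"
    if (type == "static") {
      render_blob(dim, cl$x, cl$y, cl$sigma_px, cl$mass_pg)
    } else if (type == "drift") {
      render_blob(dim, cl$x + m$v[1] * (f - 1), cl$y + m$v[2] * (f - 1),
                  cl$sigma_px, cl$mass_pg)
    } else if (type == "pulsate") {
      off <- (m$lobe_offset_px %||% 8) / 2
      hi <- cl$mass_pg * (0.5 + m$frac / 2); lo <- cl$mass_pg - hi
      a <- render_blob(dim, cl$x - off, cl$y, cl$sigma_px, if (f %% 2) hi else lo)
      b <- render_blob(dim, cl$x + off, cl$y, cl$sigma_px, if (f %% 2) lo else hi)
      a + b
    } else stopf("unknown motion type '%s'", type)
  }

  gt_rows <- list()
  frames <- vector("list", p$n_frames)
  for (f in seq_len(p$n_frames)) {
    img <- matrix(0, dim[1], dim[2])
    for (ci in seq_along(p$cells)) {
      cell_img <- render_cell(p$cells[[ci]], f)
      img <- img + cell_img
      tot <- sum(cell_img)
      xs <- col(cell_img); ys <- row(cell_img)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        cell = ci, frame = f, mass_pg = tot,
        cx_px = sum(xs * cell_img) / tot, cy_px = sum(ys * cell_img) / tot)
    }
    frames[[f]] <- mass_to_opd_nm(img, p$pixel_size_um, p$alpha)
  }
  with_seed(spec$seed, {
    if (p$background_noise > 0)
      frames <- lapply(frames, function(fr)
        fr + matrix(rnorm(length(fr), 0, p$background_noise), nrow(fr)))
  })

  # analytic percent mass fluctuation of pulsating cells: pixel-difference of
  # the two rendered states after integer-pixel centroid alignment
  fluct <- vapply(seq_along(p$cells), function(ci) {
    cl <- p$cells[[ci]]
    if (!identical(cl$motion$type, "pulsate")) return(NA_real_)
    s1 <- render_cell(cl, 1); s2 <- render_cell(cl, 2)
    c1 <- blob_centroid(s1); c2 <- blob_centroid(s2)
    s2a <- shift_matrix(s2, -round(c2 - c1))
    100 * sum(abs(s2a - s1)) / sum(s1)
  }, numeric(1))

  gt <- do.call(rbind, gt_rows)
  drift <- vapply(p$cells, function(cl)
    if (identical(cl$motion$type, "drift"))
      sqrt(sum(cl$motion$v^2)) * p$pixel_size_um else 0, numeric(1))
  stack <- phase_stack(frames, pixel_size_um = p$pixel_size_um,
                       frame_interval_min = p$frame_interval_min,
                       wavelength_nm = p$wavelength_nm)
  list(stack = stack,
       ground_truth = list(cells = gt, true_drift_um_per_frame = drift,
                           true_pct_fluct = fluct, alpha = p$alpha))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blob_centroid <- function(img) {
  tot <- sum(img)
  c(sum(col(img) * img), sum(row(img) * img)) / tot  # (x, y) in px
}

# integer shift with zero fill; s = c(dx, dy) in (col, row) pixels
shift_matrix <- function(m, s) {
  out <- matrix(0, nrow(m), ncol(m))
  dx <- s[1]; dy <- s[2]
  src_r <- seq_len(nrow(m)); dst_r <- src_r + dy
  src_c <- seq_len(ncol(m)); dst_c <- src_c + dx
  ok_r <- dst_r >= 1 & dst_r <= nrow(m); ok_c <- dst_c >= 1 & dst_c <= ncol(m)
  out[dst_r[ok_r], dst_c[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

## ---------------------------------------------------------------------------
## UMI count matrices

#' Generate a synthetic two-group UMI count matrix
#'
#' Baseline expression is negative binomial around lognormal gene means with
#' per-cell library-size factors. Declared marker genes get a programmed
#' fold-change and detection fraction in their "on" group. Engineered QC
#' casualties are constructed on top: cells detecting too few genes, cells
#' with too few total UMIs, and genes detected in too few cells. The ground
#' truth records the declared markers and, by applying the filter definitions
#' directly to the realized matrix, the exact identities of QC-failing cells
#' and genes.
#'
#' Parameters: `n_genes` (2000), `n_cells` (c(150, 150) per group),
#' `mean_log_mu` (0.8), `sd_log_mu` (1), `nb_size` (4), `lib_sd` (0.2),
#' `n_markers` (c(50, 50)), `marker_log2fc` (2), `marker_detect_high` (0.9),
#' `marker_detect_low` (0.1), `n_lowgene_cells` (0), `lowgene_genes` (150),
#' `n_lowumi_cells` (0), `lowumi_genes` (250), `n_rare_genes` (0),
#' `group_labels` (c("FHF", "SHF")).
#'
#' @param spec a [sim_spec()] with `modality = "counts"`.
#' @return list with `matrix` (a `CountMatrix`) and `ground_truth` (marker
#'   gene lists per group, QC-failing cell/gene ids).
#' @export
gen_counts <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"), spec$modality == "counts")
  p <- resolve_params(spec$params, list(
    n_genes = 2000L, n_cells = c(150L, 150L), mean_log_mu = 0.8, sd_log_mu = 1,
    nb_size = 4, lib_sd = 0.2, n_markers = c(50L, 50L), marker_log2fc = 2,
    marker_detect_high = 0.9, marker_detect_low = 0.1,
    n_lowgene_cells = 0L, lowgene_genes = 150L,
    n_lowumi_cells = 0L, lowumi_genes = 250L, n_rare_genes = 0L,
    group_labels = c("FHF", "SHF")))
  if (sum(p$n_markers) > 0 && p$marker_log2fc == 0)
    stopf("declared markers must have a fold change different from 1")

  with_seed(spec$seed, {
    G <- p$n_genes; n1 <- p$n_cells[1]; n2 <- p$n_cells[2]; n <- n1 + n2
    genes <- sprintf("gene_%04d", seq_len(G))
    cells <- sprintf("cell_%04d", seq_len(n))
    group <- rep(p$group_labels, c(n1, n2))

    mu <- rlnorm(G, p$mean_log_mu, p$sd_log_mu)
    sf <- rlnorm(n, 0, p$lib_sd)
    mk1 <- if (p$n_markers[1] > 0) seq_len(p$n_markers[1]) else integer(0)
    mk2 <- if (p$n_markers[2] > 0) p$n_markers[1] + seq_len(p$n_markers[2]) else integer(0)

    mu_mat <- matrix(mu, G, n) * matrix(sf, G, n, byrow = TRUE)
    fc <- 2^p$marker_log2fc
    # markers: strong expression + high detection in the on group, mostly-off
    # elsewhere via a per-cell detection gate
    gate <- matrix(1, G, n)
    g1 <- seq_len(n1); g2 <- n1 + seq_len(n2)
    if (length(mk1)) {
      mu_mat[mk1, g1] <- mu_mat[mk1, g1] * fc
      gate[mk1, g1] <- matrix(rbinom(length(mk1) * n1, 1, p$marker_detect_high), length(mk1))
      gate[mk1, g2] <- matrix(rbinom(length(mk1) * n2, 1, p$marker_detect_low), length(mk1))
    }
    if (length(mk2)) {
      mu_mat[mk2, g2] <- mu_mat[mk2, g2] * fc
      gate[mk2, g2] <- matrix(rbinom(length(mk2) * n2, 1, p$marker_detect_high), length(mk2))
      gate[mk2, g1] <- matrix(rbinom(length(mk2) * n1, 1, p$marker_detect_low), length(mk2))
    }
    x <- matrix(rnbinom(G * n, mu = as.vector(mu_mat * gate), size = p$nb_size), G, n)

    normal_cells <- seq_len(n)
    engineer <- function(k) {
      picked <- sample(normal_cells, k)
      normal_cells <<- setdiff(normal_cells, picked)
      picked
    }
    if (p$n_lowgene_cells > 0) {
      for (j in engineer(p$n_lowgene_cells)) {
        x[, j] <- 0L
        x[sample.int(G, p$lowgene_genes), j] <- 1L
      }
    }
    if (p$n_lowumi_cells > 0) {
      for (j in engineer(p$n_lowumi_cells)) {
        x[, j] <- 0L
        x[sample.int(G, p$lowumi_genes), j] <- 1L
      }
    }
    if (p$n_rare_genes > 0) {
      rare <- sample(setdiff(seq_len(G), c(mk1, mk2)), p$n_rare_genes)
      for (g in rare) {
        x[g, ] <- 0L
        x[g, sample(normal_cells, 2L)] <- 1L
      }
    }

    dimnames(x) <- list(genes, cells)
    # ground-truth QC bookkeeping: apply the stated rules to the realized
    # matrix (cells first, then genes on the survivors)
    det_g <- colSums(x > 0); umi <- colSums(x)
    fail_cells <- cells[det_g < 200 | umi < 3000]
    keep <- setdiff(cells, fail_cells)
    fail_genes <- genes[rowSums(x[, keep, drop = FALSE] > 0) < 3]

    cm <- count_matrix(x, group = group)
    gt <- list(markers_group1 = genes[mk1], markers_group2 = genes[mk2],
               qc_fail_cells = fail_cells, qc_fail_genes = fail_genes)
    list(matrix = cm, ground_truth = gt)
  })
}

## ---------------------------------------------------------------------------
## Genomic fixtures (TSS table + ChIP peak set)

#' Generate a synthetic TSS table and promoter-biased peak set
#'
#' Genes are laid out on a regular per-chromosome grid with spacing wide
#' enough that promoter windows can never abut, so each gene's bound status
#' is exactly the programmed Bernoulli draw: promoters of genes in
#' `enriched_set` receive an overlapping peak with probability `p_in`, all
#' others with probability `p_out`. Peaks are placed strictly inside their
#' gene's promoter window.
#'
#' Parameters: `n_genes` (2000), `n_chroms` (5), `upstream_bp` (2000),
#' `downstream_bp` (2000), `peak_width` (400), `enriched_set` (character
#' vector of gene ids, default empty), `p_in` (0.9), `p_out` (0.1),
#' `spacing_bp` (12000).
#'
#' @param spec a [sim_spec()] with `modality = "genome"`.
#' @return list with `tss` (data.frame gene/chrom/pos/strand), `peaks` (a
#'   `GRanges`), and `ground_truth` (named logical `bound` per gene).
#' @export
gen_genome_fixture <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"), spec$modality == "genome")
  p <- resolve_params(spec$params, list(
    n_genes = 2000L, n_chroms = 5L, upstream_bp = 2000L, downstream_bp = 2000L,
    peak_width = 400L, enriched_set = character(0), p_in = 0.9, p_out = 0.1,
    spacing_bp = 12000L))
  # p_in == p_out is the legitimate null configuration; only an inverted
  # direction is an invalid enrichment request
  if (length(p$enriched_set) && p$p_in < p$p_out)
    stopf("enrichment requested but p_in < p_out")
  if (p$spacing_bp < p$upstream_bp + p$downstream_bp + 2 * p$peak_width)
    stopf("spacing_bp too small to keep promoters and peaks disjoint")

  with_seed(spec$seed, {
    genes <- sprintf("gene_%04d", seq_len(p$n_genes))
    chrom <- sprintf("chr%d", 1 + (seq_len(p$n_genes) - 1) %% p$n_chroms)
    slot <- (seq_len(p$n_genes) - 1) %/% p$n_chroms
    pos <- p$upstream_bp + p$peak_width + slot * p$spacing_bp +
      sample.int(500L, p$n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), p$n_genes, replace = TRUE)
    tss <- data.frame(gene = genes, chrom = chrom, pos = pos, strand = strand,
                      stringsAsFactors = FALSE)

    prob <- ifelse(genes %in% p$enriched_set, p$p_in, p$p_out)
    bound <- as.logical(rbinom(p$n_genes, 1, prob))

    idx <- which(bound)
    # peak centred uniformly inside the promoter, fully within the window
    ctr <- pos[idx] + round(runif(length(idx),
                                  -p$upstream_bp + p$peak_width / 2,
                                  p$downstream_bp - p$peak_width / 2))
    peaks <- GenomicRanges::GRanges(
      seqnames = chrom[idx],
      ranges = IRanges::IRanges(start = ctr - p$peak_width %/% 2 + 1L,
                                width = p$peak_width),
      name = sprintf("peak_%04d", seq_along(idx)))
    peaks <- GenomicRanges::sort(peaks)
    names(bound) <- genes
    list(tss = tss, peaks = peaks, ground_truth = list(bound = bound))
  })
}

## ---------------------------------------------------------------------------
## OCR traces

#' Generate a synthetic mitochondrial stress-test OCR trace
#'
#' Produces a four-phase step trace (basal, post-oligomycin, post-FCCP,
#' post-antimycin-A plateaus) with injection timestamps between phases and
#' Gaussian measurement noise. Ground truth carries the stress-test
#' parameters implied by the plateaus.
#'
#' Parameters: `basal_raw` (100), `post_oligo` (40), `post_fccp` (150),
#' `post_antimycin` (10) (pmol O2/min), `n_per_phase` (5), `interval_min`
#' (6), `noise_sd` (0), `cell_count` (20000), `ecar_level` (20),
#' `group_label` ("group").
#'
#' @param spec a [sim_spec()] with `modality = "ocr"`.
#' @return list with `trace` (an `OCRTrace`) and `ground_truth` (true
#'   non-mito/basal/ATP-linked/proton-leak/maximal/spare values).
#' @export
gen_ocr_trace <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"), spec$modality == "ocr")
  p <- resolve_params(spec$params, list(
    basal_raw = 100, post_oligo = 40, post_fccp = 150, post_antimycin = 10,
    n_per_phase = 5L, interval_min = 6, noise_sd = 0, cell_count = 20000L,
    ecar_level = 20, group_label = "group"))
  if (p$post_antimycin > p$basal_raw)
    warning("post-antimycin OCR exceeds basal: physiologically odd trace")

  levels <- c(p$basal_raw, p$post_oligo, p$post_fccp, p$post_antimycin)
  n <- 4L * p$n_per_phase
  time_min <- (seq_len(n) - 1) * p$interval_min
  clean <- rep(levels, each = p$n_per_phase)
  ocr <- with_seed(spec$seed, clean + rnorm(n, 0, p$noise_sd))
  inj_times <- time_min[p$n_per_phase * (1:3)] + p$interval_min / 2
  trace <- ocr_trace(time_min = time_min, ocr = ocr,
                     ecar = rep(p$ecar_level, n),
                     injections = data.frame(
                       label = c("oligomycin", "FCCP", "antimycinA"),
                       time_min = inj_times, stringsAsFactors = FALSE),
                     cell_count = p$cell_count, group_label = p$group_label)
  L <- levels
  gt <- list(true_non_mito = L[4], true_basal = L[1] - L[4],
             true_atp_linked = L[1] - L[2], true_proton_leak = L[2] - L[4],
             true_maximal = L[3] - L[4], true_spare = (L[3] - L[4]) - (L[1] - L[4]))
  list(trace = trace, ground_truth = gt)
}
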