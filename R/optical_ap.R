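#' Voltage trace set
#'
#' Container for frame-rate-stamped voltage-dye fluorescence recordings: one
#' column per recording site, arbitrary fluorescence units.
#'
#' @param samples numeric matrix, samples x sites (column names are site ids).
#' @param frame_rate_hz sampling rate in frames per second.
#' @param group_label free-text population label (e.g. "FHF", "SHF").
#' @return an object of class `VoltageTraceSet`.
#' @export
voltage_trace_set <- function(samples, frame_rate_hz, group_label = "") {
  samples <- as.matrix(samples)
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be positive")
  if (nrow(samples) < 3) stopf("traces need at least 3 samples")
  check_finite(samples, "voltage trace samples")
  if (is.null(colnames(samples)))
    colnames(samples) <- sprintf("site_%02d", seq_len(ncol(samples)))
  structure(list(samples = samples, frame_rate_hz = frame_rate_hz,
                 sites = colnames(samples), group_label = group_label),
            class = "VoltageTraceSet")
}

#' Normalize a fluorescence trace for AP feature extraction
#'
#' Auto-detects optical polarity (the orientation in which the steeper
#' extreme first difference is the upstroke) and flips downward-deflecting
#' dye signals, then subtracts a slow moving-median baseline so the diastolic
#' level sits near zero. Handles photobleaching-style linear drift.
#'
#' @param x numeric vector of raw fluorescence samples for one site.
#' @param frame_rate_hz sampling rate (Hz).
#' @param baseline_window_ms running-window length for the baseline; default
#'   2000 ms, i.e. twice the longest expected cycle length, so each window
#'   always contains full cycles.
#' @param baseline_quantile order statistic tracked as the baseline (default
#'   0.25). Action potentials can occupy up to half of each cycle, so the
#'   running median would ride above the diastolic level and distort
#'   amplitudes; a low quantile stays pinned to diastole while still
#'   following slow drift.
#' @return numeric vector of normalized samples.
#' @export
normalize_trace <- function(x, frame_rate_hz, baseline_window_ms = 2000,
                            baseline_quantile = 0.25) {
  if (diff(range(x)) == 0) stopf("flat signal: trace is constant")
  d <- diff(x)
  if (max(d) < -min(d)) x <- -x  # inverted optical polarity
  n <- length(x)
  k <- round(baseline_window_ms / 1000 * frame_rate_hz)
  if (k > n)
    stopf("baseline window (%d samples) longer than trace (%d)", k, n)
  if (k >= 3) {
    # the baseline is slow by construction: evaluate the running quantile on
    # a coarse grid, then smooth it by a local line fit over one window
    # (exact for linear drift, cancels any cycle-periodic wiggle of the
    # order statistic, and stays unbiased at the trace edges)
    h <- k %/% 2
    step <- max(1L, h %/% 10L)
    # grid centres where a full window fits; the smoothed baseline is
    # extended to the trace edges by linear extrapolation of the local fit
    idx <- unique(c(seq(h + 1L, max(h + 1L, n - h), by = step), max(h + 1L, n - h)))
    bl <- vapply(idx, function(i)
      quantile(x[(i - h):min(n, i + h)], baseline_quantile, names = FALSE),
      numeric(1))
    fits <- vapply(seq_along(idx), function(j) {
      w <- which(abs(idx - idx[j]) <= h)
      if (length(w) < 3) return(c(bl[j], 0))
      t0 <- idx[w] - idx[j]
      b1 <- sum((t0 - mean(t0)) * (bl[w] - mean(bl[w]))) / sum((t0 - mean(t0))^2)
      c(mean(bl[w]) - b1 * mean(t0), b1)
    }, numeric(2))
    base <- approx(idx, fits[1, ], xout = seq_len(n), rule = 2)$y
    left <- seq_len(n) < idx[1]
    base[left] <- fits[1, 1] + fits[2, 1] * (which(left) - idx[1])
    right <- seq_len(n) > idx[length(idx)]
    base[right] <- fits[1, length(idx)] +
      fits[2, length(idx)] * (which(right) - idx[length(idx)])
    x <- x - base
  }
  x
}

#' Extract per-beat action potential features
#'
#' Segments beats at upward crossings of a detection threshold (a fraction of
#' the site's global amplitude) separated by at least a refractory minimum,
#' then measures, per beat: activation time (midpoint of the steepest
#' upstroke segment, the discrete dV/dt-max analogue), peak time, amplitude
#' (peak minus preceding diastolic level), APD30 and APD80 (time from
#' activation until the trace first falls below peak minus 30%/80% of
#' amplitude, with linear interpolation between samples for sub-frame
#' precision), and cycle length (difference of successive activation times;
#' missing for the last beat). Beats truncated by the recording edge, i.e.
#' whose 80% repolarization is never reached before the next beat or the end
#' of the trace, are dropped.
#'
#' On noisy recordings two optional refinements tighten the estimates
#' without changing the noise-free semantics: `smooth_ms` applies a centred
#' moving average before beat detection and level measurement, and
#' `refine_ms` re-estimates each repolarization crossing by an ordinary
#' least-squares line fitted to the raw samples around the detected
#' crossing (the repolarization ramp is locally linear, so the line's
#' level-crossing is an unbiased sub-frame estimate, free of the early-bias
#' that first-passage detection suffers under noise). Both default to 0
#' (off).
#'
#' @param traces a [voltage_trace_set()].
#' @param threshold_frac detection threshold as a fraction of amplitude
#'   (default 0.5).
#' @param refractory_ms minimum spacing between detected beats (default 100).
#' @param noise_floor beats with amplitude at or below this are skipped.
#' @param normalize run [normalize_trace()] first (default TRUE).
#' @param baseline_window_ms passed to [normalize_trace()].
#' @param smooth_ms moving-average window (ms) for detection/levels; 0 = off.
#' @param refine_ms half-width (ms) of the local line fit refining each
#'   repolarization crossing; 0 = off.
#' @return a data.frame of class `APFeatureTable` with columns `site`,
#'   `beat`, `activation_time_ms`, `peak_time_ms`, `apd30_ms`, `apd80_ms`,
#'   `cycle_length_ms`, `amplitude`, plus attribute `group_label`.
#' @export
extract_ap_features <- function(traces, threshold_frac = 0.5, refractory_ms = 100,
                                noise_floor = 0, normalize = TRUE,
                                baseline_window_ms = 2000, smooth_ms = 0,
                                refine_ms = 0) {
  stopifnot(inherits(traces, "VoltageTraceSet"))
  dt <- 1000 / traces$frame_rate_hz
  rows <- lapply(traces$sites, function(site) {
    v <- traces$samples[, site]
    if (normalize) v <- normalize_trace(v, traces$frame_rate_hz, baseline_window_ms)
    extract_site_features(v, dt, site, threshold_frac, refractory_ms, noise_floor,
                          smooth_ms, refine_ms)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    warning("no beats detected")
    out <- data.frame(site = character(0), beat = integer(0),
                      activation_time_ms = numeric(0), peak_time_ms = numeric(0),
                      apd30_ms = numeric(0), apd80_ms = numeric(0),
                      cycle_length_ms = numeric(0), amplitude = numeric(0))
  }
  attr(out, "group_label") <- traces$group_label
  class(out) <- c("APFeatureTable", "data.frame")
  out
}

# Per-site beat segmentation and feature measurement. Sample i sits at time
# (i-1)*dt ms; the steepest first-difference segment [i, i+1] is assigned the
# midpoint time (i-0.5)*dt.
extract_site_features <- function(v, dt, site, threshold_frac, refractory_ms,
                                  noise_floor, smooth_ms = 0, refine_ms = 0) {
  n <- length(v)
  vs <- v
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / dt))
    if (w %% 2 == 0) w <- w + 1L
    if (w >= 3) {
      vs <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
      edge <- is.na(vs)
      vs[edge] <- v[edge]
    }
  }
  # a heavier smoothing pass is used only to locate repolarization crossings
  # (first-passage detection on raw noise triggers early); the location is
  # then refined on the raw samples, so the extra smoothing adds no bias
  vdet <- vs
  if (smooth_ms > 0) {
    wd <- max(1L, round(2 * smooth_ms / dt))
    if (wd %% 2 == 0) wd <- wd + 1L
    if (wd >= 3) {
      vdet <- as.numeric(stats::filter(v, rep(1 / wd, wd), sides = 2))
      edge <- is.na(vdet)
      vdet[edge] <- v[edge]
    }
  }
  m <- max(0L, round(refine_ms / dt))
  lo <- quantile(vs, 0.02, names = FALSE)
  hi <- max(vs)
  thr <- lo + threshold_frac * (hi - lo)
  up <- which(vs[-n] < thr & vs[-1] >= thr)
  if (!length(up)) return(NULL)
  # hysteresis: a new beat is armed only once the signal has dipped below
  # half the detection threshold, so noise wiggles on the repolarization
  # ramp cannot re-trigger
  thr_low <- lo + threshold_frac / 2 * (hi - lo)
  keep <- up[1]
  for (i in up[-1]) {
    last <- keep[length(keep)]
    if ((i - last) * dt >= refractory_ms && any(vs[last:i] < thr_low))
      keep <- c(keep, i)
  }
  cross <- keep

  half_win <- max(1L, round(refractory_ms / 2 / dt))
  beats <- list()
  for (j in seq_along(cross)) {
    c_j <- cross[j]
    w0 <- max(1L, c_j - half_win); w1 <- min(n - 1L, c_j + half_win)
    dseg <- diff(v)[w0:w1]  # raw derivative: the upstroke dominates noise
    jj <- which.max(dseg)
    act_i <- w0 + jj - 1L                       # diff index i: segment [i, i+1]
    # parabolic interpolation of the derivative peak: sub-frame activation
    # time, unbiased at the upstroke midpoint for a symmetric upstroke
    off <- 0
    if (jj > 1 && jj < length(dseg)) {
      den <- dseg[jj - 1] - 2 * dseg[jj] + dseg[jj + 1]
      if (den < 0) off <- max(-1, min(1, 0.5 * (dseg[jj - 1] - dseg[jj + 1]) / den))
    }
    act_t <- (act_i - 0.5 + off) * dt           # midpoint of steepest segment
    seg_end <- if (j < length(cross)) cross[j + 1] else n
    peak_i <- act_i + which.max(vs[act_i:seg_end]) - 1L
    dias_start <- if (j > 1) cross[j - 1] else 1L
    if (smooth_ms > 0) {
      # robust levels: medians are immune to the upward bias of extremes
      d0 <- max(dias_start, act_i - round(120 / dt)); d1 <- max(dias_start, act_i - round(10 / dt))
      dias <- if (d1 > d0) median(v[d0:d1]) else min(v[dias_start:act_i])
      # raw-sample median over an early post-upstroke window anchored at the
      # activation (not at the argmax, whose selection inflates nearby
      # samples): independent noise, no extreme-value bias
      p0 <- min(seg_end - 1L, act_i + round(6 / dt)); p1 <- min(seg_end, act_i + round(36 / dt))
      peak_v <- if (p1 > p0) median(v[p0:p1]) else vs[peak_i]
    } else {
      dias <- min(v[dias_start:act_i])
      peak_v <- vs[peak_i]
    }
    amp <- peak_v - dias
    if (amp <= noise_floor) next
    apd <- vapply(c(30, 80), function(x) {
      level <- peak_v - x / 100 * amp
      below <- which(vdet[(peak_i + 1):seg_end] < level)
      if (!length(below)) return(NA_real_)     # truncated by the recording edge
      i <- peak_i + below[1]                   # first sample below the level
      tcross <- if (vdet[i - 1] > vdet[i])
        (i - 2 + (vdet[i - 1] - level) / (vdet[i - 1] - vdet[i])) * dt
      else (i - 1) * dt
      if (m >= 3) {
        # local line on the raw samples around the crossing: unbiased
        # sub-frame estimate on the locally linear repolarization ramp
        i0 <- max(1L, i - m); i1 <- min(n, i + m)
        tt <- ((i0:i1) - 1) * dt
        fit <- stats::lm.fit(cbind(1, tt), v[i0:i1])
        b <- fit$coefficients
        if (is.finite(b[2]) && b[2] < 0) tcross <- (level - b[1]) / b[2]
      }
      tcross - act_t
    }, numeric(1))
    beats[[length(beats) + 1L]] <- data.frame(
      site = site, beat = length(beats) + 1L, activation_time_ms = act_t,
      peak_time_ms = (peak_i - 1) * dt, apd30_ms = apd[1], apd80_ms = apd[2],
      cycle_length_ms = NA_real_, amplitude = amp)
  }
  if (!length(beats)) return(NULL)
  out <- do.call(rbind, beats)
  if (nrow(out) > 1)
    out$cycle_length_ms[-nrow(out)] <- diff(out$activation_time_ms)
  # beats truncated by the recording edge (no measurable repolarization)
  out <- out[!is.na(out$apd30_ms) & !is.na(out$apd80_ms), , drop = FALSE]
  if (!nrow(out)) return(NULL)
  out$beat <- seq_len(nrow(out))
  bad <- out$apd30_ms > out$apd80_ms
  if (any(bad)) {
    warning(sprintf("%d beat(s) with APD30 > APD80 dropped as detection failures", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Compare a metric between two groups (unpaired two-tailed Student's t)
#'
#' Computes per-group mean and SEM, the percent increase of group A over
#' group B, and the classic pooled-variance two-sample t statistic with a
#' two-tailed p-value. Accepts `APFeatureTable`s (with `metric` naming the
#' column), plain numeric vectors, or any data.frame holding the metric.
#'
#' @param a,b the two groups.
#' @param metric column name when `a`/`b` are tables (e.g. `"apd30_ms"`).
#' @param labels length-2 character labels for the groups.
#' @return a list of class `GroupComparison` with elements `metric`,
#'   `groups` (per-group n/mean/sem), `percent_increase`, `t_statistic`,
#'   `p_value`.
#' @export
compare_groups <- function(a, b, metric = NULL,
                           labels = c("A", "B")) {
  pull <- function(x) {
    if (is.data.frame(x)) {
      if (is.null(metric)) stopf("metric must be named for table input")
      x <- x[[metric]]
    }
    x[is.finite(x)]
  }
  va <- pull(a); vb <- pull(b)
  if (length(va) < 2 || length(vb) < 2) stopf("need at least 2 values per group")
  na <- length(va); nb <- length(vb)
  ma <- mean(va); mb <- mean(vb)
  sp2 <- ((na - 1) * stats::var(va) + (nb - 1) * stats::var(vb)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    tstat <- if (ma == mb) 0 else sign(ma - mb) * Inf
  } else tstat <- (ma - mb) / se
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = na + nb - 2)
  structure(list(
    metric = metric %||% "value",
    groups = data.frame(group = labels, n = c(na, nb), mean = c(ma, mb),
                        sem = c(sd(va) / sqrt(na), sd(vb) / sqrt(nb))),
    percent_increase = 100 * (ma - mb) / mb,
    t_statistic = tstat, p_value = min(1, p)), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s\n", x$metric))
  print(x$groups, row.names = FALSE)
  cat(sprintf("percent increase (%s vs %s): %.2f%%\n",
              x$groups$group[1], x$groups$group[2], x$percent_increase))
  cat(sprintf("Student's t (unpaired, two-tailed): t = %.3f, p = %.3g\n",
              x$t_statistic, x$p_value))
  invisible(x)
}
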