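#' Quantitative-phase image stack
#'
#' Ordered phase-shift frames (optical path difference in nm per pixel) with
#' acquisition metadata.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param pixel_size_um pixel size (um).
#' @param frame_interval_min minutes between frames.
#' @param wavelength_nm illumination wavelength (default 660).
#' @return an object of class `PhaseStack`.
#' @export
phase_stack <- function(frames, pixel_size_um, frame_interval_min,
                        wavelength_nm = 660) {
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stopf("all frames must share one shape")
  if (pixel_size_um <= 0 || frame_interval_min <= 0)
    stopf("pixel_size_um and frame_interval_min must be positive")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 wavelength_nm = wavelength_nm),
            class = "PhaseStack")
}

# Otsu threshold of a numeric matrix via EBImage on a [0, 1] rescale.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xn <- (x - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

#' Segment one phase frame by local adaptive Otsu thresholding
#'
#' The frame is tiled; an Otsu threshold is computed per tile and bilinearly
#' interpolated between tile centres to a per-pixel threshold surface.
#' Tiles whose dynamic range is small relative to the whole frame (pure
#' background) fall back to the global Otsu threshold. Pixels above the
#' surface form foreground; connected components smaller than `min_area`
#' pixels are removed. The foreground mask is first dilated by `dilate_px`:
#' an Otsu cut sits near the half-maximum of a smooth cell profile, so a
#' modest dilation recovers the faint mass skirt around each object.
#'
#' @param frame numeric matrix (OPD nm, or a mass image).
#' @param tile_size tile edge in pixels (default 64).
#' @param min_area minimum object area in pixels (default 50).
#' @param dilate_px disc radius (px) for morphological dilation of the
#'   foreground mask (default 2; increase to capture full cell mass).
#' @return integer label matrix (0 = background, 1..n = objects).
#' @export
segment_frame <- function(frame, tile_size = 64, min_area = 50, dilate_px = 2) {
  check_finite(frame, "phase frame")
  global_thr <- otsu_threshold(frame)
  global_rng <- diff(range(frame))
  nr <- nrow(frame); nc <- ncol(frame)
  rb <- unique(c(seq(1, nr, by = tile_size), nr + 1L))
  cb <- unique(c(seq(1, nc, by = tile_size), nc + 1L))
  n_tr <- length(rb) - 1L; n_tc <- length(cb) - 1L
  thr_tile <- matrix(global_thr, n_tr, n_tc)
  ctr_r <- numeric(n_tr); ctr_c <- numeric(n_tc)
  for (i in seq_len(n_tr)) {
    for (j in seq_len(n_tc)) {
      tile <- frame[rb[i]:(rb[i + 1] - 1L), cb[j]:(cb[j + 1] - 1L)]
      if (diff(range(tile)) >= 0.25 * global_rng)
        thr_tile[i, j] <- otsu_threshold(tile)
    }
  }
  for (i in seq_len(n_tr)) ctr_r[i] <- (rb[i] + rb[i + 1] - 1L) / 2
  for (j in seq_len(n_tc)) ctr_c[j] <- (cb[j] + cb[j + 1] - 1L) / 2

  # interpolate rows, then columns (constant extrapolation past tile centres)
  tmp <- if (n_tr == 1) thr_tile[rep(1, nr), , drop = FALSE] else
    apply(thr_tile, 2, function(v) approx(ctr_r, v, xout = seq_len(nr), rule = 2)$y)
  tmp <- matrix(tmp, nrow = nr)
  surf <- if (n_tc == 1) tmp[, rep(1, nc), drop = FALSE] else
    t(apply(tmp, 1, function(v) approx(ctr_c, v, xout = seq_len(nc), rule = 2)$y))

  mask <- frame > surf
  if (!any(mask)) {
    warning("empty foreground after thresholding")
    return(matrix(0L, nr, nc))
  }
  if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
    mask <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nr, nc)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel 1..n
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) lab <- matrix(match(lab, ids, nomatch = 0L), nr, nc)
  lab
}

#' Convert a phase frame to a dry-mass image
#'
#' Dry mass per pixel follows the standard QPI conversion
#' mass_pg = OPD_um * pixel_area_um2 / alpha, with alpha the specific
#' refractive increment (um^3/pg, default 0.18). Negative OPD values are
#' clipped to zero; the clipped fraction is attached as attribute
#' `clipped_fraction`.
#'
#' @param frame OPD matrix in nm.
#' @param pixel_size_um pixel size (um).
#' @param alpha specific refractive increment (um^3/pg).
#' @return mass image (pg per pixel) with attribute `clipped_fraction`.
#' @export
phase_to_mass <- function(frame, pixel_size_um, alpha = 0.18) {
  if (alpha <= 0) stopf("alpha must be positive")
  clipped <- mean(frame < 0)
  m <- pmax(frame, 0) / 1000 * pixel_size_um^2 / alpha
  attr(m, "clipped_fraction") <- clipped
  m
}

# Object table for one labelled frame: label, mass-weighted centroid (px,
# x = column, y = row) and total mass (pg).
frame_objects <- function(labels, mass) {
  ids <- sort(unique(labels[labels > 0]))
  do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    m <- mass * sel
    tot <- sum(m)
    data.frame(label = id, cx_px = sum(col(mass) * m) / tot,
               cy_px = sum(row(mass) * m) / tot, mass_pg = tot)
  }))
}

#' Link segmented objects over time into cell tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames on
#' centroid distance, gated at `max_link_um`; distance ties are broken by
#' the smallest relative mass difference. Unmatched objects terminate or
#' start tracks; merging and splitting are not modelled.
#'
#' @param masks list of label matrices (one per frame, see
#'   [segment_frame()]).
#' @param mass_images list of mass images (pg), same length.
#' @param pixel_size_um pixel size (um).
#' @param max_link_um maximum linking distance (um, default 20).
#' @return data.frame of class `CellTrackTable`: `track`, `frame`, `label`,
#'   `cx_um`, `cy_um`, `mass_pg`.
#' @export
link_tracks <- function(masks, mass_images, pixel_size_um, max_link_um = 20) {
  if (length(masks) < 2) stopf("need at least 2 frames to link")
  obs <- lapply(seq_along(masks), function(f) {
    o <- frame_objects(masks[[f]], mass_images[[f]])
    if (is.null(o)) return(NULL)
    o$frame <- f
    o
  })
  next_track <- 1L
  assign_ids <- function(o) {
    if (is.null(o)) return(NULL)
    o$track <- seq.int(next_track, length.out = nrow(o))
    next_track <<- next_track + nrow(o)
    o
  }
  obs[[1]] <- assign_ids(obs[[1]])
  any_link <- FALSE
  for (f in seq_len(length(masks) - 1L)) {
    a <- obs[[f]]; b <- obs[[f + 1L]]
    if (is.null(b)) next
    b$track <- NA_integer_
    if (!is.null(a)) {
      dmat <- sqrt(outer(a$cx_px, b$cx_px, `-`)^2 +
                   outer(a$cy_px, b$cy_px, `-`)^2) * pixel_size_um
      free_a <- rep(TRUE, nrow(a)); free_b <- rep(TRUE, nrow(b))
      repeat {
        d <- dmat
        d[!free_a, ] <- Inf; d[, !free_b] <- Inf
        mn <- min(d)
        if (!is.finite(mn) || mn > max_link_um) break
        cand <- which(d == mn, arr.ind = TRUE)
        if (nrow(cand) > 1) {  # tie: smallest relative mass difference
          rel <- abs(a$mass_pg[cand[, 1]] - b$mass_pg[cand[, 2]]) /
            pmax(a$mass_pg[cand[, 1]], 1e-12)
          cand <- cand[which.min(rel), , drop = FALSE]
        }
        i <- cand[1, 1]; j <- cand[1, 2]
        b$track[j] <- a$track[i]
        free_a[i] <- FALSE; free_b[j] <- FALSE
        any_link <- TRUE
      }
    }
    new <- is.na(b$track)
    if (any(new)) {
      b$track[new] <- seq.int(next_track, length.out = sum(new))
      next_track <- next_track + sum(new)
    }
    obs[[f + 1L]] <- b
  }
  if (!any_link) warning("no links under the gate: all tracks have length 1")
  out <- do.call(rbind, obs)
  out <- data.frame(track = out$track, frame = out$frame, label = out$label,
                    cx_um = out$cx_px * pixel_size_um,
                    cy_um = out$cy_px * pixel_size_um,
                    cx_px = out$cx_px, cy_px = out$cy_px,
                    mass_pg = out$mass_pg)
  out <- out[order(out$track, out$frame), ]
  class(out) <- c("CellTrackTable", "data.frame")
  out
}

#' Per-track motion and mass-redistribution metrics
#'
#' For each consecutive frame pair of a track: net positional displacement
#' is the Euclidean centroid distance (um); percent mass fluctuation is
#' 100 * sum_px |m2(x - s) - m1(x)| / M1, where s is the integer-pixel shift
#' aligning the two centroids, the sum runs over the union of the two
#' aligned object masks, and M1 is the cell mass in the earlier frame
#' (centroid alignment cancels rigid translation, so pure motion contributes
#' no fluctuation). The mass accumulation rate is the slope of a straight-
#' line fit of total mass against time (pg/h).
#'
#' @param tracks a `CellTrackTable` from [link_tracks()].
#' @param masks,mass_images per-frame label matrices and mass images.
#' @param pixel_size_um pixel size (um).
#' @param frame_interval_min minutes between frames.
#' @return data.frame of class `MotionMetrics`, one row per track interval:
#'   `track`, `frame_from`, `net_displacement_um`, `pct_mass_fluctuation`,
#'   `unreliable`, plus per-track summary attribute via
#'   [summarize_motion()].
#' @export
motion_metrics <- function(tracks, masks, mass_images, pixel_size_um,
                           frame_interval_min) {
  stopifnot(inherits(tracks, "CellTrackTable"))
  rows <- list()
  for (tr in unique(tracks$track)) {
    tt <- tracks[tracks$track == tr, ]
    if (nrow(tt) < 2) next
    for (i in seq_len(nrow(tt) - 1L)) {
      f1 <- tt$frame[i]; f2 <- tt$frame[i + 1L]
      disp <- sqrt((tt$cx_um[i + 1] - tt$cx_um[i])^2 +
                   (tt$cy_um[i + 1] - tt$cy_um[i])^2)
      m1 <- mass_images[[f1]] * (masks[[f1]] == tt$label[i])
      m2 <- mass_images[[f2]] * (masks[[f2]] == tt$label[i + 1])
      s <- round(c(tt$cx_px[i + 1] - tt$cx_px[i], tt$cy_px[i + 1] - tt$cy_px[i]))
      m2a <- shift_matrix(m2, -s)
      support <- (m1 > 0) | (m2a > 0)
      unreliable <- !any((m1 > 0) & (m2a > 0))
      pct <- 100 * sum(abs(m2a - m1)[support]) / sum(m1)
      rows[[length(rows) + 1L]] <- data.frame(
        track = tr, frame_from = f1, net_displacement_um = disp,
        pct_mass_fluctuation = pct, unreliable = unreliable)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track = integer(0), frame_from = integer(0),
               net_displacement_um = numeric(0),
               pct_mass_fluctuation = numeric(0), unreliable = logical(0))
  class(out) <- c("MotionMetrics", "data.frame")
  attr(out, "frame_interval_min") <- frame_interval_min
  out
}

#' Summarize motion metrics per track
#'
#' Track means of displacement and percent mass fluctuation, plus the mass
#' accumulation rate from a straight-line fit of track mass against time.
#'
#' @param metrics a `MotionMetrics` table.
#' @param tracks the matching `CellTrackTable`.
#' @return data.frame, one row per track: `track`, `mean_displacement_um`,
#'   `mean_pct_mass_fluctuation`, `mass_accumulation_rate_pg_per_h`.
#' @export
summarize_motion <- function(metrics, tracks) {
  dt_h <- attr(metrics, "frame_interval_min") / 60
  do.call(rbind, lapply(unique(metrics$track), function(tr) {
    m <- metrics[metrics$track == tr, ]
    tt <- tracks[tracks$track == tr, ]
    rate <- if (nrow(tt) >= 2)
      unname(coef(lm(tt$mass_pg ~ I(tt$frame * dt_h)))[2]) else NA_real_
    data.frame(track = tr,
               mean_displacement_um = mean(m$net_displacement_um),
               mean_pct_mass_fluctuation = mean(m$pct_mass_fluctuation),
               mass_accumulation_rate_pg_per_h = rate)
  }))
}

#' Run the full QPM motion pipeline on a phase stack
#'
#' Convenience wrapper: converts phase to mass, segments every frame, links
#' tracks and computes motion metrics.
#'
#' @param stack a [phase_stack()].
#' @param alpha specific refractive increment (um^3/pg).
#' @param tile_size,min_area,dilate_px segmentation parameters.
#' @param max_link_um linking gate (um).
#' @return list with `masks`, `mass_images`, `tracks`, `metrics`, `summary`.
#' @export
qpm_pipeline <- function(stack, alpha = 0.18, tile_size = 64, min_area = 50,
                         dilate_px = 2, max_link_um = 20) {
  stopifnot(inherits(stack, "PhaseStack"))
  mass <- lapply(stack$frames, phase_to_mass, pixel_size_um = stack$pixel_size_um,
                 alpha = alpha)
  masks <- lapply(mass, segment_frame, tile_size = tile_size, min_area = min_area,
                  dilate_px = dilate_px)
  tracks <- link_tracks(masks, mass, stack$pixel_size_um, max_link_um)
  metrics <- motion_metrics(tracks, masks, mass, stack$pixel_size_um,
                            stack$frame_interval_min)
  list(masks = masks, mass_images = mass, tracks = tracks, metrics = metrics,
       summary = summarize_motion(metrics, tracks))
}
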