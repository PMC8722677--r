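#' AFM approach/retract force curve
#'
#' One nanoindentation record: piezo position `z` and cantilever deflection
#' `d` (both um), with cantilever spring constant `k` (nN/nm), spherical tip
#' radius `R` (um) and sample Poisson ratio `nu`. Geometry: the piezo travel
#' past contact splits into cantilever bending and sample indentation,
#' z = contact + d + delta.
#'
#' @param z piezo position samples (um), strictly monotone.
#' @param d cantilever deflection samples (um).
#' @param k spring constant (nN/nm).
#' @param R tip radius (um).
#' @param nu Poisson ratio in [0, 0.5].
#' @param direction "approach" or "retract".
#' @return an object of class `ForceCurve`.
#' @export
force_curve <- function(z, d, k, R, nu, direction = "approach") {
  direction <- match.arg(direction, c("approach", "retract"))
  if (length(z) != length(d) || length(z) < 10)
    stopf("z and d must have equal length >= 10")
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0))) stopf("z must be strictly monotone")
  if (k <= 0 || R <= 0) stopf("k and R must be positive")
  if (nu < 0 || nu > 0.5) stopf("nu must lie in [0, 0.5]")
  structure(list(z = z, d = d, k = k, R = R, nu = nu, direction = direction),
            class = "ForceCurve")
}

#' Convert an approach curve to force-indentation data
#'
#' Past the contact point, force is F = k * (d - d_baseline) (nN, with d in
#' um and k in nN/nm) and indentation is delta = (z - contact) - (d -
#' d_baseline) (um), where d_baseline is the mean deflection over the
#' pre-contact samples. Pre-contact samples are excluded and delta is
#' clipped at zero.
#'
#' @param curve a [force_curve()].
#' @param contact_point_z contact point (um), within the z range.
#' @return data.frame with columns `delta_um`, `force_nN`.
#' @export
force_indentation <- function(curve, contact_point_z) {
  stopifnot(inherits(curve, "ForceCurve"))
  if (contact_point_z < min(curve$z) || contact_point_z > max(curve$z))
    stopf("contact point outside the z range")
  pre <- curve$z < contact_point_z
  if (sum(pre) < 5) stopf("fewer than 5 pre-contact samples for baseline estimation")
  baseline <- mean(curve$d[pre])
  post <- curve$z > contact_point_z
  d0 <- curve$d[post] - baseline
  delta <- pmax((curve$z[post] - contact_point_z) - d0, 0)
  data.frame(delta_um = delta, force_nN = curve$k * 1000 * d0)
}

#' Fit the spherical-tip Hertz model for Young's modulus
#'
#' For a spherical indenter, F = (4 sqrt(R) / 3) * E / (1 - nu^2) *
#' delta^{3/2}. E is estimated by least squares of force against
#' delta^{3/2} through the origin, in SI units:
#' E = 3 (1 - nu^2) / (4 sqrt(R)) * sum(F_i x_i) / sum(x_i^2), x = delta^{3/2}.
#' The fit range runs from contact up to the maximum-force point.
#'
#' @param points data.frame with `delta_um`, `force_nN` (from
#'   [force_indentation()]).
#' @param R tip radius (um).
#' @param nu Poisson ratio.
#' @param contact_point_z optional contact point carried into the result.
#' @return list of class `HertzFit`: `contact_point_z`, `E` (Pa), `rss`
#'   (nN^2), `fit_range` (um), `n_points_fit`.
#' @export
fit_hertz <- function(points, R, nu, contact_point_z = NA_real_) {
  d <- points$delta_um; f <- points$force_nN
  imax <- which.max(f)
  use <- d > 0 & seq_along(d) <= imax
  if (sum(use) < 5) stopf("degenerate fit: need >= 5 points with delta > 0")
  d <- d[use]; f <- f[use]
  x <- (d * 1e-6)^1.5                 # m^{3/2}
  fN <- f * 1e-9                      # N
  slope <- sum(fN * x) / sum(x^2)     # N / m^{3/2}
  if (slope <= 0) stopf("non-physical fit: negative force-indentation slope (slope = %.3g)", slope)
  E <- slope * 3 * (1 - nu^2) / (4 * sqrt(R * 1e-6))
  rss <- sum((f - slope * x * 1e9)^2)
  structure(list(contact_point_z = contact_point_z, E = E, rss = rss,
                 fit_range = range(d), n_points_fit = length(d)),
            class = "HertzFit")
}

# Full-curve mean squared force residual for a candidate contact point:
# zero-force model before contact, best-fit Hertz after. Inf when the
# candidate is infeasible.
contact_objective <- function(curve, zc, R, nu) {
  pre <- curve$z < zc
  post <- curve$z > zc
  if (sum(pre) < 5 || sum(post) < 5) return(list(obj = Inf))
  baseline <- mean(curve$d[pre])
  d0 <- curve$d[post] - baseline
  delta <- pmax((curve$z[post] - zc) - d0, 0)
  f <- curve$k * 1000 * d0
  x <- (delta * 1e-6)^1.5
  if (sum(delta > 0) < 5 || sum(x^2) == 0) return(list(obj = Inf))
  slope <- sum(f * 1e-9 * x) / sum(x^2)
  if (slope <= 0) return(list(obj = Inf))
  res_post <- f - slope * x * 1e9
  res_pre <- curve$k * 1000 * (curve$d[pre] - baseline)
  list(obj = mean(c(res_pre, res_post)^2), slope = slope)
}

#' Find the contact point and fit the Hertz model
#'
#' The contact point is treated as a free parameter: a grid search over the
#' sampled z positions minimizes the full-curve mean squared force residual
#' (zero force before contact, Hertz beyond), then golden-section search
#' refines the contact point to a tenth of the sample spacing. The best
#' point evaluated anywhere (grid or refinement) wins.
#'
#' @param curve a [force_curve()] (approach direction).
#' @return a `HertzFit` (see [fit_hertz()]) with `contact_point_z` set.
#' @export
find_contact_and_fit <- function(curve) {
  stopifnot(inherits(curve, "ForceCurve"))
  z <- curve$z
  spacing <- median(abs(diff(z)))
  obj <- vapply(z, function(zc) contact_objective(curve, zc, curve$R, curve$nu)$obj,
                numeric(1))
  if (!any(is.finite(obj)))
    stopf("no contact point found within the sweep (flat residual landscape)")
  best_i <- which.min(obj)
  best_z <- z[best_i]; best_obj <- obj[best_i]

  lohi <- c(max(min(z), best_z - spacing), min(max(z), best_z + spacing))
  gr <- (sqrt(5) - 1) / 2
  a <- lohi[1]; b <- lohi[2]
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- contact_objective(curve, x1, curve$R, curve$nu)$obj
  f2 <- contact_objective(curve, x2, curve$R, curve$nu)$obj
  while ((b - a) > spacing / 10) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a)
      f1 <- contact_objective(curve, x1, curve$R, curve$nu)$obj
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a)
      f2 <- contact_objective(curve, x2, curve$R, curve$nu)$obj
    }
  }
  for (cand in c(x1, x2, (a + b) / 2)) {
    o <- contact_objective(curve, cand, curve$R, curve$nu)$obj
    if (is.finite(o) && o < best_obj) { best_obj <- o; best_z <- cand }
  }
  fit <- fit_hertz(force_indentation(curve, best_z), curve$R, curve$nu,
                   contact_point_z = best_z)
  fit
}

#' Aggregate per-site Hertz fits into one cell stiffness
#'
#' The protocol probes several local regions on top of the nucleus (five by
#' default) and reports their arithmetic mean modulus as the stiffness of
#' the cell.
#'
#' @param fits list of `HertzFit` objects (or a numeric vector of E values).
#' @param cell_id identifier for the cell.
#' @param group_label population label.
#' @param expected_sites warn when the number of sites differs (default 5).
#' @return list of class `CellStiffness`: `cell_id`, `group_label`,
#'   `site_E`, `mean_E` (Pa).
#' @export
cell_stiffness <- function(fits, cell_id, group_label = "", expected_sites = 5L) {
  E <- if (is.numeric(fits)) fits else vapply(fits, `[[`, numeric(1), "E")
  if (!length(E)) stopf("insufficient data: no fits supplied")
  if (length(E) != expected_sites)
    warning(sprintf("cell %s has %d sites (protocol expects %d)",
                    cell_id, length(E), expected_sites))
  structure(list(cell_id = cell_id, group_label = group_label,
                 site_E = E, mean_E = mean(E)), class = "CellStiffness")
}
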