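# SOBP construction from weighted pristine Bragg peaks, 2D dose maps with an
# implanted marker, and the central-line cold-spot statistic.

#' Simulate a library of pristine Bragg peaks
#'
#' One laterally integrated depth-dose curve per energy, simulated with the
#' transport engine in a water phantom.
#'
#' @param energies ascending energies in MeV (within 142-169 for the
#'   standard plan).
#' @param n_per_energy primaries per curve.
#' @param seed base RNG seed (energy index is added per curve).
#' @param dz_bin depth bin in mm.
#' @param phantom_length phantom length in mm.
#' @return list `z` (bin centres), `energies`, `D` (nz x nE matrix,
#'   normalised per primary).
#' @export
pristine_peak_library <- function(energies, n_per_energy = 100000L, seed = 1,
                                  dz_bin = 0.4, phantom_length = 220) {
  if (is.unsorted(energies)) stop("energies must be ascending")
  D <- NULL; z <- NULL
  for (i in seq_along(energies)) {
    dd <- score_depth_dose(energies[i], n_per_energy, seed + i * 1000L,
                           dz_bin = dz_bin, phantom_length = phantom_length)
    if (is.null(D)) { D <- matrix(0, nrow(dd), length(energies)); z <- dd$z }
    D[, i] <- dd$dose / n_per_energy
  }
  list(z = z, energies = energies, D = D)
}

#' Solve SOBP weights for a flat dose plateau
#'
#' Non-negative least squares on the flat-region depth bins with a uniform
#' dose target. The distal (highest-energy) peak carries the largest weight.
#'
#' @param lib a [pristine_peak_library()].
#' @param flat_region numeric (lo, hi) in mm.
#' @param max_flatness error if the achieved flatness (max deviation from
#'   the mean, relative) exceeds this.
#' @return object of class `pf_sobp_plan`: `energies`, `weights` (per-primary
#'   weights summing to 1), `flatness`, `flat_region`, `lib`.
#' @export
solve_weights <- function(lib, flat_region = c(140, 190), max_flatness = 0.05) {
  sel <- lib$z >= flat_region[1] & lib$z <= flat_region[2]
  C <- lib$D[sel, , drop = FALSE]
  b <- rep(1, sum(sel))
  w <- if (ncol(C) == 1) {
    sum(C * b) / sum(C * C)
  } else {
    pracma::lsqnonneg(C, b)$x
  }
  w <- pmax(w, 0)
  fl <- .sobp_flatness(lib, w, flat_region)
  if (fl > max_flatness)
    stop(sprintf("achieved flatness %.1f%% > %.1f%%: add more energies",
                 100 * fl, 100 * max_flatness))
  structure(list(energies = lib$energies, weights = w / sum(w),
                 flatness = fl, flat_region = flat_region, lib = lib),
            class = "pf_sobp_plan")
}

.sobp_flatness <- function(lib, w, flat_region, bin_mm = 2) {
  # flatness is a macroscopic plateau property: evaluate on bin_mm averages
  # so that single-depth-bin MC noise does not dominate the criterion
  d <- as.numeric(lib$D %*% w)
  sel <- which(lib$z >= flat_region[1] & lib$z <= flat_region[2])
  k <- max(1L, min(round(bin_mm / (lib$z[2] - lib$z[1])), length(sel)))
  n <- k * (length(sel) %/% k)
  dd <- colMeans(matrix(d[sel[seq_len(n)]], nrow = k))
  max(abs(dd - mean(dd))) / mean(dd)
}

#' Standard 14-19 cm SOBP plan
#'
#' Twelve pristine peaks equally spaced in range between 142 and 169 MeV
#' (the lowest/highest experimental energies), solved for a flat 140-190 mm
#' plateau.
#' @param n_energies number of pristine peaks.
#' @param n_per_energy library statistics per peak.
#' @param seed RNG seed.
#' @export
standard_sobp_plan <- function(n_energies = 12L, n_per_energy = 100000L,
                               seed = 1) {
  # equally spaced in range, mapped back to energy (range ~ E^1.77)
  r <- seq(csda_range(142, get_material("water")),
           csda_range(169, get_material("water")), length.out = n_energies)
  r1 <- csda_range(142, get_material("water"))
  e <- 142 * (r / r1)^(1 / 1.77)
  e[length(e)] <- 169
  lib <- pristine_peak_library(e, n_per_energy, seed)
  solve_weights(lib)
}

#' SOBP dose maps with and without an implanted marker
#'
#' Both runs share the sampled primaries, energies and random streams; the
#' reference run replaces the marker material by water, so every proton that
#' never meets the marker contributes identically to both maps and cancels
#' exactly in the cold-spot ratio.
#'
#' @param plan a `pf_sobp_plan`.
#' @param marker a `pf_marker` (centre placed at `marker_depth`).
#' @param n number of primaries.
#' @param seed RNG seed (field sampling, energy draw, transport).
#' @param marker_depth implant depth of the marker centre in mm.
#' @param field_half half-width of the sampled field in mm; protons starting
#'   further out cannot reach the central-line scorer.
#' @param grid dose grid override (defaults to 0.02 mm x 0.4 mm over
#'   x in [-10, 10], z in [0, 200], y window = marker length).
#' @return list `with`, `ref` (nx x nz dose, MeV), `with2`, `ref2`
#'   (squared-deposit accumulators), `grid`, `plan`, `marker`.
#' @export
sobp_dose_maps <- function(plan, marker, n, seed, marker_depth = 150,
                           field_half = 15, grid = NULL) {
  if (is.null(grid))
    grid <- list(x0 = -10, dx = 0.02, nx = 1000L, z0 = 0, dz = 0.4,
                 nz = 500L, y_half = marker$length_mm / 2)
  geo <- sobp_phantom_geometry(marker_depth = marker_depth)
  en <- sample_sobp_energies(plan$energies, plan$weights, n, seed + 1L)
  st <- sample_field(n, seed, half_width = field_half, energies = en)
  run <- function(null_marker) {
    transport(st, geo, marker = marker, seed = seed, dose = grid,
              null_marker = null_marker)
  }
  rw <- run(FALSE); rr <- run(TRUE)
  list(with = rw$dose, with2 = rw$dose2, ref = rr$dose, ref2 = rr$dose2,
       grid = grid, plan = plan, marker = marker, marker_depth = marker_depth)
}

#' Maximum central-line cold spot behind the marker
#'
#' Central-line depth-dose curves (dose averaged over `|x| <= central_half`)
#' are extracted from both maps; the cold spot at depth z is
#' 100 (ref - with)/ref, maximised between the marker's downstream face and
#' the end of the SOBP plateau. The z position is reported relative to the
#' downstream face. The statistical uncertainty propagates both curves'
#' per-bin MC counting errors in quadrature.
#'
#' @param maps result of [sobp_dose_maps()].
#' @param central_half half-width of the central line in mm; the default
#'   samples the interior of the marker's geometric shadow,
#'   `min(od/2, 0.25)`. A line much narrower than the shadow is dominated
#'   by a handful of end-of-range Bragg peaks and its maximum becomes
#'   seed-unstable at realistic primary counts.
#' @param search_end end of the search region in mm depth (default: end of
#'   the plan's flat region).
#' @param smooth_bins width (in depth bins) of the moving average applied to
#'   the cold-spot curve before taking the maximum; the physical cold spot
#'   extends over many 0.4 mm bins, so a short window suppresses single-bin
#'   outliers without flattening the dip.
#' @return object of class `pf_cold_spot`: `max_cold_spot` (%), `z_position`
#'   (mm behind the marker face), `stat_uncertainty` (%), `z_uncertainty`
#'   (one depth bin).
#' @export
cold_spot <- function(maps, central_half = NULL, search_end = NULL,
                      smooth_bins = 5L) {
  if (is.null(central_half))
    central_half <- min(maps$marker$od_mm / 2, 0.25)
  g <- maps$grid
  if (is.null(search_end))
    search_end <- if (!is.null(maps$plan)) maps$plan$flat_region[2] else
      g$z0 + g$nz * g$dz
  x <- g$x0 + (seq_len(g$nx) - 0.5) * g$dx
  z <- g$z0 + (seq_len(g$nz) - 0.5) * g$dz
  cols <- abs(x) <= central_half
  cw <- colSums(maps$with[cols, , drop = FALSE])
  cr <- colSums(maps$ref[cols, , drop = FALSE])
  vw <- colSums(maps$with2[cols, , drop = FALSE])
  vr <- colSums(maps$ref2[cols, , drop = FALSE])
  face <- maps$marker_depth + maps$marker$od_mm / 2
  sel <- z > face & z <= search_end & cr > 0.05 * max(cr)
  cs_raw <- 100 * (cr - cw) / cr
  cs <- cs_raw
  if (smooth_bins > 1) {
    k <- rep(1 / smooth_bins, smooth_bins)
    cs <- as.numeric(stats::filter(cs_raw, k, sides = 2))
  }
  cs[!sel] <- NA
  i <- which.max(cs)
  if (!length(i) || is.na(cs[i])) stop("no valid depth bins behind the marker")
  rel_err <- sqrt(vw[i] / max(cw[i], 1e-12)^2 + vr[i] / max(cr[i], 1e-12)^2)
  structure(list(max_cold_spot = max(cs[i], 0),
                 z_position = z[i] - face,
                 stat_uncertainty = 100 * rel_err,
                 z_uncertainty = g$dz * max(1L, smooth_bins),
                 profile = data.frame(z = z, ref = cr, with = cw,
                                      cold_spot = cs_raw,
                                      cold_spot_smooth = cs)),
            class = "pf_cold_spot")
}

#' @export
print.pf_cold_spot <- function(x, ...) {
  cat(sprintf("max cold spot %.1f%% +/- %.1f at %.1f mm behind the marker\n",
              x$max_cold_spot, x$stat_uncertainty, x$z_position))
  invisible(x)
}
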