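# Condensed-history Monte Carlo front end: beam sampling, transport through a
# pf_geometry (+ optional marker), sensor-plane hits and dose scoring.

#' Beam phase-space specification
#'
#' Pencil beam at the vacuum exit window: Gaussian in position with
#' `sigma = fwhm / 2.3548`, Gaussian in angle with sigma equal to the
#' divergence, plus optional offset and tilt.
#'
#' @param energy kinetic energy in MeV.
#' @param fwhm lateral FWHM at the window in mm.
#' @param divergence angular sigma in mrad.
#' @param offset lateral (x, y) offset in mm.
#' @param tilt (x, y) tilt in mrad.
#' @export
beam_spec <- function(energy, fwhm = 3.5, divergence = 7.5,
                      offset = c(0, 0), tilt = c(0, 0)) {
  stopifnot(fwhm > 0, divergence >= 0)
  structure(list(energy = energy, fwhm = fwhm, divergence = divergence,
                 offset = offset, tilt = tilt), class = "pf_beam")
}

#' Standard beams used at the treatment facility
#'
#' The two single-energy beams (142.10 and 169.02 MeV) with the tuned
#' exit-window optics: 3.5 mm FWHM for both; divergence 7.0 mrad at 142 MeV
#' and 7.5 mrad at 169/170 MeV.
#' @param which `"142"` or `"169"`.
#' @export
standard_beam <- function(which = c("169", "142")) {
  which <- match.arg(which)
  if (which == "142") beam_spec(142.10, 3.5, 7.0) else beam_spec(169.02, 3.5, 7.5)
}

#' Sample primary protons from a beam specification
#'
#' @param beam a [beam_spec()].
#' @param n number of primaries.
#' @param seed RNG seed (mandatory; reproducible).
#' @param energies optional per-primary energy vector (length n) overriding
#'   `beam$energy`, e.g. an SOBP energy draw.
#' @return data.frame with columns x, y, tx, ty, z, energy, pid.
#' @export
sample_beam <- function(beam, n, seed, energies = NULL) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  sig <- beam$fwhm / 2.3548
  sth <- beam$divergence * 1e-3
  data.frame(
    x = stats::rnorm(n, beam$offset[1], sig),
    y = stats::rnorm(n, beam$offset[2], sig),
    tx = if (sth > 0) stats::rnorm(n, beam$tilt[1] * 1e-3, sth) else
      rep(beam$tilt[1] * 1e-3, n),
    ty = if (sth > 0) stats::rnorm(n, beam$tilt[2] * 1e-3, sth) else
      rep(beam$tilt[2] * 1e-3, n),
    z = 0,
    energy = if (is.null(energies)) rep(beam$energy, n) else energies,
    pid = seq_len(n))
}

#' Sample a laterally uniform field
#'
#' Parallel beam, uniform over the square `|x|,|y| <= half_width`; used for
#' SOBP dose simulations where the plan covers a broad field. Sampling may be
#' restricted to the sub-field that can influence a central scorer.
#' @inheritParams sample_beam
#' @param half_width half-width of the sampled square field in mm.
#' @export
sample_field <- function(n, seed, half_width = 15, energies) {
  set.seed(seed)
  data.frame(
    x = stats::runif(n, -half_width, half_width),
    y = stats::runif(n, -half_width, half_width),
    tx = 0, ty = 0, z = 0, energy = energies, pid = seq_len(n))
}

.mat_key <- function(m) paste0(m$name, "@", format(m$density, digits = 12))

# Flatten a pf_geometry (+ marker) into the interval description the C++
# kernel consumes: sorted breakpoints, per-interval material index, material
# constant matrix.
.build_transport_cfg <- function(geometry, marker = NULL, marker_center = NULL) {
  mats <- list(); midx <- function(m) {
    k <- .mat_key(m)
    if (is.null(mats[[k]])) mats[[k]] <<- m
    which(names(mats) == k) - 1L
  }
  amb_i <- midx(geometry$ambient)
  edges <- numeric(0)
  for (l in geometry$layers) edges <- c(edges, l$z_start, l$z_end)
  mk_cfg <- list(present = FALSE)
  if (!is.null(marker)) {
    cz <- if (is.null(marker_center)) geometry$marker_z else marker_center
    ro <- marker$od_mm / 2
    mk_cfg <- list(present = TRUE,
                   shape = if (marker$shape == "tube") 1L else 2L,
                   cx = marker$center[1], cy = marker$center[2], cz = cz,
                   r_out = ro, r_in = marker$id_mm / 2,
                   half_len = marker$length_mm / 2,
                   mat = midx(marker$material), fine_margin = 2.0)
    edges <- c(edges, cz - ro - 2, cz + ro + 2)
  }
  edges <- sort(unique(c(edges, geometry$sensor_z)))
  if (length(edges) < 2) edges <- c(0, 1e6)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  region_mat <- vapply(mids, function(zm) {
    for (l in geometry$layers)
      if (zm >= l$z_start && zm < l$z_end) return(midx(l$material))
    amb_i
  }, integer(1))
  mat_m <- do.call(rbind, lapply(mats, function(m)
    c(m$density, m$Z_over_A, m$I_eV, m$X0_g_cm2)))
  list(bp = edges, region_mat = as.integer(region_mat), ambient = amb_i,
       mats = mat_m, marker = mk_cfg)
}

#' Transport primaries through a geometry
#'
#' Condensed-history stepping: default 1 mm maximum step in solids, exact
#' sub-stepping at layer boundaries and 0.02 mm steps within 2 mm of the
#' marker; per step a mean Bethe loss plus Gaussian Bohr straggling draw and
#' a Highland angular kick with Fermi-Eyges-correlated lateral displacement;
#' particles are killed below 0.5 MeV with local deposition of the residual.
#' Random streams are counter-based per primary, so two runs sharing `seed`
#' differ only through material differences (e.g. marker vs no marker).
#'
#' @param states data.frame from [sample_beam()] / [sample_field()].
#' @param geometry a `pf_geometry`.
#' @param marker a `pf_marker` or NULL.
#' @param seed transport RNG seed.
#' @param dose optional dose-scoring grid:
#'   `list(x0=, dx=, nx=, z0=, dz=, nz=, y_half=)` (y_half = 0 disables the
#'   y window).
#' @param step_max,fine_step,cutoff step control (mm, mm, MeV).
#' @param z_max transport stops past this z (defaults past the last layer,
#'   sensor and dose bin).
#' @param marker_center optional z of the marker centre; defaults to the
#'   geometry's `marker_z` (plus the marker radius for the experiment preset,
#'   where `marker_z` is the mounting face).
#' @param null_marker if TRUE, keep the marker's stepping geometry but fill
#'   it with the host medium (matched reference run).
#' @param record_traj record every step (small n only).
#' @return list with `hits` (data.frame sensor/x/y/energy/pid), `stop_z`,
#'   `n_stopped`, and when dose scoring is on, `dose` and `dose2` matrices
#'   (nx x nz, MeV and MeV^2 per voxel) plus the grid.
#' @export
transport <- function(states, geometry, marker = NULL, seed = 1,
                      dose = NULL, step_max = 1.0, fine_step = 0.02,
                      cutoff = 0.5, z_max = NULL, marker_center = NULL,
                      null_marker = FALSE, record_traj = FALSE) {
  if (!is.null(marker) && is.null(marker_center)) {
    marker_center <- if (identical(geometry$preset, "experiment"))
      geometry$marker_z + marker$od_mm / 2 else geometry$marker_z
  }
  if (!is.null(marker) && null_marker) {
    # host medium at the marker centre z (marker test skipped)
    host <- locate(c(0, 0, marker_center), geometry, NULL)
    marker <- within_marker_material(marker, host)
  }
  cfg <- .build_transport_cfg(geometry, marker, marker_center)
  dose_cfg <- list(enabled = FALSE)
  if (!is.null(dose)) {
    dose_cfg <- c(list(enabled = TRUE), dose)
    if (is.null(dose_cfg$y_half)) dose_cfg$y_half <- 0
  }
  if (is.null(z_max)) {
    z_max <- max(c(cfg$bp, geometry$sensor_z,
                   if (!is.null(dose)) dose$z0 + dose$nz * dose$dz else 0)) + 1
  }
  res <- transport_cpp(as.matrix(states[, c("x", "y", "tx", "ty", "z", "energy")]),
                       as.integer(states$pid), cfg$bp, cfg$region_mat,
                       cfg$ambient, cfg$mats, unname(geometry$sensor_z),
                       cfg$marker, dose_cfg, step_max, fine_step, cutoff,
                       z_max, seed, record_traj)
  hits <- as.data.frame(res$hits)
  if (nrow(hits) && length(geometry$sensor_z))
    hits$sensor_name <- names(geometry$sensor_z)[hits$sensor]
  out <- list(hits = hits, stop_z = res$stop_z, n_stopped = res$n_stopped,
              marker_center = marker_center)
  if (!is.null(dose)) {
    out$dose <- res$dose; out$dose2 <- res$dose2; out$grid <- dose
  }
  if (record_traj) out$traj <- as.data.frame(res$traj)
  out
}

# swap a marker's material (used for matched reference runs)
within_marker_material <- function(marker, mat) {
  marker$material <- mat
  marker
}

#' Laterally integrated depth-dose curve
#'
#' Transports a beam into the water phantom and scores the laterally
#' integrated dose per depth bin.
#' @param energy beam kinetic energy in MeV (parallel pencil at x=y=0).
#' @param n number of primaries.
#' @param seed RNG seed.
#' @param dz_bin depth bin width in mm.
#' @param phantom_length phantom length in mm.
#' @return data.frame with `z` (bin centre, mm) and `dose` (MeV per bin).
#' @export
score_depth_dose <- function(energy, n, seed, dz_bin = 0.4,
                             phantom_length = 220) {
  geo <- sobp_phantom_geometry(phantom_length = phantom_length)
  st <- data.frame(x = 0, y = 0, tx = 0, ty = 0, z = 0,
                   energy = rep(energy, n), pid = seq_len(n))
  nz <- ceiling(phantom_length / dz_bin)
  res <- transport(st, geo, seed = seed,
                   dose = list(x0 = -100, dx = 200, nx = 1L,
                               z0 = 0, dz = dz_bin, nz = as.integer(nz),
                               y_half = 0))
  data.frame(z = (seq_len(nz) - 0.5) * dz_bin, dose = as.numeric(res$dose))
}

#' Draw pristine-peak energies for an SOBP plan
#'
#' Multinomial draw of the plan's pristine energies proportional to their
#' weights.
#' @param energies pristine-peak energies in MeV.
#' @param weights non-negative weights (not all zero).
#' @param n number of draws.
#' @param seed RNG seed.
#' @export
sample_sobp_energies <- function(energies, weights, n, seed) {
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  set.seed(seed)
  energies[sample.int(length(energies), n, replace = TRUE,
                      prob = weights / sum(weights))]
}
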