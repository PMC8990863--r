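# Pipeline orchestration: seeded end-to-end runs (simulate -> digitize ->
# reconstruct -> back-project -> perturbation statistic), result tables,
# run manifests.

#' End-to-end run configuration
#'
#' @param beam `"169"`, `"142"`, or a [beam_spec()].
#' @param marker marker id in {1,2,3,4,5,8} or `NA` for a marker-free run.
#' @param n_primaries number of primaries.
#' @param seed_simulate,seed_digitize mandatory stage seeds (no wall-clock
#'   defaults: reproducibility first).
#' @param y_window_frac y-integration window as a fraction of the marker
#'   length (centred).
#' @param batch_size primaries per readout frame.
#' @param noise_rate digitization noise rate per pixel per frame.
#' @param gate track-matching gate in mm.
#' @param rebin profile rebin factor passed to [max_perturbation()]
#'   (NULL = automatic).
#' @param out_dir optional output directory for artifact files.
#' @export
run_config <- function(beam = "169", marker = 2, n_primaries = 2e5,
                       seed_simulate, seed_digitize,
                       y_window_frac = 0.8, batch_size = 20L,
                       noise_rate = 1e-6, gate = 0.2, rebin = NULL,
                       out_dir = NULL) {
  if (missing(seed_simulate) || missing(seed_digitize))
    stop("stage seeds are mandatory")
  structure(list(beam = beam, marker = marker, n_primaries = n_primaries,
                 seed_simulate = seed_simulate, seed_digitize = seed_digitize,
                 y_window_frac = y_window_frac, batch_size = batch_size,
                 noise_rate = noise_rate, gate = gate, rebin = rebin,
                 out_dir = out_dir), class = "pf_run_config")
}

.config_hash <- function(config) {
  # hash the scientific configuration only (output location excluded)
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  # small stable polynomial hash over the deparsed config
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the measurement pipeline end to end
#'
#' Simulates the experimental beamline with and without the marker (shared
#' seeds, so unperturbed histories cancel), digitizes S5-S7, finds clusters,
#' reconstructs tracks, back-projects both runs into the fluence grid at the
#' marker, and evaluates the maximum-perturbation statistic.
#'
#' @param config a [run_config()].
#' @return list with `perturbation` (a `pf_perturbation`, NULL for
#'   marker-free runs compared against themselves), `maps` (with/ref
#'   `pf_fluence_map`s), `counters`, `config_hash`, and `manifest`
#'   (data.frame of written artifacts and checksums; empty when `out_dir`
#'   is NULL).
#' @export
run_pipeline <- function(config) {
  beam <- if (inherits(config$beam, "pf_beam")) config$beam else
    standard_beam(config$beam)
  geo <- build_experiment_geometry("experiment")
  marker <- if (!is.na(config$marker)) marker_from_catalog(config$marker) else NULL
  st <- sample_beam(beam, config$n_primaries, config$seed_simulate)
  counters <- list()

  one_pass <- function(null_marker) {
    mk <- if (is.null(marker)) marker_from_catalog(2) else marker
    tr <- transport(st, geo, marker = mk, seed = config$seed_simulate,
                    null_marker = null_marker || is.null(marker))
    dg <- digitize(tr$hits[tr$hits$sensor %in% 5:7, ],
                   batch_size = config$batch_size,
                   noise_rate = config$noise_rate,
                   seed = config$seed_digitize)
    cl <- find_clusters(dg$pixels)
    tk <- reconstruct_tracks(cl, geo, sensors = c(5, 6, 7),
                             gate = config$gate, z_ref = tr$marker_center)
    list(tracks = tk, dropped = dg$dropped, marker_center = tr$marker_center,
         n_hits = nrow(tr$hits), n_clusters = nrow(cl),
         unmatched = attr(tk, "unmatched"))
  }
  pw <- one_pass(FALSE)
  pr <- one_pass(TRUE)
  mk_len <- if (is.null(marker)) 5 else marker$length_mm
  gspec <- fluence_grid_spec(y_half = config$y_window_frac * mk_len / 2)
  # track intercepts are reported at the marker centre = the grid's z = 0
  mw <- integrate_map(backproject(pw$tracks, gspec))
  mr <- integrate_map(backproject(pr$tracks, gspec))
  pert <- max_perturbation(mw, mr, rebin = config$rebin)
  counters <- list(n_primaries = config$n_primaries,
                   hits_with = pw$n_hits, hits_ref = pr$n_hits,
                   clusters_with = pw$n_clusters, clusters_ref = pr$n_clusters,
                   tracks_with = nrow(pw$tracks), tracks_ref = nrow(pr$tracks),
                   dropped_with = sum(pw$dropped), dropped_ref = sum(pr$dropped),
                   unmatched_with = pw$unmatched, unmatched_ref = pr$unmatched)
  manifest <- data.frame(file = character(0), md5 = character(0))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    res_df <- data.frame(marker = if (is.null(marker)) "none" else marker$id,
                         perturbation_pct = pert$max_perturbation,
                         stat_unc_pct = pert$stat_uncertainty,
                         z_mm = pert$z_position, z_unc_mm = pert$z_uncertainty)
    f1 <- file.path(config$out_dir, "perturbation.tsv")
    write_results_table(res_df, f1,
                        units = c("id", "%", "%", "mm", "mm"),
                        seeds = c(simulate = config$seed_simulate,
                                  digitize = config$seed_digitize),
                        config_hash = .config_hash(config))
    f2 <- file.path(config$out_dir, "tracks_with.tsv")
    utils::write.table(pw$tracks, f2, sep = "\t", row.names = FALSE)
    manifest <- data.frame(file = c(f1, f2), md5 = tools::md5sum(c(f1, f2)),
                           row.names = NULL)
    f3 <- file.path(config$out_dir, "manifest.tsv")
    utils::write.table(manifest, f3, sep = "\t", row.names = FALSE)
  }
  list(perturbation = pert, maps = list(with = mw, ref = mr),
       counters = counters, config_hash = .config_hash(config),
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results table with unit and seed headers
#'
#' Delimited text mirroring the published table layouts: one row per marker
#' with value and uncertainty columns; comment headers carry the column
#' units, the stage seeds and the configuration hash. The file round-trips
#' through [read_results_table()].
#'
#' @param results homogeneous data.frame.
#' @param file output path.
#' @param units character vector, one per column.
#' @param seeds named integer vector recorded in the header.
#' @param config_hash configuration hash recorded in the header.
#' @export
write_results_table <- function(results, file, units = NULL, seeds = NULL,
                                config_hash = NULL) {
  if (!is.data.frame(results)) stop("results must be a data.frame")
  con <- file(file, "w"); on.exit(close(con))
  if (!is.null(units)) {
    if (length(units) != ncol(results))
      stop("need one unit per column")
    writeLines(paste0("# units: ", paste(units, collapse = "\t")), con)
  }
  if (!is.null(seeds))
    writeLines(paste0("# seeds: ",
                      paste(names(seeds), seeds, sep = "=", collapse = " ")), con)
  if (!is.null(config_hash)) writeLines(paste0("# config: ", config_hash), con)
  utils::write.table(results, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a results table written by [write_results_table()]
#' @param file path.
#' @return data.frame with attributes `units`, `seeds`, `config_hash`
#'   when present.
#' @export
read_results_table <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines)
  df <- utils::read.delim(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                       collapse = "\n"))
  for (h in lines[hdr]) {
    if (startsWith(h, "# units: "))
      attr(df, "units") <- strsplit(sub("^# units: ", "", h), "\t")[[1]]
    if (startsWith(h, "# seeds: "))
      attr(df, "seeds") <- sub("^# seeds: ", "", h)
    if (startsWith(h, "# config: "))
      attr(df, "config_hash") <- sub("^# config: ", "", h)
  }
  df
}
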