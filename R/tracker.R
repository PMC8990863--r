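# Virtual Mimosa-28 chain: binary-pixel digitization, cluster finding,
# software alignment and straight-line track reconstruction.

PIX_NROW <- 928L
PIX_NCOL <- 960L
PIX_PITCH <- 0.0207  # mm

#' Digitize sensor-plane hits into binary pixel frames
#'
#' Each traversing proton deposits a Gaussian charge cloud; pixels whose
#' integrated charge fraction crosses the threshold fire (binary output).
#' Uniform random noise pixels are added per frame. Primaries are batched
#' into readout frames so that the expected track multiplicity per frame
#' stays modest.
#'
#' @param hits data.frame with columns `sensor`, `x`, `y`, `pid`
#'   (from [transport()]).
#' @param sensors which sensor ids to digitize.
#' @param batch_size primaries per readout frame.
#' @param sigma charge-cloud sigma in mm.
#' @param threshold charge fraction above which a pixel fires.
#' @param noise_rate per-pixel noise probability per frame (<= 1e-3).
#' @param seed RNG seed for the noise draw.
#' @return list with `pixels` (data.frame sensor/frame/row/col) and
#'   `dropped` (hits outside the active area, per sensor).
#' @export
digitize <- function(hits, sensors = unique(hits$sensor), batch_size = 20L,
                     sigma = 0.010, threshold = 0.1, noise_rate = 1e-6,
                     seed = 1) {
  if (noise_rate < 0 || noise_rate > 1e-3)
    stop("noise_rate must be in [0, 1e-3]")
  out <- list(); dropped <- integer(0)
  for (s in sort(sensors)) {
    hs <- hits[hits$sensor == s, , drop = FALSE]
    frame <- as.integer((hs$pid - 1L) %/% batch_size)
    r <- digitize_cpp(hs$x, hs$y, frame, PIX_NROW, PIX_NCOL, PIX_PITCH,
                      sigma, threshold, noise_rate, seed, as.integer(s))
    px <- as.data.frame(r$pixels)
    if (nrow(px)) px$sensor <- s
    out[[as.character(s)]] <- px
    dropped[as.character(s)] <- r$dropped
  }
  px <- do.call(rbind, out)
  rownames(px) <- NULL
  list(pixels = px, dropped = dropped)
}

#' Find clusters of fired pixels
#'
#' Connected components with 8-connectivity; the cluster position is the
#' centre of mass of the group of fired pixels, converted to mm in the
#' sensor frame (origin at the active-area centre).
#'
#' @param pixels data.frame with `sensor`, `frame`, `row`, `col`.
#' @return data.frame with `sensor`, `frame`, `x`, `y` (mm), `size`.
#' @export
find_clusters <- function(pixels) {
  if (is.null(pixels) || nrow(pixels) == 0)
    return(data.frame(sensor = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), size = integer(0)))
  out <- lapply(sort(unique(pixels$sensor)), function(s) {
    ps <- pixels[pixels$sensor == s, , drop = FALSE]
    ps <- ps[order(ps$frame), , drop = FALSE]
    cl <- as.data.frame(cluster_cpp(as.integer(ps$frame), as.integer(ps$row),
                                    as.integer(ps$col),
                                    PIX_NROW, PIX_NCOL, PIX_PITCH)$clusters)
    names(cl)[1] <- "frame"
    cl$sensor <- s
    cl[, c("sensor", "frame", "x", "y", "size")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply an alignment solution to cluster positions
#' @param clusters cluster data.frame.
#' @param alignment data.frame `sensor`, `dx`, `dy`, `rot` (mm, mm, rad).
#' @export
apply_alignment <- function(clusters, alignment) {
  if (is.null(alignment)) return(clusters)
  for (i in seq_len(nrow(alignment))) {
    s <- alignment$sensor[i]
    k <- clusters$sensor == s
    th <- alignment$rot[i]
    x <- clusters$x[k]; y <- clusters$y[k]
    clusters$x[k] <- x + th * y - alignment$dx[i]
    clusters$y[k] <- y - th * x - alignment$dy[i]
  }
  clusters
}

# nearest-cluster chaining through the sensor list for low-occupancy
# alignment runs: seed a line from the first and last plane, pick the nearest
# cluster on every middle plane within the gate
.chain_tracks <- function(clusters, sensor_ids, sensor_z, gate = 1.0) {
  first <- sensor_ids[1]; last <- sensor_ids[length(sensor_ids)]
  frames <- intersect(unique(clusters$frame[clusters$sensor == first]),
                      unique(clusters$frame[clusters$sensor == last]))
  rows <- list(); n <- 0
  cl_by <- split(clusters, list(clusters$sensor, clusters$frame), drop = TRUE)
  key <- function(s, f) paste0(s, ".", f)
  for (f in frames) {
    c1 <- cl_by[[key(first, f)]]; cL <- cl_by[[key(last, f)]]
    if (is.null(c1) || is.null(cL)) next
    used_L <- rep(FALSE, nrow(cL))
    for (i in seq_len(nrow(c1))) {
      d2 <- (cL$x - c1$x[i])^2 + (cL$y - c1$y[i])^2
      d2[used_L] <- Inf
      j <- which.min(d2)
      if (!length(j) || !is.finite(d2[j]) || d2[j] > 16) next
      used_L[j] <- TRUE
      z1 <- sensor_z[as.character(first)]; zL <- sensor_z[as.character(last)]
      tx <- (cL$x[j] - c1$x[i]) / (zL - z1)
      ty <- (cL$y[j] - c1$y[i]) / (zL - z1)
      pts <- data.frame(sensor = c(first, last),
                        z = c(z1, zL),
                        x = c(c1$x[i], cL$x[j]),
                        y = c(c1$y[i], cL$y[j]))
      ok <- TRUE
      for (s in setdiff(sensor_ids, c(first, last))) {
        cs <- cl_by[[key(s, f)]]
        if (is.null(cs)) { ok <- FALSE; break }
        zs <- sensor_z[as.character(s)]
        xp <- c1$x[i] + tx * (zs - z1); yp <- c1$y[i] + ty * (zs - z1)
        d2s <- (cs$x - xp)^2 + (cs$y - yp)^2
        k <- which.min(d2s)
        if (d2s[k] > gate^2) { ok <- FALSE; break }
        pts <- rbind(pts, data.frame(sensor = s, z = zs, x = cs$x[k], y = cs$y[k]))
      }
      if (ok) { n <- n + 1; rows[[n]] <- pts }
    }
  }
  rows
}

#' Software alignment from a no-target run
#'
#' Iterative procedure: chain tracks through the sensors with the current
#' alignment, take the line defined by the first and last sensor (the gauge
#' axis), subtract the mean residual per middle sensor (and, optionally, the
#' residual-vs-position slope as an in-plane rotation), and repeat until the
#' largest offset update falls below 0.1 um or 50 iterations.
#'
#' @param clusters cluster data.frame from a no-target run (>= 500 tracks).
#' @param geometry the `pf_geometry` giving sensor z positions.
#' @param sensors sensor ids to align (default: all present).
#' @param rotations estimate in-plane rotations as well (default FALSE).
#' @param max_iter,tol iteration control (tol in mm).
#' @param min_tracks required chained-track count.
#' @return data.frame `sensor`, `dx`, `dy`, `rot` with an attribute
#'   `history` of per-iteration maximum updates; the first and last sensors
#'   are fixed at zero.
#' @export
align_sensors <- function(clusters, geometry, sensors = sort(unique(clusters$sensor)),
                          rotations = FALSE, max_iter = 50L, tol = 1e-4,
                          min_tracks = 500L) {
  sensor_z <- geometry$sensor_z
  names(sensor_z) <- sub("^S", "", names(sensor_z))
  align <- data.frame(sensor = sensors, dx = 0, dy = 0, rot = 0)
  history <- numeric(0)
  mids <- setdiff(sensors, c(sensors[1], sensors[length(sensors)]))
  for (it in seq_len(max_iter)) {
    cc <- apply_alignment(clusters, align)
    trks <- .chain_tracks(cc, sensors, sensor_z)
    if (it == 1 && length(trks) < min_tracks)
      stop("alignment needs >= ", min_tracks, " tracks; got ", length(trks))
    upd_max <- 0
    for (s in mids) {
      rx <- ry <- xs <- ys <- numeric(0)
      for (tk in trks) {
        i1 <- 1; iL <- 2  # rows 1, 2 are first/last
        im <- which(tk$sensor == s)
        if (!length(im)) next
        fz <- (tk$z[im] - tk$z[i1]) / (tk$z[iL] - tk$z[i1])
        rx <- c(rx, tk$x[im] - (tk$x[i1] + (tk$x[iL] - tk$x[i1]) * fz))
        ry <- c(ry, tk$y[im] - (tk$y[i1] + (tk$y[iL] - tk$y[i1]) * fz))
        xs <- c(xs, tk$x[im]); ys <- c(ys, tk$y[im])
      }
      if (!length(rx)) next
      k <- align$sensor == s
      ux <- mean(rx); uy <- mean(ry)
      align$dx[k] <- align$dx[k] + ux
      align$dy[k] <- align$dy[k] + uy
      upd_max <- max(upd_max, abs(ux), abs(uy))
      if (rotations) {
        uth <- (sum(xs * ry) - sum(ys * rx)) / sum(xs^2 + ys^2)
        align$rot[k] <- align$rot[k] + uth
        upd_max <- max(upd_max, abs(uth))
      }
    }
    history <- c(history, upd_max)
    if (upd_max < tol) break
  }
  if (history[length(history)] >= tol)
    warning("alignment did not converge; residual history attached")
  attr(align, "history") <- history
  align
}

#' Reconstruct straight tracks from three tracker planes
#'
#' Candidate cluster triplets are formed inside a transverse search window
#' (an MCS-motivated residual gate at the middle plane), fitted with a
#' least-squares straight line, and accepted greedily in increasing chi2 so
#' that no cluster is used twice.
#'
#' @param clusters cluster data.frame (aligned, see [apply_alignment()]).
#' @param geometry `pf_geometry` with the sensor z positions.
#' @param sensors the three plane ids (default 5, 6, 7).
#' @param gate middle-plane residual gate in mm.
#' @param z_ref z at which intercepts are reported (default: the marker
#'   centre so back-projection uses marker-frame coordinates directly).
#' @return data.frame `frame`, `x0`, `y0`, `tx`, `ty`, `chi2`, `resid_mid`
#'   with attribute `unmatched` (clusters left unused).
#' @export
reconstruct_tracks <- function(clusters, geometry, sensors = c(5, 6, 7),
                               gate = 0.2, z_ref = NULL) {
  if (is.null(z_ref)) z_ref <- geometry$marker_z
  zz <- geometry$sensor_z[paste0("S", sensors)]
  get <- function(s) {
    cs <- clusters[clusters$sensor == s, , drop = FALSE]
    cs[order(cs$frame), , drop = FALSE]
  }
  c1 <- get(sensors[1]); c2 <- get(sensors[2]); c3 <- get(sensors[3])
  r <- match_triplets_cpp(as.integer(c1$frame), c1$x, c1$y,
                          as.integer(c2$frame), c2$x, c2$y,
                          as.integer(c3$frame), c3$x, c3$y,
                          zz[1], zz[2], zz[3], gate, z_ref)
  trk <- as.data.frame(r$tracks)
  attr(trk, "unmatched") <- r$unmatched
  trk
}
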