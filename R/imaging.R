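# Marker imaging metrics on synthetic phantom images: square-ring streak
# profiles with the 3%-of-background extent, and the radiograph contrast.

#' Synthetic CT slice with marker streak artifacts
#'
#' Uniform gelatin-like background plus, per marker, saturated pixels and an
#' alternating-sign radial streak pattern decaying as
#' `amplitude * exp(-r/lambda) * cos(k_fold * theta)`, plus Gaussian noise;
#' values are clipped to the CT range [-1024, 3060]. This is a stand-in
#' image generator: it emulates the appearance of metal streak artifacts,
#' not their reconstruction physics.
#'
#' @param markers data.frame with columns `x`, `y` (mm from image centre),
#'   `amplitude` (HU), `lambda` (decay length, mm), and optional `k_fold`
#'   (angular periodicity, default 8) and `saturation` (default 3060).
#' @param n_pix image side in pixels.
#' @param spacing pixel spacing in mm (treatment-planning CT default 0.977).
#' @param background background level in HU.
#' @param noise_sd Gaussian pixel noise sigma in HU.
#' @param seed RNG seed.
#' @return object of class `pf_image`: `pixels` (matrix, HU), `spacing`,
#'   `modality`.
#' @export
synth_ct_slice <- function(markers, n_pix = 121L, spacing = 0.977,
                           background = 30, noise_sd = 8, seed = 1) {
  set.seed(seed)
  half <- n_pix * spacing / 2
  if (nrow(markers) &&
      any(abs(markers$x) > half | abs(markers$y) > half))
    stop("marker outside the image field")
  cc <- (seq_len(n_pix) - (n_pix + 1) / 2) * spacing
  img <- matrix(background, n_pix, n_pix)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(n_pix^2, 0, noise_sd),
                                        n_pix, n_pix)
  for (i in seq_len(nrow(markers))) {
    dx <- outer(cc - markers$x[i], rep(1, n_pix))
    dy <- outer(rep(1, n_pix), cc - markers$y[i])
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    kf <- if (!is.null(markers$k_fold)) markers$k_fold[i] else 8
    img <- img + markers$amplitude[i] * exp(-r / markers$lambda[i]) * cos(kf * th)
    sat <- if (!is.null(markers$saturation)) markers$saturation[i] else 3060
    img[r <= spacing / 2] <- sat
  }
  img <- pmin(pmax(img, -1024), 3060)
  structure(list(pixels = img, spacing = spacing, modality = "ct"),
            class = "pf_image")
}

#' Ring membership by Chebyshev distance (pixels)
#' @keywords internal
.ring_index <- function(n_pix, center) {
  ri <- outer(seq_len(n_pix) - center[1], rep(1, n_pix))
  ci <- outer(rep(1, n_pix), seq_len(n_pix) - center[2])
  pmax(abs(ri), abs(ci))
}

#' Square-ring minimum/maximum statistics around a marker
#'
#' Ring 0 is the ~2 mm square at the marker (Chebyshev distance <= 1 pixel
#' from the maximum-HU pixel); each further ring is a one-pixel-thick square
#' annulus whose inner length equals the previous ring's outer length.
#' Per ring, the minimum and maximum pixel values and the inner half-length
#' in mm are reported.
#'
#' @param image a `pf_image`.
#' @param center pixel (row, col) of the ring centre; default: the global
#'   maximum (the marker saturates there).
#' @return data.frame `ring`, `distance_mm` (inner half-length), `min`,
#'   `max`, `truncated` (ring exceeds image bounds).
#' @export
ring_minmax <- function(image, center = NULL) {
  img <- image$pixels; n_pix <- nrow(img)
  if (is.null(center)) {
    i <- which.max(img)
    center <- c((i - 1) %% n_pix + 1, (i - 1) %/% n_pix + 1)
  }
  d <- .ring_index(n_pix, center)
  dmax <- max(d)
  # ring 0: d <= 1 (the ~2 mm square); ring r >= 1: the annulus d == r + 1
  rings <- lapply(0:(dmax - 1), function(r) {
    v <- if (r == 0) img[d <= 1] else img[d == r + 1]
    full <- if (r == 0) 9 else 8 * (r + 1)
    data.frame(ring = r,
               distance_mm = if (r == 0) 0 else (r + 0.5) * image$spacing,
               min = min(v), max = max(v), truncated = length(v) < full)
  })
  out <- do.call(rbind, rings)
  rownames(out) <- NULL
  out
}

#' Streak-artifact extent (3%-of-background criterion)
#'
#' Smallest ring distance beyond which, for every larger ring, both
#' `|max - background|` and `|background - min|` stay below
#' `threshold_frac` of the background offset scale. Because a CT background
#' near 0 HU would make "3% of background" sub-noise, the scale is anchored
#' at the water-air span: `background + 1000`.
#'
#' @param rings data.frame from [ring_minmax()].
#' @param background background HU (median of an artifact-free region).
#' @param threshold_frac criterion fraction (default 0.03).
#' @return extent in mm; if the criterion is never satisfied, the largest
#'   ring distance with attribute `censored = TRUE`.
#' @export
artifact_extent <- function(rings, background, threshold_frac = 0.03) {
  thr <- threshold_frac * (background + 1000)
  ok <- (rings$max - background) < thr & (background - rings$min) < thr
  # smallest distance from which all outer rings are quiet
  quiet_from <- rev(cumprod(rev(ok))) > 0
  if (!any(quiet_from)) {
    out <- max(rings$distance_mm)
    attr(out, "censored") <- TRUE
    return(out)
  }
  rings$distance_mm[which(quiet_from)[1]]
}

#' Radiograph contrast of a vertical marker
#'
#' The marker window (6 mm wide, 3 mm high by default, in mm units of the
#' image) is integrated perpendicular to the vertical marker, i.e. averaged
#' over rows to give a profile along x; the contrast is
#' `C = |I_max - I_b|` with `I_b` and the pixel noise sigma taken from an
#' equally sized, marker-free background window, and uncertainty
#' `sigma * sqrt(2/N)`.
#'
#' @param image a `pf_image`.
#' @param marker_window list `x` (centre, mm), `y` (centre, mm),
#'   `w` (width, mm), `h` (height, mm).
#' @param background_window same shape, marker-free, equal size.
#' @return object of class `pf_contrast`: `C`, `uncertainty`, `I_max`,
#'   `I_b`, `sigma`, `N`.
#' @export
contrast <- function(image, marker_window, background_window) {
  if (!isTRUE(all.equal(c(marker_window$w, marker_window$h),
                        c(background_window$w, background_window$h))))
    stop("windows must have equal size")
  sel <- function(win) {
    n_pix <- nrow(image$pixels)
    cc <- (seq_len(n_pix) - (n_pix + 1) / 2) * image$spacing
    rows <- which(abs(cc - win$y) <= win$h / 2)
    cols <- which(abs(cc - win$x) <= win$w / 2)
    list(rows = rows, cols = cols)
  }
  mw <- sel(marker_window); bw <- sel(background_window)
  if (length(intersect(mw$rows, bw$rows)) && length(intersect(mw$cols, bw$cols)))
    stop("marker and background windows overlap")
  sub_m <- image$pixels[mw$rows, mw$cols, drop = FALSE]
  sub_b <- image$pixels[bw$rows, bw$cols, drop = FALSE]
  profile <- colMeans(sub_m)   # integrate perpendicular to the marker
  I_max <- max(profile)
  I_b <- mean(sub_b)
  sigma <- stats::sd(as.numeric(sub_b))
  N <- length(sub_b)
  structure(list(C = abs(I_max - I_b),
                 uncertainty = sigma * sqrt(2 / N),
                 I_max = I_max, I_b = I_b, sigma = sigma, N = N,
                 profile = data.frame(
                   x = ((seq_len(ncol(sub_m))) - (ncol(sub_m) + 1) / 2) *
                     image$spacing + marker_window$x,
                   I = profile)),
            class = "pf_contrast")
}

#' @export
print.pf_contrast <- function(x, ...) {
  cat(sprintf("contrast C = %.1f +/- %.2f (I_max %.1f, I_b %.1f, sigma %.1f)\n",
              x$C, x$uncertainty, x$I_max, x$I_b, x$sigma))
  invisible(x)
}
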