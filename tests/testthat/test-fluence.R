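# Back-projection, map integration, reference fitting, perturbation statistic.

test_that("parallel tracks fill one voxel column across all z slices", {
  gs <- fluence_grid_spec(x_half = 1, y_half = 1, z_range = c(0, 4),
                          dx = 0.1, dy = 0.1, dz = 0.5)
  tk <- data.frame(x0 = rep(0.05, 7), y0 = rep(-0.35, 7), tx = 0, ty = 0)
  g <- backproject(tk, gs)
  ix <- floor((0.05 - gs$x0) / gs$dx) + 1
  iy <- floor((-0.35 - gs$y0) / gs$dy) + 1
  expect_true(all(g$counts[ix, iy, ] == 7))
  expect_equal(sum(g$counts), 7 * gs$nz)
  # empty track list: all-zero grid
  g0 <- backproject(data.frame(x0 = numeric(0), y0 = numeric(0),
                               tx = numeric(0), ty = numeric(0)), gs)
  expect_true(all(g0$counts == 0))
})

test_that("oblique-track traversal matches a fine-step ray-marching oracle", {
  gs <- fluence_grid_spec(x_half = 2, y_half = 2, z_range = c(-1, 3),
                          dx = 0.13, dy = 0.11, dz = 0.37)
  set.seed(21)
  for (k in 1:12) {
    tk <- data.frame(x0 = runif(1, -1, 1), y0 = runif(1, -1, 1),
                     tx = runif(1, -0.3, 0.3), ty = runif(1, -0.3, 0.3))
    g <- backproject(tk, gs)
    # oracle: 1 um marching along z, unique voxel set
    zm <- seq(gs$z0 + 5e-7, gs$z0 + gs$nz * gs$dz - 5e-7, by = 1e-3)
    ix <- floor((tk$x0 + tk$tx * zm - gs$x0) / gs$dx)
    iy <- floor((tk$y0 + tk$ty * zm - gs$y0) / gs$dy)
    iz <- floor((zm - gs$z0) / gs$dz)
    ok <- ix >= 0 & ix < gs$nx & iy >= 0 & iy < gs$ny
    vox <- unique(paste(ix[ok], iy[ok], iz[ok]))
    hit <- which(g$counts > 0, arr.ind = TRUE)
    got <- paste(hit[, 1] - 1, hit[, 2] - 1, hit[, 3] - 1)
    expect_setequal(got, vox)
    expect_true(all(g$counts[hit] == 1))
  }
})

test_that("back-projection conserves per-slice track crossings", {
  gs <- fluence_grid_spec(x_half = 6, y_half = 6, z_range = c(0, 5),
                          dx = 0.05, dy = 0.05, dz = 0.5)
  set.seed(3)
  n <- 200
  tk <- data.frame(x0 = runif(n, -3, 3), y0 = runif(n, -3, 3),
                   tx = rnorm(n, 0, 0.02), ty = rnorm(n, 0, 0.02))
  g <- backproject(tk, gs)
  for (iz in c(1, 5, 10)) {
    zc <- gs$z0 + (iz - 0.5) * gs$dz
    inside <- sum(abs(tk$x0 + tk$tx * zc) < 6 - 0.06 &
                    abs(tk$y0 + tk$ty * zc) < 6 - 0.06)
    # each track inside the slice crosses >= 1 voxel of it
    expect_gte(sum(g$counts[, , iz] > 0), inside * 0.95)
  }
})

test_that("map integration is exact partial summation", {
  gs <- fluence_grid_spec(x_half = 1, y_half = 1, z_range = c(0, 2),
                          dx = 0.2, dy = 0.2, dz = 0.5)
  set.seed(5)
  g <- backproject(data.frame(x0 = runif(50, -1, 1), y0 = runif(50, -1, 1),
                              tx = rnorm(50, 0, 0.1), ty = rnorm(50, 0, 0.1)),
                   gs)
  full <- integrate_map(g)
  expect_equal(full$counts, apply(g$counts, c(1, 3), sum))
  lo <- integrate_map(g, c(-1, 0))
  hi <- integrate_map(g, c(0, 1))
  expect_equal(lo$counts + hi$counts, full$counts)
  expect_error(integrate_map(g, c(-5, 0)), "outside")
  expect_error(integrate_map(g, c(0.99999, 1.00001) + 5), "outside")
})

test_that("reference fit recovers clean and dip-masked baselines", {
  x <- seq(-6, 6, by = 0.05)
  gauss <- 800 * exp(-x^2 / (2 * 1.8^2))
  f <- fit_reference(data.frame(x = x, n = gauss))
  expect_true(f$converged)
  expect_lt(max(abs(f$baseline - gauss)) / 800, 0.005)
  # 20% dip, masked explicitly: baseline within 1% of the clean Gaussian
  dip <- gauss * ifelse(abs(x - 0.5) < 0.4, 0.8, 1)
  f2 <- fit_reference(data.frame(x = x, n = dip), mask_region = c(-0.2, 1.2))
  expect_lt(max(abs(f2$baseline - gauss) / pmax(gauss, 80)), 0.01)
  # automatic dip masking finds and excludes the dip
  set.seed(8)
  noisy <- rpois(length(x), dip)
  f3 <- fit_reference(data.frame(x = x, n = noisy))
  expect_true(any(f3$mask[abs(x - 0.5) < 0.3]))
  expect_lt(abs(f3$baseline[which.min(abs(x - 0.5))] -
                  gauss[which.min(abs(x - 0.5))]) /
              gauss[which.min(abs(x - 0.5))], 0.10)
})

test_that("a skewed two-Gaussian blend is fitted with reduced chi2 <= 2", {
  x <- seq(-6, 6, by = 0.05)
  blend <- 600 * exp(-(x + 0.8)^2 / (2 * 1.4^2)) +
    350 * exp(-(x - 1.6)^2 / (2 * 2.4^2))
  set.seed(9)
  noisy <- rpois(length(x), blend)
  f <- fit_reference(data.frame(x = x, n = noisy))
  expect_lte(f$chi2red, 2)
})

test_that("perturbation statistic behaves on constructed maps", {
  x <- seq(-4, 4, by = 0.02)
  z <- seq(0.1, 5, by = 0.2)
  ref <- outer(2000 * exp(-x^2 / (2 * 2^2)), rep(1, length(z)))
  mk_map <- function(cnt) structure(list(counts = cnt, x = x, z = z),
                                    class = "pf_fluence_map")
  # identical maps: zero perturbation
  p0 <- max_perturbation(mk_map(ref), mk_map(ref), rebin = 1, z_smooth = 1)
  expect_equal(p0$max_perturbation, 0)
  # 20% deficit in a 0.2 mm band at one z
  with <- ref
  band <- abs(x - 0.5) <= 0.1
  with[band, 10] <- ref[band, 10] * 0.8
  p <- max_perturbation(mk_map(with), mk_map(ref), rebin = 1, z_smooth = 1)
  expect_equal(p$max_perturbation, 20, tolerance = 1e-9)
  expect_equal(p$z_position, z[10])
  expect_lt(abs(p$x_position - 0.5), 0.15)
  expect_equal(p$z_uncertainty, 1.5)
  # invariance under common rescaling
  p2 <- max_perturbation(mk_map(with * 4), mk_map(ref * 4), rebin = 1, z_smooth = 1)
  expect_equal(p2$max_perturbation, p$max_perturbation, tolerance = 1e-12)
  # deficits only: an excess region is not reported
  hot <- ref; hot[band, 3] <- ref[band, 3] * 1.5
  ph <- max_perturbation(mk_map(hot), mk_map(ref), rebin = 1, z_smooth = 1)
  expect_equal(ph$max_perturbation, 0)
})

test_that("fitted-baseline mode recovers an injected dip without a reference map", {
  # skewed profile (two-Gaussian blend) so the single-Gaussian nested case
  # does not trivially fit; 20% dip in a narrow band at a few z slices
  x <- seq(-5, 5, by = 0.1)
  z <- seq(0.25, 2.5, by = 0.25)
  shape <- 900 * exp(-(x + 0.5)^2 / (2 * 1.6^2)) +
    400 * exp(-(x - 1.8)^2 / (2 * 2.2^2))
  lam <- outer(shape, rep(1, length(z)))
  dipband <- abs(x - 0.3) <= 0.25
  lam[dipband, 5:7] <- lam[dipband, 5:7] * 0.8
  set.seed(12)
  cnt <- matrix(rpois(length(lam), lam), nrow(lam))
  mp <- structure(list(counts = cnt, x = x, z = z), class = "pf_fluence_map")
  p <- max_perturbation(mp, reference = NULL, rebin = 1, z_smooth = 1)
  expect_gt(p$max_perturbation, 12)
  expect_lt(p$max_perturbation, 30)
  expect_true(p$z_position %in% z[5:7])
  expect_lt(abs(p$x_position - 0.3), 0.5)
})

test_that("marker-free maps give perturbations consistent with counting noise", {
  x <- seq(-4, 4, by = 0.1)
  z <- seq(0.1, 3, by = 0.2)
  lam <- outer(400 * exp(-x^2 / (2 * 2^2)), rep(1, length(z)))
  mk_map <- function(cnt) structure(list(counts = cnt, x = x, z = z),
                                    class = "pf_fluence_map")
  nbin <- sum(lam >= 0.2 * max(lam))
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(rpois(length(lam), lam), nrow(lam))
    b <- matrix(rpois(length(lam), lam), nrow(lam))
    p <- max_perturbation(mk_map(a), mk_map(b), rebin = 1, z_smooth = 1)
    # extreme-value bound on the maximum relative Poisson fluctuation
    bound <- 100 * sqrt(2 / (0.2 * max(lam))) * qnorm(1 - 0.005 / nbin)
    expect_lt(p$max_perturbation, bound)
  }
})

test_that("sensor profiles and their comparator find an injected deficit", {
  set.seed(2)
  hits <- data.frame(sensor = 5, x = rnorm(40000, 0, 3),
                     y = runif(40000, -3, 3), energy = 80, pid = 1:40000)
  keep <- !(abs(hits$x - 0.4) < 0.2 & runif(40000) < 0.3)
  pw <- sensor_profile(hits[keep, ], 5, y_window = c(-2, 2), binwidth = 0.2)
  pr <- sensor_profile(hits, 5, y_window = c(-2, 2), binwidth = 0.2)
  p <- profile_perturbation(pw, pr)
  expect_gt(p$max_perturbation, 20)
  expect_lt(abs(p$x_position - 0.4), 0.3)
})
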