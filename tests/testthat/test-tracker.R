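# Digitization, cluster finding, alignment and track reconstruction.

pitch <- 0.0207

# straight synthetic tracks through the S5-S7 tracker planes, optionally
# digitized; used by several blocks below
make_tracker_hits <- function(n_tracks, seed, per_frame = 5L,
                              slope_sd = 3e-3) {
  set.seed(seed)
  geo <- build_experiment_geometry("experiment")
  zz <- geo$sensor_z[c("S5", "S6", "S7")]
  tk <- data.frame(x0 = rnorm(n_tracks, 0, 4), y0 = rnorm(n_tracks, 0, 4),
                   tx = rnorm(n_tracks, 0, slope_sd),
                   ty = rnorm(n_tracks, 0, slope_sd),
                   pid = seq_len(n_tracks))
  hits <- do.call(rbind, lapply(1:3, function(s) {
    z <- zz[s] - geo$marker_z  # track parameters relative to the marker
    data.frame(sensor = s + 4, x = tk$x0 + tk$tx * (zz[s] - geo$marker_z),
               y = tk$y0 + tk$ty * (zz[s] - geo$marker_z),
               energy = 80, pid = tk$pid)
  }))
  list(tracks = tk, hits = hits, geo = geo, zz = zz)
}

test_that("digitization with a point-like cloud fires exactly the containing pixel", {
  hits <- data.frame(sensor = 5, x = 3 * pitch + pitch / 2,
                     y = -10 * pitch + pitch / 2, energy = 80, pid = 1)
  d <- digitize(hits, sigma = 0, noise_rate = 0, seed = 1)
  expect_equal(nrow(d$pixels), 1)
  expect_equal(d$pixels$col, 960 / 2 + 3)
  expect_equal(d$pixels$row, 928 / 2 - 10)
  # out-of-area hits are dropped and counted
  far <- data.frame(sensor = 5, x = 50, y = 0, energy = 80, pid = 1)
  d2 <- digitize(far, sigma = 0, noise_rate = 0, seed = 1)
  expect_equal(nrow(d2$pixels), 0)
  expect_equal(unname(d2$dropped["5"]), 1L)
  expect_error(digitize(hits, noise_rate = 0.5), "noise_rate")
})

test_that("well-separated hits give exactly k clusters and sub-pixel COM accuracy", {
  set.seed(4)
  k <- 40
  hits <- data.frame(sensor = 5, x = seq(-8, 8, length.out = k),
                     y = rep(c(-4, 4), length.out = k), energy = 80,
                     pid = seq_len(k))
  d <- digitize(hits, sigma = 0.010, noise_rate = 0, seed = 1)
  cl <- find_clusters(d$pixels)
  expect_equal(nrow(cl), k)
  expect_true(all(cl$size >= 1))
  # quantization bound: sigma -> 0 gives COM error RMS <= pitch/sqrt(12)
  set.seed(5)
  hq <- data.frame(sensor = 5, x = runif(500, -5, 5), y = runif(500, -5, 5),
                   energy = 80, pid = 1:500)
  dq <- digitize(hq, sigma = 0, noise_rate = 0, seed = 1)
  clq <- find_clusters(dq$pixels)
  clq <- clq[order(clq$frame), ]
  # one cluster per frame batch is not guaranteed; match clusters to the
  # nearest true hit instead
  err <- vapply(seq_len(nrow(clq)), function(i) {
    min(sqrt((hq$x - clq$x[i])^2 + (hq$y - clq$y[i])^2))
  }, numeric(1))
  expect_lte(sqrt(mean(err^2)), 1.05 * sqrt(2) * pitch / sqrt(12))
})

test_that("clustering follows 8-connectivity and matches a flood-fill oracle", {
  # two diagonally adjacent pixels form one cluster
  px <- data.frame(sensor = 5, frame = 0L, row = c(10L, 11L), col = c(10L, 11L))
  expect_equal(nrow(find_clusters(px)), 1)
  # plus-shaped group: one cluster with COM at the central pixel
  plus <- data.frame(sensor = 5, frame = 0L,
                     row = c(20L, 19L, 21L, 20L, 20L),
                     col = c(30L, 30L, 30L, 29L, 31L))
  cp <- find_clusters(plus)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$size, 5)
  expect_equal(cp$x, (30 + 0.5) * pitch - 960 * pitch / 2, tolerance = 1e-12)
  expect_equal(cp$y, (20 + 0.5) * pitch - 928 * pitch / 2, tolerance = 1e-12)

  # random frame vs a brute-force flood-fill oracle
  set.seed(11)
  rc <- unique(data.frame(row = sample(0:60, 500, TRUE),
                          col = sample(0:60, 500, TRUE)))
  px <- data.frame(sensor = 5, frame = 0L, row = rc$row, col = rc$col)
  cl <- find_clusters(px)
  flood <- function(rc) {  # oracle: BFS with 8-neighbourhood
    key <- paste(rc$row, rc$col)
    seen <- setNames(rep(FALSE, nrow(rc)), key)
    comp <- integer(nrow(rc)); cid <- 0
    for (i in seq_len(nrow(rc))) {
      if (seen[key[i]]) next
      cid <- cid + 1; queue <- i; seen[key[i]] <- TRUE
      while (length(queue)) {
        j <- queue[1]; queue <- queue[-1]; comp[j] <- cid
        for (dr in -1:1) for (dc in -1:1) {
          kk <- paste(rc$row[j] + dr, rc$col[j] + dc)
          m <- match(kk, key)
          if (!is.na(m) && !seen[kk]) { seen[kk] <- TRUE; queue <- c(queue, m) }
        }
      }
    }
    comp
  }
  comp <- flood(rc)
  expect_equal(nrow(cl), max(comp))
  # component size multisets agree
  expect_equal(sort(cl$size), sort(as.integer(table(comp))))
  # permutation invariance: shuffled pixel order gives the same clusters
  # (COMs rounded: summation order shifts the last ulp)
  perm <- sample(nrow(px))
  cl2 <- find_clusters(px[perm, ])
  key <- function(d) {
    d$x <- round(d$x, 9); d$y <- round(d$y, 9)
    d <- d[order(d$x, d$y), c("x", "y", "size")]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(cl), key(cl2))
})

test_that("alignment recovers injected offsets and rotations", {
  mk <- make_tracker_hits(900, seed = 9)
  cl <- data.frame(sensor = mk$hits$sensor,
                   frame = as.integer((mk$hits$pid - 1) %/% 5),
                   x = mk$hits$x, y = mk$hits$y, size = 3L)
  # inject +50 um in x and -30 um in y on the middle sensor
  mis <- cl
  k <- mis$sensor == 6
  mis$x[k] <- mis$x[k] + 0.050
  mis$y[k] <- mis$y[k] - 0.030
  al <- align_sensors(mis, mk$geo, sensors = 5:7, min_tracks = 500)
  expect_lt(abs(al$dx[al$sensor == 6] - 0.050), 1e-3)
  expect_lt(abs(al$dy[al$sensor == 6] + 0.030), 1e-3)
  expect_equal(al$dx[al$sensor %in% c(5, 7)], c(0, 0))
  # already aligned input: all updates below 0.1 um
  al0 <- align_sensors(cl, mk$geo, sensors = 5:7, min_tracks = 500)
  expect_lt(max(abs(c(al0$dx, al0$dy))), 1e-4)
  # pure rotation: recovered within 0.05 mrad with negligible offsets
  rot <- cl
  th <- 5e-4
  rot$x[k] <- cl$x[k] - th * cl$y[k]
  rot$y[k] <- cl$y[k] + th * cl$x[k]
  alr <- align_sensors(rot, mk$geo, sensors = 5:7, rotations = TRUE,
                       min_tracks = 500)
  expect_lt(abs(alr$rot[alr$sensor == 6] - th), 5e-5)
  expect_lt(abs(alr$dx[alr$sensor == 6]), 5e-3)
  # corrected clusters reproduce the true ones
  fixed <- apply_alignment(rot, alr)
  expect_lt(max(abs(fixed$x[k] - cl$x[k])), 5e-3)
})

test_that("noiseless collinear triplets are reconstructed exactly", {
  mk <- make_tracker_hits(50, seed = 3)
  cl <- data.frame(sensor = mk$hits$sensor,
                   frame = as.integer((mk$hits$pid - 1) %/% 5),
                   x = mk$hits$x, y = mk$hits$y, size = 1L)
  tk <- reconstruct_tracks(cl, mk$geo)
  expect_equal(nrow(tk), 50)
  expect_equal(attr(tk, "unmatched"), 0)
  o <- order(tk$x0); ot <- order(mk$tracks$x0)
  expect_equal(tk$x0[o], mk$tracks$x0[ot], tolerance = 1e-9)
  expect_equal(tk$tx[o], mk$tracks$tx[ot], tolerance = 1e-9)
  expect_lt(max(tk$chi2), 1e-18)
})

test_that("two crossing tracks are both recovered without sharing clusters", {
  geo <- build_experiment_geometry("experiment")
  zz <- geo$sensor_z[c("S5", "S6", "S7")] - geo$marker_z
  # two tracks crossing exactly at the middle plane
  t1 <- list(x0 = -1, tx = (1 - -1) / (zz[2] - zz[1]) * 0.5)
  cl <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(sensor = s + 4, frame = 0L,
               x = c(-1 + 0.02 * (zz[s] - zz[1]), 1 - 0.02 * (zz[s] - zz[1])),
               y = c(0, 0.1), size = 1L)
  }))
  tk <- reconstruct_tracks(cl, geo, gate = 0.5)
  expect_equal(nrow(tk), 2)
  expect_equal(attr(tk, "unmatched"), 0)
  expect_equal(sort(sign(tk$tx)), c(-1, 1))
})

test_that("digitized track residual RMS at the middle plane is below 10 um", {
  mk <- make_tracker_hits(1000, seed = 13)
  d <- digitize(mk$hits, batch_size = 5L, sigma = 0.010, noise_rate = 0,
                seed = 2)
  cl <- find_clusters(d$pixels)
  tk <- reconstruct_tracks(cl, mk$geo)
  expect_gt(nrow(tk), 900)
  expect_lt(sqrt(mean(tk$resid_mid^2)), 0.010)
})
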