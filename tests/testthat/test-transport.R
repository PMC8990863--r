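# Monte Carlo transport engine: beam sampling, stepping physics, scoring.

test_that("beam sampling is reproducible and has the stated moments", {
  b <- beam_spec(169.02, fwhm = 3.5, divergence = 7.5)
  s1 <- sample_beam(b, 1e5, 123)
  s2 <- sample_beam(b, 1e5, 123)
  expect_identical(s1, s2)
  # sigma = FWHM/2.3548 = 1.486 mm; sample sd within 3 sigma of its
  # sampling distribution (sd/sqrt(2n))
  expect_lt(abs(sd(s1$x) - 3.5 / 2.3548), 3 * 1.486 / sqrt(2e5))
  expect_lt(abs(sd(s1$ty) - 7.5e-3), 3 * 7.5e-3 / sqrt(2e5))
  b0 <- beam_spec(169.02, fwhm = 3.5, divergence = 0)
  s0 <- sample_beam(b0, 100, 1)
  expect_true(all(s0$tx == 0) && all(s0$ty == 0))
  expect_error(sample_beam(b, 0, 1), "n must be")
})

test_that("transport through vacuum is exact straight-line propagation", {
  geo <- vacuum_geometry(sensor_z = c(100, 250))
  st <- data.frame(x = c(0, 1, -2), y = c(0, -1, 3),
                   tx = c(0, 0.01, -0.02), ty = c(0.005, 0, 0.015),
                   z = 0, energy = 150, pid = 1:3)
  r <- transport(st, geo, seed = 1)
  for (i in 1:3) for (s in 1:2) {
    z <- c(100, 250)[s]
    h <- r$hits[r$hits$pid == i & r$hits$sensor == s, ]
    expect_equal(h$x, st$x[i] + st$tx[i] * z, tolerance = 1e-9)
    expect_equal(h$y, st$y[i] + st$ty[i] * z, tolerance = 1e-9)
    expect_equal(h$energy, 150, tolerance = 1e-12)
  }
})

test_that("transport is deterministic under a fixed seed", {
  geo <- sobp_phantom_geometry()
  st <- sample_beam(beam_spec(160, 3.5, 7.5), 500, 5)
  r1 <- transport(st, geo, seed = 99)
  r2 <- transport(st, geo, seed = 99)
  expect_identical(r1$stop_z, r2$stop_z)
})

test_that("mean stopping depth matches the CSDA range at the beam energies", {
  geo <- sobp_phantom_geometry()
  st <- data.frame(x = 0, y = 0, tx = 0, ty = 0, z = 0,
                   energy = 142.10, pid = 1:4000)
  r <- transport(st, geo, seed = 17)
  expect_equal(r$n_stopped, 4000)
  expect_lt(abs(mean(r$stop_z) - 143.6) / 143.6, 0.005)
})

test_that("beam width growth in water matches a Fermi-Eyges evaluation within 5%", {
  # parallel pencil into a water phantom; record planes inside the water
  geo <- sobp_phantom_geometry(phantom_length = 120)
  geo$sensor_z <- c(S1 = 40, S2 = 80, S3 = 110)
  st <- data.frame(x = 0, y = 0, tx = 0, ty = 0, z = 0,
                   energy = 169.02, pid = 1:30000)
  r <- transport(st, geo, seed = 31)
  # oracle: numerical Fermi-Eyges moments with the same Highland scattering
  # power (cumulative-thickness log factor)
  w <- get_material("water")
  du <- 0.02  # cm
  u <- seq(du / 2, 12, by = du)
  E <- 169.02; Tcum <- 1e-12; mp <- 938.27208816
  sig2 <- setNames(numeric(3), c("40", "80", "110"))
  for (ui in u) {
    pc <- sqrt(E * (E + 2 * mp)); beta <- pc / (E + mp)
    t_rl <- du / 36.08
    Tcum <- Tcum + t_rl
    f <- 1 + 0.038 * log(Tcum)
    dth2 <- (13.6 / (beta * pc))^2 * t_rl * max(f, 0.1)^2
    for (zp in c(40, 80, 110)) {
      if (ui * 10 < zp) {
        lever <- zp - ui * 10
        sig2[as.character(zp)] <- sig2[as.character(zp)] + dth2 * lever^2
      }
    }
    E <- E - stopping_power(E, w) * du
    if (E < 1) break
  }
  sds <- sapply(1:3, function(s) sd(r$hits$x[r$hits$sensor == s]))
  expect_true(all(diff(sds) > 0))  # monotone growth
  for (s in 1:3) {
    zp <- c(40, 80, 110)[s]
    expect_lt(abs(sds[s] - sqrt(sig2[as.character(zp)])) /
                sqrt(sig2[as.character(zp)]), 0.05,
              label = paste("plane z =", zp))
  }
})

test_that("depth-dose scoring conserves energy and peaks at the range", {
  dd <- score_depth_dose(142.10, 8000, 5)
  # the straggled peak sits ~1.4 mm upstream of the CSDA range
  expect_lt(abs(dd$z[which.max(dd$dose)] - 143.6), 2.0)
  expect_equal(sum(dd$dose), 8000 * 142.10, tolerance = 1e-6)
  expect_true(all(dd$dose >= 0))
  dd2 <- score_depth_dose(142.10, 16000, 6)
  expect_lt(abs(sum(dd2$dose) / sum(dd$dose) - 2), 0.01)
})

test_that("fluence is conserved across sensor planes without a marker", {
  geo <- build_experiment_geometry("experiment")
  st <- sample_beam(standard_beam("169"), 2000, 8)
  r <- transport(st, geo, seed = 8)
  expect_equal(r$n_stopped, 0)
  counts <- table(r$hits$sensor)
  expect_true(all(counts == 2000))
})

test_that("a marker filled with the host medium is indistinguishable from no marker", {
  geo <- build_experiment_geometry("experiment")
  mk <- marker_from_catalog(2)
  st <- sample_beam(standard_beam("169"), 30000, 21)
  r_null <- transport(st, geo, marker = mk, seed = 21, null_marker = TRUE)
  r_none <- transport(st, geo, seed = 21)
  x1 <- r_null$hits$x[r_null$hits$sensor == 5]
  x2 <- r_none$hits$x[r_none$hits$sensor == 5]
  expect_gt(suppressWarnings(ks.test(x1, x2)$p.value), 0.01)
})

test_that("SOBP energy draws follow the weights and are reproducible", {
  e <- c(142, 150, 160, 169)
  expect_error(sample_sobp_energies(e, c(0, 0, 0, 0), 10, 1), "not all zero")
  expect_true(all(sample_sobp_energies(e, c(0, 1, 0, 0), 50, 1) == 150))
  w <- c(0.1, 0.2, 0.3, 0.4)
  d1 <- sample_sobp_energies(e, w, 2e4, 2)
  d2 <- sample_sobp_energies(e, w, 2e4, 2)
  expect_identical(d1, d2)
  fr <- as.numeric(table(factor(d1, levels = e))) / 2e4
  expect_true(all(abs(fr - w) < 3 * sqrt(w * (1 - w) / 2e4)))
})

test_that("thicker and lower-energy conditions give larger sensor-plane dips", {
  # ordering: 0.5 mm gold tube > 0.35 mm gold tube at 169 MeV, and the
  # same marker perturbs more at 142 than at 169 MeV
  geo <- build_experiment_geometry("experiment")
  st <- sample_beam(standard_beam("169"), 5e4, 77)
  ref <- transport(st, geo, marker = marker_from_catalog(2), seed = 77,
                   null_marker = TRUE)
  pr <- sensor_profile(ref$hits, 5, c(-2, 2), 0.2)
  dip <- function(marker_id, states, reference) {
    rw <- transport(states, geo, marker = marker_from_catalog(marker_id),
                    seed = 77)
    profile_perturbation(sensor_profile(rw$hits, 5, c(-2, 2), 0.2),
                         reference)$max_perturbation
  }
  d2 <- dip(2, st, pr)
  d1 <- dip(1, st, pr)
  expect_gt(d2, d1)
  st142 <- sample_beam(standard_beam("142"), 5e4, 78)
  ref142 <- transport(st142, geo, marker = marker_from_catalog(2), seed = 78,
                      null_marker = TRUE)
  pr142 <- sensor_profile(ref142$hits, 5, c(-2, 2), 0.2)
  rw142 <- transport(st142, geo, marker = marker_from_catalog(2), seed = 78)
  d2_142 <- profile_perturbation(sensor_profile(rw142$hits, 5, c(-2, 2), 0.2),
                                 pr142)$max_perturbation
  expect_gt(d2_142, d2)
})
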