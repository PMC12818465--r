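test_that("Noll-indexed Zernike values match closed forms", {
  expect_equal(zernike(1, 0.3, 1.2), 1.0)
  expect_equal(zernike(1, 0.9, -2), 1.0)
  expect_equal(zernike(4, 0, 0), -sqrt(3))
  expect_equal(zernike(4, 1, 0), sqrt(3))
  expect_error(zernike(4, 1.2, 0), "pupil")
})

test_that("Zernike basis is orthonormal over the unit disk", {
  n <- 512
  ax <- (seq_len(n) - 0.5) / (n / 2) - 1
  u <- matrix(ax, n, n); v <- matrix(ax, n, n, byrow = TRUE)
  rho <- sqrt(u^2 + v^2); inside <- rho <= 1
  th <- atan2(v, u)
  Z <- sapply(1:15, function(j) zernike(j, rho[inside], th[inside]))
  G <- crossprod(Z) / sum(inside)   # inner products relative to disk area
  expect_lt(max(abs(G - diag(15))), 1e-3)
})

test_that("wavefront_map synthesizes phase linearly with unit-RMS modes", {
  pupil <- metric_pupil()
  expect_true(all(wavefront_map(numeric(5), pupil) == 0))
  m4 <- wavefront_map(c(0, 0, 0, 1), pupil)
  rms <- sqrt(mean(m4[pupil$mask]^2))
  expect_equal(rms, 2 * pi, tolerance = 0.01)
  a <- runif(6); b <- runif(6)
  expect_equal(wavefront_map(a + b, pupil),
               wavefront_map(a, pupil) + wavefront_map(b, pupil),
               tolerance = 1e-12)
})

test_that("the unaberrated two-photon PSF has unit peak; tilt only shifts it", {
  pupil <- pupil_spec()
  psf0 <- psf_2p(pupil, z_planes = 0)
  n <- dim(psf0$intensity)[1]; ctr <- (n + 1) %/% 2
  expect_equal(psf0$intensity[ctr, ctr, 1], 1.0, tolerance = 1e-9)
  expect_equal(max(psf0$intensity), 1.0, tolerance = 1e-9)

  psft <- psf_2p(pupil, wavefront_map(c(0, 0.5, 0), pupil), z_planes = 0)
  expect_equal(max(psft$intensity), 1.0, tolerance = 1e-3)  # shape preserved
  pk <- which(psft$intensity[, , 1] == max(psft$intensity), arr.ind = TRUE)
  expect_false(all(pk == ctr))                              # but displaced
  xs <- (seq_len(n) - ctr) * psf0$lateral_pitch
  f0 <- half_max_width(xs, psf0$intensity[ctr, , 1])
  ft <- half_max_width(xs, psft$intensity[pk[1], , 1])
  expect_equal(ft, f0, tolerance = 0.01)
})

test_that("lateral FWHM agrees with a Debye-integral oracle", {
  pupil <- pupil_spec()
  psf <- psf_2p(pupil, z_planes = 0)
  n <- dim(psf$intensity)[1]; ctr <- (n + 1) %/% 2
  xs <- (seq_len(n) - ctr) * psf$lateral_pitch
  fwhm_fft <- half_max_width(xs, psf$intensity[ctr, , 1])
  # independent scalar Debye integral: h(r) = int_0^1 J0(k NA r rho) rho drho
  k <- 2 * pi / pupil$wavelength
  amp <- function(r) sapply(r, function(ri)
    stats::integrate(function(rho) besselJ(k * pupil$na * ri * rho, 0) * rho,
                     0, 1, rel.tol = 1e-10)$value)
  rr <- seq(0, 2, by = 0.005)
  i2p <- (amp(rr) / amp(0))^4
  half <- 0.5
  i_cross <- which(i2p < half)[1]
  r_half <- rr[i_cross - 1] + 0.005 * (i2p[i_cross - 1] - half) /
    (i2p[i_cross - 1] - i2p[i_cross])
  expect_equal(fwhm_fft, 2 * r_half, tolerance = 0.03)
})

test_that("two-photon Strehl is bounded by 1 and strictly below for real aberrations", {
  pupil <- metric_pupil()
  set.seed(21)
  for (i in 1:10) {
    cc <- numeric(15)
    cc[4:15] <- rnorm(12, sd = runif(1, 0.02, 0.3))
    s <- tp_strehl(pupil, cc)
    expect_lte(s, 1 + 1e-9)
    if (sqrt(sum(cc[4:15]^2)) > 0.05) expect_lt(s, 1)
  }
})

test_that("plane-integrated two-photon signal decreases with aberration RMS", {
  pupil <- metric_pupil()
  set.seed(3)
  shape <- numeric(15); shape[4:15] <- rnorm(12)
  shape <- shape / sqrt(sum(shape^2))
  vals <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(a) tp_plane_signal(pupil, a * shape))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
})

test_that("pupil and focal plane satisfy Parseval's identity", {
  pupil <- metric_pupil()
  phase <- wavefront_map(c(0, 0, 0, 0.3, 0.2), pupil)
  h <- cmatsim:::focal_amplitude(pupil, phase, 0)
  p_pupil <- sum(pupil$mask)  # |P| = 1 on the disk
  p_focal <- sum(Mod(h)^2) / pupil$n_fft^2
  expect_equal(p_focal, p_pupil, tolerance = 1e-6)
})

test_that("the two-photon PSF is narrower than the one-photon intensity PSF", {
  pupil <- pupil_spec()
  psf <- psf_2p(pupil, z_planes = 0)
  n <- dim(psf$intensity)[1]; ctr <- (n + 1) %/% 2
  xs <- (seq_len(n) - ctr) * psf$lateral_pitch
  f2 <- half_max_width(xs, psf$intensity[ctr, , 1])
  f1 <- half_max_width(xs, sqrt(psf$intensity[ctr, , 1]))
  expect_gt(f2 / f1, 0.6)
  expect_lt(f2 / f1, 0.8)
})

test_that("psf_2p refuses a grid too coarse for the focal spot", {
  expect_error(psf_2p(pupil_spec(pad_factor = 2)), "pad_factor")
})

test_that("truth field vanishes at the centre and is deterministic", {
  f0 <- aberration_field(random_amp = 0)
  expect_equal(truth_coeffs(f0, c(0, 0)), numeric(15))
  f <- aberration_field(seed = 5)
  a <- truth_coeffs(f, c(1500, -2200))
  b <- truth_coeffs(f, c(1500, -2200))
  expect_identical(a, b)
  expect_error(truth_coeffs(f, c(5800, 0)), "outside")
  # deterministic part at a chosen radius follows the stated growth laws
  pos <- c(3000, 0)
  det <- truth_coeffs(aberration_field(random_amp = 0), pos)
  rr <- 3000 / 4000
  expect_equal(det[6], 0.2 * rr^2)      # cos-astigmatism along +x
  expect_equal(det[8], 0.15 * rr)       # x-coma
  expect_equal(det[11], 0.08 * rr^2)    # spherical
  expect_equal(det[5], 0)
  expect_equal(det[7], 0)
})

test_that("residual arithmetic and stroke clipping behave as specified", {
  truth <- c(0, 0, 0, 0.4, -0.2)
  expect_equal(residual(truth, -truth), numeric(5))
  expect_equal(residual(truth, numeric(5)), truth)
  set.seed(9)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(residual(a, dm_state(b)), a + b)

  small <- dm_state(c(0, 0, 0, 2), stroke_limit = 30)   # peak 2*sqrt(3) << 30
  expect_identical(clip_stroke(small), small)
  # defocus surface peak is sqrt(3)*c4: choose c4 for a 60-wavelength peak
  big <- dm_state(c(0, 0, 0, 60 / sqrt(3)), stroke_limit = 30)
  expect_warning(clipped <- clip_stroke(big), "stroke")
  expect_equal(clipped$coeffs[4], big$coeffs[4] / 2, tolerance = 5e-3)

  set.seed(10)
  for (i in 1:100) {
    dm <- dm_state(rnorm(12, sd = 8), stroke_limit = 30)
    clipped <- suppressWarnings(clip_stroke(dm))
    surf <- wavefront_map(clipped$coeffs, metric_pupil()) / (2 * pi)
    expect_lte(max(abs(surf)), 30 * (1 + 1e-6))
  }
})
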