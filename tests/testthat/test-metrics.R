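test_that("Gaussian FWHM fits recover 2*sqrt(2 ln 2)*sigma without bias", {
  g <- gaussian_volume(1, 2)
  m <- fit_fwhm(g$vol, matrix(g$center, 1), window_um = g$window)
  expect_equal(m$per_bead$lateral_fwhm_um, 2 * sqrt(2 * log(2)), tolerance = 0.005)
  expect_equal(m$per_bead$axial_fwhm_um, 2 * 2 * sqrt(2 * log(2)), tolerance = 0.005)

  # sigma sweep at the bead-stack sampling: bias below 1%
  for (s in c(0.5, 1, 2, 5)) {
    g <- gaussian_volume(s, s)
    m <- fit_fwhm(g$vol, matrix(g$center, 1), window_um = g$window)
    expect_equal(m$per_bead$lateral_fwhm_um, 2 * sqrt(2 * log(2)) * s,
                 tolerance = 0.01)
    expect_equal(m$per_bead$axial_fwhm_um, 2 * sqrt(2 * log(2)) * s,
                 tolerance = 0.01)
  }

  # isotropic grid scaling scales the FWHM accordingly
  g1 <- gaussian_volume(1, 1, lp = 0.0542, ap = 0.27)
  g2 <- gaussian_volume(2, 2, lp = 2 * 0.0542, ap = 2 * 0.27)
  m1 <- fit_fwhm(g1$vol, matrix(g1$center, 1), window_um = g1$window)
  m2 <- fit_fwhm(g2$vol, matrix(g2$center, 1), window_um = g2$window)
  expect_equal(m2$per_bead$lateral_fwhm_um / m1$per_bead$lateral_fwhm_um, 2,
               tolerance = 0.01)
})

test_that("fitted bead FWHM matches the PSF's direct half-maximum width", {
  pupil <- pupil_spec()
  fw <- measure_bead_fwhm(pupil, numeric(15), bead_diameter_um = 0.1)
  psf <- psf_2p(pupil, z_planes = 0)
  n <- dim(psf$intensity)[1]; ctr <- (n + 1) %/% 2
  xs <- (seq_len(n) - ctr) * psf$lateral_pitch
  direct <- half_max_width(xs, psf$intensity[ctr, , 1])
  expect_equal(fw$lateral_um, direct, tolerance = 0.03)
})

test_that("beads with failed or sub-pixel fits are flagged and excluded", {
  set.seed(2)
  noise <- array(runif(20 * 20 * 9), c(20, 20, 9))
  vol <- volume(noise, 0.5, 0.5)
  g <- gaussian_volume(1, 1, lp = 0.5, ap = 0.5)
  suppressMessages({
    m <- fit_fwhm(g$vol, matrix(g$center, 1), window_um = 2.4)
    bad <- fit_fwhm(vol, matrix(c(5, 5, 2.5), 1), window_um = 3)
  })
  expect_true(m$per_bead$ok[1])
  expect_equal(m$summary$n[1], 1)
  if (!bad$per_bead$ok[1]) expect_equal(bad$summary$n[1], 0)
})

test_that("line profiles interpolate bilinearly with optional normalization", {
  img <- matrix(5, 12, 12)
  pr <- line_profile(img, c(2, 3), c(10, 9))
  expect_true(all(pr$value == 5))

  img2 <- matrix(seq_len(144), 12, 12)
  row7 <- line_profile(img2, c(1, 7), c(12, 7))
  expect_equal(row7$value[row7$t %% 1 == 0], img2[7, ])

  # diagonal chord across a disk: plateau width equals the diameter
  n <- 101
  ax <- seq_len(n) - (n + 1) / 2
  disk <- outer(ax, ax, function(x, y) (x^2 + y^2 <= 30^2) * 1)
  pr2 <- line_profile(disk, c(15, 15), c(87, 87), normalization = "minmax")
  plateau_px <- sum(pr2$value > 0.5)   # unit steps along the diagonal
  expect_lt(abs(plateau_px - 60), 1.5)

  expect_error(line_profile(img, c(3, 3), c(3, 3)), "degenerate")
  expect_error(line_profile(img, c(0, 3), c(5, 5)), "outside")
})

test_that("dF/F applies neuropil subtraction and a percentile baseline", {
  ts <- trace_set(rep(2, 50), rep(1, 50))
  d <- dff(ts)
  expect_true(all(d == 0))
  expect_equal(attr(d, "F0"), 1.3)

  d2 <- dff(trace_set(c(1, 1, 1, 3)))
  expect_equal(as.numeric(d2), c(0, 0, 0, 2))
  expect_equal(attr(d2, "F0"), 1)   # type-7 percentile at rank 0.25*(n-1)

  # gain invariance
  set.seed(4)
  cell <- runif(100, 2, 4); neu <- runif(100, 0.5, 1)
  d3 <- dff(trace_set(cell, neu))
  d4 <- dff(trace_set(7.3 * cell, 7.3 * neu))
  expect_equal(as.numeric(d3), as.numeric(d4), tolerance = 1e-12)

  # no neuropil: reduces to the plain baseline-normalized change
  d5 <- dff(trace_set(cell), r_neuropil = 0.7)
  f0 <- unname(quantile(cell, 0.25, type = 7))
  expect_equal(as.numeric(d5), (cell - f0) / f0, tolerance = 1e-12)

  expect_error(dff(trace_set(rep(0.5, 20), rep(1, 20))), "baseline")
})

test_that("SNR follows the top-decile / sub-90th-percentile definition", {
  expect_error(snr(rep(0.3, 100)), "zero")
  expect_error(snr(1:5), "10")

  set.seed(7)
  x <- c(rnorm(900, 0, 0.05), rnorm(100, 0.5, 0.05))
  # independent direct-formula implementation
  q90 <- unname(quantile(x, 0.9, type = 7))
  oracle <- mean(x[x >= q90]) / sd(x[x < q90])
  expect_equal(snr(x), oracle)
  expect_equal(snr(3.7 * x), snr(x), tolerance = 1e-12)

  # interval reading: best contiguous 10% window
  k <- 100
  means <- vapply(seq_len(1000 - k + 1), function(i) mean(x[i:(i + k - 1)]),
                  numeric(1))
  expect_equal(snr(x, top = "interval"), max(means) / sd(x[x < q90]))
})

test_that("rank tests match exhaustive enumeration for small samples", {
  # all 20 assignments of {1..6} ranks: separated groups are maximally extreme
  out <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p_value, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$p_value, 0.1)
  expect_true(out$exact)

  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:8, sample(3:6, 1), replace = TRUE)  # ties included
    b <- sample(1:8, sample(3:6, 1), replace = TRUE)
    expect_equal(compare_groups(a, b)$p_value, mw_exact_oracle(a, b),
                 info = sprintf("unpaired case %d", i))
  }
  for (i in 1:10) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.3)
    expect_equal(compare_groups(a, b, paired = TRUE)$p_value,
                 sr_exact_oracle(a, b),
                 info = sprintf("paired case %d", i))
  }
})

test_that("rank tests agree with the reference implementation on tie-free data", {
  set.seed(8)
  a <- rnorm(6); b <- rnorm(5, 0.8)
  expect_equal(compare_groups(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value)
  a2 <- rnorm(30); b2 <- rnorm(28, 0.4)
  expect_equal(compare_groups(a2, b2)$p_value,
               wilcox.test(a2, b2, exact = FALSE, correct = FALSE)$p.value)
  a3 <- rnorm(20); b3 <- a3 + rnorm(20, 0.2)
  expect_equal(compare_groups(a3, b3, paired = TRUE)$p_value,
               wilcox.test(a3, b3, paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value)
})

test_that("rank tests are invariant under monotone transforms and handle ties", {
  a <- c(0.2, 0.5, 1.1, 2.0); b <- c(0.9, 1.4, 3.2)
  p1 <- compare_groups(a, b)$p_value
  p2 <- compare_groups(exp(a), exp(b))$p_value
  expect_equal(p1, p2)

  expect_warning(out <- compare_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
                 "zero")
  expect_equal(out$p_value, 1)
  expect_warning(out2 <- compare_groups(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(out2$p_value, 1)
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal length")
})
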