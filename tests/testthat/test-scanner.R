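# An idealized calibration table (exact negatives of the truth at each
# point) isolates scan-plan geometry from calibration accuracy.
ideal_calib <- function(grid, field, n_terms = 15) {
  tab <- t(vapply(seq_len(nrow(grid$points)),
                  function(i) -truth_coeffs(field, grid$points[i, ]),
                  numeric(n_terms)))
  structure(list(coeffs = tab, grid = grid, n_terms = n_terms),
            class = "calibration_table")
}

test_that("the 4x4 plan tiles an 8 mm FOV into sixteen 2 mm tiles", {
  grid <- build_correction_grid()
  field <- aberration_field()
  calib <- ideal_calib(grid, field)
  plan <- plan_full_fov(fov_spec(), 4, grid, calib)
  expect_equal(nrow(plan$tiles), 16)
  expect_equal(plan$dm_load_events, 16)
  expect_equal(plan$tile_size, 2000)
  expect_equal(length(unique(plan$tiles$stripe)), 4)
  expect_true(all(plan$tiles$x1 - plan$tiles$x0 == 2000))
  expect_true(all(plan$tiles$y1 - plan$tiles$y0 == 2000))
  # stripe order: top stripe first, left-to-right within each stripe
  expect_equal(plan$tiles$cy[1:4], rep(3000, 4))
  expect_equal(plan$tiles$cx[1:4], c(-3000, -1000, 1000, 3000))

  # tile centres equal an independent meshgrid construction
  cx <- rep(seq(-3000, 3000, by = 2000), times = 4)
  cy <- rep(seq(3000, -3000, by = -2000), each = 4)
  expect_equal(plan$tiles$cx, cx)
  expect_equal(plan$tiles$cy, cy)

  # nearest-point assignment equals the linear-scan oracle
  for (k in seq_len(16)) {
    d2 <- rowSums((grid$points - matrix(c(cx[k], cy[k]), nrow(grid$points), 2,
                                        byrow = TRUE))^2)
    expect_equal(plan$tiles$point_index[k], which.min(d2))
  }
})

test_that("tiles partition the FOV square exactly (half-open extents)", {
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, aberration_field())
  for (n in c(1, 3, 4)) {
    plan <- plan_full_fov(fov_spec(), n, grid, calib)
    expect_equal(nrow(plan$tiles), n^2)
    expect_equal(sum((plan$tiles$x1 - plan$tiles$x0) * (plan$tiles$y1 - plan$tiles$y0)),
                 8000^2)
    for (i in seq_len(n^2 - 1)) for (j in (i + 1):n^2) {
      xo <- min(plan$tiles$x1[i], plan$tiles$x1[j]) - max(plan$tiles$x0[i], plan$tiles$x0[j])
      yo <- min(plan$tiles$y1[i], plan$tiles$y1[j]) - max(plan$tiles$y0[i], plan$tiles$y0[j])
      expect_true(xo <= 1e-9 || yo <= 1e-9)  # no interior overlap
    }
  }
})

test_that("a missing calibration entry is reported with its point", {
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, aberration_field())
  calib$coeffs[nearest_point(grid, c(-3000, 3000)), ] <- NA
  expect_error(plan_full_fov(fov_spec(), 4, grid, calib), "missing calibration")
})

test_that("with nothing to correct, cmat and ceao render identically", {
  field0 <- aberration_field(astig_edge = 0, coma_edge = 0, sph_edge = 0,
                             random_amp = 0)
  sim <- optics_simulator(pupil_spec(), field0)
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, field0)
  plan <- plan_full_fov(fov_spec(), 2, grid, calib)
  phantom <- cmatsim:::blob_phantom(seed = 5)
  f_cmat <- scan_frame(sim, phantom, plan, "cmat", pixels_per_tile = 24)
  f_ceao <- scan_frame(sim, phantom, plan, "ceao",
                       center_dm = calib$coeffs[nearest_point(grid, c(0, 0)), ],
                       pixels_per_tile = 24)
  expect_equal(f_cmat$pixels, f_ceao$pixels, tolerance = 1e-12)
})

test_that("a constant sample yields a seamless constant frame", {
  field0 <- aberration_field(astig_edge = 0, coma_edge = 0, sph_edge = 0,
                             random_amp = 0)
  sim <- optics_simulator(pupil_spec(), field0)
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, field0)
  plan <- plan_full_fov(fov_spec(), 4, grid, calib)
  fr <- scan_frame(sim, function(X, Y) matrix(1, nrow(X), ncol(X)), plan, "cmat",
                   pixels_per_tile = 16)
  expect_lt(max(fr$pixels) - min(fr$pixels), 1e-6 * mean(fr$pixels))
  expect_equal(nrow(fr$provenance), 16)
  expect_equal(length(unique(fr$provenance$point_index)) <= 16, TRUE)
  expect_equal(nrow(fr$excluded_log), 16)
  expect_true(all(fr$excluded_log$samples_retained == 0))
})

test_that("a point-like sample renders as the residual two-photon PSF", {
  field0 <- aberration_field(astig_edge = 0, coma_edge = 0, sph_edge = 0,
                             random_amp = 0)
  sim <- optics_simulator(pupil_spec(), field0)
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, field0)
  plan <- plan_full_fov(fov_spec(800, 390), 1, grid, calib)
  pitch <- 800 / 160
  delta <- function(X, Y) (abs(X - pitch / 2) < pitch / 2) * (abs(Y + pitch / 2) < pitch / 2)
  img <- render_tile(sim, delta, plan$tiles[1, ], plan$dm[1, ], pixels_per_tile = 160)
  psf <- psf_2p(sim$pupil, z_planes = 0)
  ker <- cmatsim:::resample_kernel(psf$intensity[, , 1], psf$lateral_pitch, pitch)
  pk_img <- which(img == max(img), arr.ind = TRUE)[1, ]
  m <- (nrow(ker) - 1) / 2
  sel_r <- pk_img[1] + (-m:m); sel_c <- pk_img[2] + (-m:m)
  expect_gt(cor(as.vector(img[sel_r, sel_c]), as.vector(ker)), 0.99)
})

test_that("multipoint correction dominates centre-only correction per tile", {
  pupil <- metric_pupil()
  grid <- build_correction_grid()
  for (seed in 1:20) {
    field <- aberration_field(seed = seed)
    calib <- ideal_calib(grid, field)
    plan <- plan_full_fov(fov_spec(), 4, grid, calib)
    dm_center <- calib$coeffs[nearest_point(grid, c(0, 0)), ]
    for (k in seq_len(16)) {
      truth_k <- truth_coeffs(field, c(plan$tiles$cx[k], plan$tiles$cy[k]))
      s_cmat <- tp_strehl(pupil, residual(truth_k, plan$dm[k, ]))
      s_ceao <- tp_strehl(pupil, residual(truth_k, dm_center))
      expect_gte(s_cmat, s_ceao - 1e-9)
      if (sqrt(sum(c(plan$tiles$cx[k], plan$tiles$cy[k])^2)) >= 2000)
        expect_gt(s_cmat, s_ceao)
    }
  }
})

test_that("frames are bit-identical under identical seeds", {
  field <- aberration_field(seed = 2)
  sim <- optics_simulator(pupil_spec(), field)
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, field)
  plan <- plan_full_fov(fov_spec(), 2, grid, calib)
  phantom <- cmatsim:::blob_phantom(seed = 9)
  f1 <- scan_frame(sim, phantom, plan, "cmat", pixels_per_tile = 16,
                   photon_gain = 5, seed = 42)
  f2 <- scan_frame(sim, phantom, plan, "cmat", pixels_per_tile = 16,
                   photon_gain = 5, seed = 42)
  expect_identical(f1$pixels, f2$pixels)
})

test_that("frame tiles match the same tile rendered alone", {
  field <- aberration_field(seed = 2)
  sim <- optics_simulator(pupil_spec(), field)
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, field)
  plan <- plan_full_fov(fov_spec(), 2, grid, calib)
  phantom <- cmatsim:::blob_phantom(seed = 9)
  fr <- scan_frame(sim, phantom, plan, "cmat", pixels_per_tile = 16)
  k <- 3
  alone <- render_tile(sim, phantom, plan$tiles[k, ], plan$dm[k, ],
                       pixels_per_tile = 16)
  r0 <- (plan$tiles$stripe[k] - 1) * 16
  c0 <- (plan$tiles$col[k] - 1) * 16
  expect_equal(fr$pixels[r0 + 1:16, c0 + 1:16], alone, tolerance = 1e-12)
})

test_that("ROI scans hold a single nearest-point correction", {
  field <- aberration_field(seed = 4)
  sim <- optics_simulator(pupil_spec(), field)
  grid <- build_correction_grid()
  calib <- ideal_calib(grid, field)
  phantom <- cmatsim:::blob_phantom(seed = 3)

  # ROI centred exactly on a correction point selects that point
  i <- 17
  roi <- roi_request(grid$points[i, ], width_um = 100, height_um = 100,
                     pitch_um = 2, frames = 2)
  out <- scan_roi(sim, phantom, roi, grid, calib)
  expect_equal(out$point_index, i)
  expect_equal(out$dm_coeffs, calib$coeffs[i, ])
  expect_equal(length(out$frames), 2)

  # the in-vivo ROI geometry: 1000 x 1000 px at 0.5 um/px = 500 x 500 um
  roi2 <- roi_request(c(1000, 1000), width_um = 500, height_um = 500,
                      pitch_um = 0.5, frames = 1)
  out2 <- scan_roi(sim, phantom, roi2, grid, calib)
  expect_equal(dim(out2$frames[[1]]), c(1000, 1000))

  # two ROIs straddling a Voronoi boundary pick different points
  p1 <- grid$points[1, ]; p2 <- grid$points[2, ]
  mid <- (p1 + p2) / 2
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  ra <- roi_request(mid - 30 * u, width_um = 40, height_um = 40, pitch_um = 2)
  rb <- roi_request(mid + 30 * u, width_um = 40, height_um = 40, pitch_um = 2)
  ia <- scan_roi(sim, phantom, ra, grid, calib)$point_index
  ib <- scan_roi(sim, phantom, rb, grid, calib)$point_index
  expect_equal(ia, 1)
  expect_equal(ib, 2)

  expect_error(scan_roi(sim, phantom,
                        roi_request(c(3900, 0), width_um = 500, height_um = 500),
                        grid, calib),
               "outside the FOV")
})
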