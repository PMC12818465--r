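# Tiled full-FOV and ROI scanning: build the stripe-ordered scan plan,
# assign each tile its nearest correction point, render tiles through the
# field-varying optics with the assigned DM state, and mosaic frames.

#' Bundle the optical model, the truth field, and a calibration phantom
#'
#' @param pupil a [pupil_spec()].
#' @param field an [aberration_field()].
#' @param phantom 2-D calibration scene (default [make_pollen()]).
#' @return object of class `optics_simulator`.
#' @export
optics_simulator <- function(pupil = pupil_spec(), field = aberration_field(),
                             phantom = make_pollen()) {
  stopifnot(inherits(pupil, "pupil_spec"), inherits(field, "aberration_field"))
  structure(list(pupil = pupil, field = field, phantom = phantom),
            class = "optics_simulator")
}

#' Plan a full-FOV tiled scan
#'
#' Divides the FOV square into an `n x n` matrix of half-open tiles and
#' orders them as the instrument scans: stripes top to bottom, tiles left to
#' right within each stripe. Each tile is assigned the calibrated
#' coefficient vector of the correction point nearest its centre; one DM
#' load event occurs per tile, so a frame needs `n^2` loads.
#'
#' @param fov a [fov_spec()].
#' @param n grid order (4 gives the 16 x (2 x 2 mm2) protocol on an 8 mm
#'   FOV).
#' @param grid a [build_correction_grid()] result.
#' @param calib a `calibration_table` covering the assigned points.
#' @return object of class `scan_plan`: `tiles` data.frame (stripe, col,
#'   cx, cy, x0, x1, y0, y1, point_index), `dm` matrix (n^2 x n_terms),
#'   `dm_load_events`, `tile_size`, `fov`.
#' @export
plan_full_fov <- function(fov, n, grid, calib) {
  stopifnot(inherits(fov, "fov_spec"), n >= 1, inherits(grid, "correction_grid"),
            inherits(calib, "calibration_table"))
  D <- fov$diameter
  ts <- D / n
  rows <- list()
  k <- 0
  for (stripe in seq_len(n)) {        # stripe 1 = top (max y)
    for (col in seq_len(n)) {         # left to right
      k <- k + 1
      x0 <- -D / 2 + (col - 1) * ts
      y1 <- D / 2 - (stripe - 1) * ts
      cx <- x0 + ts / 2
      cy <- y1 - ts / 2
      pi_ <- nearest_point(grid, c(cx, cy))
      rows[[k]] <- data.frame(tile = k, stripe = stripe, col = col,
                              cx = cx, cy = cy,
                              x0 = x0, x1 = x0 + ts, y0 = y1 - ts, y1 = y1,
                              point_index = pi_)
    }
  }
  tiles <- do.call(rbind, rows)
  dm <- matrix(NA_real_, n^2, calib$n_terms)
  for (k in seq_len(n^2)) {
    v <- calib$coeffs[tiles$point_index[k], ]
    if (anyNA(v))
      stop(sprintf("missing calibration entry for correction point %d (tile %d)",
                   tiles$point_index[k], k))
    dm[k, ] <- v
  }
  structure(list(tiles = tiles, dm = dm, dm_load_events = as.integer(n^2),
                 tile_size = ts, n = n, fov = fov),
            class = "scan_plan")
}

# Render a 2-D scene through the two-photon PSF of a residual aberration.
# The PSF kernel is resampled onto the scene pitch by bilinear interpolation
# and the convolution is evaluated by FFT. Absolute scale: the kernel is the
# peak-normalized two-photon PSF times the pixel-area ratio, so the rendered
# brightness drops as aberration spreads the focus.
render_scene <- function(scene, pitch_um, pupil, res_coeffs,
                         photon_gain = NA, noise_seed = NULL) {
  psf <- psf_2p(pupil, wavefront_map(res_coeffs, pupil), z_planes = 0)
  ker <- resample_kernel(psf$intensity[, , 1], psf$lateral_pitch, pitch_um)
  img <- fft_conv2(scene, ker)
  img[img < 0] <- 0
  if (is.finite(photon_gain)) {
    seed <- if (is.null(noise_seed)) 0 else noise_seed
    img <- with_seed(seed, matrix(stats::rpois(length(img), img * photon_gain) / photon_gain,
                                  nrow(img)))
  }
  img
}

# Bilinear resampling of a centred kernel from pitch p_in to pitch p_out,
# scaled by (p_out/p_in)^2 so the kernel integral (in physical units) is
# preserved.
resample_kernel <- function(ker, p_in, p_out) {
  n_in <- nrow(ker)
  ctr_in <- (n_in + 1) / 2
  half_um <- (n_in - 1) / 2 * p_in
  n_out <- 2 * floor(half_um / p_out) + 1
  if (n_out < 3) n_out <- 3
  ctr_out <- (n_out + 1) / 2
  pos <- ((seq_len(n_out)) - ctr_out) * p_out / p_in + ctr_in
  i0 <- pmin(pmax(floor(pos), 1), n_in - 1)
  fr <- pos - i0
  out <- matrix(0, n_out, n_out)
  for (a in 0:1) for (b in 0:1) {
    w <- outer(a * fr + (1 - a) * (1 - fr), b * fr + (1 - b) * (1 - fr))
    out <- out + w * ker[cbind(rep(i0 + a, n_out), rep(i0 + b, each = n_out))]
  }
  out * (p_out / p_in)^2
}

# Same-size 2-D convolution via zero-padded FFT.
fft_conv2 <- function(img, ker) {
  ni <- dim(img); nk <- dim(ker)
  n1 <- ni[1] + nk[1] - 1; n2 <- ni[2] + nk[2] - 1
  A <- matrix(0, n1, n2); A[seq_len(ni[1]), seq_len(ni[2])] <- img
  B <- matrix(0, n1, n2); B[seq_len(nk[1]), seq_len(nk[2])] <- ker
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (n1 * n2)
  r0 <- (nk[1] + 1) %/% 2; c0 <- (nk[2] + 1) %/% 2
  full[r0:(r0 + ni[1] - 1), c0:(c0 + ni[2] - 1)]
}

# Render a rectangular view of the full-FOV phantom at the given pixel
# centres (xs increasing, ys decreasing = row 1 on top). The phantom is
# sampled with a margin of half the PSF-kernel width so convolution edge
# effects never reach the returned window (tiles mosaic seamlessly).
render_view <- function(pupil, phantom_fn, xs, ys, pitch, res_coeffs,
                        photon_gain = NA, noise_seed = NULL) {
  psf <- psf_2p(pupil, wavefront_map(res_coeffs, pupil), z_planes = 0)
  ker <- resample_kernel(psf$intensity[, , 1], psf$lateral_pitch, pitch)
  m <- (nrow(ker) - 1) %/% 2
  xs_p <- c(xs[1] - rev(seq_len(m)) * pitch, xs, xs[length(xs)] + seq_len(m) * pitch)
  ys_p <- c(ys[1] + rev(seq_len(m)) * pitch, ys, ys[length(ys)] - seq_len(m) * pitch)
  X <- matrix(xs_p, length(ys_p), length(xs_p), byrow = TRUE)
  Y <- matrix(ys_p, length(ys_p), length(xs_p))
  scene <- phantom_fn(X, Y)
  img <- fft_conv2(scene, ker)
  img <- img[m + seq_along(ys), m + seq_along(xs), drop = FALSE]
  img[img < 0] <- 0
  if (is.finite(photon_gain)) {
    seed <- if (is.null(noise_seed)) 0 else noise_seed
    img <- with_seed(seed, matrix(stats::rpois(length(img), img * photon_gain) / photon_gain,
                                  nrow(img)))
  }
  img
}

#' Render one scan tile
#'
#' The tile is imaged with a spatially constant PSF evaluated for the
#' residual aberration at the tile centre: ground truth there plus the DM
#' state (`"cmat"`: the tile's assigned correction point; `"ceao"`: the
#' FOV-centre correction applied everywhere).
#'
#' @param simulator an [optics_simulator()].
#' @param phantom_fn function(x_um, y_um matrices) -> intensity matrix,
#'   defining the sample in FOV coordinates.
#' @param tile one row of `plan$tiles`.
#' @param dm_coeffs DM coefficient vector for this tile (mode already
#'   resolved by the caller; see [scan_frame()]).
#' @param pixels_per_tile image size per tile.
#' @param photon_gain Poisson gain; `NA` disables noise.
#' @param noise_seed seed for the tile's noise stream.
#' @return `pixels_per_tile` square matrix; row 1 is the tile's top edge
#'   (maximum y).
#' @export
render_tile <- function(simulator, phantom_fn, tile, dm_coeffs,
                        pixels_per_tile = 64, photon_gain = NA,
                        noise_seed = NULL) {
  ts <- tile$x1 - tile$x0
  pitch <- ts / pixels_per_tile
  xs <- tile$x0 + (seq_len(pixels_per_tile) - 0.5) * pitch
  ys <- tile$y1 - (seq_len(pixels_per_tile) - 0.5) * pitch  # row 1 = top
  res <- residual(truth_coeffs(simulator$field, c(tile$cx, tile$cy)), dm_coeffs)
  render_view(simulator$pupil, phantom_fn, xs, ys, pitch, res,
              photon_gain = photon_gain, noise_seed = noise_seed)
}

#' Scan a full-FOV frame
#'
#' Renders every tile of the plan in stripe order and mosaics them at their
#' half-open extents. `mode = "cmat"` uses each tile's assigned correction;
#' `mode = "ceao"` applies the FOV-centre point's correction to every tile.
#' Data collected during the galvo jump / DM load interval between tiles is
#' excluded: the transition log records one event per tile change with zero
#' samples retained.
#'
#' @param simulator an [optics_simulator()].
#' @param phantom_fn sample function, as in [render_tile()].
#' @param plan a [plan_full_fov()] result.
#' @param mode `"cmat"` or `"ceao"`.
#' @param center_dm DM vector used by `"ceao"` (the FOV-centre calibration);
#'   required for that mode.
#' @param pixels_per_tile per-tile image size (frame is `n *
#'   pixels_per_tile` square).
#' @param photon_gain Poisson gain; `NA` disables noise.
#' @param seed master seed for per-tile noise streams.
#' @return object of class `scan_frame`: `pixels` matrix, `pitch_um`,
#'   `provenance` (per-tile correction indices and extents),
#'   `excluded_log`, `mode`.
#' @export
scan_frame <- function(simulator, phantom_fn, plan, mode = c("cmat", "ceao"),
                       center_dm = NULL, pixels_per_tile = 64,
                       photon_gain = NA, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "scan_plan"))
  if (mode == "ceao" && is.null(center_dm))
    stop("ceao mode needs the FOV-centre DM vector (center_dm)")
  n <- plan$n
  npx <- n * pixels_per_tile
  frame <- matrix(0, npx, npx)
  excl <- data.frame(after_tile = integer(0), samples_retained = integer(0))
  for (k in seq_len(nrow(plan$tiles))) {
    tile <- plan$tiles[k, ]
    dmv <- if (mode == "cmat") plan$dm[k, ] else center_dm
    img <- render_tile(simulator, phantom_fn, tile, dmv,
                       pixels_per_tile = pixels_per_tile,
                       photon_gain = photon_gain,
                       noise_seed = derive_seed(seed, sprintf("tile_%d_%s", k, mode)))
    r0 <- (tile$stripe - 1) * pixels_per_tile
    c0 <- (tile$col - 1) * pixels_per_tile
    frame[r0 + seq_len(pixels_per_tile), c0 + seq_len(pixels_per_tile)] <- img
    excl <- rbind(excl, data.frame(after_tile = k, samples_retained = 0L))
  }
  structure(list(pixels = frame,
                 pitch_um = plan$tile_size / pixels_per_tile,
                 provenance = plan$tiles[, c("tile", "stripe", "col", "point_index")],
                 excluded_log = excl,
                 mode = mode),
            class = "scan_frame")
}

#' Region-of-interest scan request
#'
#' @param center length-2 numeric, ROI centroid in um.
#' @param width_um,height_um ROI extent in um.
#' @param pitch_um pixel pitch (0.5 um at 1000 x 1000 px gives the 500 x
#'   500 um2 in-vivo ROI geometry).
#' @param frames number of frames.
#' @param frame_rate_hz acquisition rate.
#' @return object of class `roi_request`.
#' @export
roi_request <- function(center, width_um = 500, height_um = 500,
                        pitch_um = 0.5, frames = 1, frame_rate_hz = 15) {
  stopifnot(length(center) == 2, width_um > 0, height_um > 0, pitch_um > 0,
            frames >= 1)
  structure(list(center = center, width_um = width_um, height_um = height_um,
                 pitch_um = pitch_um, frames = frames,
                 frame_rate_hz = frame_rate_hz),
            class = "roi_request")
}

#' Scan a user-specified ROI
#'
#' A single DM vector -- the calibrated coefficients of the correction point
#' nearest the ROI centroid -- is loaded once and held for the whole frame
#' sequence.
#'
#' @param simulator an [optics_simulator()].
#' @param phantom_fn sample function, as in [render_tile()].
#' @param roi a [roi_request()].
#' @param grid a [build_correction_grid()] result.
#' @param calib a `calibration_table`.
#' @param fov a [fov_spec()].
#' @param photon_gain Poisson gain; `NA` disables noise.
#' @param seed master seed for per-frame noise.
#' @return list with `frames` (list of matrices), `point_index`,
#'   `dm_coeffs`, `pitch_um`.
#' @export
scan_roi <- function(simulator, phantom_fn, roi, grid, calib,
                     fov = fov_spec(), photon_gain = NA, seed = 1) {
  stopifnot(inherits(roi, "roi_request"))
  half <- fov$diameter / 2
  if (abs(roi$center[1]) + roi$width_um / 2 > half + 1e-9 ||
      abs(roi$center[2]) + roi$height_um / 2 > half + 1e-9)
    stop("ROI extends outside the FOV")
  idx <- nearest_point(grid, roi$center)
  dmv <- calib$coeffs[idx, ]
  if (anyNA(dmv)) stop(sprintf("missing calibration entry for correction point %d", idx))
  nx <- round(roi$width_um / roi$pitch_um)
  ny <- round(roi$height_um / roi$pitch_um)
  xs <- roi$center[1] - roi$width_um / 2 + (seq_len(nx) - 0.5) * roi$pitch_um
  ys <- roi$center[2] + roi$height_um / 2 - (seq_len(ny) - 0.5) * roi$pitch_um
  res <- residual(truth_coeffs(simulator$field, roi$center), dmv)
  frames <- lapply(seq_len(roi$frames), function(f)
    render_view(simulator$pupil, phantom_fn, xs, ys, roi$pitch_um, res,
                photon_gain = photon_gain,
                noise_seed = derive_seed(seed, sprintf("roi_frame_%d", f))))
  list(frames = frames, point_index = idx, dm_coeffs = dmv,
       pitch_um = roi$pitch_um)
}
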