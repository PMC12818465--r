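# End-to-end comparison of the multipoint (cmat) and centre-only (ceao)
# correction modes at a field position: bead resolution, soma brightness,
# and calcium SNR under the two residual aberrations.

#' Simulate a bead z-stack and measure its FWHM
#'
#' Renders a fluorescent bead through the two-photon PSF of the given
#' residual aberration (full 3-D convolution of the PSF stack with the
#' rasterized bead) on the bead-acquisition grid (0.27 um axial steps), then
#' Gaussian-fits the lateral and axial FWHM.
#'
#' @param pupil a [pupil_spec()]; use a high `pad_factor` (>= 8) so the
#'   lateral pitch resolves the focal spot.
#' @param res_coeffs residual Zernike coefficients (wavelengths).
#' @param bead_diameter_um bead size (default 0.5).
#' @param z_half_um axial half-range of the stack (default 6).
#' @param axial_pitch_um z step (default 0.27).
#' @return list with `lateral_um`, `axial_um`, `peak`.
#' @export
measure_bead_fwhm <- function(pupil, res_coeffs, bead_diameter_um = 0.5,
                              z_half_um = 6, axial_pitch_um = 0.27) {
  lat_half <- 24L
  phase <- wavefront_map(res_coeffs, pupil)
  # residual spherical/defocus shifts the best focus; locate it with a
  # coarse scan so the fine stack is centred on the actual focal plane
  zc_scan <- seq(-15, 15, by = 1)
  coarse <- psf_2p(pupil, phase, z_planes = zc_scan, crop = lat_half)
  z0 <- zc_scan[which.max(apply(coarse$intensity, 3, max))]
  zs <- z0 + seq(-z_half_um, z_half_um, by = axial_pitch_um)
  psf <- psf_2p(pupil, phase, z_planes = zs, crop = lat_half)
  lp <- psf$lateral_pitch
  np <- 2 * lat_half + 1
  # rasterize the bead on the same grid, centred
  brad <- bead_diameter_um / 2
  nb_l <- 2 * ceiling(brad / lp + 1) + 1
  nb_a <- 2 * ceiling(brad / axial_pitch_um + 1) + 1
  bead <- array(0, c(nb_l, nb_l, nb_a))
  ctr <- c((nb_l + 1) / 2 * lp, (nb_l + 1) / 2 * lp, (nb_a + 1) / 2 * axial_pitch_um)
  bead <- add_sphere(bead, ctr, brad, 1, lp, axial_pitch_um)
  img <- fft_conv3(psf$intensity, bead)
  vol <- volume(pmax(img, 0), lp, axial_pitch_um)
  ctr_um <- c(np / 2 * lp, np / 2 * lp, length(zs) / 2 * axial_pitch_um)
  m <- fit_fwhm(vol, matrix(ctr_um, 1), window_um = 3)
  list(lateral_um = m$per_bead$lateral_fwhm_um[1],
       axial_um = m$per_bead$axial_fwhm_um[1],
       peak = max(img))
}

# 3-D linear convolution via zero-padded FFT, returning the same size as a.
fft_conv3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  dn <- da + db - 1
  A <- array(0, dn); A[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  B <- array(0, dn); B[seq_len(db[1]), seq_len(db[2]), seq_len(db[3])] <- b
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / prod(dn)
  o <- (db + 1) %/% 2
  full[o[1]:(o[1] + da[1] - 1), o[2]:(o[2] + da[2] - 1), o[3]:(o[3] + da[3] - 1)]
}

#' Compare cmat and ceao corrections at one field position
#'
#' Given the two DM vectors (the nearest correction point's calibration and
#' the FOV-centre calibration), computes for each mode: bead lateral/axial
#' FWHM, mean soma intensity of a rendered neuron scene, and mean calcium
#' SNR of a synthetic movie whose brightness is scaled by the mode's
#' relative two-photon collection efficiency.
#'
#' @param simulator an [optics_simulator()].
#' @param position length-2 numeric, um.
#' @param dm_cmat,dm_ceao DM coefficient vectors.
#' @param hr_pupil high-resolution pupil for the bead stack (default
#'   `pupil_spec(grid_size = 64, pad_factor = 8)` with the simulator's
#'   optical constants).
#' @param movie_spec a [calcium_movie_spec()] for the SNR comparison. The
#'   default is photon-limited (baseline 8 photons/pixel/frame, sparse
#'   0.1 Hz firing), the regime of in-vivo recordings at 15 Hz, so the SNR
#'   difference between modes reflects their photon collection.
#' @param scene_spec a [neuron_scene_spec()] for the brightness comparison.
#' @param seed integer seed.
#' @return data.frame with one row per mode and columns `lateral_fwhm_um`,
#'   `axial_fwhm_um`, `soma_intensity`, `mean_snr`.
#' @export
compare_modes_at <- function(simulator, position, dm_cmat, dm_ceao,
                             hr_pupil = NULL,
                             movie_spec = calcium_movie_spec(
                               n_cells = 5, duration_s = 60, img_size = 32,
                               spike_rate_hz = 0.1, baseline = 8,
                               neuropil_level = 3.2, photon_gain = 1),
                             scene_spec = neuron_scene_spec(
                               n_somata = 5, extent_um = 120, pitch_um = 1),
                             seed = 1) {
  if (is.null(hr_pupil))
    hr_pupil <- pupil_spec(na = simulator$pupil$na,
                           wavelength = simulator$pupil$wavelength,
                           refractive_index = simulator$pupil$refractive_index,
                           grid_size = 64, pad_factor = 8)
  truth <- truth_coeffs(simulator$field, position)
  scene_spec$seed <- seed
  movie_spec$seed <- seed
  scene <- make_neuron_scene(scene_spec)
  rows <- lapply(list(cmat = dm_cmat, ceao = dm_ceao), function(dmv) {
    res <- residual(truth, dmv)
    fw <- measure_bead_fwhm(hr_pupil, res)
    img <- render_scene(scene$img, scene$pitch_um, simulator$pupil, res)
    soma <- mean(img[scene$soma_mask > 0])
    sig <- tp_plane_signal(simulator$pupil, res)
    mov <- make_calcium_movie(movie_spec, signal_scale = sig)
    traces <- extract_traces(mov$movie, mov$cell_masks, mov$neuropil_mask)
    snrs <- vapply(traces, function(tr) snr(dff(tr)), numeric(1))
    data.frame(lateral_fwhm_um = fw$lateral_um, axial_fwhm_um = fw$axial_um,
               soma_intensity = soma, mean_snr = mean(snrs))
  })
  out <- do.call(rbind, rows)
  out$mode <- names(rows)
  out[, c("mode", "lateral_fwhm_um", "axial_fwhm_um", "soma_intensity", "mean_snr")]
}
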