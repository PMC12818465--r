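# Ground-truth field-varying aberrations and the modal deformable-mirror
# state. The field model is the simulator's stand-in for the real system
# aberrations that the sensorless calibration has to discover: deterministic
# off-axis terms (astigmatism, coma, field-dependent spherical) that grow
# with field radius and vanish at the FOV centre, plus a smooth seeded
# band-limited random component.

#' Field-varying ground-truth aberration model
#'
#' Zernike coefficients (in wavelengths) as continuous functions of the
#' object-plane position. The deterministic part is zero at the FOV centre
#' and grows radially: astigmatism (Noll 5/6) as `(r/R)^2` oriented along the
#' field azimuth, coma (Noll 7/8) linearly in `r` pointing radially, and
#' spherical (Noll 11) as `(r/R)^2`. On top sits a seeded band-limited random
#' field per term (sum of low-frequency cosines, correlation length
#' ~2 mm).
#'
#' @param n_terms number of Noll terms carried (default 15).
#' @param fov_radius field radius R in um used to normalize the growth laws
#'   (default 4000).
#' Default amplitudes place the whole field inside the capture range of
#' per-term modal sweeps (~0.3 wavelengths total RMS), the regime in which
#' sensorless calibration converges within a handful of rounds -- the
#' operating point of a working instrument. The uncorrected edge still loses
#' more than 99% of its two-photon peak signal.
#'
#' @param astig_edge,coma_edge,sph_edge deterministic amplitudes in
#'   wavelengths at `r = fov_radius` (defaults 0.2, 0.15, 0.08).
#' @param random_amp RMS amplitude (wavelengths) of the random component per
#'   optimized term (default 0.02); 0 disables it.
#' @param random_corr_um correlation length of the random component (um).
#' @param seed integer seed for the random component.
#' @return object of class `aberration_field`.
#' @export
aberration_field <- function(n_terms = 15, fov_radius = 4000,
                             astig_edge = 0.2, coma_edge = 0.15, sph_edge = 0.08,
                             random_amp = 0.02, random_corr_um = 2000,
                             seed = 1) {
  stopifnot(n_terms >= 4, fov_radius > 0, random_amp >= 0)
  n_waves <- 6L
  rc <- with_seed(derive_seed(seed, "aberration_field"), {
    lapply(seq_len(n_terms), function(j) {
      # per-term random plane waves; amplitude scaled so the field RMS over
      # positions is ~random_amp
      ang <- stats::runif(n_waves, 0, 2 * pi)
      fmag <- stats::runif(n_waves, 0.2, 1) / random_corr_um
      list(amp = stats::rnorm(n_waves) * random_amp / sqrt(n_waves / 2),
           fx = fmag * cos(ang), fy = fmag * sin(ang),
           phase = stats::runif(n_waves, 0, 2 * pi))
    })
  })
  structure(list(n_terms = n_terms, fov_radius = fov_radius,
                 astig_edge = astig_edge, coma_edge = coma_edge,
                 sph_edge = sph_edge, random_amp = random_amp,
                 random_corr_um = random_corr_um, seed = seed,
                 random_comp = rc),
            class = "aberration_field")
}

#' Ground-truth Zernike coefficients at a field position
#'
#' @param field an [aberration_field()].
#' @param position length-2 numeric, object-plane um; must lie within the
#'   field radius.
#' @return numeric vector of length `field$n_terms`, wavelengths (Noll
#'   order; entries 1-3 are always 0).
#' @export
truth_coeffs <- function(field, position) {
  stopifnot(inherits(field, "aberration_field"))
  stopifnot(is.numeric(position), length(position) == 2, all(is.finite(position)))
  r <- sqrt(sum(position^2))
  # the field is defined over the full square FOV, whose corners reach
  # sqrt(2) times the inscribed-circle radius used to normalize growth laws
  if (r > field$fov_radius * sqrt(2) * (1 + 1e-9))
    stop(sprintf("position at radius %.1f um outside the field domain %.1f um",
                 r, field$fov_radius * sqrt(2)))
  x <- position[1]; y <- position[2]
  R <- field$fov_radius
  th <- atan2(y, x)
  c_det <- numeric(field$n_terms)
  rr <- r / R
  if (field$n_terms >= 5)  c_det[5]  <- field$astig_edge * rr^2 * sin(2 * th)
  if (field$n_terms >= 6)  c_det[6]  <- field$astig_edge * rr^2 * cos(2 * th)
  if (field$n_terms >= 7)  c_det[7]  <- field$coma_edge * (y / R)
  if (field$n_terms >= 8)  c_det[8]  <- field$coma_edge * (x / R)
  if (field$n_terms >= 11) c_det[11] <- field$sph_edge * rr^2
  if (field$random_amp > 0) {
    c_rand <- vapply(seq_len(field$n_terms), function(j) {
      rcj <- field$random_comp[[j]]
      sum(rcj$amp * cos(2 * pi * (rcj$fx * x + rcj$fy * y) + rcj$phase))
    }, numeric(1))
    c_rand[1:3] <- 0  # piston/tip/tilt carry no image-quality information
    c_det + c_rand
  } else c_det
}

#' Modal deformable-mirror state
#'
#' @param coeffs Zernike coefficients in wavelengths (Noll order).
#' @param stroke_limit peak wavefront surface amplitude in wavelengths the
#'   mirror can produce each way (default 30).
#' @return object of class `dm_state`.
#' @export
dm_state <- function(coeffs, stroke_limit = 30) {
  stopifnot(is.numeric(coeffs), stroke_limit > 0)
  structure(list(coeffs = coeffs, stroke_limit = stroke_limit),
            class = "dm_state")
}

#' Residual aberration after mirror correction
#'
#' The mirror phase adds to the sample-path phase, so perfect correction is
#' `dm$coeffs == -truth`. Vectors are zero-padded to a common length.
#'
#' @param truth ground-truth coefficient vector (wavelengths).
#' @param dm a [dm_state()] or plain coefficient vector.
#' @return residual coefficient vector.
#' @export
residual <- function(truth, dm) {
  dc <- if (inherits(dm, "dm_state")) dm$coeffs else dm
  n <- max(length(truth), length(dc))
  tr <- c(truth, numeric(n - length(truth)))
  dc <- c(dc, numeric(n - length(dc)))
  tr + dc
}

#' Clip a mirror state to its stroke range
#'
#' If the synthesized wavefront surface exceeds the stroke limit anywhere on
#' the pupil, the whole coefficient vector is scaled by
#' `stroke_limit / max|surface|` (preserving the wavefront shape) and a
#' warning is emitted.
#'
#' @param dm a [dm_state()].
#' @param grid_size pupil sampling used to evaluate the surface extremum.
#' @return a `dm_state` honouring the stroke limit.
#' @export
clip_stroke <- function(dm, grid_size = 64) {
  stopifnot(inherits(dm, "dm_state"))
  if (length(dm$coeffs) == 0 || all(dm$coeffs == 0)) return(dm)
  ax <- (seq_len(grid_size) - 0.5) / (grid_size / 2) - 1
  u <- matrix(ax, grid_size, grid_size)
  v <- matrix(ax, grid_size, grid_size, byrow = TRUE)
  rho <- sqrt(u^2 + v^2)
  inside <- rho <= 1
  B <- zernike_basis_matrix(rho[inside], atan2(v, u)[inside], length(dm$coeffs))
  surface <- as.vector(B %*% dm$coeffs)  # wavelengths
  peak <- max(abs(surface))
  if (peak <= dm$stroke_limit) return(dm)
  warning(sprintf(
    "DM stroke limit: wavefront peak %.2f wavelengths exceeds +/-%.2f; scaling coefficients by %.4f",
    peak, dm$stroke_limit, dm$stroke_limit / peak))
  dm_state(dm$coeffs * dm$stroke_limit / peak, dm$stroke_limit)
}
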