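# Evaluation statistics: 3-D bead FWHM by 1-D Gaussian fitting along the
# lateral and axial lines through each bead's maximum, intensity line
# profiles, neuropil-subtracted dF/F, SNR, and rank-based group comparisons.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # FWHM of a Gaussian = 2.3548 sigma

# 1-D Gaussian fit y ~ b + A exp(-(x-mu)^2 / (2 sigma^2)); moment-based
# starting values, Levenberg-Marquardt refinement. Returns NULL on failure.
fit_gaussian_1d <- function(x, y) {
  b0 <- min(y)
  yc <- pmax(y - b0, 0)
  if (sum(yc) <= 0) return(NULL)
  mu0 <- sum(x * yc) / sum(yc)
  s0 <- sqrt(sum((x - mu0)^2 * yc) / sum(yc))
  if (!is.finite(s0) || s0 <= 0) return(NULL)
  dx <- stats::median(diff(x))
  fit <- NULL
  # exactly symmetric noiseless profiles zero the mu-gradient at the moment
  # start; retry from slightly offset starts before giving up
  for (jit in c(0, 0.3, -0.3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + A * exp(-(x - mu)^2 / (2 * sigma^2)),
                        start = list(b = b0, A = max(yc),
                                     mu = mu0 + jit * dx,
                                     sigma = s0 * (1 + jit / 2)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (!is.finite(p["sigma"]) || p["sigma"] <= 0) return(NULL)
  list(mu = unname(p["mu"]), sigma = abs(unname(p["sigma"])),
       A = unname(p["A"]), b = unname(p["b"]))
}

#' Bead FWHM measurement by Gaussian fitting
#'
#' For each bead: locate the intensity maximum within a window around the
#' given centre, extract the lateral line (along x) through that maximum and
#' the axial profile (the bead's per-plane peak intensity within the lateral
#' window, the usual way a bead's z-profile is read off a stack), fit a 1-D
#' Gaussian to each, and report
#' `FWHM = 2 sqrt(2 ln 2) sigma`. Beads whose fit fails or whose FWHM falls
#' below 2 pixels are flagged and excluded from the site summary
#' (mean +/- SD over the remaining beads).
#'
#' @param stack a [volume()].
#' @param centers n x 3 matrix of approximate bead centres, um (x, y, z from
#'   the volume corner).
#' @param window_um half-width of the search/fit window in um (lateral;
#'   axial uses the full stack by default).
#' @return object of class `bead_measurement`: data.frame `per_bead`
#'   (lateral_fwhm_um, axial_fwhm_um, ok, note) and `summary` (mean/sd per
#'   axis over the included beads, n).
#' @export
fit_fwhm <- function(stack, centers, window_um = 3) {
  stopifnot(inherits(stack, "volume"))
  centers <- matrix(centers, ncol = 3)
  d <- dim(stack$data)
  lp <- stack$lateral_pitch; ap <- stack$axial_pitch
  res <- lapply(seq_len(nrow(centers)), function(i) {
    ct <- centers[i, ]
    ix <- round(ct[1] / lp + 0.5); iy <- round(ct[2] / lp + 0.5)
    iz <- round(ct[3] / ap + 0.5)
    wl <- max(2, round(window_um / lp)); wa <- max(2, round(window_um * 2 / ap))
    sx <- max(1, ix - wl):min(d[2], ix + wl)
    sy <- max(1, iy - wl):min(d[1], iy + wl)
    sz <- max(1, iz - wa):min(d[3], iz + wa)
    sub <- stack$data[sy, sx, sz, drop = FALSE]
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    py <- sy[pk[1]]; px <- sx[pk[2]]; pz <- sz[pk[3]]
    lat_x <- (sx - 0.5) * lp
    lat_y <- stack$data[py, sx, pz]
    ax_x <- ((1:d[3]) - 0.5) * ap
    ax_y <- apply(stack$data[sy, sx, , drop = FALSE], 3, max)
    f_lat <- fit_gaussian_1d(lat_x, lat_y)
    f_ax <- fit_gaussian_1d(ax_x, ax_y)
    lat <- if (!is.null(f_lat)) FWHM_FACTOR * f_lat$sigma else NA_real_
    axl <- if (!is.null(f_ax)) FWHM_FACTOR * f_ax$sigma else NA_real_
    note <- ""
    ok <- TRUE
    if (is.na(lat) || is.na(axl)) { ok <- FALSE; note <- "fit failed" }
    else if (lat < 2 * lp || axl < 2 * ap) { ok <- FALSE; note <- "FWHM below 2 pixels" }
    if (!ok) cmat_log(sprintf("bead %d excluded from summary: %s", i, note))
    data.frame(bead = i, lateral_fwhm_um = lat, axial_fwhm_um = axl,
               ok = ok, note = note)
  })
  per_bead <- do.call(rbind, res)
  inc <- per_bead[per_bead$ok, ]
  summary <- data.frame(
    axis = c("lateral", "axial"),
    mean_um = c(mean(inc$lateral_fwhm_um), mean(inc$axial_fwhm_um)),
    sd_um = c(stats::sd(inc$lateral_fwhm_um), stats::sd(inc$axial_fwhm_um)),
    n = nrow(inc))
  structure(list(per_bead = per_bead, summary = summary),
            class = "bead_measurement")
}

#' Intensity profile along a line
#'
#' Bilinear interpolation at unit-pixel steps from `p0` to `p1` (pixel
#' coordinates: column = x, row = y, 1-based pixel centres).
#'
#' @param image 2-D matrix.
#' @param p0,p1 length-2 numeric `(x, y)` endpoints, in pixels.
#' @param normalization `"none"` or `"minmax"` (rescale to `[0, 1]`).
#' @return data.frame with `t` (distance along the line, pixels) and
#'   `value`.
#' @export
line_profile <- function(image, p0, p1, normalization = c("none", "minmax")) {
  normalization <- match.arg(normalization)
  stopifnot(length(p0) == 2, length(p1) == 2)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("degenerate line: p0 equals p1")
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > ncol(image) || p[2] < 1 || p[2] > nrow(image))
      stop("line endpoint outside the image")
  tt <- seq(0, len, by = 1)
  if (tt[length(tt)] < len) tt <- c(tt, len)
  xs <- p0[1] + (p1[1] - p0[1]) * tt / len
  ys <- p0[2] + (p1[2] - p0[2]) * tt / len
  vals <- bilinear_at(image, xs, ys)
  if (normalization == "minmax") {
    rng <- range(vals)
    vals <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else vals * 0
  }
  data.frame(t = tt, value = vals)
}

bilinear_at <- function(image, xs, ys) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- pmin(pmax(floor(xs), 1), nc - 1)
  y0 <- pmin(pmax(floor(ys), 1), nr - 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    image[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Paired cell / neuropil fluorescence traces
#'
#' @param f_cell,f_neu equal-length numeric vectors.
#' @param rate_hz sampling rate (optional metadata).
#' @return object of class `trace_set`.
#' @export
trace_set <- function(f_cell, f_neu = rep(0, length(f_cell)), rate_hz = NA) {
  stopifnot(length(f_cell) == length(f_neu))
  structure(list(f_cell = as.numeric(f_cell), f_neu = as.numeric(f_neu),
                 rate_hz = rate_hz),
            class = "trace_set")
}

#' Relative fluorescence change with neuropil subtraction
#'
#' `F = F_cell - r_neuropil * F_neu`; the baseline `F0` is the
#' `f0_percentile` linear-interpolation percentile of `F` over the whole
#' recording; `dF/F = (F - F0) / F0`.
#'
#' @param traces a [trace_set()] (or plain numeric vector, taken as `F`
#'   with no neuropil).
#' @param r_neuropil neuropil subtraction factor (default 0.7).
#' @param f0_percentile baseline percentile (default 25).
#' @return numeric dF/F series with attributes `F0` and `F`.
#' @export
dff <- function(traces, r_neuropil = 0.7, f0_percentile = 25) {
  if (is.numeric(traces)) traces <- trace_set(traces)
  stopifnot(inherits(traces, "trace_set"))
  f <- traces$f_cell - r_neuropil * traces$f_neu
  f0 <- unname(stats::quantile(f, f0_percentile / 100, type = 7))
  if (f0 <= 0) stop(sprintf("degenerate baseline: F0 = %.4g <= 0 after neuropil subtraction", f0))
  out <- (f - f0) / f0
  attr(out, "F0") <- f0
  attr(out, "F") <- f
  out
}

#' Signal-to-noise ratio of a dF/F series
#'
#' Signal: mean of the samples at or above the 90th percentile of dF/F
#' (with `top = "interval"`, instead the best contiguous window holding 10%
#' of the samples). Noise: standard deviation (n-1 denominator) of the
#' samples strictly below the 90th percentile. SNR = signal / noise.
#'
#' @param dff_series numeric dF/F vector (length >= 10).
#' @param top `"value"` (default) or `"interval"`.
#' @return scalar SNR.
#' @export
snr <- function(dff_series, top = c("value", "interval")) {
  top <- match.arg(top)
  x <- as.numeric(dff_series)
  if (length(x) < 10) stop("need at least 10 samples")
  q90 <- unname(stats::quantile(x, 0.9, type = 7))
  noise <- stats::sd(x[x < q90])
  if (!is.finite(noise) || noise == 0)
    stop("noise standard deviation is zero (degenerate noiseless input)")
  signal <- if (top == "value") {
    mean(x[x >= q90])
  } else {
    k <- max(1, round(0.1 * length(x)))
    cs <- cumsum(c(0, x))
    wins <- (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
    max(wins)
  }
  signal / noise
}

#' Rank-based two-group comparison
#'
#' Wilcoxon signed-rank for paired samples, Mann-Whitney (rank-sum) for
#' independent ones; two-sided. For combined sample size <= 12 the p-value
#' is computed by exact enumeration of the permutation distribution
#' (mid-ranks under ties; zero differences dropped for the paired test);
#' larger samples use the normal approximation with tie correction.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return list with `statistic` (`W`: rank sum of `a` minus its minimum for
#'   unpaired, positive-rank sum for paired), `p_value`, `method`, `exact`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      warning("all paired differences are zero; p = 1")
      return(list(statistic = 0, p_value = 1,
                  method = "Wilcoxon signed-rank", exact = TRUE))
    }
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    if (n <= 12) {
      # enumerate all 2^n sign patterns of the rank magnitudes
      stats_all <- apply(expand.grid(rep(list(c(0, 1)), n)), 1,
                         function(s) sum(r * s))
      mu <- n * (n + 1) / 4
      p <- mean(abs(stats_all - mu) >= abs(v - mu) - 1e-9)
      list(statistic = v, p_value = min(1, p),
           method = "Wilcoxon signed-rank (exact)", exact = TRUE)
    } else {
      mu <- n * (n + 1) / 4
      ties <- table(r)
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
      z <- (v - mu) / sqrt(sig2)
      list(statistic = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
           method = "Wilcoxon signed-rank (normal approximation)", exact = FALSE)
    }
  } else {
    m <- length(a); n <- length(b)
    if (m == 0 || n == 0) stop("empty sample")
    r <- rank(c(a, b))
    if (max(r) == min(r)) {
      warning("all observations tied; p = 1")
      return(list(statistic = m * n / 2, p_value = 1,
                  method = "Mann-Whitney", exact = TRUE))
    }
    w <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U of sample a
    if (m + n <= 12) {
      combs <- utils::combn(m + n, m)
      stats_all <- apply(combs, 2, function(ix) sum(r[ix])) - m * (m + 1) / 2
      mu <- m * n / 2
      p <- mean(abs(stats_all - mu) >= abs(w - mu) - 1e-9)
      list(statistic = w, p_value = min(1, p),
           method = "Mann-Whitney (exact)", exact = TRUE)
    } else {
      mu <- m * n / 2
      N <- m + n
      ties <- table(r)
      sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      z <- (w - mu) / sqrt(sig2)
      list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
           method = "Mann-Whitney (normal approximation)", exact = FALSE)
    }
  }
}

#' Interpolated half-maximum width of a sampled profile
#'
#' Model-free FWHM: linear interpolation of the half-maximum crossings on
#' either side of the profile peak. Used as the direct, fit-free companion
#' to [fit_fwhm()].
#'
#' @param x sample coordinates (increasing).
#' @param y sampled profile.
#' @return width in `x` units.
#' @export
half_max_width <- function(x, y) {
  pk <- which.max(y)
  half <- (max(y) + min(y)) / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(pk, 2)) if (y[i - 1] < half && y[i] >= half) {
    left <- x[i - 1] + (x[i] - x[i - 1]) * (half - y[i - 1]) / (y[i] - y[i - 1]); break
  }
  for (i in seq(pk, length(y) - 1)) if (y[i] >= half && y[i + 1] < half) {
    right <- x[i] + (x[i + 1] - x[i]) * (y[i] - half) / (y[i] - y[i + 1]); break
  }
  right - left
}
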