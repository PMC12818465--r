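# Shared fixtures: a coarse pupil for metric-only work (pad 2 keeps the
# plane-signal identity exact), and the default rendering pupil.
metric_pupil <- function() pupil_spec(grid_size = 64, pad_factor = 2)

# Brute-force triangular-lattice count oracle, independent of the package's
# basis orientation (counts are rotation-invariant).
count_lattice_points <- function(side, radius) {
  kmax <- ceiling(radius / (side * sqrt(3) / 2)) + 2
  total <- 0L; centers <- 0L
  for (k1 in -kmax:kmax) for (k2 in -kmax:kmax) {
    x <- k1 * side + k2 * side / 2
    y <- k2 * side * sqrt(3) / 2
    if (sqrt(x^2 + y^2) <= radius) {
      total <- total + 1L
      if ((k2 - k1) %% 3 == 0) centers <- centers + 1L
    }
  }
  list(total = total, centers = centers)
}

# Noiseless separable Gaussian "bead" volume, thin in y (the FWHM fit reads
# the lateral line along x and the per-plane peak), so large sigmas stay
# cheap. Returns the volume, the bead centre, and a fit window.
gaussian_volume <- function(sigma_lat, sigma_ax, lp = 0.0542, ap = 0.27) {
  nx <- 2 * ceiling(2.5 * sigma_lat / lp) + 1
  ny <- 2 * ceiling(0.75 * sigma_lat / lp) + 1
  nz <- 2 * ceiling(2.5 * sigma_ax / ap) + 1
  cx <- (nx + 1) / 2 * lp; cy <- (ny + 1) / 2 * lp; cz <- (nz + 1) / 2 * ap
  gx <- exp(-(((1:nx) - 0.5) * lp - cx)^2 / (2 * sigma_lat^2))
  gy <- exp(-(((1:ny) - 0.5) * lp - cy)^2 / (2 * sigma_lat^2))
  gz <- exp(-(((1:nz) - 0.5) * ap - cz)^2 / (2 * sigma_ax^2))
  data <- outer(outer(gy, gx), gz)
  list(vol = volume(data, lp, ap), center = c(cx, cy, cz),
       window = 2.4 * sigma_lat)
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all group
# assignments of the pooled ranks (mid-ranks under ties).
mw_exact_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  combs <- utils::combn(m + n, m)
  ws <- apply(combs, 2, function(ix) sum(r[ix])) - m * (m + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exhaustive two-sided Wilcoxon signed-rank p-value over all sign patterns.
sr_exact_oracle <- function(a, b) {
  d <- a - b; d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}
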