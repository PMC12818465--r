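# Zernike polynomials, Noll single-index convention, normalized to unit RMS
# over the unit disk (so a coefficient in wavelengths is directly the RMS
# wavefront contribution of that mode).

#' Noll index to radial degree and azimuthal frequency
#'
#' @param j Noll index (1 = piston, 2/3 = tip/tilt, 4 = defocus, ...).
#' @return list with `n` (radial degree) and `m` (signed azimuthal
#'   frequency; negative means the sine mode).
#' @export
noll_to_nm <- function(j) {
  stopifnot(j >= 1, j == round(j))
  n <- 0
  j1 <- j - 1
  while (j1 > n) {
    n <- n + 1
    j1 <- j1 - n
  }
  m <- (-1)^j * ((n %% 2) + 2 * ((j1 + ((n + 1) %% 2)) %/% 2))
  list(n = n, m = m)
}

# Radial polynomial R_n^|m|(rho); exact factorial coefficients (n <= 22
# stays within double precision integer range).
zernike_radial <- function(n, m_abs, rho) {
  val <- 0
  for (k in 0:((n - m_abs) / 2)) {
    c_k <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) * factorial((n - m_abs) / 2 - k))
    val <- val + c_k * rho^(n - 2 * k)
  }
  val
}

#' Evaluate a Zernike polynomial (Noll index, unit-RMS normalization)
#'
#' @param j Noll index >= 1.
#' @param rho radial coordinate(s) in `[0, 1]`.
#' @param theta azimuth(s) in radians.
#' @return numeric value(s); piston (j = 1) is identically 1, defocus
#'   (j = 4) is `sqrt(3) * (2 rho^2 - 1)`.
#' @export
zernike <- function(j, rho, theta) {
  if (any(rho < 0 | rho > 1, na.rm = TRUE)) stop("rho outside the unit pupil [0, 1]")
  nm <- noll_to_nm(j)
  n <- nm$n; m <- nm$m
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  r <- zernike_radial(n, abs(m), rho)
  if (m == 0) norm * r
  else if (m > 0) norm * r * cos(m * theta)
  else norm * r * sin(abs(m) * theta)
}

# Basis matrix: rows = pupil pixels (inside disk), cols = Noll terms 1..J.
zernike_basis_matrix <- function(rho, theta, n_terms) {
  sapply(seq_len(n_terms), function(j) zernike(j, rho, theta))
}
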