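#' Field-of-view specification
#'
#' Describes the circular full field of the mesoscope in object-plane
#' micrometres. The origin is the FOV centre O; x points right, y up.
#'
#' @param diameter full-field diameter in um (default 8000, the 8 x 8 mm2
#'   imaging area).
#' @param inclusion_radius radius in um used to admit triangular-lattice
#'   points into the correction grid. Default 3950: the printed grid
#'   (55 hexagons, 163 points) requires excluding lattice points at
#'   ~3997.6 um while keeping those at <= 3950; any value in
#'   [3790, 3995] reproduces the printed counts.
#' @return an object of class `fov_spec`.
#' @export
fov_spec <- function(diameter = 8000, inclusion_radius = 3950) {
  stopifnot(diameter > 0)
  if (!(inclusion_radius > 0 && inclusion_radius <= diameter / 2))
    stop("inclusion_radius must satisfy 0 < inclusion_radius <= diameter/2")
  structure(list(diameter = diameter, inclusion_radius = inclusion_radius),
            class = "fov_spec")
}

#' Hexagonal tiling specification
#'
#' The correction-point layout is the honeycomb of regular hexagons of side
#' `side`; centres and vertices together form a triangular lattice of pitch
#' `side`. Each point carries an effective compensation disk of radius
#' `effective_radius` (the isoplanatic patch).
#'
#' @param side hexagon side length s in um (default 577).
#' @param effective_radius compensation-disk radius in um (default 330).
#' @return an object of class `hex_tiling_spec`.
#' @export
hex_tiling_spec <- function(side = 577, effective_radius = 330) {
  stopifnot(side > 0)
  # coverage condition: the disk must reach the triangle circumcentre;
  # 5 um slack admits the conventional value 330 (= 577/sqrt(3) rounded to
  # the nearest 10 um)
  if (effective_radius < side / sqrt(3) - 5)
    stop("effective_radius below the coverage bound side/sqrt(3)")
  structure(list(side = side, effective_radius = effective_radius),
            class = "hex_tiling_spec")
}

#' Circumradius of the compensation triangle
#'
#' A hexagon centre and two adjacent vertices form an equilateral triangle of
#' side `side`; its circumcentre sits `side/sqrt(3)` from each corner. This is
#' the farthest any object-plane location can be from its nearest correction
#' point, hence the required effective compensation radius (577 um -> 333.1,
#' i.e. roughly 330).
#'
#' @param side triangle (= hexagon) side length in um.
#' @return circumradius in um.
#' @export
hex_circumradius <- function(side) {
  if (!is.numeric(side) || length(side) != 1 || !is.finite(side) || side <= 0)
    stop("side must be a positive finite scalar")
  side / sqrt(3)
}

#' Build the honeycomb correction-point grid
#'
#' Enumerates all triangular-lattice points of pitch `tiling$side` (hexagon
#' centres plus vertices) whose distance from the FOV centre does not exceed
#' `fov$inclusion_radius`, and flags the hexagon-centre sublattice (pitch
#' `sqrt(3) * side`, containing the origin). Orientation convention: the
#' centre sublattice has a basis vector along +x, so hexagon vertices lie at
#' 30 + k*60 degrees from each centre. Points are ordered by distance from
#' the origin, then by angle from +x.
#'
#' With the defaults (side 577 um, inclusion radius 3950 um) the grid has
#' 163 points of which 55 are hexagon centres.
#'
#' Because only lattice points inside `inclusion_radius` are admitted, full
#' compensation coverage (every location within the triangle circumradius
#' `side/sqrt(3)` of an admitted point) holds on a slightly smaller disk;
#' the grid is checked over `coverage_radius`, which defaults to
#' `inclusion_radius - side`. Passing a larger `coverage_radius` turns an
#' uncovered rim into an explicit error naming the uncovered location.
#'
#' @param fov a [fov_spec()].
#' @param tiling a [hex_tiling_spec()].
#' @param coverage_radius radius (um) of the disk over which compensation
#'   coverage is asserted at build time; default `inclusion_radius - side`.
#' @return an object of class `correction_grid`: a list with `points`
#'   (n x 2 matrix, um), `kind` (`"center"`/`"vertex"`), `side`,
#'   `effective_radius`, `inclusion_radius`.
#' @export
build_correction_grid <- function(fov = fov_spec(), tiling = hex_tiling_spec(),
                                  coverage_radius = NULL) {
  stopifnot(inherits(fov, "fov_spec"), inherits(tiling, "hex_tiling_spec"))
  s <- tiling$side
  R <- fov$inclusion_radius
  # fine-lattice basis at +/-30 deg so the centre sublattice basis
  # (b1 + b2 = (sqrt(3) s, 0)) lies along +x
  b1 <- s * c(sqrt(3) / 2,  1 / 2)
  b2 <- s * c(sqrt(3) / 2, -1 / 2)
  kmax <- ceiling(R / (s * sqrt(3) / 2)) + 2
  k <- as.matrix(expand.grid(k1 = -kmax:kmax, k2 = -kmax:kmax))
  xy <- cbind(k[, 1] * b1[1] + k[, 2] * b2[1],
              k[, 1] * b1[2] + k[, 2] * b2[2])
  d <- sqrt(rowSums(xy^2))
  keep <- d <= R + 1e-9
  xy <- xy[keep, , drop = FALSE]
  k <- k[keep, , drop = FALSE]
  d <- d[keep]
  # dedup (construction cannot duplicate, but honour the stated tolerance)
  key <- paste(round(xy[, 1] / 1e-6), round(xy[, 2] / 1e-6))
  dup <- duplicated(key)
  xy <- xy[!dup, , drop = FALSE]; k <- k[!dup, , drop = FALSE]; d <- d[!dup]

  ang <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
  ang[d < 1e-9] <- 0
  ord <- order(round(d, 6), round(ang, 9))
  xy <- xy[ord, , drop = FALSE]; k <- k[ord, , drop = FALSE]
  is_center <- ((k[, 1] - k[, 2]) %% 3) == 0

  grid <- structure(list(
    points = unname(xy),
    kind = ifelse(is_center, "center", "vertex"),
    side = s,
    effective_radius = tiling$effective_radius,
    inclusion_radius = R,
    fov_diameter = fov$diameter
  ), class = "correction_grid")

  if (is.null(coverage_radius)) coverage_radius <- max(0, R - s)
  cov <- check_coverage(grid, radius = coverage_radius)
  if (!cov$covered)
    stop(sprintf(
      "correction disks do not cover the FOV disk: location (%.1f, %.1f) um is %.1f um from the nearest point (limit %.1f)",
      cov$worst[1], cov$worst[2], cov$worst_dist, tiling$effective_radius))
  grid
}

# Sample the disk of given radius on a square grid of the given step and
# report the worst distance to the nearest correction point.
check_coverage <- function(grid, radius, step = 50) {
  ax <- seq(-radius, radius, by = step)
  g <- as.matrix(expand.grid(x = ax, y = ax))
  g <- g[g[, 1]^2 + g[, 2]^2 <= radius^2, , drop = FALSE]
  g <- rbind(c(0, 0), g)  # never empty, even for radii below the step
  dmin <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(grid$points))) {
    d2 <- (g[, 1] - grid$points[i, 1])^2 + (g[, 2] - grid$points[i, 2])^2
    dmin <- pmin(dmin, d2)
  }
  dmin <- sqrt(dmin)
  w <- which.max(dmin)
  # the exact coverage bound is the triangle circumradius side/sqrt(3);
  # effective_radius is conventionally that value rounded (330 for side 577)
  limit <- max(grid$effective_radius, grid$side / sqrt(3))
  list(covered = dmin[w] <= limit * (1 + 1e-6),
       worst = g[w, ], worst_dist = dmin[w])
}

#' @export
print.correction_grid <- function(x, ...) {
  cat(sprintf("correction_grid: %d points (%d hexagon centers, %d vertices)\n",
              nrow(x$points), sum(x$kind == "center"), sum(x$kind == "vertex")))
  cat(sprintf("  side %.1f um, effective radius %.1f um, inclusion radius %.1f um\n",
              x$side, x$effective_radius, x$inclusion_radius))
  invisible(x)
}

#' Nearest correction point to a position
#'
#' @param grid a [build_correction_grid()] result.
#' @param position length-2 numeric, object-plane um.
#' @return 1-based index of the grid point minimising Euclidean distance;
#'   exact ties go to the lower index (the grid ordering is deterministic).
#' @export
nearest_point <- function(grid, position) {
  stopifnot(inherits(grid, "correction_grid"))
  if (nrow(grid$points) == 0) stop("empty correction grid")
  stopifnot(is.numeric(position), length(position) == 2, all(is.finite(position)))
  d2 <- (grid$points[, 1] - position[1])^2 + (grid$points[, 2] - position[2])^2
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

#' Coverage-overlap economics of a correction-point layout
#'
#' Adjacent compensation disks must overlap for the union to cover the plane;
#' the overlap is wasted calibration area. For the honeycomb layout the
#' point spacing that just covers is `sqrt(3) * r` (the triangle-circumradius
#' relation), giving a pairwise overlap of ~5.77% of one disk's area and
#' ~34.6% total over 6 neighbours. The minimal fully covering square lattice
#' has spacing `sqrt(2) * r`, giving ~18.17% pairwise and ~72.7% over 4
#' neighbours. Both are scale-invariant in `r`.
#'
#' @param scheme `"cmat"` (honeycomb, 6 neighbours) or `"square"` (4).
#' @param effective_radius disk radius r in um (> 0); percentages do not
#'   depend on it.
#' @return list with `scheme`, `pairwise_pct`, `total_pct`, `neighbors`,
#'   `spacing`.
#' @export
overlap_report <- function(scheme = c("cmat", "square"), effective_radius = 330) {
  scheme <- match.arg(scheme)
  r <- effective_radius
  stopifnot(is.numeric(r), length(r) == 1, r > 0)
  d <- if (scheme == "cmat") sqrt(3) * r else sqrt(2) * r
  nb <- if (scheme == "cmat") 6L else 4L
  pairwise <- lens_overlap_pct(r, d)
  list(scheme = scheme,
       pairwise_pct = pairwise,
       total_pct = nb * pairwise,
       neighbors = nb,
       spacing = d)
}

# Percent of one disk's area shared with a second equal disk at separation d.
lens_overlap_pct <- function(r, d) {
  if (d >= 2 * r) return(0)
  area <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  100 * area / (pi * r^2)
}

#' Galvanometer calibration
#'
#' Linear, odd mapping from object-plane position to scan-mirror drive
#' voltage: a position at the FOV edge corresponds to the full-scale
#' mechanical angle.
#'
#' @param full_scale_angle mirror angle in degrees at the FOV edge
#'   (default 45, the slow-axis pair's maximum).
#' @param volts_per_degree drive gain in V/deg.
#' @return object of class `galvo_calib`.
#' @export
galvo_calib <- function(full_scale_angle = 45, volts_per_degree = 0.2) {
  stopifnot(full_scale_angle > 0, volts_per_degree > 0)
  structure(list(full_scale_angle = full_scale_angle,
                 volts_per_degree = volts_per_degree),
            class = "galvo_calib")
}

#' Galvo drive voltages for an object-plane position
#'
#' @param position length-2 numeric (um), FOV-centred.
#' @param calib a [galvo_calib()].
#' @param fov a [fov_spec()].
#' @return length-2 numeric, volts (x, y).
#' @export
galvo_voltages <- function(position, calib = galvo_calib(), fov = fov_spec()) {
  stopifnot(inherits(calib, "galvo_calib"), inherits(fov, "fov_spec"))
  stopifnot(is.numeric(position), length(position) == 2)
  half <- fov$diameter / 2
  for (ax in 1:2) {
    if (abs(position[ax]) > half + 1e-9)
      stop(sprintf("position %s = %.1f um outside the FOV (|.| <= %.1f)",
                   c("x", "y")[ax], position[ax], half))
  }
  position / half * calib$full_scale_angle * calib$volts_per_degree
}

#' Write / read a correction grid as tab-separated text
#'
#' Columns: index, x_um, y_um, kind; `#`-prefixed header lines carry the
#' geometry parameters.
#'
#' @param grid a `correction_grid`.
#' @param path output file.
#' @return `write_grid_tsv` returns `path` invisibly; `read_grid_tsv`
#'   returns a `correction_grid`.
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "correction_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cmatsim correction grid"),
    sprintf("# side_um=%.10g effective_radius_um=%.10g inclusion_radius_um=%.10g fov_diameter_um=%.10g",
            grid$side, grid$effective_radius, grid$inclusion_radius, grid$fov_diameter),
    "# index\tx_um\ty_um\tkind"), con)
  df <- data.frame(index = seq_len(nrow(grid$points)) - 1L,
                   x_um = grid$points[, 1], y_um = grid$points[, 2],
                   kind = grid$kind)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  par_line <- hdr[grepl("side_um=", hdr)][1]
  get_par <- function(name) as.numeric(sub(sprintf(".*%s=([0-9.eE+-]+).*", name), "\\1", par_line))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          col.names = c("index", "x_um", "y_um", "kind"))
  df <- df[order(df$index), ]
  structure(list(points = unname(cbind(df$x_um, df$y_um)),
                 kind = as.character(df$kind),
                 side = get_par("side_um"),
                 effective_radius = get_par("effective_radius_um"),
                 inclusion_radius = get_par("inclusion_radius_um"),
                 fov_diameter = get_par("fov_diameter_um")),
            class = "correction_grid")
}

#' Image extent from pixel count and pitch
#'
#' Convenience helper: 1200 px at 0.0542 um/px spans 65 um (rounded).
#'
#' @param n_px pixels along one side.
#' @param pitch_um pixel pitch in um.
#' @param digits rounding digits for the returned extent (default 0).
#' @return extent in um.
#' @export
px_extent_um <- function(n_px, pitch_um, digits = 0) {
  stopifnot(n_px > 0, pitch_um > 0)
  round(n_px * pitch_um, digits)
}
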