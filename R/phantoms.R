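# Seeded synthetic samples: fluorescent bead volumes, a pollen-like spiky
# calibration target, neuron scenes (somata, dendrites with spines, diffuse
# neuropil) with ground-truth masks, and GCaMP-like calcium movies with
# known spikes. All generators are pure functions of (spec, seed).

#' A 3-D intensity volume
#'
#' @param data numeric array `[y, x, z]`, non-negative finite.
#' @param lateral_pitch um per voxel in x and y.
#' @param axial_pitch um per voxel in z.
#' @return object of class `volume`.
#' @export
volume <- function(data, lateral_pitch, axial_pitch = lateral_pitch) {
  stopifnot(is.array(data), all(is.finite(data)), all(data >= 0),
            lateral_pitch > 0, axial_pitch > 0)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1)
  structure(list(data = data, lateral_pitch = lateral_pitch,
                 axial_pitch = axial_pitch),
            class = "volume")
}

#' Bead-field specification
#'
#' @param bead_diameter bead diameter in um (0.5 for resolution phantoms,
#'   10 for brightness phantoms).
#' @param count number of beads.
#' @param amplitude peak intensity per bead.
#' @param extent_um c(x, y, z) volume extent in um.
#' @param lateral_pitch,axial_pitch voxel pitches in um (defaults 0.0542
#'   lateral, 0.27 axial, the bead-stack acquisition settings).
#' @param seed integer seed for bead placement.
#' @return object of class `bead_field_spec`.
#' @export
bead_field_spec <- function(bead_diameter = 0.5, count = 6, amplitude = 1,
                            extent_um = c(20, 20, 10),
                            lateral_pitch = 0.0542, axial_pitch = 0.27,
                            seed = 1) {
  stopifnot(bead_diameter > 0, count >= 0, amplitude > 0,
            length(extent_um) == 3, all(extent_um > 0))
  structure(as.list(environment()), class = "bead_field_spec")
}

#' Rasterize a field of fluorescent beads
#'
#' Beads are solid spheres with anti-aliased (linearly ramped) edges, placed
#' uniformly at random, fully inside the volume and with centre separation
#' at least two diameters. Placement uses rejection sampling.
#'
#' @param spec a [bead_field_spec()].
#' @return list with `vol` (a [volume()]) and `centers` (count x 3 matrix,
#'   um, x/y/z from the volume corner).
#' @export
make_beads <- function(spec) {
  stopifnot(inherits(spec, "bead_field_spec"))
  nx <- max(1L, round(spec$extent_um[1] / spec$lateral_pitch))
  ny <- max(1L, round(spec$extent_um[2] / spec$lateral_pitch))
  nz <- max(1L, round(spec$extent_um[3] / spec$axial_pitch))
  vol <- array(0, c(ny, nx, nz))
  centers <- matrix(numeric(0), 0, 3)
  if (spec$count > 0) {
    rad <- spec$bead_diameter / 2
    lo <- c(rad, rad, rad)
    hi <- spec$extent_um - rad
    if (any(hi <= lo)) stop("beads do not fit inside the volume")
    centers <- with_seed(derive_seed(spec$seed, "beads"), {
      acc <- matrix(NA_real_, spec$count, 3)
      placed <- 0; tries <- 0
      while (placed < spec$count) {
        tries <- tries + 1
        if (tries > 1e4) stop("bead density too high: separation constraint unsatisfiable after 10000 attempts")
        cand <- stats::runif(3, lo, hi)
        if (placed == 0 ||
            min(sqrt(rowSums((acc[seq_len(placed), , drop = FALSE] -
                                matrix(cand, placed, 3, byrow = TRUE))^2))) >= 2 * spec$bead_diameter) {
          placed <- placed + 1
          acc[placed, ] <- cand
        }
      }
      acc
    })
    for (i in seq_len(spec$count))
      vol <- add_sphere(vol, centers[i, ], rad, spec$amplitude,
                        spec$lateral_pitch, spec$axial_pitch)
  }
  list(vol = volume(vol, spec$lateral_pitch, spec$axial_pitch),
       centers = centers)
}

# Add an anti-aliased solid sphere; centre in um from the volume corner,
# voxel centres at (i - 0.5) * pitch. A sphere smaller than a voxel becomes
# a single-voxel impulse carrying the full integrated amplitude.
add_sphere <- function(vol, center, radius, amplitude, lp, ap) {
  d <- dim(vol)
  if (2 * radius < min(lp, ap)) {
    iy <- min(max(1L, ceiling(center[2] / lp)), d[1])
    ix <- min(max(1L, ceiling(center[1] / lp)), d[2])
    iz <- min(max(1L, ceiling(center[3] / ap)), d[3])
    vol[iy, ix, iz] <- vol[iy, ix, iz] +
      amplitude * (4 / 3 * pi * radius^3) / (lp * lp * ap)
    return(vol)
  }
  edge <- min(lp, ap)  # anti-aliasing ramp width: one voxel
  ix <- which(abs((seq_len(d[2]) - 0.5) * lp - center[1]) <= radius + edge)
  iy <- which(abs((seq_len(d[1]) - 0.5) * lp - center[2]) <= radius + edge)
  iz <- which(abs((seq_len(d[3]) - 0.5) * ap - center[3]) <= radius + edge)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  xs <- (ix - 0.5) * lp - center[1]
  ys <- (iy - 0.5) * lp - center[2]
  zs <- (iz - 0.5) * ap - center[3]
  for (k in seq_along(iz)) {
    r2d <- sqrt(outer(ys^2, xs^2, "+") + zs[k]^2)
    w <- pmin(1, pmax(0, (radius + edge / 2 - r2d) / edge))
    vol[iy, ix, iz[k]] <- vol[iy, ix, iz[k]] + amplitude * w
  }
  vol
}

#' Pollen-like calibration phantom
#'
#' A spiky ball: a bright sphere with cosine-lobed surface spikes, the
#' desk-scale stand-in for the pollen grains used to calibrate wavefront
#' correction. Returned as a 2-D focal-plane scene (the calibration metric
#' integrates over the focal plane).
#'
#' @param radius_um ball radius (default 15, pollen-grain scale).
#' @param n_spikes number of surface spikes.
#' @param extent_um scene side length in um.
#' @param pitch_um pixel pitch in um.
#' @param amplitude peak intensity.
#' @param seed integer seed for spike placement.
#' @return a 2-D matrix scene plus attributes `pitch_um`.
#' @export
make_pollen <- function(radius_um = 15, n_spikes = 24, extent_um = 60,
                        pitch_um = 0.5, amplitude = 1, seed = 1) {
  n <- round(extent_um / pitch_um)
  ax <- (seq_len(n) - 0.5) * pitch_um - extent_um / 2
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  spikes <- with_seed(derive_seed(seed, "pollen"), {
    list(ang = stats::runif(n_spikes, 0, 2 * pi),
         len = stats::runif(n_spikes, 0.15, 0.35) * radius_um)
  })
  rim <- radius_um * (1 + 0 * th)
  for (i in seq_len(n_spikes)) {
    dth <- (th - spikes$ang[i] + pi) %% (2 * pi) - pi
    rim <- rim + spikes$len[i] * exp(-(dth / 0.12)^2)
  }
  img <- amplitude * pmin(1, pmax(0, (rim - r) / pitch_um + 0.5))
  img <- img * (0.6 + 0.4 * exp(-(r / radius_um)^2))  # brighter core
  attr(img, "pitch_um") <- pitch_um
  img
}

#' Neuron-scene specification
#'
#' @param n_somata number of cell bodies.
#' @param soma_radius_um range (min, max) of soma radii.
#' @param n_dendrites number of dendritic segments.
#' @param spine_density spine bumps per um of dendrite.
#' @param neuropil_level diffuse background intensity relative to soma
#'   amplitude 1.
#' @param extent_um scene side in um.
#' @param pitch_um pixel pitch in um.
#' @param seed integer seed.
#' @return object of class `neuron_scene_spec`.
#' @export
neuron_scene_spec <- function(n_somata = 8, soma_radius_um = c(5, 8),
                              n_dendrites = 6, spine_density = 0.4,
                              neuropil_level = 0.15, extent_um = 200,
                              pitch_um = 1, seed = 1) {
  stopifnot(n_somata >= 0, n_dendrites >= 0, neuropil_level >= 0)
  structure(as.list(environment()), class = "neuron_scene_spec")
}

#' Render a neuron scene with ground-truth masks
#'
#' Somata are bright disks, dendrites are thin bright segments decorated
#' with spine bumps, and the neuropil is a smooth dim background. The
#' labelled masks (`0` background/neuropil, `1..n` somata) are returned
#' alongside, standing in for an external segmentation.
#'
#' @param spec a [neuron_scene_spec()].
#' @return list with `img` (2-D matrix), `soma_mask` (integer matrix, 0 =
#'   not soma), `soma_centers` (n x 2, um), `pitch_um`.
#' @export
make_neuron_scene <- function(spec) {
  stopifnot(inherits(spec, "neuron_scene_spec"))
  n <- round(spec$extent_um / spec$pitch_um)
  ax <- (seq_len(n) - 0.5) * spec$pitch_um
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  img <- matrix(0, n, n)
  mask <- matrix(0L, n, n)
  centers <- matrix(numeric(0), 0, 2)
  gen <- with_seed(derive_seed(spec$seed, "neuron_scene"), {
    sc <- if (spec$n_somata > 0)
      cbind(stats::runif(spec$n_somata, 0.12, 0.88) * spec$extent_um,
            stats::runif(spec$n_somata, 0.12, 0.88) * spec$extent_um)
    else matrix(numeric(0), 0, 2)
    sr <- if (spec$n_somata > 0)
      stats::runif(spec$n_somata, spec$soma_radius_um[1], spec$soma_radius_um[2])
    else numeric(0)
    sa <- if (spec$n_somata > 0) stats::runif(spec$n_somata, 0.7, 1.0) else numeric(0)
    dd <- if (spec$n_dendrites > 0) lapply(seq_len(spec$n_dendrites), function(i) {
      p0 <- stats::runif(2, 0.1, 0.9) * spec$extent_um
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.2, 0.5) * spec$extent_um
      nsp <- stats::rpois(1, spec$spine_density * len)
      list(p0 = p0, ang = ang, len = len,
           spine_t = stats::runif(max(0, nsp), 0, 1))
    }) else list()
    # smooth neuropil texture
    np <- matrix(stats::runif(16), 4, 4)
    list(sc = sc, sr = sr, sa = sa, dd = dd, np = np)
  })
  # neuropil: bilinear upsample of a coarse random field
  if (spec$neuropil_level > 0) {
    gx <- seq(1, 4, length.out = n)
    npil <- matrix(0, n, n)
    i0 <- pmin(3, floor(gx)); fr <- gx - i0
    rowi <- outer(i0, rep(1, n)); rowf <- outer(fr, rep(1, n))
    coli <- t(rowi); colf <- t(rowf)
    for (a in 0:1) for (b in 0:1) {
      w <- (a * rowf + (1 - a) * (1 - rowf)) * (b * colf + (1 - b) * (1 - colf))
      npil <- npil + w * gen$np[cbind(as.vector(rowi + a), as.vector(coli + b))]
    }
    img <- img + spec$neuropil_level * (0.5 + 0.5 * npil)
  }
  for (d in gen$dd) {
    p1 <- d$p0 + d$len * c(cos(d$ang), sin(d$ang))
    # distance from each pixel to the segment
    vx <- p1[1] - d$p0[1]; vy <- p1[2] - d$p0[2]
    tt <- pmin(1, pmax(0, ((X - d$p0[1]) * vx + (Y - d$p0[2]) * vy) / (vx^2 + vy^2)))
    dist <- sqrt((X - (d$p0[1] + tt * vx))^2 + (Y - (d$p0[2] + tt * vy))^2)
    img <- img + 0.5 * exp(-(dist / 0.8)^2)
    for (t0 in d$spine_t) {
      sp <- d$p0 + t0 * c(vx, vy) + 1.5 * c(-sin(d$ang), cos(d$ang))
      dist_s <- sqrt((X - sp[1])^2 + (Y - sp[2])^2)
      img <- img + 0.6 * exp(-(dist_s / 0.6)^2)
    }
  }
  if (spec$n_somata > 0) {
    for (i in seq_len(spec$n_somata)) {
      dist <- sqrt((X - gen$sc[i, 1])^2 + (Y - gen$sc[i, 2])^2)
      disk <- pmin(1, pmax(0, (gen$sr[i] - dist) / spec$pitch_um + 0.5))
      img <- img + gen$sa[i] * disk
      mask[dist <= gen$sr[i]] <- i
    }
    centers <- gen$sc
  }
  list(img = img, soma_mask = mask, soma_centers = centers,
       pitch_um = spec$pitch_um)
}

#' Calcium-movie specification
#'
#' Defaults follow the in-vivo ROI acquisition conditions: 15 Hz for 300 s.
#'
#' @param n_cells number of cells.
#' @param frame_rate_hz acquisition rate (default 15).
#' @param duration_s recording length (default 300).
#' @param spike_rate_hz Poisson firing rate per cell (default 0.2).
#' @param tau_decay_s calcium-kernel exponential decay constant (default
#'   1.5, GCaMP6s-like).
#' @param dff_amplitude fractional fluorescence jump per spike (default 1).
#' @param neuropil_fraction contamination fraction of neuropil added to the
#'   measured cell signal (default 0.3).
#' @param baseline cell baseline fluorescence (photons/frame scale).
#' @param neuropil_level neuropil fluorescence level.
#' @param photon_gain photons per fluorescence unit for Poisson noise;
#'   `NA` disables noise.
#' @param img_size movie frame side in pixels.
#' @param pitch_um pixel pitch in um.
#' @param seed integer seed.
#' @return object of class `calcium_movie_spec`.
#' @export
calcium_movie_spec <- function(n_cells = 10, frame_rate_hz = 15,
                               duration_s = 300, spike_rate_hz = 0.2,
                               tau_decay_s = 1.5, dff_amplitude = 1,
                               neuropil_fraction = 0.3, baseline = 50,
                               neuropil_level = 20, photon_gain = 1,
                               img_size = 64, pitch_um = 2, seed = 1) {
  stopifnot(n_cells >= 0, frame_rate_hz > 0, duration_s > 0,
            spike_rate_hz >= 0, tau_decay_s > 0, baseline > 0)
  structure(as.list(environment()), class = "calcium_movie_spec")
}

#' Generate a synthetic calcium movie with ground truth
#'
#' Per-cell fluorescence is `baseline * (1 + dff_amplitude * c(t))` with
#' `c(t)` the spike train convolved with a single-exponential decay kernel;
#' the measured cell trace adds `neuropil_fraction` of the neuropil signal,
#' matching the contamination model the 0.7-subtraction is designed to
#' remove. Poisson photon noise is applied per pixel when `photon_gain` is
#' finite. Ground-truth spike times, clean traces, and ROI/neuropil masks
#' are returned.
#'
#' @param spec a [calcium_movie_spec()].
#' @param signal_scale multiplicative factor on all fluorescence (e.g. the
#'   relative two-photon collection efficiency of an imaging mode).
#' @return list with `movie` (array `[y, x, t]`), `cell_masks` (integer
#'   matrix), `neuropil_mask` (logical matrix), `true_dff` (frames x cells),
#'   `spike_times` (list of numeric vectors, s), `cell_traces`,
#'   `neuropil_trace`, `frame_rate_hz`.
#' @export
make_calcium_movie <- function(spec, signal_scale = 1) {
  stopifnot(inherits(spec, "calcium_movie_spec"), signal_scale > 0)
  n_frames <- round(spec$frame_rate_hz * spec$duration_s)
  n <- spec$img_size
  tt <- (seq_len(n_frames) - 1) / spec$frame_rate_hz

  gen <- with_seed(derive_seed(spec$seed, "calcium"), {
    # cell centres on a jittered grid so masks never overlap
    ngrid <- ceiling(sqrt(max(1, spec$n_cells)))
    cell_r <- max(2, floor(n / (ngrid * 4)))
    step <- n / ngrid
    ctr <- expand.grid(gx = seq_len(ngrid), gy = seq_len(ngrid))[seq_len(spec$n_cells), , drop = FALSE]
    cx <- (ctr$gx - 0.5) * step + stats::runif(spec$n_cells, -step / 8, step / 8)
    cy <- (ctr$gy - 0.5) * step + stats::runif(spec$n_cells, -step / 8, step / 8)
    spikes <- lapply(seq_len(spec$n_cells), function(i) {
      k <- stats::rpois(1, spec$spike_rate_hz * spec$duration_s)
      sort(stats::runif(k, 0, spec$duration_s))
    })
    noise_seed <- stats::runif(1)
    list(cx = cx, cy = cy, cell_r = cell_r, spikes = spikes)
  })

  # kernel-convolved spike trains (exact exponential between frames)
  true_dff <- matrix(0, n_frames, max(1, spec$n_cells))
  for (i in seq_len(spec$n_cells)) {
    c_t <- numeric(n_frames)
    for (s in gen$spikes[[i]])
      c_t <- c_t + ifelse(tt >= s, exp(-(tt - s) / spec$tau_decay_s), 0)
    true_dff[, i] <- spec$dff_amplitude * c_t
  }

  cell_f <- spec$baseline * (1 + true_dff) * signal_scale     # frames x cells
  neu_f <- rep(spec$neuropil_level * signal_scale, n_frames)  # shared neuropil

  # masks
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  cell_masks <- matrix(0L, n, n)
  for (i in seq_len(spec$n_cells))
    cell_masks[(xg - gen$cx[i])^2 + (yg - gen$cy[i])^2 <= gen$cell_r^2] <- i
  neuropil_mask <- cell_masks == 0L

  movie <- array(0, c(n, n, n_frames))
  base_img <- matrix(spec$neuropil_level * signal_scale, n, n)
  for (f in seq_len(n_frames)) {
    img <- base_img
    for (i in seq_len(spec$n_cells)) {
      sel <- cell_masks == i
      # measured cell pixels carry the cell signal plus neuropil contamination
      img[sel] <- cell_f[f, i] + spec$neuropil_fraction * neu_f[f]
    }
    movie[, , f] <- img
  }
  if (is.finite(spec$photon_gain)) {
    movie <- with_seed(derive_seed(spec$seed, "calcium_noise"), {
      array(stats::rpois(length(movie), movie * spec$photon_gain) / spec$photon_gain,
            dim(movie))
    })
  }
  list(movie = movie, cell_masks = cell_masks, neuropil_mask = neuropil_mask,
       true_dff = true_dff[, seq_len(spec$n_cells), drop = FALSE],
       spike_times = gen$spikes,
       cell_traces = cell_f, neuropil_trace = neu_f,
       frame_rate_hz = spec$frame_rate_hz)
}

#' Extract cell and neuropil traces from a movie using masks
#'
#' @param movie array `[y, x, t]`.
#' @param cell_masks integer matrix (0 = no cell).
#' @param neuropil_mask logical matrix.
#' @return list of `trace_set` objects (one per cell), each with `f_cell`
#'   and `f_neu`.
#' @export
extract_traces <- function(movie, cell_masks, neuropil_mask) {
  n_cells <- max(cell_masks)
  n_frames <- dim(movie)[3]
  flat <- matrix(movie, ncol = n_frames)
  neu <- colMeans(flat[as.vector(neuropil_mask), , drop = FALSE])
  lapply(seq_len(n_cells), function(i) {
    sel <- as.vector(cell_masks == i)
    trace_set(colMeans(flat[sel, , drop = FALSE]), neu)
  })
}

#' Write a volume or movie as multi-page TIFF
#'
#' @param x a [volume()] or a 3-D array.
#' @param path output path.
#' @return `path`, invisibly. Values are scaled into `[0, 1]`; the scale is
#'   recorded in a `<path>.txt` sidecar.
#' @export
write_volume_tiff <- function(x, path) {
  data <- if (inherits(x, "volume")) x$data else x
  mx <- max(data, 1e-12)
  pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(sprintf("intensity_scale\t%.10g", mx), paste0(path, ".txt"))
  invisible(path)
}
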