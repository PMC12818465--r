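# Sensorless modal wavefront calibration: for each Zernike term in turn,
# sweep the coefficient over a fixed grid while recording a fluorescence
# metric, repeat the sweep over several cycles, and average the per-cycle
# argmax values. Rounds of full-term passes repeat, with shrinking sweep
# ranges, until the metric gain stalls.

#' Calibration configuration
#'
#' @param n_terms highest Noll term optimized (default 15 at desk scale;
#'   200 is supported at full scale). Terms 1-3 (piston/tip/tilt) are never
#'   swept: piston leaves the two-photon signal unchanged and tip/tilt only
#'   translate the field.
#' @param cycles_per_term sweep repetitions per term (default 5).
#' @param steps_per_cycle metric evaluations per sweep (default 21; must be
#'   odd so the current value is a grid point).
#' @param rounds_min,rounds_max bounds on full-term rounds (defaults 4, 8).
#' @param first_half_range half-range of the round-1 sweep in wavelengths
#'   (default 0.5); shrunk by a factor 1.5 after every round whose term
#'   updates stay interior to the sweep window (a railed update keeps the
#'   range, since the optimum is still out of reach).
#' @param convergence_threshold relative metric gain per round below which
#'   (once `rounds_min` is reached) calibration stops (default 0.01).
#' @param metric `"total"` (plane-integrated fluorescence, noise-robust
#'   default) or `"peak"` (image maximum).
#' @param metric_noise_sd multiplicative Gaussian noise sigma applied to
#'   each metric evaluation (default 0 = noiseless).
#' @param stroke_limit DM stroke bound in wavelengths (default 30).
#' @param seed integer seed for metric noise.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(n_terms = 15, cycles_per_term = 5,
                               steps_per_cycle = 21, rounds_min = 4,
                               rounds_max = 8, first_half_range = 0.5,
                               convergence_threshold = 0.01,
                               metric = c("total", "peak"),
                               metric_noise_sd = 0, stroke_limit = 30,
                               seed = 1) {
  metric <- match.arg(metric)
  if (steps_per_cycle %% 2 != 1) stop("steps_per_cycle must be odd")
  if (rounds_min > rounds_max) stop("rounds_min must be <= rounds_max")
  stopifnot(n_terms >= 4, cycles_per_term >= 1, first_half_range > 0,
            metric_noise_sd >= 0)
  structure(as.list(environment()), class = "calibration_config")
}

#' One sequential sweep of a single Zernike term
#'
#' Evaluates `metric_fn` at `steps_per_cycle` equally spaced coefficient
#' values in `[current_j - half_range, current_j + half_range]` (all other
#' terms held fixed), takes the argmax coefficient, repeats for
#' `cycles_per_term` cycles, and returns the mean of the per-cycle argmax
#' values. Metric ties go to the first (lowest) grid value.
#'
#' @param metric_fn function(coefficient vector) -> scalar metric.
#' @param j Noll index of the term swept.
#' @param current current coefficient vector (wavelengths).
#' @param half_range sweep half-range in wavelengths (> 0).
#' @param config a [calibration_config()].
#' @param deterministic set `TRUE` when `metric_fn` is noiseless: the five
#'   cycles then evaluate identically, so the first cycle's values are
#'   reused (same result, fewer evaluations).
#' @return the updated coefficient for term `j` (scalar).
#' @export
sweep_term <- function(metric_fn, j, current, half_range,
                       config = calibration_config(), deterministic = FALSE) {
  stopifnot(half_range > 0, j >= 1, j <= length(current))
  grid <- seq(current[j] - half_range, current[j] + half_range,
              length.out = config$steps_per_cycle)
  peaks <- numeric(config$cycles_per_term)
  vals <- NULL
  for (cy in seq_len(config$cycles_per_term)) {
    if (is.null(vals) || !deterministic) {
      vals <- vapply(grid, function(g) {
        cc <- current; cc[j] <- g
        m <- metric_fn(cc)
        if (!is.finite(m))
          stop(sprintf("non-finite metric at term %d, coefficient %.4f", j, g))
        m
      }, numeric(1))
    }
    peaks[cy] <- grid[which.max(vals)]
  }
  mean(peaks)
}

#' Build the fluorescence metric for a calibration phantom at a position
#'
#' The metric is the simulated fluorescence of the phantom imaged through
#' the system with residual aberration `truth(position) + dm`. For the
#' `"total"` metric the image integral factorizes into
#' `sum(phantom) * sum(focal-plane two-photon PSF)`, so it is evaluated
#' without an explicit convolution; `"peak"` renders the scene.
#'
#' @param simulator an [optics_simulator()].
#' @param position object-plane position (um) of the phantom.
#' @param config a [calibration_config()].
#' @return function(dm coefficient vector) -> scalar metric.
#' @export
calibration_metric <- function(simulator, position, config = calibration_config()) {
  truth <- truth_coeffs(simulator$field, position)
  pupil <- simulator$pupil
  noisy <- config$metric_noise_sd > 0
  rng_seed <- derive_seed(config$seed, sprintf("metric_%g_%g", position[1], position[2]))
  noise_i <- 0
  fast_total <- if (config$metric == "total")
    fast_plane_signal(pupil_repad(pupil, 2)) else NULL
  function(dm_coeffs) {
    res <- residual(truth, dm_coeffs)
    base <- if (config$metric == "total") {
      fast_total(res)
    } else {
      img <- render_scene(simulator$phantom, attr(simulator$phantom, "pitch_um"),
                          pupil, res)
      max(img)
    }
    if (noisy) {
      noise_i <<- noise_i + 1
      base * (1 + with_seed(rng_seed + noise_i, stats::rnorm(1, 0, config$metric_noise_sd)))
    } else base
  }
}

# Precomputed evaluator of the plane-integrated two-photon signal for many
# coefficient vectors against one pupil: identical values to
# tp_plane_signal(), organized for the sweep loop's call volume.
fast_plane_signal <- function(pupil) {
  n <- pupil$n_fft
  sub <- which(pupil$mask, arr.ind = TRUE)
  i0 <- (n - pupil$grid_size) %/% 2
  lin_idx <- (sub[, 2] + i0 - 1) * n + (sub[, 1] + i0)
  template <- matrix(0 + 0i, n, n)
  ref <- .plane_signal_ref(pupil)
  basis_env <- new.env(parent = emptyenv())
  function(coeffs) {
    key <- as.character(length(coeffs))
    B <- basis_env[[key]]
    if (is.null(B)) {
      B <- pupil_basis(pupil, length(coeffs))
      basis_env[[key]] <- B
    }
    ph <- 2 * pi * as.vector(B %*% coeffs)
    P <- template
    P[lin_idx] <- complex(real = cos(ph), imaginary = sin(ph))
    h <- stats::fft(P)
    re <- Re(h); im <- Im(h)
    sum((re * re + im * im)^2) / ref
  }
}

#' Calibrate one correction point
#'
#' Runs rounds of sequential single-term sweeps (Noll 4..n_terms) against
#' the fluorescence metric at the given position. The sweep half-range
#' starts at `first_half_range` and is halved each round. Calibration stops
#' once the relative round-over-round metric gain falls below the threshold
#' (after at least `rounds_min` rounds) or at `rounds_max`. The returned
#' coefficients are stroke-clipped.
#'
#' @param simulator an [optics_simulator()].
#' @param position length-2 numeric, object-plane um.
#' @param config a [calibration_config()].
#' @return object of class `calibration_result`: `coeffs` (wavelengths),
#'   `metric_trace` (per-round best metric), `rounds`, `converged`.
#' @export
calibrate_point <- function(simulator, position, config = calibration_config()) {
  metric_fn <- calibration_metric(simulator, position, config)
  deterministic <- config$metric_noise_sd == 0
  coeffs <- numeric(config$n_terms)
  trace <- numeric(0)
  m_prev <- metric_fn(coeffs)
  converged <- FALSE
  rounds <- 0
  hr <- config$first_half_range
  for (r in seq_len(config$rounds_max)) {
    rounds <- r
    m_start <- metric_fn(coeffs)
    edge_frac <- 0
    for (j in 4:config$n_terms) {
      old_j <- coeffs[j]
      coeffs[j] <- sweep_term(metric_fn, j, coeffs, hr, config,
                              deterministic = deterministic)
      edge_frac <- max(edge_frac, abs(coeffs[j] - old_j) / hr)
      m_now <- metric_fn(coeffs)
      if (m_now < 0.8 * m_start)
        stop(sprintf(
          "calibration runaway at position (%.0f, %.0f), round %d, term %d: metric fell %.1f%% below the round start",
          position[1], position[2], r, j, 100 * (1 - m_now / m_start)))
    }
    m_round <- metric_fn(coeffs)
    trace <- c(trace, m_round)
    gain <- (m_round - m_prev) / abs(m_prev)
    m_prev <- m_round
    if (r >= config$rounds_min && gain < config$convergence_threshold) {
      converged <- TRUE
      break
    }
    # shrink the sweep range only once the round's updates stay interior to
    # the window; a railed term means the optimum is still out of reach, and
    # a gentle factor keeps pace with coupled terms that move diagonally
    if (edge_frac < 0.9) hr <- hr / 1.5
  }
  dm <- clip_stroke(dm_state(coeffs, config$stroke_limit))
  structure(list(coeffs = dm$coeffs, metric_trace = trace,
                 rounds = rounds, converged = converged,
                 position = position),
            class = "calibration_result")
}

#' Calibrate every point of a correction grid
#'
#' Independent [calibrate_point()] runs in grid-index order.
#'
#' @param simulator an [optics_simulator()].
#' @param grid a [build_correction_grid()] result.
#' @param config a [calibration_config()].
#' @param indices optional subset of point indices to calibrate (others are
#'   left `NA`); by default all points.
#' @return object of class `calibration_table`: matrix (points x n_terms) of
#'   coefficients plus the grid.
#' @export
calibrate_grid <- function(simulator, grid, config = calibration_config(),
                           indices = NULL) {
  stopifnot(inherits(grid, "correction_grid"))
  n <- nrow(grid$points)
  if (is.null(indices)) indices <- seq_len(n)
  tab <- matrix(NA_real_, n, config$n_terms)
  for (i in indices) {
    res <- tryCatch(
      calibrate_point(simulator, grid$points[i, ], config),
      error = function(e) stop(sprintf("calibration failed at grid point %d: %s",
                                       i, conditionMessage(e))))
    tab[i, ] <- res$coeffs
  }
  structure(list(coeffs = tab, grid = grid, n_terms = config$n_terms),
            class = "calibration_table")
}

#' Write / read a calibration table as tab-separated text
#'
#' Columns: point index (0-based), x_um, y_um, then the coefficients
#' `c1..cJ` in wavelengths.
#'
#' @param table a `calibration_table`.
#' @param path file path.
#' @return `write_calib_tsv` returns `path` invisibly; `read_calib_tsv`
#'   returns a `calibration_table` (without the grid geometry metadata
#'   beyond point coordinates).
#' @export
write_calib_tsv <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cmatsim calibration table",
               sprintf("# n_terms=%d", table$n_terms),
               paste0("# index\tx_um\ty_um\t",
                      paste(sprintf("c%d", seq_len(table$n_terms)), collapse = "\t"))),
             con)
  df <- data.frame(index = seq_len(nrow(table$coeffs)) - 1L,
                   x_um = table$grid$points[, 1],
                   y_um = table$grid$points[, 2])
  df <- cbind(df, as.data.frame(table$coeffs))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_calib_tsv
#' @param grid optionally, the `correction_grid` the table belongs to.
#' @export
read_calib_tsv <- function(path, grid = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t")
  df <- df[order(df[, 1]), ]
  coeffs <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(coeffs) <- NULL
  if (is.null(grid)) {
    grid <- structure(list(points = unname(as.matrix(df[, 2:3])),
                           kind = rep(NA_character_, nrow(df)),
                           side = NA_real_, effective_radius = NA_real_,
                           inclusion_radius = NA_real_, fov_diameter = NA_real_),
                      class = "correction_grid")
  }
  structure(list(coeffs = coeffs, grid = grid, n_terms = ncol(coeffs)),
            class = "calibration_table")
}
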