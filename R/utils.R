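#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a in doubles (R has no unsigned 32-bit integer type).
fnv_hash <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two non-negative doubles interpreted as 32-bit unsigned ints
xor32 <- function(a, b) {
  r <- 0; p <- 1
  for (i in 1:32) {
    r <- r + p * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2; b <- b %/% 2; p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic components (phantoms, calibration noise, rendering noise)
#' draw their seeds from one master seed through named streams, so that a
#' single integer reproduces an entire run.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"phantom"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(name))
  h <- fnv_hash(paste0(name, ":", format(master, scientific = FALSE)))
  as.integer(h %% 2147483647)
}

#' Hash a configuration (or any R list) to a short provenance tag
#'
#' @param x an R object (typically a run configuration list).
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- fnv_hash(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

cmat_log <- function(...) message("[cmatsim] ", ...)
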