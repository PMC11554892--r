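# Shared small utilities: unit conversions, logging, config.

# 1 mmHg in kPa
.KPA_PER_MMHG <- 0.1333224

mmhg_to_kpa <- function(p) p * .KPA_PER_MMHG
kpa_to_mmhg <- function(p) p / .KPA_PER_MMHG

#' Run configuration
#'
#' Bundles the reproducibility-critical settings shared by the simulation
#' pipeline: the random seed (every stochastic step in the package draws from
#' it), the mechanics time step, the number of beats simulated to reach the
#' limit cycle, and the target mesh edge length.
#'
#' @param seed integer seed controlling all randomness.
#' @param dt time step for the mechanics phase machine (s).
#' @param n_beats number of cardiac cycles chained before the analysed beat.
#' @param mesh_h target mesh edge length (mm).
#' @param log_level one of "quiet", "info", "debug".
#' @return An object of class `crt_config`.
#' @export
run_config <- function(seed = 1L, dt = 1e-4, n_beats = 5L, mesh_h = 3,
                       log_level = "quiet") {
  stopifnot(dt > 0, n_beats >= 1, mesh_h > 0)
  structure(list(seed = as.integer(seed), dt = dt, n_beats = as.integer(n_beats),
                 mesh_h = mesh_h, log_level = match.arg(log_level, c("quiet", "info", "debug"))),
            class = "crt_config")
}

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "quiet"

#' Set package logging level
#' @param level "quiet", "info" or "debug".
#' @export
crt_log_level <- function(level = c("quiet", "info", "debug")) {
  .log_env$level <- match.arg(level)
  invisible(.log_env$level)
}

crt_log <- function(..., level = "info") {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[.log_env$level]] >= lv[[level]]) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
  }
  invisible(NULL)
}

# Row-wise cross product of n x 3 matrices
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowdot <- function(a, b) rowSums(a * b)

rownorm <- function(a) sqrt(rowSums(a * a))

rowunit <- function(a) a / pmax(rownorm(a), .Machine$double.eps)

# Symmetric 3x3 tensors stored as n x 6 matrices [11,22,33,12,13,23].
# Multiply each tensor by the matching row of v (n x 3).
sym3_mv <- function(S, v) {
  cbind(S[, 1] * v[, 1] + S[, 4] * v[, 2] + S[, 5] * v[, 3],
        S[, 4] * v[, 1] + S[, 2] * v[, 2] + S[, 6] * v[, 3],
        S[, 5] * v[, 1] + S[, 6] * v[, 2] + S[, 3] * v[, 3])
}

# Closed-form inverse of symmetric 3x3 tensors in n x 6 packed form.
sym3_inv <- function(S) {
  a <- S[, 1]; b <- S[, 2]; c <- S[, 3]; d <- S[, 4]; e <- S[, 5]; f <- S[, 6]
  A <- b * c - f * f
  B <- e * f - d * c
  C <- d * f - b * e
  det <- a * A + d * B + e * C
  cbind(A, a * c - e * e, a * b - d * d,
        B, C, d * e - a * f) / det
}

# Quadratic roots a x^2 - 2 b x + c = 0, vectorized; returns larger root (NA when
# complex or degenerate).
quad_larger_root <- function(a, b, c) {
  disc <- b * b - a * c
  out <- rep(NA_real_, length(a))
  ok <- is.finite(disc) & disc >= 0 & a > 0
  out[ok] <- (b[ok] + sqrt(disc[ok])) / a[ok]
  out
}
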