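#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a root seed
#'
#' One root seed drives a whole simulation; per-cell (and per-stage) child
#' seeds are derived deterministically so cells are independent but the whole
#' run is reproducible from a single integer.
#'
#' @param root integer root seed
#' @param index positive integer stream index (cell number, stage, ...)
#' @return an integer seed in [1, 2^31 - 2]
#' @export
child_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1L, is.numeric(index))
  # affine hash mod a Mersenne prime; keeps results in 32-bit integer range
  s <- (as.double(root) * 48271 + as.double(index) * 16807 + 11) %% 2147483647
  as.integer(s) + 1L
}

stop_if_not_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive", what), call. = FALSE)
  }
  invisible(x)
}

vec_norm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Unsigned acute angle between two vectors, in degrees
#' @keywords internal
acute_angle_deg <- function(u, v) {
  cu <- abs(sum(u * v)) / (vec_norm(u) * vec_norm(v))
  cu <- min(1, max(0, cu))
  acos(cu) * 180 / pi
}

# truncated normal draw (simple rejection-free clamp at quantile bounds)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(upper, pmax(lower, x))
}
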