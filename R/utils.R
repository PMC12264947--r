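# Shared internal helpers.

#' @importFrom rlang %||% abort warn
#' @importFrom Rcpp sourceCpp
#' @useDynLib ensembledecomp, .registration = TRUE
NULL

# round-half-up to the nearest integer (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

abort_ed <- function(message, kind, ...) {
  abort(message, class = c(paste0("ensembledecomp_error_", kind), "ensembledecomp_error"), ...)
}

check_finite <- function(x, what, kind = "invalid_input") {
  if (!all(is.finite(x))) {
    abort_ed(sprintf("`%s` must contain only finite values.", what), kind)
  }
  invisible(x)
}

check_scalar_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_ed(sprintf("`%s` must be a single finite number.", what), "parameter")
  }
  if (positive && x <= 0) {
    abort_ed(sprintf("`%s` must be positive.", what), "parameter")
  }
  invisible(x)
}

# cross product of rows of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

rownorm <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) m / rownorm(m)

# quasi-uniform points on the unit sphere (golden-spiral construction);
# deterministic, so SASA values are reproducible across platforms
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# random rigid motion used by property tests and the medoid subsampler
random_rotation_matrix <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Boltzmann constant times Avogadro, kJ mol^-1 K^-1
KB_KJ_PER_MOL_K <- 0.008314462618
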