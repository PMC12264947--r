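# Scattering-curve post-processing and model comparison.

#' Rebin a scattering curve by joining consecutive points
#'
#' Non-overlapping blocks of `block` consecutive points are replaced by
#' their arithmetic means (q and intensity); uncertainties propagate as
#' \eqn{\sqrt{\sum \sigma^2} / n}. A trailing partial block is averaged
#' as-is.
#'
#' @param curve A [scatter_curve()].
#' @param block Points per block (default 10).
#' @return The rebinned [scatter_curve()].
#' @export
rebin_join <- function(curve, block = 10) {
  if (nrow(curve) == 0L) abort_ed("Empty curve.", "empty_input")
  if (block < 1L) abort_ed("`block` must be >= 1.", "parameter")
  if (block == 1L) return(curve)
  g <- (seq_len(nrow(curve)) - 1L) %/% block
  q <- as.numeric(tapply(curve$q, g, mean))
  intensity <- as.numeric(tapply(curve$intensity, g, mean))
  sigma <- NULL
  if ("sigma" %in% names(curve)) {
    sigma <- as.numeric(tapply(curve$sigma, g, function(s) sqrt(sum(s^2)) / length(s)))
  }
  scatter_curve(q, intensity, sigma = sigma, i0 = curve_i0(curve))
}

#' Normalize a scattering curve
#'
#' Either by the zero-angle intensity I(0) (taken from the curve's `i0`
#' attribute or supplied) or by the interpolated intensity at a reference
#' q. Uncertainties scale identically.
#'
#' @param curve A [scatter_curve()].
#' @param mode `"at_i0"` or `"at_q"`.
#' @param q_ref Reference q (1/Angstrom) for `mode = "at_q"`.
#' @param i0 Zero-angle intensity for `mode = "at_i0"`; defaults to the
#'   curve's `i0` attribute (set by [guinier_rg()]).
#' @return The normalized [scatter_curve()] (its `i0` becomes 1 for
#'   `"at_i0"`).
#' @export
normalize_curve <- function(curve, mode = c("at_i0", "at_q"), q_ref = NULL,
                            i0 = NULL) {
  mode <- match.arg(mode)
  if (mode == "at_i0") {
    i0 <- i0 %||% curve_i0(curve)
    if (is.null(i0)) {
      abort_ed("No I(0) available; run guinier_rg() first or pass `i0`.", "parameter")
    }
    scale <- i0
  } else {
    if (is.null(q_ref)) abort_ed("`q_ref` is required for mode 'at_q'.", "parameter")
    if (q_ref < min(curve$q) || q_ref > max(curve$q)) {
      abort_ed("`q_ref` lies outside the measured q range.", "range")
    }
    scale <- stats::approx(curve$q, curve$intensity, xout = q_ref)$y
  }
  scatter_curve(
    curve$q, curve$intensity / scale,
    sigma = if ("sigma" %in% names(curve)) curve$sigma / scale else NULL,
    i0 = if (mode == "at_i0") 1 else curve_i0(curve)
  )
}

#' Chi-squared between an experimental and a simulated curve
#'
#' The model-denominator statistic
#' \deqn{\chi^2 = \sum_{i=1}^{N} \frac{(E_i - S_i)^2}{S_i}}
#' over all N points, with no division by N and no measurement sigma in the
#' denominator. Both curves are assumed pre-normalized (see
#' [chi_squared_protocol()]) and must have identical point counts. A
#' conventional sigma-weighted reduced chi-squared is available as a
#' clearly separate variant.
#'
#' @param experimental,simulated [scatter_curve()]s with equal point
#'   counts.
#' @param variant `"model_denominator"` (default) or `"sigma_reduced"`
#'   (\eqn{\sum ((E_i-S_i)/\sigma_i)^2 / (N-1)}, requires `sigma` on the
#'   experimental curve).
#' @return The dimensionless statistic.
#' @export
chi_squared <- function(experimental, simulated,
                        variant = c("model_denominator", "sigma_reduced")) {
  variant <- match.arg(variant)
  if (nrow(experimental) != nrow(simulated)) {
    abort_ed(
      sprintf(
        "Point counts differ (%d vs %d); the statistic assumes identical grids.",
        nrow(experimental), nrow(simulated)
      ),
      "alignment"
    )
  }
  e <- experimental$intensity
  s <- simulated$intensity
  if (variant == "model_denominator") {
    if (any(s <= 0)) abort_ed("Simulated intensities must be positive.", "division")
    sum((e - s)^2 / s)
  } else {
    if (!"sigma" %in% names(experimental)) {
      abort_ed("`sigma` required on the experimental curve for the reduced variant.", "parameter")
    }
    sum(((e - s) / experimental$sigma)^2) / (nrow(experimental) - 1L)
  }
}

#' Full chi-squared comparison protocol
#'
#' Both curves are normalized by their own I(0) (from a Guinier fit if not
#' already attached), the experimental curve is rebinned by joining every
#' `block` points, and the simulated curve is linearly interpolated onto
#' the rebinned grid so both have identical point counts; then
#' [chi_squared()] is applied.
#'
#' @param experimental,simulated [scatter_curve()]s.
#' @param block Rebinning block for the experimental curve (default 10).
#' @param qrg_limit Guinier qRg limit used when an I(0) must be fitted.
#' @return A list: `chi_squared`, `n_points`, `experimental`, `simulated`
#'   (the processed curves).
#' @export
chi_squared_protocol <- function(experimental, simulated, block = 10,
                                 qrg_limit = 1.1) {
  ensure_i0 <- function(curve) {
    if (is.null(curve_i0(curve))) {
      fit <- guinier_rg(curve, qrg_limit = qrg_limit)
      attr(curve, "i0") <- fit$i0
    }
    curve
  }
  e <- normalize_curve(ensure_i0(experimental), "at_i0")
  s <- normalize_curve(ensure_i0(simulated), "at_i0")
  e <- rebin_join(e, block)
  keep <- e$q >= min(s$q) & e$q <= max(s$q)
  e <- scatter_curve(e$q[keep], e$intensity[keep],
    sigma = if ("sigma" %in% names(e)) e$sigma[keep] else NULL, i0 = 1
  )
  s_interp <- scatter_curve(
    e$q, stats::approx(s$q, s$intensity, xout = e$q)$y,
    i0 = 1
  )
  list(
    chi_squared = chi_squared(e, s_interp),
    n_points = nrow(e),
    experimental = e,
    simulated = s_interp
  )
}

#' Guinier fit of the low-q region
#'
#' Iterative linear regression of \eqn{\ln I} on \eqn{q^2}: an initial
#' window of the `min_points` lowest-q points yields a first Rg; the window
#' is then grown/shrunk to \eqn{q \cdot R_g \le} `qrg_limit` and the fit
#' repeated until the window stabilizes. \eqn{R_g = \sqrt{-3 \,
#' \mathrm{slope}}}, \eqn{I(0) = e^{\mathrm{intercept}}}.
#'
#' @param curve A [scatter_curve()] with positive intensities at low q.
#' @param qrg_limit Largest allowed q*Rg in the fit window (default 1.1).
#' @param min_points Smallest usable window (default 5).
#' @param max_iter Window iteration cap (default 20).
#' @return A list of class `guinier_fit`: `rg` (Angstrom), `i0`,
#'   `fit_range` (q min/max used), `qrg_max` (the limit), `n_points`,
#'   `r_squared`, `residual_sd`, `converged`.
#' @export
guinier_rg <- function(curve, qrg_limit = 1.1, min_points = 5, max_iter = 20) {
  if (nrow(curve) < min_points) {
    abort_ed("Too few points for a Guinier fit.", "insufficient_data")
  }
  fit_window <- function(n) {
    q2 <- curve$q[seq_len(n)]^2
    intens <- curve$intensity[seq_len(n)]
    if (any(intens <= 0)) {
      abort_ed("Non-positive intensity inside the Guinier window.", "fit_failure")
    }
    stats::lm(log(intens) ~ q2)
  }
  n <- min_points
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- fit_window(n)
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) {
      abort_ed("Positive Guinier slope: no decaying low-q regime found.", "fit_failure")
    }
    rg <- sqrt(-3 * slope)
    n_new <- max(which(curve$q * rg <= qrg_limit))
    if (n_new < min_points) {
      abort_ed("Guinier window collapsed below the minimum point count.", "insufficient_data")
    }
    if (n_new == n) {
      converged <- TRUE
      break
    }
    n <- n_new
  }
  fit <- fit_window(n)
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) abort_ed("Positive Guinier slope after iteration.", "fit_failure")
  rg <- sqrt(-3 * slope)
  ss_res <- sum(stats::residuals(fit)^2)
  obs <- log(curve$intensity[seq_len(n)])
  ss_tot <- sum((obs - mean(obs))^2)
  structure(
    list(
      rg = rg,
      i0 = exp(stats::coef(fit)[[1]]),
      fit_range = c(q_min = curve$q[1], q_max = curve$q[n]),
      qrg_max = qrg_limit,
      n_points = n,
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
      residual_sd = sqrt(ss_res / max(n - 2L, 1L)),
      converged = converged
    ),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.2f A, I(0) = %.4g, %d points (q %.4g..%.4g, qRg <= %.2f)\n",
    x$rg, x$i0, x$n_points, x$fit_range[1], x$fit_range[2], x$qrg_max
  ))
  invisible(x)
}

#' Normalized Kratky transform
#'
#' \eqn{y = (qR_g)^2 \, I(q)/I(0)} against \eqn{x = qR_g}. For a purely
#' Guinier-shaped curve y peaks at \eqn{x = \sqrt{3}} with height
#' \eqn{3/e}; an ideal Gaussian chain plateaus toward 2; a rising high-q
#' tail signals disorder.
#'
#' @param curve A [scatter_curve()].
#' @param rg Radius of gyration (Angstrom), e.g. from [guinier_rg()].
#' @param i0 Zero-angle intensity; defaults to the curve's `i0` attribute.
#' @return A tibble with columns `qrg` and `kratky` (dimensionless).
#' @export
kratky_normalized <- function(curve, rg, i0 = NULL) {
  i0 <- i0 %||% curve_i0(curve)
  if (is.null(i0)) abort_ed("No I(0) available; pass `i0` or fit Guinier first.", "parameter")
  check_scalar_number(rg, "rg", positive = TRUE)
  check_scalar_number(i0, "i0", positive = TRUE)
  x <- curve$q * rg
  tibble::tibble(qrg = x, kratky = x^2 * curve$intensity / i0)
}

#' Debye-formula scattering from coordinates (unit form factors)
#'
#' \eqn{I(q) = \sum_i \sum_j \mathrm{sinc}(q\, r_{ij})} with unit form
#' factors, so \eqn{I(q \to 0) = N^2}. A toy model curve: no atomic form
#' factors and no hydration shell, but exact for testing Guinier recovery
#' and curve plumbing. For an ensemble the per-frame intensities are
#' averaged.
#'
#' @param x An `ensemble` or a single `n_atoms x 3` coordinate matrix
#'   (Angstrom).
#' @param q_grid Positive scattering vector values (1/Angstrom).
#' @param frames Optional frame subset when `x` is an ensemble.
#' @return A [scatter_curve()] with `i0` set to \eqn{N^2}.
#' @export
debye_scatter <- function(x, q_grid, frames = NULL) {
  check_finite(q_grid, "q_grid")
  if (any(q_grid <= 0)) abort_ed("`q_grid` must be positive.", "parameter")
  one_frame <- function(xyz) {
    d <- as.numeric(stats::dist(xyz))
    n <- nrow(xyz)
    vapply(q_grid, function(q) {
      qd <- q * d
      n + 2 * sum(ifelse(qd == 0, 1, sin(qd) / qd))
    }, 0)
  }
  if (inherits(x, "ensemble")) {
    frames <- check_frames(x, frames)
    intens <- Reduce(`+`, lapply(frames, function(f) one_frame(frame_coords(x, f)))) /
      length(frames)
    n_at <- x$n_atoms
  } else {
    xyz <- as.matrix(x)
    if (nrow(xyz) < 1L) abort_ed("Need at least one atom.", "empty_input")
    intens <- one_frame(xyz)
    n_at <- nrow(xyz)
  }
  ord <- order(q_grid)
  scatter_curve(q_grid[ord], intens[ord], i0 = n_at^2)
}
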