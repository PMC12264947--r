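# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rg", "i0"),
    estimate = c(x$rg, x$i0),
    units = c("angstrom", "intensity")
  )
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(
    rg = x$rg, i0 = x$i0,
    q_min = x$fit_range[["q_min"]], q_max = x$fit_range[["q_max"]],
    qrg_max = x$qrg_max, n_points = x$n_points,
    r_squared = x$r_squared, residual_sd = x$residual_sd,
    converged = x$converged
  )
}

#' @export
tidy.kmeans_fit <- function(x, ...) {
  centers <- tibble::as_tibble(as.data.frame(x$centers))
  sizes <- as.integer(table(factor(x$labels$cluster, levels = seq_len(x$k))))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$k), size = sizes), centers)
}

#' @export
glance.kmeans_fit <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, seed = x$seed)
}

#' @export
augment.kmeans_fit <- function(x, ...) x$labels

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.pca_projection <- function(x, ...) x$scores

#' @export
glance.pca_projection <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance),
    explained_variance = x$explained_variance
  )
}

#' @export
tidy.tica_projection <- function(x, ...) x$scores

#' @export
glance.tica_projection <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    lag = x$lag
  )
}

#' @export
tidy.elbow_curve <- function(x, ...) x$curve

#' @export
glance.elbow_curve <- function(x, ...) tibble::tibble(k = x$k)

#' @export
tidy.free_energy_landscape <- function(x, ...) {
  xc <- (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2
  yc <- (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2
  tibble::tibble(
    x = rep(xc, times = length(yc)),
    y = rep(yc, each = length(xc)),
    delta_f = as.vector(x$delta_f),
    count = as.vector(x$counts),
    occupied = as.vector(x$occupied)
  )
}

#' @export
tidy.contact_map <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    residue_i = rep(seq_len(n), times = n),
    residue_j = rep(seq_len(n), each = n),
    value = as.vector(unclass(x))
  )
}
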