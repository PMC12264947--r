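# ggplot2 autoplot() methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_vline scale_fill_viridis_c labs theme_minimal .data
#' @export
ggplot2::autoplot

#' @export
autoplot.contact_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(.data$residue_i, .data$residue_j, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = attr(object, "units")) +
    labs(
      x = "residue", y = "residue",
      title = sprintf("Contact map (%s)", attr(object, "statistic"))
    ) +
    theme_minimal()
}

#' @export
autoplot.free_energy_landscape <- function(object, ...) {
  df <- tidy(object)
  ggplot(df[df$occupied, ], aes(.data$x, .data$y, fill = .data$delta_f)) +
    geom_raster() +
    scale_fill_viridis_c(name = bquote(Delta * F ~ "(" * .(object$units) * ")")) +
    labs(x = "component 1", y = "component 2", title = "Free-energy landscape") +
    theme_minimal()
}

#' @export
autoplot.elbow_curve <- function(object, ...) {
  ggplot(object$curve, aes(.data$k, .data$inertia)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = object$k, linetype = "dashed") +
    labs(x = "k", y = "within-cluster sum of squares", title = "Elbow curve") +
    theme_minimal()
}

#' @export
autoplot.scatter_curve <- function(object, ...) {
  ggplot(object, aes(.data$q, .data$intensity)) +
    geom_line() +
    ggplot2::scale_y_log10() +
    labs(
      x = expression(q ~ (ring(A)^-1)), y = "I(q)",
      title = "Scattering curve"
    ) +
    theme_minimal()
}

#' @export
autoplot.guinier_fit <- function(object, ...) {
  stop("autoplot.guinier_fit needs the source curve; use plot_guinier(curve, fit).")
}

#' Guinier plot (ln I vs q^2) with the fitted line
#' @param curve The fitted [scatter_curve()].
#' @param fit The matching [guinier_rg()] result.
#' @return A ggplot object.
#' @export
plot_guinier <- function(curve, fit) {
  df <- tibble::tibble(q2 = curve$q^2, log_i = log(curve$intensity))
  used <- seq_len(fit$n_points)
  ggplot(df, aes(.data$q2, .data$log_i)) +
    geom_point(alpha = 0.4) +
    geom_point(data = df[used, ], colour = "firebrick") +
    ggplot2::geom_abline(
      intercept = log(fit$i0), slope = -fit$rg^2 / 3,
      linetype = "dashed"
    ) +
    labs(
      x = expression(q^2 ~ (ring(A)^-2)), y = "ln I(q)",
      title = sprintf("Guinier fit: Rg = %.2f A", fit$rg)
    ) +
    theme_minimal()
}

#' Normalized Kratky plot
#' @param curve A [scatter_curve()].
#' @param rg,i0 Guinier parameters (see [kratky_normalized()]).
#' @return A ggplot object.
#' @export
plot_kratky <- function(curve, rg, i0 = NULL) {
  df <- kratky_normalized(curve, rg, i0)
  ggplot(df, aes(.data$qrg, .data$kratky)) +
    geom_line() +
    labs(
      x = expression(q * R[g]),
      y = expression((q * R[g])^2 ~ I(q) / I(0)),
      title = "Normalized Kratky plot"
    ) +
    theme_minimal()
}

#' @export
autoplot.decomposition <- function(object, ...) {
  sizes <- group_sizes(object)
  ggplot(sizes, aes(factor(.data$group), .data$n_frames)) +
    ggplot2::geom_col() +
    labs(
      x = "conformation-parameter group", y = "frames",
      title = "Decomposition group sizes"
    ) +
    theme_minimal()
}

#' @export
autoplot.ss_ree_kde <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(object$x, times = length(object$y)),
    y = rep(object$y, each = length(object$x)),
    density = as.vector(object$z)
  )
  ggplot(df, aes(.data$x, .data$y, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(
      x = sprintf("fraction of residues in class %s", object$ss_class),
      y = expression(R[ee] ~ (ring(A))),
      title = "Secondary structure vs end-to-end distance"
    ) +
    theme_minimal()
}
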