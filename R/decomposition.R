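# Single-parameter and multivariable decomposition of an ensemble into
# conformation-parameter groups, plus per-group summaries.

#' Conformation parameter X_conf per frame
#'
#' For each frame i,
#' \deqn{X_{conf,i} = \alpha \left( \frac{R_{g,i}}{R_{g,ave}} +
#'   \frac{R_{ee,i}}{R_{ee,ave}} + \frac{SASA_i}{SASA_{ave}} \right)}
#' where the averages are the arithmetic means of each descriptor over all
#' frames in `data`. The resolution parameter \eqn{\alpha} controls how
#' finely the values spread over integer group labels: because each ratio
#' averages to 1, the ensemble mean of X_conf is exactly \eqn{3\alpha}
#' (15 at the default \eqn{\alpha = 5}). Higher values indicate extended,
#' solvent-exposed conformations.
#'
#' @param data Data frame with numeric columns `rg`, `ree`, `sasa`
#'   (see [frame_descriptors()]).
#' @param alpha Positive resolution multiplier, default 5.
#' @return `data` with an added `xconf` column; the descriptor means and
#'   `alpha` are attached as the `xconf_config` attribute.
#' @export
conformation_parameter <- function(data, alpha = 5) {
  check_scalar_number(alpha, "alpha", positive = TRUE)
  needed <- c("rg", "ree", "sasa")
  if (!all(needed %in% names(data))) {
    abort_ed("`data` must contain `rg`, `ree` and `sasa` columns.", "parameter")
  }
  aves <- vapply(needed, function(col) mean(data[[col]]), 0)
  if (any(!is.finite(aves)) || any(aves <= 0)) {
    abort_ed("Degenerate ensemble: descriptor averages must be positive.", "degenerate_ensemble")
  }
  out <- dplyr::mutate(
    data,
    xconf = alpha * (.data$rg / aves[["rg"]] +
      .data$ree / aves[["ree"]] +
      .data$sasa / aves[["sasa"]])
  )
  attr(out, "xconf_config") <- list(alpha = alpha, averages = aves)
  out
}

new_decomposition <- function(data, config) {
  stopifnot(all(c("frame", "group") %in% names(data)))
  structure(
    data,
    class = c("decomposition", class(tibble::tibble())),
    decomposition_config = config
  )
}

#' Decompose frames into integer conformation-parameter groups
#'
#' Each frame is assigned to the nearest integer of its `xconf` value
#' (ties at .5 round half-up). The result is a partition: every frame lies
#' in exactly one group, and the assignment is monotone in `xconf`.
#'
#' @param data Data frame with an `xconf` column, as returned by
#'   [conformation_parameter()].
#' @return A `decomposition` tibble (the input plus a `group` column).
#'   Group sizes are available via [group_sizes()]; empty integer labels in
#'   the spanned range are simply absent.
#' @export
decompose <- function(data) {
  if (!"xconf" %in% names(data)) {
    abort_ed("`data` must contain an `xconf` column; run conformation_parameter() first.", "parameter")
  }
  check_finite(data$xconf, "xconf")
  if (!"frame" %in% names(data)) data$frame <- seq_len(nrow(data))
  out <- dplyr::mutate(data, group = as.integer(round_half_up(.data$xconf)))
  new_decomposition(out, c(
    attr(data, "xconf_config"),
    list(grouping_rule = "nearest_integer")
  ))
}

#' Decompose frames by fixed-width binning of a single descriptor
#'
#' Bins are anchored at the minimum of the series, so a width larger than
#' the data range always yields a single group. Group labels are the bin
#' centers.
#'
#' @param data Data frame holding the descriptor.
#' @param col Column name of the descriptor to bin (e.g. `"rg"`).
#' @param bin_width Positive bin width in the descriptor's units.
#' @return A `decomposition` tibble with a `group` column of bin centers.
#' @export
decompose_single <- function(data, col, bin_width) {
  check_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (!col %in% names(data)) {
    abort_ed(sprintf("Column `%s` not found.", col), "parameter")
  }
  x <- data[[col]]
  check_finite(x, col)
  if (!"frame" %in% names(data)) data$frame <- seq_len(nrow(data))
  bin <- pmin(floor((x - min(x)) / bin_width), floor((max(x) - min(x)) / bin_width))
  out <- dplyr::mutate(data, group = min(x) + (bin + 0.5) * bin_width)
  new_decomposition(out, list(
    parameter = col, bin_width = bin_width,
    grouping_rule = "fixed_width_bins"
  ))
}

#' Group sizes of a decomposition
#' @param groups A `decomposition`.
#' @return A tibble with columns `group` and `n_frames`, sorted by group.
#' @export
group_sizes <- function(groups) {
  dplyr::count(tibble::as_tibble(groups), .data$group, name = "n_frames")
}

#' Frame indices of one decomposition group
#' @param groups A `decomposition`.
#' @param group_label The group to extract.
#' @return Integer frame indices.
#' @export
group_frames <- function(groups, group_label) {
  idx <- groups$frame[groups$group == group_label]
  if (length(idx) == 0L) {
    abort_ed(sprintf("Group %s is empty or absent.", group_label), "empty_selection")
  }
  idx
}

#' Secondary-structure fractions per decomposition group
#'
#' For each group and DSSP class, the fraction of all residue-frame slots in
#' that group carrying the class. Fractions sum to 1 per group. The
#' unassigned class `~` is reported; set `hide_unassigned = TRUE` to drop it
#' from the output (as done when displaying only ordered elements).
#'
#' @param labels An [ss_series()] matrix with one row per frame.
#' @param groups A `decomposition` over the same frames.
#' @param hide_unassigned Drop the `~` class from the output.
#' @return A tibble with columns `group`, `ss_class`, `fraction`.
#' @export
group_ss_fractions <- function(labels, groups, hide_unassigned = FALSE) {
  if (nrow(labels) != nrow(groups)) {
    abort_ed("Label frame count does not match the decomposition.", "alignment")
  }
  res <- lapply(sort(unique(groups$group)), function(g) {
    fr <- groups$frame[groups$group == g]
    block <- unclass(labels)[fr, , drop = FALSE]
    tab <- table(factor(as.vector(block), levels = DSSP_ALPHABET))
    tibble::tibble(
      group = g,
      ss_class = names(tab),
      fraction = as.numeric(tab) / length(block)
    )
  })
  out <- dplyr::bind_rows(res)
  if (hide_unassigned) out <- dplyr::filter(out, .data$ss_class != "~")
  out
}

#' Hydrogen-bond contact maps per decomposition group
#'
#' [hbond_contact_map()] restricted to each group's frames.
#'
#' @param ensemble An `ensemble` with hydrogens.
#' @param groups A `decomposition` over the ensemble's frames.
#' @param ... Passed to [hbond_contact_map()] (`d_cut`, `angle_cut`, ...).
#' @return A named list of `contact_map`s, one per group label.
#' @export
group_hbond_maps <- function(ensemble, groups, ...) {
  labels <- sort(unique(groups$group))
  maps <- lapply(labels, function(g) {
    hbond_contact_map(ensemble, frames = group_frames(groups, g), ...)
  })
  names(maps) <- labels
  maps
}

#' Mean minimum pair distances per group, Table-style
#'
#' [mean_min_pair_distance()] for each residue pair within each group,
#' arranged with pair rows and group columns.
#'
#' @param ensemble An `ensemble`.
#' @param groups A `decomposition`.
#' @param pairs List of length-2 residue index vectors.
#' @return A tibble: `pair` label column, then one numeric column per group
#'   (Angstrom).
#' @export
group_pair_distance_table <- function(ensemble, groups, pairs) {
  labels <- sort(unique(groups$group))
  rows <- lapply(pairs, function(pr) {
    vals <- vapply(labels, function(g) {
      mean_min_pair_distance(ensemble, pr, frames = group_frames(groups, g))
    }, 0)
    nm <- paste0(
      ensemble$atoms$residue_name[match(pr, ensemble$atoms$residue_index)],
      pr
    )
    tibble::as_tibble(c(
      list(pair = paste(nm[1], nm[2], sep = "-")),
      stats::setNames(as.list(vals), paste0("group_", labels))
    ))
  })
  dplyr::bind_rows(rows)
}

#' 2D kernel density of secondary-structure propensity vs end-to-end distance
#'
#' Per frame, the propensity is the fraction of residues carrying
#' `ss_class`; a Gaussian-kernel 2D density (Scott's-rule bandwidths) is
#' estimated on (propensity, Ree). The grid extends beyond the data range so
#' the density integrates to 1 over the grid to within about 1%.
#'
#' @param labels An [ss_series()] matrix.
#' @param ree Numeric per-frame end-to-end distances (or a data frame with
#'   a `ree` column).
#' @param ss_class One DSSP class character.
#' @param n_grid Grid points per axis (default 101).
#' @return A list of class `ss_ree_kde` with `x` (propensity), `y` (Ree),
#'   `z` (density matrix), and the per-axis bandwidths.
#' @export
ss_vs_ree_kde <- function(labels, ree, ss_class, n_grid = 101) {
  if (is.data.frame(ree)) ree <- ree$ree
  if (!ss_class %in% DSSP_ALPHABET) {
    abort_ed(sprintf("Class %s is not in the DSSP alphabet.", sQuote(ss_class)), "parameter")
  }
  if (nrow(labels) != length(ree)) {
    abort_ed("Label frame count does not match `ree`.", "alignment")
  }
  propensity <- rowMeans(unclass(labels) == ss_class)
  if (stats::sd(propensity) == 0 || stats::sd(ree) == 0) {
    abort_ed(
      "Degenerate KDE axis (zero variance). The class never varies across frames; density estimation needs spread on both axes.",
      "degenerate_kde"
    )
  }
  n <- length(ree)
  # Scott's rule in 2D: sd * n^(-1/6) per axis; kde2d's `h` is 4x kernel sd
  h <- 4 * c(stats::sd(propensity), stats::sd(ree)) * n^(-1 / 6)
  lims <- c(
    range(propensity) + c(-1, 1) * h[1],
    range(ree) + c(-1, 1) * h[2]
  )
  dens <- MASS::kde2d(propensity, ree, h = h, n = n_grid, lims = lims)
  structure(
    list(x = dens$x, y = dens$y, z = dens$z, bandwidths = h, ss_class = ss_class),
    class = "ss_ree_kde"
  )
}

#' Per-residue occurrence profile of one secondary-structure class
#'
#' Each residue's count of the class over all frames, divided by the total
#' class count over all residues and frames; the profile sums to 1 whenever
#' the class occurs.
#'
#' @param labels An [ss_series()] matrix.
#' @param ss_class One DSSP class character.
#' @return A tibble with columns `residue` and `occurrence`. If the class
#'   never occurs the profile is all zero (with a warning), never NaN.
#' @export
ss_residue_occurrence <- function(labels, ss_class) {
  if (!ss_class %in% DSSP_ALPHABET) {
    abort_ed(sprintf("Class %s is not in the DSSP alphabet.", sQuote(ss_class)), "parameter")
  }
  counts <- colSums(unclass(labels) == ss_class)
  total <- sum(counts)
  if (total == 0) {
    warn(sprintf("Class %s never occurs; returning an all-zero profile.", sQuote(ss_class)))
    occ <- rep(0, ncol(labels))
  } else {
    occ <- counts / total
  }
  tibble::tibble(residue = seq_len(ncol(labels)), occurrence = occ)
}
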