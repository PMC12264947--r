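# Dihedral featurization, PCA/tICA projections and 2D free-energy
# landscapes.

# torsion angle (degrees, in (-180, 180]) for stacked quadruples;
# p1..p4 are n x 3 matrices
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(unit_rows(b2), n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

backbone_index_table <- function(ensemble) {
  at <- ensemble$atoms
  out <- lapply(c("N", "CA", "C"), function(nm) {
    idx <- integer(ensemble$n_residues)
    for (r in seq_len(ensemble$n_residues)) {
      hit <- which(at$residue_index == r & at$atom_name == nm)
      if (length(hit) != 1L) {
        abort_ed(
          sprintf("Backbone atom %s missing (or duplicated) in residue %d.", nm, r),
          "topology"
        )
      }
      idx[r] <- hit
    }
    idx
  })
  names(out) <- c("N", "CA", "C")
  out
}

#' Backbone phi/psi dihedral angles per frame
#'
#' \eqn{\phi_i} from C(i-1)-N(i)-CA(i)-C(i) (residues 2..n) and
#' \eqn{\psi_i} from N(i)-CA(i)-C(i)-N(i+1) (residues 1..n-1).
#'
#' @param ensemble An `ensemble` with backbone N, CA, C atoms.
#' @return A tibble with columns `frame`, `residue`, `angle`
#'   (`"phi"`/`"psi"`) and `value` (degrees).
#' @export
backbone_dihedrals <- function(ensemble) {
  bb <- backbone_index_table(ensemble)
  nf <- ensemble$n_frames
  nr <- ensemble$n_residues
  get <- function(atom_idx) {
    matrix(ensemble$coords[, atom_idx, , drop = FALSE], nrow = nf * length(atom_idx), ncol = 3)
  }
  stack <- function(idx) {
    # frames vary fastest: rows are (frame 1..nf) for residue block 1, ...
    m <- ensemble$coords[, idx, , drop = FALSE]
    matrix(m, ncol = 3L)
  }
  phi <- psi <- NULL
  if (nr >= 2L) {
    res_phi <- 2:nr
    phi_val <- dihedral_angle(
      stack(bb$C[res_phi - 1L]), stack(bb$N[res_phi]),
      stack(bb$CA[res_phi]), stack(bb$C[res_phi])
    )
    phi <- tibble::tibble(
      frame = rep(seq_len(nf), times = length(res_phi)),
      residue = rep(res_phi, each = nf),
      angle = "phi", value = phi_val
    )
    res_psi <- 1:(nr - 1L)
    psi_val <- dihedral_angle(
      stack(bb$N[res_psi]), stack(bb$CA[res_psi]),
      stack(bb$C[res_psi]), stack(bb$N[res_psi + 1L])
    )
    psi <- tibble::tibble(
      frame = rep(seq_len(nf), times = length(res_psi)),
      residue = rep(res_psi, each = nf),
      angle = "psi", value = psi_val
    )
  }
  dplyr::bind_rows(phi, psi)
}

#' Sin/cos dihedral feature matrix
#'
#' Every defined phi and psi angle contributes a (sin, cos) pair, removing
#' the angular periodicity; for an n-residue chain this yields
#' `4 * (n - 1)` columns.
#'
#' @param ensemble An `ensemble` with backbone N, CA, C atoms.
#' @return A numeric `feature_matrix` (frames x features) with named
#'   columns (`phi_2_sin`, `phi_2_cos`, ...).
#' @export
dihedral_features <- function(ensemble) {
  di <- backbone_dihedrals(ensemble)
  if (nrow(di) == 0L) abort_ed("No dihedral angles defined (need >= 2 residues).", "topology")
  nf <- ensemble$n_frames
  wide <- tidyr::pivot_wider(
    di,
    names_from = c("angle", "residue"), values_from = "value",
    names_glue = "{angle}_{residue}"
  )
  wide <- wide[order(wide$frame), , drop = FALSE]
  ang <- as.matrix(wide[, -1, drop = FALSE]) * pi / 180
  feats <- matrix(0, nrow = nf, ncol = 2L * ncol(ang))
  nm <- character(2L * ncol(ang))
  for (j in seq_len(ncol(ang))) {
    feats[, 2L * j - 1L] <- sin(ang[, j])
    feats[, 2L * j] <- cos(ang[, j])
    nm[2L * j - 1L] <- paste0(colnames(ang)[j], "_sin")
    nm[2L * j] <- paste0(colnames(ang)[j], "_cos")
  }
  colnames(feats) <- nm
  structure(feats, class = c("feature_matrix", "matrix"))
}

#' Principal component projection of a feature matrix
#'
#' Mean-centered eigendecomposition of the covariance, with a deterministic
#' sign convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param features Numeric matrix, frames x features.
#' @param n_components Number of components to keep (default 2). Requests
#'   beyond the matrix rank are reduced with a warning, not an error.
#' @return A list of class `pca_projection`: `scores` tibble
#'   (`frame`, `pc1`, ...), `rotation`, `sdev`, `explained_variance`
#'   (fraction per kept component).
#' @export
pca_project <- function(features, n_components = 2) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) abort_ed("PCA needs at least 2 frames.", "parameter")
  if (n_components > ncol(features)) {
    abort_ed("`n_components` exceeds the number of features.", "parameter")
  }
  fit <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-10)
  if (rank == 0L) {
    # all frames identical: a single zero-variance component
    warn("Features have no variance; returning a single constant component.")
    return(structure(
      list(
        scores = tibble::tibble(frame = seq_len(nrow(features)), pc1 = 0),
        rotation = fit$rotation[, 1, drop = FALSE],
        sdev = fit$sdev,
        explained_variance = 1
      ),
      class = "pca_projection"
    ))
  }
  if (n_components > rank) {
    warn(sprintf("Requested %d components but rank is %d; reducing.", n_components, rank))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  rot <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  for (k in keep) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- paste0("pc", keep)
  structure(
    list(
      scores = tibble::tibble(frame = seq_len(nrow(features)), !!!as.data.frame(scores)),
      rotation = rot,
      sdev = fit$sdev,
      explained_variance = fit$sdev[keep]^2 / sum(fit$sdev^2)
    ),
    class = "pca_projection"
  )
}

#' Time-lagged independent component analysis (tICA)
#'
#' Solves the generalized eigenproblem \eqn{C(\tau) v = \lambda C(0) v} on
#' mean-free features, with the time-lagged covariance symmetrized and a
#' small ridge added to the instantaneous covariance for well-posedness.
#' Eigenvalues are real and bounded by 1 in magnitude after symmetrization;
#' leading components capture the slowest-decorrelating coordinates.
#'
#' @param features Numeric matrix, frames x features.
#' @param lag Lag time in frames (default 50).
#' @param n_components Components to keep (default 2).
#' @param epsilon Ridge added to the diagonal of C(0) (default 1e-6).
#' @return A list of class `tica_projection`: `scores` tibble
#'   (`frame`, `tic1`, ...), `eigenvalues` (all, decreasing), `components`
#'   (feature loadings), `lag`.
#' @export
tica_project <- function(features, lag = 50, n_components = 2, epsilon = 1e-6) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (lag < 1L) abort_ed("`lag` must be at least 1 frame.", "parameter")
  if (lag >= n) abort_ed("`lag` must be smaller than the number of frames.", "parameter")
  x <- sweep(features, 2L, colMeans(features))
  x0 <- x[seq_len(n - lag), , drop = FALSE]
  xt <- x[(lag + 1L):n, , drop = FALSE]
  m <- n - lag
  c0 <- (crossprod(x0) + crossprod(xt)) / (2 * m)
  ct <- (crossprod(x0, xt) + crossprod(xt, x0)) / (2 * m)
  diag(c0) <- diag(c0) + epsilon
  ch <- tryCatch(chol(c0), error = function(e) {
    abort_ed(
      "Instantaneous covariance is singular; increase `epsilon` for regularization.",
      "conditioning"
    )
  })
  li <- backsolve(ch, diag(ncol(c0)), transpose = TRUE) # inv(t(ch))
  w <- li %*% ct %*% t(li)
  eig <- eigen((w + t(w)) / 2, symmetric = TRUE)
  vecs <- t(li) %*% eig$vectors
  keep <- seq_len(min(n_components, ncol(vecs)))
  comp <- vecs[, keep, drop = FALSE]
  for (k in keep) {
    j <- which.max(abs(comp[, k]))
    if (comp[j, k] < 0) comp[, k] <- -comp[, k]
  }
  scores <- x %*% comp
  colnames(scores) <- paste0("tic", keep)
  structure(
    list(
      scores = tibble::tibble(frame = seq_len(n), !!!as.data.frame(scores)),
      eigenvalues = eig$values,
      components = comp,
      lag = lag
    ),
    class = "tica_projection"
  )
}

#' 2D free-energy landscape from a projection
#'
#' Bins the projected points on their bounding box and converts occupancies
#' to free energies, \eqn{\Delta F_i = -k_B T \ln(n_i / n_{max})}. Occupied
#' bins are non-negative with minimum exactly 0 (the most populated bin);
#' with `shift_to_zero_max` the maximum occupied value is subtracted so the
#' least-populated occupied bin sits at 0 and all others are negative.
#' Unoccupied bins are `NA` (masked), never infinite.
#'
#' @param points Two-column matrix or data frame of projected coordinates
#'   (e.g. the `scores` of [tica_project()] without the frame column).
#' @param n_bins Bins per axis (default 64).
#' @param temperature Temperature in Kelvin (default 298).
#' @param units `"kT"` (default) or `"kJ/mol"`.
#' @param shift_to_zero_max Apply the highest-energy-state normalization.
#' @return A list of class `free_energy_landscape`: `delta_f` (n_bins x
#'   n_bins matrix, `NA` where unoccupied), `x_edges`, `y_edges`, `counts`,
#'   `occupied` (logical mask), `temperature`, `units`.
#' @export
free_energy_landscape <- function(points, n_bins = 64, temperature = 298,
                                  units = c("kT", "kJ/mol"),
                                  shift_to_zero_max = FALSE) {
  units <- match.arg(units)
  if (is.data.frame(points)) {
    points <- as.matrix(points[, setdiff(names(points), "frame"), drop = FALSE])
  }
  if (ncol(points) != 2L) abort_ed("`points` must have exactly 2 columns.", "parameter")
  if (nrow(points) < 1L) abort_ed("Need at least one point.", "empty_input")
  if (n_bins < 2L) abort_ed("`n_bins` must be at least 2.", "parameter")
  check_finite(points, "points")
  rx <- range(points[, 1])
  ry <- range(points[, 2])
  if (rx[1] == rx[2] && ry[1] == ry[2]) {
    warn("All points identical: landscape degenerates to a single occupied bin.")
    rx <- rx + c(-0.5, 0.5)
    ry <- ry + c(-0.5, 0.5)
  }
  x_edges <- seq(rx[1], rx[2], length.out = n_bins + 1L)
  y_edges <- seq(ry[1], ry[2], length.out = n_bins + 1L)
  ix <- findInterval(points[, 1], x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(points[, 2], y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ix, levels = 1:n_bins), factor(iy, levels = 1:n_bins))
  counts[] <- as.integer(tab)
  occupied <- counts > 0L
  kbt <- if (units == "kT") 1 else KB_KJ_PER_MOL_K * temperature
  delta_f <- matrix(NA_real_, n_bins, n_bins)
  delta_f[occupied] <- -kbt * log(counts[occupied] / max(counts))
  if (shift_to_zero_max) {
    delta_f[occupied] <- delta_f[occupied] - max(delta_f[occupied])
  }
  structure(
    list(
      delta_f = delta_f, x_edges = x_edges, y_edges = y_edges,
      counts = counts, occupied = occupied,
      temperature = temperature, units = units,
      shifted = shift_to_zero_max
    ),
    class = "free_energy_landscape"
  )
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf(
    "<free_energy_landscape> %d x %d bins, %d occupied, units %s, T = %g K%s\n",
    nrow(x$delta_f), ncol(x$delta_f), sum(x$occupied), x$units, x$temperature,
    if (x$shifted) " (shifted to zero max)" else ""
  ))
  invisible(x)
}

#' Write a landscape grid as TSV with a mask channel
#'
#' Masked (unoccupied) bins are written as the sentinel token `"masked"`,
#' never as a number.
#'
#' @param landscape A [free_energy_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  m <- landscape$delta_f
  out <- matrix(as.character(signif(m, 10)), nrow(m), ncol(m))
  out[!landscape$occupied] <- "masked"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
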