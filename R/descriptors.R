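# Per-frame and per-residue structural descriptors.

#' Radius of gyration per frame
#'
#' \eqn{R_g = \sqrt{\sum_i w_i |r_i - \bar r|^2 / \sum_i w_i}} with
#' \eqn{w_i} the atomic mass (default, the `gmx gyrate` convention) or 1.
#'
#' @param ensemble An [new_ensemble()] object.
#' @param mass_weighted Use atomic masses as weights (default `TRUE`).
#' @return A tibble with columns `frame` and `rg` (Angstrom).
#' @export
radius_of_gyration <- function(ensemble, mass_weighted = TRUE) {
  w <- if (mass_weighted) ensemble$atoms$mass else rep(1, ensemble$n_atoms)
  if (sum(w) <= 0) {
    abort_ed("All-zero weights: cannot mass-weight the radius of gyration.", "degenerate_weights")
  }
  w <- w / sum(w)
  rg <- vapply(seq_len(ensemble$n_frames), function(f) {
    xyz <- frame_coords(ensemble, f)
    ctr <- colSums(xyz * w)
    dev <- sweep(xyz, 2L, ctr)
    sqrt(sum(w * rowSums(dev^2)))
  }, 0)
  tibble::tibble(frame = seq_len(ensemble$n_frames), rg = rg)
}

# resolve a selector to exactly one atom index; selector is either an atom
# index, or list(residue =, atom =)
resolve_atom <- function(ensemble, selector, what) {
  if (is.numeric(selector) && length(selector) == 1L) {
    idx <- as.integer(selector)
    if (idx < 1L || idx > ensemble$n_atoms) {
      abort_ed(sprintf("`%s` atom index out of range.", what), "selection")
    }
    return(idx)
  }
  if (is.list(selector)) {
    hit <- which(
      ensemble$atoms$residue_index == selector$residue &
        ensemble$atoms$atom_name == selector$atom
    )
    if (length(hit) != 1L) {
      abort_ed(
        sprintf("`%s` selector matches %d atoms (needs exactly 1).", what, length(hit)),
        "selection"
      )
    }
    return(hit)
  }
  abort_ed(sprintf("Cannot interpret `%s` selector.", what), "selection")
}

#' End-to-end distance per frame
#'
#' Euclidean distance between two selected atoms; defaults to the
#' first-residue backbone N and the last-residue backbone C.
#'
#' @param ensemble An `ensemble`.
#' @param start_atom,end_atom Either a single atom index or
#'   `list(residue =, atom =)`; must resolve to exactly one atom.
#' @return A tibble with columns `frame` and `ree` (Angstrom).
#' @export
end_to_end_distance <- function(ensemble, start_atom = NULL, end_atom = NULL) {
  start_atom <- start_atom %||% list(residue = 1L, atom = "N")
  end_atom <- end_atom %||% list(residue = ensemble$n_residues, atom = "C")
  i <- resolve_atom(ensemble, start_atom, "start_atom")
  j <- resolve_atom(ensemble, end_atom, "end_atom")
  d <- sqrt(rowSums((ensemble$coords[, i, , drop = FALSE] -
    ensemble$coords[, j, , drop = FALSE])^2, dims = 1L))
  tibble::tibble(frame = seq_len(ensemble$n_frames), ree = as.numeric(d))
}

#' Polymer shape parameter per frame
#'
#' \eqn{P_S = R_{ee}^2 / R_g^2}: 12 for a thin rod, about 6.3 for an ideal
#' chain, smaller for compact globules. Takes a data frame holding `rg` and
#' `ree` columns (as produced by [frame_descriptors()]) and appends `ps`.
#'
#' @param data Data frame with numeric columns `rg` and `ree`.
#' @return `data` with an added `ps` column (dimensionless).
#' @export
polymer_shape <- function(data) {
  if (!all(c("rg", "ree") %in% names(data))) {
    abort_ed("`data` must contain `rg` and `ree` columns.", "parameter")
  }
  zero <- which(data$rg <= 0)
  if (length(zero) > 0L) {
    abort_ed(
      sprintf("Rg is zero in frame(s) %s: polymer shape undefined.", paste(utils::head(zero, 5L), collapse = ", ")),
      "division"
    )
  }
  dplyr::mutate(data, ps = .data$ree^2 / .data$rg^2)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For every atom, the fraction of quasi-uniform test points on a sphere of
#' radius \eqn{r_{vdw} + r_{probe}} not buried inside any neighbour's
#' expanded sphere, times \eqn{4\pi (r_{vdw}+r_{probe})^2}. Summed per
#' residue and per frame.
#'
#' @param ensemble An `ensemble` (all atoms need known radii).
#' @param probe_radius Probe radius in Angstrom (water: 1.4, the default).
#' @param n_sphere_points Number of test points per atom (default 960).
#' @param per_residue If `TRUE` return a long tibble
#'   (`frame`, `residue`, `sasa`); otherwise per-frame totals.
#' @param frames Optional 1-based frame subset.
#' @return A tibble: `frame`, `sasa` (Angstrom^2), or the per-residue long
#'   form.
#' @export
sasa_shrake_rupley <- function(ensemble, probe_radius = 1.4,
                               n_sphere_points = 960, per_residue = FALSE,
                               frames = NULL) {
  if (probe_radius < 0) abort_ed("`probe_radius` must be >= 0.", "parameter")
  frames <- check_frames(ensemble, frames)
  sphere <- golden_sphere_points(n_sphere_points)
  per_res <- sasa_frames_cpp(
    ensemble$coords, ensemble$atoms$radius, probe_radius, sphere,
    ensemble$atoms$residue_index, ensemble$n_residues, as.integer(frames)
  )
  if (per_residue) {
    tibble::tibble(
      frame = rep(frames, times = ensemble$n_residues),
      residue = rep(seq_len(ensemble$n_residues), each = length(frames)),
      sasa = as.vector(per_res)
    )
  } else {
    tibble::tibble(frame = frames, sasa = rowSums(per_res))
  }
}

#' Per-frame descriptor table
#'
#' Computes the four per-frame descriptors used throughout the package in
#' one call: radius of gyration, end-to-end distance, solvent-accessible
#' surface area and polymer shape.
#'
#' @inheritParams sasa_shrake_rupley
#' @param mass_weighted Mass-weight the radius of gyration.
#' @return A tibble with columns `frame`, `rg`, `ree`, `sasa`, `ps`.
#' @export
frame_descriptors <- function(ensemble, probe_radius = 1.4,
                              n_sphere_points = 960, mass_weighted = TRUE) {
  out <- radius_of_gyration(ensemble, mass_weighted = mass_weighted)
  out$ree <- end_to_end_distance(ensemble)$ree
  out$sasa <- sasa_shrake_rupley(
    ensemble,
    probe_radius = probe_radius, n_sphere_points = n_sphere_points
  )$sasa
  polymer_shape(out)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation (proper, det = +1) and translation mapping
#' `mobile` onto `reference`, fitted on `subset` atoms.
#'
#' @param reference,mobile `n_atoms x 3` coordinate matrices.
#' @param subset Optional atom indices used for the fit (default all).
#' @return A list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the subset after superposition), and `transform(x)`,
#'   a function applying the fitted motion to any `n x 3` matrix.
#' @export
kabsch_superpose <- function(reference, mobile, subset = NULL) {
  subset <- subset %||% seq_len(nrow(reference))
  if (length(subset) < 3L) {
    abort_ed("Need at least 3 atoms to superpose.", "degeneracy")
  }
  a <- mobile[subset, , drop = FALSE]
  b <- reference[subset, , drop = FALSE]
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca)
  b0 <- sweep(b, 2L, cb)
  # collinear subsets leave the rotation about the axis undetermined
  sv_a <- svd(a0, nu = 0, nv = 0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1e-12)) {
    abort_ed("Superposition subset is (near-)collinear.", "degeneracy")
  }
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transform <- function(x) sweep(sweep(x, 2L, ca) %*% t(rot), 2L, cb, "+")
  moved <- transform(a)
  list(
    rotation = rot,
    translation = as.numeric(cb - ca %*% t(rot)),
    rmsd = sqrt(mean(rowSums((moved - b)^2))),
    transform = transform
  )
}

backbone_atom_indices <- function(ensemble) {
  which(ensemble$atoms$atom_name %in% c("N", "CA", "C"))
}

#' Root-mean-square fluctuation per residue
#'
#' Two-pass procedure: all frames are superposed onto the iterated mean
#' structure (fit on `superpose_subset`, default backbone N/CA/C), then
#' per-atom \eqn{\sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}} is
#' averaged within each residue.
#'
#' @param ensemble An `ensemble` with at least 2 frames.
#' @param superpose_subset Atom indices used for the fit; default backbone.
#' @param n_iter Mean-structure refinement passes (default 2).
#' @return A tibble with columns `residue` and `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, superpose_subset = NULL, n_iter = 2) {
  if (ensemble$n_frames < 2L) {
    abort_ed("RMSF needs at least 2 frames.", "insufficient_frames")
  }
  subset <- superpose_subset %||% backbone_atom_indices(ensemble)
  nf <- ensemble$n_frames
  frames <- lapply(seq_len(nf), function(f) frame_coords(ensemble, f))
  ref <- frames[[1]]
  for (it in seq_len(n_iter)) {
    fitted <- lapply(frames, function(x) {
      kabsch_superpose(ref, x, subset = subset)$transform(x)
    })
    ref <- Reduce(`+`, fitted) / nf
  }
  fitted <- lapply(frames, function(x) {
    kabsch_superpose(ref, x, subset = subset)$transform(x)
  })
  mean_xyz <- Reduce(`+`, fitted) / nf
  msd <- Reduce(`+`, lapply(fitted, function(x) rowSums((x - mean_xyz)^2))) / nf
  atom_rmsf <- sqrt(msd)
  tibble::tibble(
    residue = seq_len(ensemble$n_residues),
    rmsf = as.numeric(tapply(atom_rmsf, ensemble$atoms$residue_index, mean))
  )
}

new_contact_map <- function(matrix, statistic, units) {
  structure(matrix, class = c("contact_map", "matrix"),
            statistic = statistic, units = units)
}

#' Minimum-distance residue contact map
#'
#' Entry (i, j) is the minimum over the selected frames and over all atom
#' pairs of residues i and j of the interatomic distance; the diagonal is 0.
#'
#' @param ensemble An `ensemble`.
#' @param frames Optional 1-based frame subset (default all).
#' @param normalize Divide by the largest entry so values span `[0, 1]`.
#' @return A symmetric `contact_map` matrix (Angstrom, or dimensionless if
#'   normalized).
#' @export
min_distance_map <- function(ensemble, frames = NULL, normalize = FALSE) {
  frames <- check_frames(ensemble, frames)
  m <- min_distance_map_cpp(
    ensemble$coords, ensemble$atoms$residue_index,
    ensemble$n_residues, as.integer(frames)
  )
  units <- "angstrom"
  if (normalize) {
    m <- m / max(m)
    units <- "fraction_of_max"
  }
  new_contact_map(m, "min_distance", units)
}

residue_atoms <- function(ensemble, residue) {
  idx <- which(ensemble$atoms$residue_index == residue)
  if (length(idx) == 0L) {
    abort_ed(sprintf("Residue %s not present.", residue), "selection")
  }
  idx
}

#' Average per-frame minimum distance between two residues
#'
#' Averages, over the selected frames, the per-frame minimum interatomic
#' distance between the two residues. Contrast with [min_distance_map()],
#' which takes the global minimum over all frames.
#'
#' @param ensemble An `ensemble`.
#' @param pair Length-2 vector of residue indices.
#' @param frames Optional 1-based frame subset.
#' @return Mean minimum pair distance in Angstrom.
#' @export
mean_min_pair_distance <- function(ensemble, pair, frames = NULL) {
  if (length(pair) != 2L) abort_ed("`pair` must name two residues.", "selection")
  if (pair[1] == pair[2]) abort_ed("Self-pairs have no pair distance.", "self_pair")
  frames <- check_frames(ensemble, frames)
  ai <- residue_atoms(ensemble, pair[1])
  aj <- residue_atoms(ensemble, pair[2])
  mean(pair_min_frames_cpp(ensemble$coords, ai, aj, as.integer(frames)))
}

# donors: N/O heavy atoms with a covalently bound hydrogen (bond detected
# geometrically in the first selected frame, cutoff 1.25 A)
find_hbond_partners <- function(ensemble, frame1) {
  el <- ensemble$atoms$element
  h_idx <- which(el == "H")
  if (length(h_idx) == 0L) {
    abort_ed("Topology contains no hydrogens: cannot detect hydrogen bonds.", "missing_hydrogen")
  }
  heavy_idx <- which(el %in% c("N", "O"))
  xyz <- frame_coords(ensemble, frame1)
  donors <- list()
  for (h in h_idx) {
    d2 <- rowSums(sweep(xyz[heavy_idx, , drop = FALSE], 2L, xyz[h, ])^2)
    j <- which.min(d2)
    if (d2[j] < 1.25^2) {
      donors[[length(donors) + 1L]] <- c(heavy = heavy_idx[j], hydrogen = h)
    }
  }
  list(
    donors = do.call(rbind, donors),
    acceptors = heavy_idx
  )
}

#' Hydrogen-bond residue contact map
#'
#' Geometric criterion: donor-acceptor distance at most `d_cut` and
#' hydrogen-donor-acceptor angle at most `angle_cut` (the `gmx hbond`
#' defaults of 3.5 Angstrom / 30 degrees). Entry (i, j) is the number of
#' bonds with the donor in residue i and the acceptor in residue j, summed
#' over the selected frames and divided by the number of frames. The map is
#' not symmetrized unless requested; intra-residue pairs are excluded.
#'
#' @param ensemble An `ensemble` whose topology includes hydrogens.
#' @param frames Optional 1-based frame subset.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom.
#' @param angle_cut Hydrogen-donor-acceptor angle cutoff, degrees.
#' @param symmetrize Add the transpose so donor/acceptor roles are pooled.
#' @return A `contact_map` in bonds per frame.
#' @export
hbond_contact_map <- function(ensemble, frames = NULL, d_cut = 3.5,
                              angle_cut = 30, symmetrize = FALSE) {
  frames <- check_frames(ensemble, frames)
  partners <- find_hbond_partners(ensemble, frames[1])
  donors <- partners$donors
  acceptors <- partners$acceptors
  n_res <- ensemble$n_residues
  counts <- matrix(0, n_res, n_res)
  if (is.null(donors)) {
    return(new_contact_map(counts, "hbonds_per_frame", "bonds_per_frame"))
  }
  res_of <- ensemble$atoms$residue_index
  cos_cut <- cos(angle_cut * pi / 180)
  for (f in frames) {
    xyz <- frame_coords(ensemble, f)
    for (r in seq_len(nrow(donors))) {
      d_heavy <- donors[r, "heavy"]
      d_h <- donors[r, "hydrogen"]
      acc <- acceptors[acceptors != d_heavy & res_of[acceptors] != res_of[d_heavy]]
      if (length(acc) == 0L) next
      da <- sweep(xyz[acc, , drop = FALSE], 2L, xyz[d_heavy, ])
      dist_da <- sqrt(rowSums(da^2))
      ok <- dist_da <= d_cut
      if (!any(ok)) next
      dh <- xyz[d_h, ] - xyz[d_heavy, ]
      dh <- dh / sqrt(sum(dh^2))
      cos_ang <- (da[ok, , drop = FALSE] %*% dh) / dist_da[ok]
      hit <- acc[ok][cos_ang >= cos_cut]
      for (a in hit) {
        counts[res_of[d_heavy], res_of[a]] <- counts[res_of[d_heavy], res_of[a]] + 1
      }
    }
  }
  m <- counts / length(frames)
  if (symmetrize) m <- m + t(m)
  new_contact_map(m, "hbonds_per_frame", "bonds_per_frame")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %d x %d, statistic = %s (%s)\n",
    nrow(x), ncol(x), attr(x, "statistic"), attr(x, "units")
  ))
  invisible(x)
}
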