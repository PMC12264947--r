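# Shared fixtures and independent brute-force oracles.

# a bare point-cloud ensemble (all-carbon, one residue per atom)
point_ensemble <- function(coords, element = "C") {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  n <- dim(coords)[2]
  new_ensemble(
    coords,
    atom_name = rep(element, n),
    residue_index = seq_len(n),
    residue_name = rep("ALA", n)
  )
}

# brute-force radius of gyration by the definition, double loop over atoms
rg_brute <- function(xyz, w) {
  w <- w / sum(w)
  ctr <- c(sum(xyz[, 1] * w), sum(xyz[, 2] * w), sum(xyz[, 3] * w))
  acc <- 0
  for (i in seq_len(nrow(xyz))) {
    acc <- acc + w[i] * sum((xyz[i, ] - ctr)^2)
  }
  sqrt(acc)
}

# brute-force residue-pair minimum distance over frames
min_map_brute <- function(ensemble, frames = seq_len(n_frames(ensemble))) {
  nr <- n_residues(ensemble)
  res <- ensemble$atoms$residue_index
  out <- matrix(Inf, nr, nr)
  diag(out) <- 0
  for (f in frames) {
    xyz <- matrix(ensemble$coords[f, , ], ncol = 3)
    dmat <- as.matrix(stats::dist(xyz))
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        d <- min(dmat[res == i, res == j])
        if (d < out[i, j]) out[i, j] <- out[j, i] <- d
      }
    }
  }
  out
}

# apply a random rigid motion to every frame (same or per-frame motion)
rigid_move <- function(ensemble, per_frame = FALSE, seed = 99) {
  withr::with_seed(seed, {
    coords <- ensemble$coords
    rot <- ensembledecomp:::random_rotation_matrix()
    shift <- stats::rnorm(3, sd = 10)
    for (f in seq_len(dim(coords)[1])) {
      if (per_frame) {
        rot <- ensembledecomp:::random_rotation_matrix()
        shift <- stats::rnorm(3, sd = 10)
      }
      coords[f, , ] <- sweep(matrix(ensemble$coords[f, , ], ncol = 3) %*% rot, 2, shift, "+")
    }
    new_ensemble(
      coords, ensemble$atoms$atom_name, ensemble$atoms$residue_index,
      ensemble$atoms$residue_name
    )
  })
}

# four well-separated Gaussian blobs with ground-truth labels
make_blobs <- function(centers = rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20)),
                       n_per = 50, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(
        stats::rnorm(n_per, centers[i, 1], sd),
        stats::rnorm(n_per, centers[i, 2], sd)
      )
    }))
    list(points = pts, truth = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# exhaustive delta_max over ALL charge arrangements of a composition
delta_max_exhaustive <- function(n_pos, n_neg, len, g) {
  best <- 0
  for (pp in utils::combn(len, n_pos, simplify = FALSE)) {
    rest <- setdiff(seq_len(len), pp)
    for (mm in utils::combn(rest, n_neg, simplify = FALSE)) {
      ch <- integer(len)
      ch[pp] <- 1L
      ch[mm] <- -1L
      d <- ensembledecomp:::delta_blob(ch, g)
      if (d > best) best <- d
    }
  }
  best
}

random_sequence <- function(len, seed) {
  withr::with_seed(seed, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    len,
    replace = TRUE
  ), collapse = ""))
}
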