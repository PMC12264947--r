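# Synthetic fixture generators: dihedral-built peptide backbones with
# tunable compactness, trend-carrying secondary-structure labels, two-state
# time series for tICA validation, and closed-form Gaussian-chain
# scattering curves. Every generator is a pure function of its arguments
# (seeded, platform-stable), so analyses are testable with no download.

# ideal backbone geometry (Angstrom / degrees), trans peptide bond
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_N_H <- 1.010
BOND_CA_CB <- 1.521
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
ANGLE_C_N_H <- 119.0
OMEGA_TRANS <- 180

# dihedral basins: helix-like (compact) vs extended/PPII-like
BASIN_HELIX <- c(phi = -60, psi = -45)
BASIN_EXTENDED <- c(phi = -70, psi = 145)

# natural-extension-reference-frame placement: position d with |d-c| = bond,
# angle(b,c,d) = angle and torsion(a,b,c,d) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# build one backbone conformation from per-residue phi/psi (degrees).
# atoms per residue: N, H (from residue 2), CA, CB, C, O.
build_backbone_frame <- function(phi, psi, with_cb = TRUE) {
  nr <- length(phi)
  atoms <- list()
  n_prev <- c(0, 0, 0)
  ca_prev <- c(BOND_N_CA, 0, 0)
  c_prev <- place_atom(
    c(0, 1, 0), n_prev, ca_prev, BOND_CA_C, ANGLE_N_CA_C,
    phi[1] + 180 # reference torsion from a dummy direction; phi_1 unused
  )
  add <- function(res, name, pos) {
    atoms[[length(atoms) + 1L]] <<- list(res = res, name = name, pos = pos)
  }
  add(1L, "N", n_prev)
  add(1L, "CA", ca_prev)
  if (with_cb) {
    add(1L, "CB", place_atom(n_prev, c_prev, ca_prev, BOND_CA_CB, 110.1, 122.6))
  }
  add(1L, "C", c_prev)
  for (i in 2:nr) {
    n_i <- place_atom(n_prev, ca_prev, c_prev, BOND_C_N, ANGLE_CA_C_N, psi[i - 1L])
    ca_i <- place_atom(ca_prev, c_prev, n_i, BOND_N_CA, ANGLE_C_N_CA, OMEGA_TRANS)
    c_i <- place_atom(c_prev, n_i, ca_i, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    # carbonyl O of residue i-1: anti to the new amide N
    o_prev <- place_atom(n_prev, ca_prev, c_prev, BOND_C_O, ANGLE_CA_C_O, psi[i - 1L] + 180)
    add(i - 1L, "O", o_prev)
    add(i, "N", n_i)
    # amide hydrogen: in the peptide plane, anti to the carbonyl O
    add(i, "H", place_atom(ca_prev, c_prev, n_i, BOND_N_H, ANGLE_C_N_H, 0))
    add(i, "CA", ca_i)
    if (with_cb) {
      add(i, "CB", place_atom(n_i, c_i, ca_i, BOND_CA_CB, 110.1, 122.6))
    }
    add(i, "C", c_i)
    n_prev <- n_i
    ca_prev <- ca_i
    c_prev <- c_i
  }
  # terminal carbonyl O placed with the sampled psi of the last residue
  add(nr, "O", place_atom(n_prev, ca_prev, c_prev, BOND_C_O, ANGLE_CA_C_O, psi[nr] + 180))
  ord <- order(vapply(atoms, function(a) a$res, 0L) * 10L +
    match(
      vapply(atoms, function(a) a$name, ""),
      c("N", "H", "CA", "CB", "C", "O")
    ))
  atoms <- atoms[ord]
  list(
    coords = do.call(rbind, lapply(atoms, function(a) a$pos)),
    atom_name = vapply(atoms, function(a) a$name, ""),
    residue_index = vapply(atoms, function(a) a$res, 0L)
  )
}

sample_dihedrals <- function(n_residues, compactness, jitter_sd, helix_span) {
  helix <- stats::runif(n_residues) < compactness
  if (!is.null(helix_span)) helix[helix_span] <- TRUE
  phi <- ifelse(helix, BASIN_HELIX["phi"], BASIN_EXTENDED["phi"]) +
    stats::rnorm(n_residues, sd = jitter_sd)
  psi <- ifelse(helix, BASIN_HELIX["psi"], BASIN_EXTENDED["psi"]) +
    stats::rnorm(n_residues, sd = jitter_sd)
  list(phi = phi, psi = psi, helix = helix)
}

#' Generate a dihedral-built peptide backbone ensemble
#'
#' Frames are built residue-by-residue from sampled (phi, psi) angles with
#' ideal bond lengths and angles and a fixed trans omega. Each residue's
#' basin is helix-like (compact) with probability `compactness`, otherwise
#' extended/PPII-like; both basins carry Gaussian jitter. Atoms per
#' residue: backbone N, CA, C, O, the amide H (from residue 2) and a
#' C-beta stub. Self-clashes are not resolved (no excluded volume). The
#' sampled ground-truth dihedrals are returned for oracle tests.
#'
#' @param n_residues Chain length (>= 2).
#' @param n_frames Number of conformations.
#' @param compactness Probability of the helix basin per residue, in
#'   `[0, 1]`; may be a per-frame vector.
#' @param jitter_sd Gaussian jitter around the basin centers, degrees
#'   (default 15).
#' @param helix_span Optional residue indices always placed in the helix
#'   basin (planted helix).
#' @param seed Integer RNG seed.
#' @return A list: `ensemble`, `phi`/`psi` (frames x residues ground-truth
#'   matrices, degrees), `helix` (logical matrix of basin assignments),
#'   `compactness` (per frame).
#' @export
gen_backbone_ensemble <- function(n_residues = 38, n_frames = 100,
                                  compactness = 0.5, jitter_sd = 15,
                                  helix_span = NULL, seed = 1L) {
  if (n_residues < 2L) abort_ed("Need at least 2 residues.", "parameter")
  if (any(compactness < 0 | compactness > 1)) {
    abort_ed("`compactness` must lie in [0, 1].", "parameter")
  }
  compactness <- rep_len(compactness, n_frames)
  withr::with_seed(as.integer(seed), {
    phi <- psi <- hel <- matrix(0, n_frames, n_residues)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      di <- sample_dihedrals(n_residues, compactness[f], jitter_sd, helix_span)
      phi[f, ] <- di$phi
      psi[f, ] <- di$psi
      hel[f, ] <- di$helix
      frames[[f]] <- build_backbone_frame(di$phi, di$psi)
    }
    coords <- array(0, dim = c(n_frames, nrow(frames[[1]]$coords), 3L))
    for (f in seq_len(n_frames)) coords[f, , ] <- frames[[f]]$coords
    ens <- new_ensemble(
      coords,
      atom_name = frames[[1]]$atom_name,
      residue_index = frames[[1]]$residue_index,
      residue_name = rep("ALA", nrow(frames[[1]]$coords))
    )
    list(
      ensemble = ens, phi = phi, psi = psi, helix = hel == 1,
      compactness = compactness
    )
  })
}

#' Generate a heterogeneous compact-to-extended ensemble
#'
#' Per-frame compactness is drawn from a Beta distribution (default
#' Beta(2, 2), broad and symmetric), so radius of gyration, end-to-end
#' distance and solvent-accessible surface area are broad and mutually
#' positively correlated -- the premise of the combined conformation
#' parameter. With the default resolution `alpha = 5`, decomposition of
#' such an ensemble populates several integer groups around 15.
#'
#' @inheritParams gen_backbone_ensemble
#' @param shape1,shape2 Beta parameters for the per-frame compactness
#'   (default 2, 2).
#' @return As [gen_backbone_ensemble()].
#' @export
gen_heterogeneous_ensemble <- function(n_residues = 38, n_frames = 2000,
                                       shape1 = 2, shape2 = 2,
                                       jitter_sd = 15, seed = 1L) {
  if (n_frames < 100L) abort_ed("Heterogeneous ensembles need >= 100 frames.", "parameter")
  compact <- withr::with_seed(
    as.integer(seed) + 1L,
    stats::rbeta(n_frames, shape1, shape2)
  )
  gen_backbone_ensemble(
    n_residues = n_residues, n_frames = n_frames,
    compactness = compact, jitter_sd = jitter_sd, seed = seed
  )
}

#' Generate secondary-structure labels with an extension-correlated trend
#'
#' Per-frame, per-residue labels drawn with class probabilities that depend
#' monotonically on the frame's end-to-end-distance percentile: the PPII
#' (`P`) probability increases with extension at rate `trend_strength`
#' (compensated by the unassigned class), emulating the increased PPII
#' tendency of less compact conformations. Residues in `helix_span` are
#' always labeled `H`.
#'
#' @param ree Per-frame end-to-end distances (numeric vector or a data
#'   frame with a `ree` column).
#' @param n_residues Residues per frame.
#' @param trend_strength Slope of the P-class probability over the Ree
#'   percentile, in probability units (default 0.2; 0 removes the trend).
#' @param helix_span Optional residue indices always labeled `H`.
#' @param seed Integer RNG seed.
#' @return An [ss_series()] matrix (frames x residues).
#' @export
gen_ss_labels <- function(ree, n_residues, trend_strength = 0.2,
                          helix_span = NULL, seed = 1L) {
  if (is.data.frame(ree)) ree <- ree$ree
  if (!is.null(helix_span) && any(helix_span < 1 | helix_span > n_residues)) {
    abort_ed("`helix_span` outside 1..n_residues.", "alignment")
  }
  n_frames <- length(ree)
  # disordered peptides carry mostly bends/turns/PPII; helix and strand are
  # rare, transient elements
  base <- c(H = 0.02, E = 0.03, T = 0.22, S = 0.22, P = 0.20, `~` = 0.31)
  pct <- (rank(ree, ties.method = "average") - 0.5) / n_frames
  withr::with_seed(as.integer(seed), {
    labels <- matrix("~", n_frames, n_residues)
    for (f in seq_len(n_frames)) {
      p <- base
      shift <- trend_strength * (pct[f] - 0.5)
      p["P"] <- max(base["P"] + shift, 0)
      p["~"] <- max(base["~"] - shift, 0)
      labels[f, ] <- sample(names(p), n_residues, replace = TRUE, prob = p)
    }
    if (!is.null(helix_span)) labels[, helix_span] <- "H"
    ss_series(labels)
  })
}

#' Generate a two-state Markov time series for tICA validation
#'
#' A symmetric two-state Markov chain (switch probability per step) drives
#' state-dependent channel means; each channel adds Gaussian noise. The
#' true state sequence is returned so recovery can be scored.
#'
#' @param n_frames Series length.
#' @param switch_prob Per-step switching probability, in (0, 1).
#' @param n_channels Observation channels (default 6).
#' @param noise_sd Gaussian noise standard deviation per channel.
#' @param seed Integer RNG seed.
#' @return A list: `features` (frames x channels `feature_matrix`),
#'   `states` (integer vector of 0/1).
#' @export
gen_two_state_series <- function(n_frames, switch_prob = 0.01, n_channels = 6,
                                 noise_sd = 0.5, seed = 1L) {
  if (switch_prob <= 0 || switch_prob >= 1) {
    abort_ed("`switch_prob` must lie strictly between 0 and 1.", "parameter")
  }
  withr::with_seed(as.integer(seed), {
    flips <- stats::runif(n_frames) < switch_prob
    states <- cumsum(flips) %% 2L
    loadings <- stats::runif(n_channels, 0.5, 1.5) *
      sample(c(-1, 1), n_channels, replace = TRUE)
    signal <- outer(2 * states - 1, loadings)
    feats <- signal + matrix(
      stats::rnorm(n_frames * n_channels, sd = noise_sd),
      n_frames, n_channels
    )
    colnames(feats) <- paste0("ch", seq_len(n_channels))
    list(
      features = structure(feats, class = c("feature_matrix", "matrix")),
      states = as.integer(states)
    )
  })
}

#' Generate a Gaussian-chain (Debye-function) scattering curve
#'
#' \eqn{I(q)/I(0) = 2 (e^{-x} + x - 1)/x^2} with \eqn{x = (q R_g)^2}: the
#' closed-form scattering of an ideal Gaussian chain. Optional
#' multiplicative Gaussian noise with a matching sigma column.
#'
#' @param rg Radius of gyration, Angstrom.
#' @param q_grid Scattering vector grid (default 200 points over
#'   0.008..0.495, the typical measured range).
#' @param i0 Zero-angle intensity scale (default 1).
#' @param noise_fraction Relative noise amplitude (default 0 = noiseless).
#' @param seed Integer RNG seed (used only when noisy).
#' @return A [scatter_curve()]; `sigma` present when `noise_fraction > 0`.
#' @export
gen_gaussian_chain_curve <- function(rg, q_grid = seq(0.008, 0.495, length.out = 200),
                                     i0 = 1, noise_fraction = 0, seed = 1L) {
  check_scalar_number(rg, "rg", positive = TRUE)
  x <- (q_grid * rg)^2
  # series expansion below x ~ 1e-3: the closed form cancels catastrophically
  intensity <- i0 * ifelse(
    x < 1e-3,
    1 - x / 3 + x^2 / 12,
    2 * (exp(-x) + x - 1) / x^2
  )
  if (noise_fraction > 0) {
    intensity <- withr::with_seed(
      as.integer(seed),
      intensity * (1 + noise_fraction * stats::rnorm(length(intensity)))
    )
    scatter_curve(q_grid, intensity, sigma = pmax(noise_fraction * abs(intensity), 1e-12))
  } else {
    scatter_curve(q_grid, intensity)
  }
}
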