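test_that("dihedral features recover the generator's ground truth", {
  gen <- gen_backbone_ensemble(n_residues = 10, n_frames = 5, seed = 3)
  di <- backbone_dihedrals(gen$ensemble)
  phi <- di[di$angle == "phi", ]
  phi <- phi[order(phi$frame, phi$residue), ]
  expect_lt(
    max(abs(phi$value - as.vector(t(gen$phi[, 2:10])))),
    1e-6
  )
  psi <- di[di$angle == "psi", ]
  psi <- psi[order(psi$frame, psi$residue), ]
  expect_lt(
    max(abs(psi$value - as.vector(t(gen$psi[, 1:9])))),
    1e-6
  )

  feats <- dihedral_features(gen$ensemble)
  expect_equal(ncol(feats), 4 * 9) # 4 * (n_residues - 1)
  # every sin/cos pair lies on the unit circle
  sin_cols <- seq(1, ncol(feats), by = 2)
  expect_equal(
    as.vector(feats[, sin_cols]^2 + feats[, sin_cols + 1]^2),
    rep(1, length(sin_cols) * 5)
  )

  two <- gen_backbone_ensemble(n_residues = 2, n_frames = 3, seed = 4)
  expect_equal(ncol(dihedral_features(two$ensemble)), 4L)

  broken <- point_ensemble(matrix(rnorm(9), 3, 3))
  expect_error(dihedral_features(broken), class = "ensembledecomp_error_topology")
})

test_that("PCA projection matches a direct eigendecomposition", {
  withr::with_seed(5, {
    line <- outer(rnorm(100), c(1, 2, 3)) + matrix(rnorm(300, sd = 1e-4), 100, 3)
    x <- matrix(rnorm(50 * 8), 50, 8)
  })
  p_line <- pca_project(line, 2)
  expect_gte(p_line$explained_variance[1], 0.9999)

  p <- pca_project(x, 4)
  proj_cov <- stats::cov(as.matrix(p$scores[, -1]))
  expect_lt(max(abs(proj_cov[upper.tri(proj_cov)])), 1e-8)

  eig <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(
    p$explained_variance,
    (eig$values / sum(eig$values))[1:4],
    tolerance = 1e-10
  )
  for (k in 1:4) {
    expect_equal(abs(sum(p$rotation[, k] * eig$vectors[, k])), 1, tolerance = 1e-8)
  }

  rankdef <- cbind(x[, 1], x[, 1], x[, 1])
  expect_warning(pca_project(rankdef, 3), "rank")
})

test_that("tICA separates slow processes from noise", {
  withr::with_seed(6, {
    wn <- matrix(rnorm(5000 * 6), 5000, 6)
  })
  tw <- tica_project(wn, lag = 50)
  expect_lt(max(abs(tw$eigenvalues)), 0.1)

  ts <- gen_two_state_series(5000, switch_prob = 0.01, n_channels = 6,
    noise_sd = 0.5, seed = 7)
  tp <- tica_project(ts$features, lag = 50)
  expect_gt(abs(stats::cor(tp$scores$tic1, ts$states)), 0.9)
  expect_true(all(abs(tp$eigenvalues) <= 1 + 1e-8))

  # lag-1 on an AR(1) series recovers the autoregressive coefficient
  a <- 0.8
  withr::with_seed(8, {
    n <- 20000
    ar <- as.numeric(stats::arima.sim(list(ar = a), n))
    noise <- rnorm(n)
  })
  ta <- tica_project(cbind(ar, noise), lag = 1, n_components = 1)
  expect_equal(ta$eigenvalues[1], a, tolerance = 0.05)

  # when the slow direction is also the high-variance direction, the
  # leading tIC and PC coincide
  withr::with_seed(9, {
    slow <- 5 * as.numeric(stats::arima.sim(list(ar = 0.99), 4000))
    feats <- cbind(slow, matrix(rnorm(4000 * 3), 4000, 3))
  })
  tic1 <- tica_project(feats, lag = 20, n_components = 1)$scores$tic1
  pc1 <- pca_project(feats, 1)$scores$pc1
  expect_gt(abs(stats::cor(tic1, pc1)), 0.99)

  expect_error(tica_project(wn, lag = 5000), class = "ensembledecomp_error_parameter")
  expect_error(tica_project(wn, lag = 0), class = "ensembledecomp_error_parameter")
})

test_that("free-energy landscapes implement the occupancy formula exactly", {
  # uniform occupancy: all occupied bins at dF = 0, before and after shift
  withr::with_seed(10, {
    grid_pts <- as.matrix(expand.grid(x = 1:8, y = 1:8))[rep(1:64, 5), ]
  })
  uni <- free_energy_landscape(grid_pts, n_bins = 8)
  expect_true(all(uni$delta_f[uni$occupied] == 0))
  uni_s <- free_energy_landscape(grid_pts, n_bins = 8, shift_to_zero_max = TRUE)
  expect_true(all(uni_s$delta_f[uni_s$occupied] == 0))

  # two bins with counts {n, n*e}: unshifted gap exactly kB T
  n_small <- 200
  n_big <- round(n_small * exp(1))
  pts <- rbind(
    cbind(rep(0.25, n_big), 0.5),
    cbind(rep(0.75, n_small), 0.5)
  )
  fel2 <- free_energy_landscape(pts, n_bins = 2, units = "kJ/mol", temperature = 298)
  kbt <- 0.008314462618 * 298
  occ <- sort(fel2$delta_f[fel2$occupied])
  expect_equal(diff(occ), -kbt * log(n_small / n_big), tolerance = 1e-6)
  expect_equal(min(occ), 0)

  # large Gaussian sample against the brute-force histogram oracle
  withr::with_seed(11, {
    gauss <- cbind(rnorm(1e5), rnorm(1e5))
  })
  fel <- free_energy_landscape(gauss, n_bins = 64)
  ix <- findInterval(gauss[, 1], fel$x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(gauss[, 2], fel$y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- unclass(table(factor(ix, 1:64), factor(iy, 1:64)))
  oracle <- ifelse(cnt > 0, -log(cnt / max(cnt)), NA_real_)
  expect_equal(unname(fel$delta_f), unname(oracle), tolerance = 1e-12)

  # invariants: minimum occupied dF exactly 0; permutation invariance;
  # masked bins are NA, never infinite
  expect_identical(min(fel$delta_f[fel$occupied]), 0)
  perm <- withr::with_seed(12, sample(nrow(gauss)))
  fel_p <- free_energy_landscape(gauss[perm, ], n_bins = 64)
  expect_identical(fel$delta_f, fel_p$delta_f)
  expect_true(all(is.na(fel$delta_f[!fel$occupied])))
  expect_false(any(is.infinite(fel$delta_f), na.rm = TRUE))

  shifted <- free_energy_landscape(gauss, n_bins = 64, shift_to_zero_max = TRUE)
  expect_equal(max(shifted$delta_f[shifted$occupied]), 0)
  expect_true(all(shifted$delta_f[shifted$occupied] <= 0))

  expect_warning(
    free_energy_landscape(matrix(1, 5, 2), n_bins = 4),
    "identical"
  )

  # serialization writes a sentinel token for masked bins
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape_tsv(fel, path)
  grid <- utils::read.table(path, sep = "\t", colClasses = "character")
  expect_true(any(grid == "masked"))
})
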