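test_that("radius of gyration matches symmetry cases and brute force", {
  ens <- point_ensemble(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(radius_of_gyration(ens)$rg, 1.0)
  expect_equal(radius_of_gyration(point_ensemble(rbind(c(3, 4, 5))))$rg, 0)

  withr::with_seed(11, {
    xyz <- matrix(rnorm(150, sd = 4), 50, 3)
  })
  ens50 <- point_ensemble(xyz)
  expect_lt(
    abs(radius_of_gyration(ens50)$rg - rg_brute(xyz, ens50$atoms$mass)),
    1e-10
  )
  expect_lt(
    abs(radius_of_gyration(ens50, mass_weighted = FALSE)$rg - rg_brute(xyz, rep(1, 50))),
    1e-10
  )
})

test_that("end-to-end distance resolves selectors and hits 3-4-5", {
  ens <- new_ensemble(
    rbind(c(0, 0, 0), c(3, 4, 0)),
    c("N", "C"), c(1L, 2L), c("ALA", "ALA")
  )
  expect_equal(end_to_end_distance(ens)$ree, 5.0)
  expect_equal(end_to_end_distance(ens, start_atom = 1, end_atom = 1)$ree, 0)

  dup <- new_ensemble(
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    c("N", "N", "C"), c(1L, 1L, 2L), c("ALA", "ALA", "ALA")
  )
  expect_error(end_to_end_distance(dup), class = "ensembledecomp_error_selection")

  # near-extended chains sit in the rod-like regime, Ree > Rg * sqrt(3)
  gen <- gen_backbone_ensemble(n_residues = 38, n_frames = 20, compactness = 0, seed = 2)
  d <- dplyr::left_join(
    radius_of_gyration(gen$ensemble), end_to_end_distance(gen$ensemble),
    by = "frame"
  )
  expect_true(all(d$ree > d$rg * sqrt(3)))
})

test_that("polymer shape follows the closed forms", {
  expect_equal(
    polymer_shape(tibble::tibble(rg = c(2, 3), ree = c(2, 3)))$ps,
    c(1, 1)
  )
  # a discrete uniform rod: Rg^2 = L^2 (n+1) / (12 (n-1)), so the shape
  # parameter is 12 (n-1)/(n+1), converging to the continuum value 12
  n <- 2001
  rod <- point_ensemble(cbind(seq(0, 100, length.out = n), 0, 0))
  d <- tibble::tibble(
    rg = radius_of_gyration(rod, mass_weighted = FALSE)$rg,
    ree = 100
  )
  expect_equal(polymer_shape(d)$ps, 12 * (n - 1) / (n + 1), tolerance = 1e-9)
  expect_equal(polymer_shape(d)$ps, 12, tolerance = 2e-3)

  withr::with_seed(3, {
    rg <- runif(5, 5, 15)
    ree <- runif(5, 5, 40)
  })
  expect_equal(
    polymer_shape(tibble::tibble(rg = rg, ree = ree))$ps,
    ree^2 / rg^2
  )
  expect_error(
    polymer_shape(tibble::tibble(rg = c(1, 0), ree = c(1, 1))),
    class = "ensembledecomp_error_division"
  )
})

test_that("Shrake-Rupley SASA matches closed forms and a fine-grid oracle", {
  one <- point_ensemble(rbind(c(0, 0, 0)), element = "O") # r = 1.52
  expect_equal(
    sasa_shrake_rupley(one, probe_radius = 1.4)$sasa,
    4 * pi * (1.52 + 1.4)^2,
    tolerance = 0.01
  )
  # two coincident identical atoms bury each other completely
  two <- new_ensemble(matrix(0, 2, 3), c("O", "O"), c(1L, 2L), c("HOH", "HOH"))
  expect_equal(sasa_shrake_rupley(two)$sasa, 0)

  withr::with_seed(4, {
    xyz <- matrix(rnorm(60, sd = 2), 20, 3)
  })
  cluster <- point_ensemble(xyz)
  coarse <- sasa_shrake_rupley(cluster, n_sphere_points = 960)$sasa
  fine <- sasa_shrake_rupley(cluster, n_sphere_points = 10000)$sasa
  expect_lt(abs(coarse - fine) / fine, 0.02)

  # burial grows monotonically as two atoms approach
  sep <- c(7, 5, 4, 3, 2, 1, 0.5)
  areas <- vapply(sep, function(d) {
    sum(sasa_shrake_rupley(point_ensemble(rbind(c(0, 0, 0), c(d, 0, 0))))$sasa)
  }, 0)
  expect_true(all(diff(areas) < 0))

  per_res <- sasa_shrake_rupley(cluster, per_residue = TRUE)
  expect_equal(sum(per_res$sasa), coarse)
})

test_that("Kabsch superposition is exact, optimal and matches bio3d", {
  withr::with_seed(5, {
    a <- matrix(rnorm(30), 10, 3)
    axis <- c(0, 0, 1)
  })
  same <- kabsch_superpose(a, a)
  expect_equal(same$rmsd, 0)
  expect_equal(same$rotation, diag(3))

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_lt(kabsch_superpose(a, a %*% rot90)$rmsd, 1e-10)

  withr::with_seed(6, {
    b <- matrix(rnorm(30), 10, 3)
    random_rmsds <- replicate(100, {
      r <- ensembledecomp:::random_rotation_matrix()
      sqrt(mean(rowSums((sweep(b, 2, colMeans(b)) %*% r -
        sweep(a, 2, colMeans(a)))^2)))
    })
  })
  fit <- kabsch_superpose(a, b)
  expect_true(all(fit$rmsd <= random_rmsds + 1e-12))

  ref_fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref_fit, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-8)

  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), class = "ensembledecomp_error_degeneracy")
})

test_that("RMSF recovers planted jitter and ignores rigid motion", {
  withr::with_seed(7, {
    base <- matrix(rnorm(60, sd = 5), 20, 3)
  })
  nf <- 2000
  coords <- array(rep(base, each = nf), c(nf, 20, 3))
  sigma <- 0.4
  withr::with_seed(8, {
    coords[, 20, ] <- coords[, 20, ] + rnorm(nf * 3, sd = sigma)
  })
  ens <- new_ensemble(coords, rep("CA", 20), 1:20, rep("ALA", 20))
  prof <- rmsf(ens, superpose_subset = 1:19)
  expect_equal(prof$rmsf[20], sigma * sqrt(3), tolerance = 0.05)
  expect_true(all(prof$rmsf[1:19] < 1e-8))

  ident <- new_ensemble(
    array(rep(base, each = 5), c(5, 20, 3)),
    rep("CA", 20), 1:20, rep("ALA", 20)
  )
  expect_lt(max(rmsf(ident, superpose_subset = 1:20)$rmsf), 1e-7)

  gen <- gen_backbone_ensemble(n_residues = 8, n_frames = 30, seed = 9)
  moved <- rigid_move(gen$ensemble, per_frame = TRUE)
  expect_lt(
    max(abs(rmsf(gen$ensemble)$rmsf - rmsf(moved)$rmsf)),
    1e-6
  )
  expect_error(rmsf(subset_frames(gen$ensemble, 1L)),
    class = "ensembledecomp_error_insufficient_frames"
  )
})

test_that("minimum-distance maps agree with brute force and are invariant", {
  gen <- gen_backbone_ensemble(n_residues = 6, n_frames = 10, seed = 10)
  m <- min_distance_map(gen$ensemble)
  expect_true(all(diag(m) == 0))
  expect_identical(unclass(m), t(unclass(m)))
  expect_equal(unclass(m), min_map_brute(gen$ensemble),
    tolerance = 1e-10, ignore_attr = TRUE
  )

  moved <- rigid_move(gen$ensemble)
  expect_lt(max(abs(min_distance_map(moved) - m)), 1e-8)

  norm <- min_distance_map(gen$ensemble, normalize = TRUE)
  expect_equal(max(norm), 1)

  expect_error(min_distance_map(gen$ensemble, frames = integer(0)),
    class = "ensembledecomp_error_empty_selection"
  )
})

test_that("mean minimum pair distance averages per-frame minima", {
  # 3 frames with planted per-frame minima 2, 3, 4 between residues 1 and 2
  coords <- array(0, c(3, 2, 3))
  coords[, 2, 1] <- c(2, 3, 4)
  ens <- new_ensemble(coords, c("CA", "CA"), c(1L, 2L), c("ALA", "ALA"))
  expect_equal(mean_min_pair_distance(ens, c(1, 2)), 3.0)

  gen <- gen_backbone_ensemble(n_residues = 5, n_frames = 8, seed = 11)
  pairdist <- mean_min_pair_distance(gen$ensemble, c(1, 4))
  expect_gte(pairdist, min_distance_map(gen$ensemble)[1, 4])

  ident <- subset_frames(gen$ensemble, rep(1L, 4))
  expect_equal(
    mean_min_pair_distance(ident, c(1, 4)),
    min_distance_map(ident)[1, 4]
  )
  expect_error(mean_min_pair_distance(gen$ensemble, c(2, 2)),
    class = "ensembledecomp_error_self_pair"
  )
})

test_that("hydrogen-bond maps apply the geometric criterion", {
  # donor N-H and acceptor O planted at controlled geometry
  make_geom <- function(da_dist, angle_deg) {
    h <- c(1.0, 0, 0)
    acc <- da_dist * c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
    new_ensemble(
      rbind(c(0, 0, 0), h, acc),
      c("N", "H", "O"), c(1L, 1L, 2L), c("ALA", "ALA", "ALA")
    )
  }
  inside <- hbond_contact_map(make_geom(2.9, 10))
  expect_equal(inside[1, 2], 1)
  too_far <- hbond_contact_map(make_geom(3.6, 10))
  expect_equal(sum(too_far), 0)
  bad_angle <- hbond_contact_map(make_geom(2.9, 40))
  expect_equal(sum(bad_angle), 0)

  # ideal helix backbone shows the i -> i-4 band
  hx <- gen_backbone_ensemble(n_residues = 10, n_frames = 3, compactness = 1,
    jitter_sd = 0, seed = 1)
  hb <- hbond_contact_map(hx$ensemble)
  band <- vapply(5:10, function(i) hb[i, i - 4L], 0)
  expect_true(all(band > 0))

  no_h <- point_ensemble(matrix(rnorm(9), 3, 3))
  expect_error(hbond_contact_map(no_h), class = "ensembledecomp_error_missing_hydrogen")
})
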