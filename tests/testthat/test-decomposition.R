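make_descriptor_table <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    frame = seq_len(n),
    rg = exp(rnorm(n, log(12), 0.2)),
    ree = exp(rnorm(n, log(25), 0.3)),
    sasa = exp(rnorm(n, log(1200), 0.15))
  ))
}

test_that("the conformation parameter obeys its exact identities", {
  d <- make_descriptor_table(200)
  centered <- tibble::tibble(
    frame = 1L, rg = mean(d$rg), ree = mean(d$ree), sasa = mean(d$sasa)
  )
  both <- conformation_parameter(dplyr::bind_rows(d, centered), alpha = 5)
  expect_equal(both$xconf[201], 15, tolerance = 1e-12)

  x <- conformation_parameter(d, alpha = 5)
  expect_equal(mean(x$xconf), 15, tolerance = 1e-12)

  d10 <- make_descriptor_table(10, seed = 2)
  x10 <- conformation_parameter(d10, alpha = 3.2)
  by_hand <- 3.2 * (d10$rg / mean(d10$rg) + d10$ree / mean(d10$ree) +
    d10$sasa / mean(d10$sasa))
  expect_equal(x10$xconf, by_hand, tolerance = 1e-12)

  # doubling alpha doubles every value and never reorders frames
  x2 <- conformation_parameter(d10, alpha = 6.4)
  expect_equal(x2$xconf, 2 * x10$xconf)
  expect_identical(order(x2$xconf), order(x10$xconf))

  degen <- tibble::tibble(rg = c(0, 0), ree = c(1, 1), sasa = c(1, 1))
  expect_error(conformation_parameter(degen), class = "ensembledecomp_error_degenerate_ensemble")
})

test_that("decomposition partitions frames by nearest integer", {
  g <- decompose(tibble::tibble(frame = 1:3, xconf = c(9.6, 15.2, 20.4)))
  expect_equal(g$group, c(10L, 15L, 20L))

  same <- decompose(tibble::tibble(frame = 1:5, xconf = rep(14.9, 5)))
  expect_equal(unique(same$group), 15L)
  expect_equal(nrow(group_sizes(same)), 1L)

  withr::with_seed(4, {
    xconf <- runif(1e4, 5, 30)
  })
  g4 <- decompose(tibble::tibble(frame = seq_len(1e4), xconf = xconf))
  # partition: every frame in exactly one group
  expect_equal(sort(unlist(lapply(
    group_sizes(g4)$group, group_frames, groups = g4
  ))), seq_len(1e4))
  # labels equal brute-force nearest-integer assignment (half-up)
  expect_equal(g4$group, as.integer(floor(xconf + 0.5)))
  # histogram oracle for the sizes
  sizes <- group_sizes(g4)
  hist_oracle <- table(floor(xconf + 0.5))
  expect_equal(sizes$n_frames, as.integer(hist_oracle))
  # monotone: higher xconf never maps to a lower group
  ord <- order(xconf)
  expect_true(all(diff(g4$group[ord]) >= 0))
})

test_that("single-descriptor binning honors the bin width", {
  d <- tibble::tibble(frame = 1:3, rg = c(10.1, 10.4, 13.2))
  g <- decompose_single(d, "rg", 1)
  expect_equal(length(unique(g$group)), 2L)

  gwide <- decompose_single(d, "rg", 10)
  expect_equal(length(unique(gwide$group)), 1L)

  withr::with_seed(5, {
    vals <- runif(1e3, 0, 50)
  })
  gb <- decompose_single(tibble::tibble(frame = seq_len(1e3), v = vals), "v", 2.5)
  oracle <- floor((vals - min(vals)) / 2.5)
  expect_equal(length(unique(gb$group)), length(unique(oracle)))
  expect_true(all(tapply(oracle, gb$group, function(x) length(unique(x))) == 1))

  expect_error(decompose_single(d, "rg", 0), class = "ensembledecomp_error_parameter")
})

test_that("per-group secondary-structure fractions sum to one and track trends", {
  lab <- ss_series(c("H~", "H~"))
  g <- decompose(tibble::tibble(frame = 1:2, xconf = c(10, 10)))
  fr <- group_ss_fractions(lab, g)
  expect_equal(fr$fraction[fr$ss_class == "H"], 0.5)
  expect_equal(fr$fraction[fr$ss_class == "~"], 0.5)
  expect_equal(sum(fr$fraction), 1)

  pure <- group_ss_fractions(ss_series(c("PPP", "PPP")), g)
  expect_equal(pure$fraction[pure$ss_class == "P"], 1)

  hidden <- group_ss_fractions(lab, g, hide_unassigned = TRUE)
  expect_false("~" %in% hidden$ss_class)

  expect_error(group_ss_fractions(lab, decompose(tibble::tibble(frame = 1:3, xconf = 1:3))),
    class = "ensembledecomp_error_alignment"
  )

  # extension-correlated PPII trend shows up across low/mid/high groups
  gen <- gen_heterogeneous_ensemble(n_residues = 12, n_frames = 1500, seed = 6)
  ree <- end_to_end_distance(gen$ensemble)
  ss <- gen_ss_labels(ree, 12, trend_strength = 0.3, seed = 7)
  terciles <- cut(ree$ree, stats::quantile(ree$ree, c(0, 1 / 3, 2 / 3, 1)),
    include.lowest = TRUE, labels = FALSE
  )
  g3 <- structure(
    tibble::tibble(frame = ree$frame, group = terciles),
    class = class(decompose(tibble::tibble(frame = 1, xconf = 1)))
  )
  fr3 <- group_ss_fractions(ss, g3)
  p_frac <- fr3$fraction[fr3$ss_class == "P"]
  expect_true(all(diff(p_frac) > 0))
})

test_that("group-wise hydrogen-bond maps add up over the partition", {
  gen <- gen_backbone_ensemble(n_residues = 8, n_frames = 40, compactness = 0.5, seed = 8)
  d <- frame_descriptors(gen$ensemble, n_sphere_points = 120)
  g <- decompose(conformation_parameter(d))
  maps <- group_hbond_maps(gen$ensemble, g)
  whole <- hbond_contact_map(gen$ensemble)
  sizes <- group_sizes(g)
  weighted <- Reduce(`+`, Map(
    function(m, n) unclass(m) * n,
    maps[as.character(sizes$group)], sizes$n_frames
  )) / n_frames(gen$ensemble)
  expect_equal(weighted, unclass(whole), tolerance = 1e-12)

  # compact (helix-basin) frames bond far more than extended frames
  compact <- gen_backbone_ensemble(8, 15, compactness = 1, jitter_sd = 3, seed = 9)
  extended <- gen_backbone_ensemble(8, 15, compactness = 0, jitter_sd = 3, seed = 9)
  expect_gt(
    sum(hbond_contact_map(compact$ensemble)),
    sum(hbond_contact_map(extended$ensemble))
  )
})

test_that("pair-distance tables have the Table-style layout", {
  gen <- gen_backbone_ensemble(n_residues = 10, n_frames = 30, seed = 10)
  d <- frame_descriptors(gen$ensemble, n_sphere_points = 120)
  g <- decompose(conformation_parameter(d))
  n_groups <- nrow(group_sizes(g))
  pairs <- list(c(5, 3), c(9, 7), c(2, 1))
  tab <- group_pair_distance_table(gen$ensemble, g, pairs)
  expect_equal(dim(tab), c(3L, n_groups + 1L))
  expect_match(tab$pair[1], "^ALA5-ALA3$")

  one_group <- structure(
    tibble::tibble(frame = seq_len(n_frames(gen$ensemble)), group = 1L),
    class = class(g)
  )
  tab1 <- group_pair_distance_table(gen$ensemble, one_group, list(c(5, 3)))
  expect_equal(
    tab1$group_1,
    mean_min_pair_distance(gen$ensemble, c(5, 3))
  )

  # direct neighbors along a near-rigid backbone stay near-constant
  rigid <- gen_backbone_ensemble(10, 60, compactness = 0.5, jitter_sd = 2, seed = 11)
  dr <- frame_descriptors(rigid$ensemble, n_sphere_points = 120)
  gr <- decompose(conformation_parameter(dr))
  tabn <- group_pair_distance_table(rigid$ensemble, gr, list(c(6, 5)))
  vals <- as.numeric(tabn[1, -1])
  expect_lt(max(vals) - min(vals), 0.35)
})

test_that("propensity-vs-Ree KDE normalizes and finds planted modes", {
  gen <- gen_heterogeneous_ensemble(n_residues = 10, n_frames = 400, seed = 12)
  ree <- end_to_end_distance(gen$ensemble)
  ss <- gen_ss_labels(ree, 10, trend_strength = 0.3, seed = 13)
  kd <- ss_vs_ree_kde(ss, ree, "P")
  dx <- diff(kd$x[1:2])
  dy <- diff(kd$y[1:2])
  expect_equal(sum(kd$z) * dx * dy, 1, tolerance = 0.01)

  # two planted, well-separated modes are both recovered as local maxima
  withr::with_seed(14, {
    prop <- c(rnorm(300, 0.1, 0.02), rnorm(300, 0.8, 0.02))
    ree2 <- c(rnorm(300, 15, 1), rnorm(300, 45, 1))
    lab2 <- ss_series(matrix(
      ifelse(stats::runif(600 * 10) < rep(prop, 10), "H", "~"), 600, 10
    ))
  })
  # both planted (propensity, Ree) modes appear as strong density ridges
  kde_pkg <- ss_vs_ree_kde(lab2, ree2, "H")
  zmax_low <- max(kde_pkg$z[kde_pkg$y < 30, ])
  zmax_high <- max(kde_pkg$z[, kde_pkg$y > 30])
  expect_gt(zmax_low, 0.5 * max(kde_pkg$z))
  expect_gt(zmax_high, 0.5 * max(kde_pkg$z))

  const <- ss_series(matrix("~", 50, 10))
  expect_error(ss_vs_ree_kde(const, rnorm(50, 20), "P"),
    class = "ensembledecomp_error_degenerate_kde"
  )
})

test_that("per-residue occurrence profiles normalize by the class total", {
  lab <- ss_series(c("~~H~~", "~~H~~"))
  prof <- ss_residue_occurrence(lab, "H")
  expect_equal(prof$occurrence, c(0, 0, 1, 0, 0))

  uni <- ss_series(matrix("T", 4, 6))
  expect_equal(ss_residue_occurrence(uni, "T")$occurrence, rep(1 / 6, 6))

  expect_warning(
    empty <- ss_residue_occurrence(lab, "G"),
    "never occurs"
  )
  expect_equal(empty$occurrence, rep(0, 5))

  # planted helix span dominates the H profile
  gen <- gen_heterogeneous_ensemble(n_residues = 38, n_frames = 300, seed = 15)
  ree <- end_to_end_distance(gen$ensemble)
  ss <- gen_ss_labels(ree, 38, helix_span = 28:37, seed = 16)
  prof_h <- ss_residue_occurrence(ss, "H")
  expect_gte(sum(prof_h$occurrence[28:37]), 0.9)
})
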