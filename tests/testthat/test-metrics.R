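test_that("riemann distance: identity, similarity invariance, orthogonal case", {
  L <- efa_inverse(efa_normalize(efa_forward(wobbly_pts(100), 8)), 150)
  expect_identical(riemann_distance(L, L), 0)

  ang <- 73 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  L2 <- L %*% t(R) * 4.2 + matrix(c(11, -3), nrow(L), 2, byrow = TRUE)
  expect_lt(riemann_distance(L, L2), 1e-10)

  # equilateral triangle vs its reflection: orthogonal preshapes, pi/2
  tri <- cbind(cos(2 * pi * (0:2) / 3), sin(2 * pi * (0:2) / 3))
  tri_ref <- cbind(tri[, 1], -tri[, 2])
  expect_equal(riemann_distance(tri, tri_ref), pi / 2, tolerance = 1e-12)

  expect_error(riemann_distance(L, L[1:10, ]), "different numbers")
  expect_error(riemann_distance(L * 0, L), "degenerate")
})

test_that("riemann distance agrees with the rotation-grid Procrustes oracle", {
  set.seed(101)
  for (i in 1:100) {
    L1 <- random_landmarks(12)
    L2 <- random_landmarks(12)
    expect_equal(riemann_distance(L1, L2), grid_riemann_oracle(L1, L2),
                 tolerance = 1e-4)
  }
})

test_that("metric axioms hold numerically on random triples", {
  set.seed(7)
  shapes <- replicate(60, random_landmarks(15), simplify = FALSE)
  worst <- 0
  for (i in 1:1000) {
    abc <- sample(60, 3)
    dab <- riemann_distance(shapes[[abc[1]]], shapes[[abc[2]]])
    dbc <- riemann_distance(shapes[[abc[2]]], shapes[[abc[3]]])
    dac <- riemann_distance(shapes[[abc[1]]], shapes[[abc[3]]])
    expect_gte(dab, 0)
    expect_lte(dab, pi / 2)
    worst <- max(worst, dac - (dab + dbc))
  }
  expect_lte(worst, 1e-9)
  # symmetry is exact; indiscernibility under similarity transforms
  d12 <- riemann_distance(shapes[[1]], shapes[[2]])
  d21 <- riemann_distance(shapes[[2]], shapes[[1]])
  expect_identical(d12, d21)
  expect_lt(riemann_distance(shapes[[1]], shapes[[1]] * 3 + 1), 1e-10)
  expect_gt(d12, 1e-3)
})

test_that("preshape centers and scales to the unit sphere", {
  p <- preshape(random_landmarks(40) * 7 + 3)
  expect_lt(max(abs(colMeans(p))), 1e-12)
  expect_equal(sum(p^2), 1, tolerance = 1e-12)
})

test_that("mean shape: identity, rotation removal, equivariance", {
  L <- efa_inverse(efa_normalize(efa_forward(wobbly_pts(80), 6)), 150)
  expect_lt(riemann_distance(mean_shape(list(L)), L), 1e-12)

  ang <- 40 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  m <- mean_shape(list(L, L %*% t(R)))
  expect_lt(riemann_distance(m, L), 1e-10)

  # equivariance: transforming every input leaves the mean's shape fixed
  set.seed(3)
  sets <- replicate(5, L + matrix(rnorm(300, 0, 0.02), 150, 2),
                    simplify = FALSE)
  m1 <- mean_shape(sets)
  S <- matrix(c(cos(1.3), sin(1.3), -sin(1.3), cos(1.3)), 2) * 2.2
  m2 <- mean_shape(lapply(sets, function(s)
    s %*% t(S) + matrix(c(5, 5), 150, 2, byrow = TRUE)))
  expect_lt(riemann_distance(m1, m2), 1e-9)
  expect_error(mean_shape(list()), "non-empty")
  expect_error(mean_shape(list(L, L[1:10, ])), "same number")
})

test_that("averaging jittered copies moves toward the truth", {
  truth <- generate_population(lm2_templates(), seed = 9)$landmarks[[1]]
  ds <- structure(list(
    specimens = data.frame(specimen_id = "S001", class_label = "A",
                           tooth_position = "LM2"),
    landmarks = list(S001 = truth),
    tracings = list(S001 = list()), seed = 9, K = 150),
    class = "tooth_dataset")
  wins <- 0
  for (rep in 1:20) {
    sim <- simulate_worker_tracings(
      ds, worker_noise_model(jitter_sd = 0.02, p_gross_error = 0,
                             p_missing = 0, n_replicates = 25),
      seed = 1000 + rep)
    trs <- sim$tracings$S001
    d_ind <- vapply(trs, riemann_distance, 1, L2 = truth)
    d_mean <- riemann_distance(mean_shape(trs), truth)
    if (d_mean < stats::median(d_ind)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("gold-standard filtering applies the 0.2 threshold rule", {
  pop <- generate_population(lm2_templates(), seed = 21)
  gold <- pop$landmarks[[1]]
  far <- star_landmarks()      # shape far beyond the rejection threshold
  trs <- lapply(c(0.05, 0.15, 0.25), function(d)
    blend_to_distance(gold, far, d))
  b <- filter_tracings(tracing_bundle("S001", gold = gold, tracings = trs),
                       consensus_config(threshold = 0.2))
  expect_equal(b$distances, c(0.05, 0.15, 0.25), tolerance = 1e-6)
  expect_identical(b$kept, c(TRUE, TRUE, FALSE))
  expect_false(b$no_usable)

  # all beyond threshold -> flagged unusable
  b2 <- filter_tracings(
    tracing_bundle("S002", gold = gold,
                   tracings = lapply(c(0.3, 0.4), function(d)
                     blend_to_distance(gold, far, d))),
    consensus_config(threshold = 0.2))
  expect_true(b2$no_usable)
  expect_identical(b2$kept, c(FALSE, FALSE))

  # monotone in threshold: kept sets are nested
  b_lo <- filter_tracings(b, consensus_config(threshold = 0.1))
  expect_true(all(which(b_lo$kept) %in% which(b$kept)))
  expect_error(filter_tracings(tracing_bundle("x", tracings = trs),
                               consensus_config()), "gold")
})

test_that("worker-mean filtering excludes a gross error and improves consensus", {
  pop <- generate_population(lm2_templates(), seed = 33)
  truth <- pop$landmarks[[5]]
  wins <- 0
  for (rep in 1:25) {
    set.seed(400 + rep)
    good <- replicate(2, truth + matrix(rnorm(300, 0, 0.02 *
      sqrt(mean(rowSums(sweep(truth, 2, colMeans(truth))^2)))), 150, 2),
      simplify = FALSE)
    gross <- blend_to_distance(truth, star_landmarks(), 0.45)
    b <- filter_tracings(
      tracing_bundle("S005", tracings = c(good, list(gross))),
      consensus_config(reference_mode = "worker_mean"))
    expect_false(b$kept[3])
    d_filtered <- riemann_distance(consensus_shape(b), truth)
    d_all <- riemann_distance(mean_shape(c(good, list(gross))), truth)
    if (d_filtered < d_all) wins <- wins + 1
  }
  expect_gte(wins, 23)
})

test_that("error summaries compute order statistics and histograms", {
  pop <- generate_population(lm2_templates(), seed = 2)
  gold <- pop$landmarks[[1]]
  far <- star_landmarks()
  mk <- function(id, ds) filter_tracings(
    tracing_bundle(id, gold = gold,
                   tracings = lapply(ds, blend_to_distance,
                                     from = gold, toward = far)),
    consensus_config(threshold = 10))
  b1 <- mk("a", c(0.1, 0.2, 0.3))
  es <- error_summary(list(b1))
  expect_equal(es$summary$median, 0.2, tolerance = 1e-6)
  expect_equal(es$summary$min, 0.1, tolerance = 1e-6)
  expect_equal(es$summary$max, 0.3, tolerance = 1e-6)
  expect_equal(sum(es$histogram$count), 3)

  # all-zero distances
  b0 <- filter_tracings(
    tracing_bundle("z", gold = gold, tracings = list(gold, gold)),
    consensus_config())
  es0 <- error_summary(list(b0))
  expect_true(all(es0$summary[, c("min", "median", "max")] == 0))

  # a noisier group has the higher median
  b2 <- mk("b", c(0.02, 0.04, 0.06))
  es2 <- error_summary(list(b1, b2), groups = c("LM1", "LM2"))
  med <- setNames(es2$summary$median, es2$summary$group)
  expect_gt(med["LM1"], med["LM2"])
})
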