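test_that("default population reproduces the campaign layout", {
  pop <- generate_population(default_templates(), seed = 1)
  expect_identical(nrow(pop$specimens), 96L)
  expect_identical(as.vector(table(pop$specimens$class_label)[
    c("Alcelaphini", "Bovini", "Hippotragini", "Neotragini")]),
    c(33L, 10L, 35L, 18L))
  lm2 <- generate_population(lm2_templates(), seed = 1)
  expect_identical(nrow(lm2$specimens), 38L)
  expect_identical(sort(as.vector(table(lm2$specimens$class_label))),
                   c(8L, 15L, 15L))
})

test_that("same seed reproduces the dataset bit-for-bit", {
  a <- generate_population(lm2_templates(), seed = 77)
  b <- generate_population(lm2_templates(), seed = 77)
  expect_identical(a, b)
  n <- worker_noise_model()
  expect_identical(simulate_worker_tracings(a, n, seed = 5),
                   simulate_worker_tracings(b, n, seed = 5))
  # serialization round trip is byte-identical
  s1 <- serialize(simulate_worker_tracings(a, n, seed = 5), NULL)
  s2 <- serialize(simulate_worker_tracings(b, n, seed = 5), NULL)
  expect_identical(s1, s2)
})

test_that("zero dispersion collapses a class onto its mean shape", {
  tp <- list(shape_class_template("only", molar_mean_shape(), 0, 5))
  pop <- generate_population(tp, seed = 4)
  lms <- pop$landmarks
  for (i in 2:5)
    expect_lt(riemann_distance(lms[[1]], lms[[i]]), 1e-10)
})

test_that("well-separated templates separate in Riemann distance", {
  tps <- list(
    shape_class_template("round", molar_mean_shape(1.0, 1.0, waist = 0),
                         0.02, 8),
    shape_class_template("long", molar_mean_shape(2.0, 1.0, waist = 0),
                         0.02, 8))
  pop <- generate_population(tps, seed = 6)
  lab <- pop$specimens$class_label
  ids <- pop$specimens$specimen_id
  within <- c(); between <- c()
  for (i in 1:15) for (j in (i + 1):16) {
    d <- riemann_distance(pop$landmarks[[ids[i]]], pop$landmarks[[ids[j]]])
    if (lab[i] == lab[j]) within <- c(within, d) else between <- c(between, d)
  }
  expect_gt(mean(between), mean(within))
})

test_that("degenerate generator inputs error", {
  expect_error(generate_population(list(), 1), "non-empty")
  tp <- lm2_templates()
  tp[[2]]$class_label <- tp[[1]]$class_label
  expect_error(generate_population(tp, 1), "distinct")
  bad <- molar_mean_shape()
  bad$an[2] <- NaN
  expect_error(shape_class_template("x", bad, 0.1, 3), "finite")
  expect_error(worker_noise_model(p_missing = 1.4), "probabilities")
})

test_that("noiseless workers copy the truth; certain dropout empties tracings", {
  pop <- generate_population(lm2_templates(), seed = 8)
  clean <- simulate_worker_tracings(
    pop, worker_noise_model(jitter_sd = 0, boundary_bias = 0,
                            p_gross_error = 0, p_missing = 0), seed = 2)
  for (id in pop$specimens$specimen_id[1:10]) {
    expect_length(clean$tracings[[id]], 3)
    for (tr in clean$tracings[[id]])
      expect_lt(riemann_distance(tr, pop$landmarks[[id]]), 1e-12)
  }
  gone <- simulate_worker_tracings(
    pop, worker_noise_model(p_missing = 1), seed = 2)
  expect_true(all(lengths(gone$tracings) == 0))
})

test_that("gross-error and dropout frequencies match their probabilities", {
  # ~1150 candidate tracings; 99% binomial CI on the observed fractions
  tp <- list(shape_class_template("a", molar_mean_shape(), 0.04, 96))
  pop <- generate_population(tp, seed = 12)
  noise <- worker_noise_model(jitter_sd = 0.01, p_gross_error = 0.1,
                              p_missing = 0.1, n_replicates = 4)
  sim <- simulate_worker_tracings(pop, noise, seed = 13)
  n_cand <- 96 * 4
  n_returned <- sum(lengths(sim$tracings))
  p_miss_hat <- 1 - n_returned / n_cand
  ci_miss <- qnorm(0.995) * sqrt(0.1 * 0.9 / n_cand)
  expect_lt(abs(p_miss_hat - 0.1), ci_miss)

  d <- unlist(lapply(names(sim$tracings), function(id)
    vapply(sim$tracings[[id]], riemann_distance, 1,
           L2 = sim$landmarks[[id]])))
  frac_far <- mean(d > 0.2)
  ci_gross <- qnorm(0.995) * sqrt(0.1 * 0.9 / n_returned)
  expect_lt(abs(frac_far - 0.1), ci_gross)
  # the far tracings are exactly the flagged gross errors at this jitter
  gross_flag <- unlist(lapply(sim$tracings, function(trs)
    vapply(trs, function(t) isTRUE(attr(t, "gross")), TRUE)))
  expect_identical(sum(gross_flag), sum(d > 0.2))
})

test_that("median worker error increases strictly with jitter_sd", {
  pop <- generate_population(lm2_templates(), seed = 18)
  meds <- vapply(c(0.05, 0.1, 0.15), function(js) {
    sim <- simulate_worker_tracings(
      pop, worker_noise_model(jitter_sd = js, p_gross_error = 0,
                              p_missing = 0), seed = 19)
    stats::median(unlist(lapply(names(sim$tracings), function(id)
      vapply(sim$tracings[[id]], riemann_distance, 1,
             L2 = sim$landmarks[[id]]))))
  }, 1)
  expect_true(all(diff(meds) > 0))
})

test_that("default noise hits the intended median worker error scale", {
  pop <- generate_population(lm2_templates(), seed = 25)
  sim <- simulate_worker_tracings(pop, worker_noise_model(), seed = 26)
  d <- unlist(lapply(names(sim$tracings), function(id)
    vapply(sim$tracings[[id]], function(tr)
      riemann_distance(
        efa_inverse(efa_normalize(efa_forward(tr, 10)), 150),
        sim$landmarks[[id]]), 1)))
  med <- stats::median(d)
  expect_gt(med, 0.08)
  expect_lt(med, 0.16)
})
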