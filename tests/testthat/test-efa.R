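test_that("closed-form shapes are recovered: circle and ellipse", {
  ef <- efa_forward(circle_pts(360), H = 2)
  expect_equal(ef$A0, 0, tolerance = 1e-3)
  expect_equal(ef$C0, 0, tolerance = 1e-3)
  expect_equal(c(ef$an[1], ef$bn[1], ef$cn[1], ef$dn[1]), c(1, 0, 0, 1),
               tolerance = 1e-3)
  expect_lt(max(abs(c(ef$an[2], ef$bn[2], ef$cn[2], ef$dn[2]))), 1e-3)

  # chord-length parameterization of a 2:1 ellipse; expected first-harmonic
  # values frozen from a dense (2e6-point) trapezoidal Fourier integration
  # of the arc-length parameterized ellipse
  ef2 <- efa_forward(ellipse_pts(360, 2, 1), H = 2)
  expect_equal(c(ef2$an[1], ef2$bn[1], ef2$cn[1], ef2$dn[1]),
               c(1.82841, 0, 0, 1.07302), tolerance = 1e-3)
})

test_that("polygon coefficients match the numeric-integration oracle", {
  for (poly in list(square_pts(), wobbly_pts(40))) {
    H <- 8
    ef <- efa_forward(poly, H)
    o <- dense_efa_oracle(poly, H)
    expect_equal(ef$A0, o$A0, tolerance = 1e-6)
    expect_equal(ef$C0, o$C0, tolerance = 1e-6)
    got <- rbind(ef$an, ef$bn, ef$cn, ef$dn)
    expect_lt(max(abs(got - o$coef)), 1e-6)
  }
})

test_that("A0, C0 equal the chord-length parameterization centroid", {
  poly <- wobbly_pts(60)
  ef <- efa_forward(poly, 4)
  o <- dense_efa_oracle(poly, 1)
  expect_equal(c(ef$A0, ef$C0), c(o$A0, o$C0), tolerance = 1e-8)
})

test_that("normalization is a fixed point on canonical circle coefficients", {
  ec <- efa_normalize(efa_forward(circle_pts(720), H = 2))
  ec2 <- efa_normalize(new_unnormalized(ec))
  expect_lt(max(abs(unlist(ec[c("an", "bn", "cn", "dn")]) -
                      unlist(ec2[c("an", "bn", "cn", "dn")]))), 1e-9)
})

test_that("normalized coefficients are invariant to start vertex, rotation, translation", {
  shp <- wobbly_pts(200)
  base <- efa_normalize(efa_forward(shp, 10))
  cv <- function(e) unlist(e[c("an", "bn", "cn", "dn")])

  for (shift in c(17, 50, 133)) {
    e2 <- efa_normalize(efa_forward(shp[c((shift + 1):200, 1:shift), ], 10))
    expect_lt(max(abs(cv(base) - cv(e2))), 1e-6)
  }
  for (ang in c(pi / 6, 1.2, -2.5)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    e3 <- efa_normalize(efa_forward(shp %*% t(R) +
                                      matrix(c(3, -7), 200, 2, byrow = TRUE),
                                    10))
    expect_lt(max(abs(cv(base) - cv(e3))), 1e-6)
  }
  # scaling scales all coefficients proportionally
  e4 <- efa_normalize(efa_forward(shp * 2.5, 10))
  expect_lt(max(abs(cv(base) * 2.5 - cv(e4))), 1e-6)
  # pinned entries
  expect_equal(base$bn[1], 0)
  expect_equal(base$cn[1], 0)
  expect_gt(base$an[1], 0)
})

test_that("per-harmonic power is start-vertex invariant before normalization", {
  shp <- wobbly_pts(120)
  p1 <- harmonic_power(efa_forward(shp, 8))
  p2 <- harmonic_power(efa_forward(shp[c(41:120, 1:40), ], 8))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("landmark regeneration: count, circle geometry, K validation", {
  ec <- efa_normalize(efa_forward(circle_pts(720), H = 4))
  lm <- efa_inverse(ec, K = 150)
  expect_identical(nrow(lm), 150L)
  r <- sqrt(rowSums(lm^2))
  expect_lt(max(abs(r - 1)), 1e-3)
  ang <- atan2(lm[, 2], lm[, 1])
  gaps <- diff(ang) %% (2 * pi)
  expect_lt(max(abs(gaps - 2 * pi / 150)), 1e-3)
  expect_error(efa_inverse(ec, K = 2), "K")
  # default K is 150 on any decomposition
  expect_identical(nrow(efa_inverse(efa_normalize(efa_forward(wobbly_pts(), 10)))),
                   150L)
})

test_that("square reconstruction stays near the boundary despite corner ringing", {
  sq <- square_pts()
  lm <- suppressWarnings(efa_inverse(efa_forward(sq, 20), 500))
  expect_lt(max(dist_to_poly(lm, sq)), 0.02)
})

test_that("round-trip Hausdorff error is non-increasing in H and small by H = 32", {
  set.seed(11)
  poly <- generate_population(lm2_templates(), seed = 5)$landmarks[[1]]
  ct <- extract_contour(rasterize_landmarks(poly, 512))
  rms <- sqrt(mean(rowSums(sweep(ct, 2, colMeans(ct))^2)))
  prev <- Inf
  for (H in c(1, 2, 4, 8, 16, 32)) {
    lmH <- suppressWarnings(efa_inverse(efa_forward(ct, H), 1000))
    h <- hausdorff_to_poly(lmH, ct)
    expect_lte(h, prev + 1e-12)
    prev <- h
  }
  expect_lt(prev / rms, 0.01)
})

test_that("feature vectors: packing, lengths, congruence invariance", {
  shp <- wobbly_pts(150)
  ef <- efa_normalize(efa_forward(shp, 10))
  v <- efa_features(ef)
  expect_length(v, 40)
  expect_identical(unname(v[1:4]), c(ef$an[1], ef$bn[1], ef$cn[1], ef$dn[1]))
  expect_length(efa_features(ef, drop_pinned = TRUE), 38)
  expect_length(efa_features(ef, size_invariant = TRUE), 37)

  # congruent shape at another rotation and start vertex: same features
  R <- matrix(c(cos(1.1), sin(1.1), -sin(1.1), cos(1.1)), 2)
  shp2 <- (shp %*% t(R))[c(61:150, 1:60), ]
  v2 <- efa_features(efa_normalize(efa_forward(shp2, 10)))
  expect_lt(max(abs(v - v2)), 1e-6)
  expect_error(efa_features(efa_forward(shp, 10)), "normalized")
})

test_that("degenerate inputs are refused", {
  expect_error(efa_forward(cbind(c(0, 1), c(0, 0)), 1), "3 distinct")
  expect_error(efa_forward(wobbly_pts(50), 0), "positive integer")
  expect_error(efa_forward(cbind(c(0, 0, 1), c(0, 0, 1)), 1), "coincident")
})
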