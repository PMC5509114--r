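# Shared fixtures and independent oracles for the test suite.

circle_pts <- function(n = 360, r = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(t), r * sin(t))
}

ellipse_pts <- function(n = 360, a = 2, b = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(t), b * sin(t))
}

square_pts <- function() cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

# a smooth asymmetric closed test outline (no special symmetry, so every
# harmonic is informative)
wobbly_pts <- function(n = 200) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(1.2 * cos(t) + 0.2 * cos(2 * t) + 0.05 * sin(3 * t),
        0.7 * sin(t) + 0.1 * sin(3 * t) + 0.04 * cos(2 * t))
}

# Oracle 1: dense trapezoidal numeric Fourier integration of the
# chord-length parameterization of a polygon. Independent of efa_forward
# (which uses the closed-form segment integrals).
dense_efa_oracle <- function(xy, H, m = 200000) {
  n <- nrow(xy)
  nxt <- xy[c(2:n, 1), , drop = FALSE]
  dl <- sqrt(rowSums((nxt - xy)^2))
  Tt <- sum(dl)
  s0 <- c(0, cumsum(dl))
  s <- seq(0, Tt, length.out = m + 1)
  seg <- findInterval(s, s0, rightmost.closed = TRUE)
  seg[seg > n] <- n
  f <- (s - s0[seg]) / dl[seg]
  x <- xy[seg, 1] + f * (nxt[seg, 1] - xy[seg, 1])
  y <- xy[seg, 2] + f * (nxt[seg, 2] - xy[seg, 2])
  trap <- function(g) sum(diff(s) * (g[-1] + g[-length(g)]) / 2)
  coef <- sapply(seq_len(H), function(j) {
    w <- 2 * pi * j * s / Tt
    c(a = 2 / Tt * trap(x * cos(w)), b = 2 / Tt * trap(x * sin(w)),
      c = 2 / Tt * trap(y * cos(w)), d = 2 / Tt * trap(y * sin(w)))
  })
  list(A0 = trap(x) / Tt, C0 = trap(y) / Tt, coef = coef)
}

# Oracle 2: Riemannian distance via brute-force minimization of the
# chordal (full) Procrustes fit over a dense rotation grid, mapped through
# the arccos relation. Independent of the complex inner-product shortcut.
grid_riemann_oracle <- function(L1, L2, steps = 1e5) {
  pre <- function(L) {
    L <- sweep(L, 2, colMeans(L))
    z <- complex(real = L[, 1], imaginary = L[, 2])
    z / sqrt(sum(Mod(z)^2))
  }
  cc <- sum(Conj(pre(L1)) * pre(L2))
  th <- seq(0, 2 * pi, length.out = steps + 1)[-(steps + 1)]
  # at rotation th with optimal nonnegative scale, the residual is
  # 1 - max(0, Re(e^{i th} c))^2; minimizing it maximizes the real part
  best <- max(Re(exp(1i * th) * cc))
  acos(min(1, max(0, best)))
}

# Oracle 3: exact distances from a point set to a polygon boundary
# (vectorized point-to-segment), used for Hausdorff-type bounds.
dist_to_poly <- function(pts, poly) {
  n <- nrow(poly)
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- nxt[i, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    L2 <- abx^2 + aby^2
    if (L2 == 0) next
    tt <- pmax(0, pmin(1, ((pts[, 1] - a[1]) * abx +
                             (pts[, 2] - a[2]) * aby) / L2))
    d <- pmin(d, sqrt((a[1] + tt * abx - pts[, 1])^2 +
                        (a[2] + tt * aby - pts[, 2])^2))
  }
  d
}

hausdorff_to_poly <- function(p1, p2)
  max(max(dist_to_poly(p1, p2)), max(dist_to_poly(p2, p1)))

poly_area_signed <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  0.5 * sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])
}

poly_perimeter <- function(xy) {
  n <- nrow(xy)
  sum(sqrt(rowSums((xy[c(2:n, 1), , drop = FALSE] - xy)^2)))
}

# construct a landmark set at (approximately) a target Riemannian distance
# from `from`, by blending toward `toward` (root-finding on the blend)
blend_to_distance <- function(from, toward, target) {
  f <- function(a) riemann_distance((1 - a) * from + a * toward, from) - target
  a <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
  (1 - a) * from + a * toward
}

random_landmarks <- function(K = 20) matrix(stats::rnorm(2 * K), K, 2)

# a five-lobed star: far from every molar-like outline in shape space
# (Riemann distance > 0.48), for constructing gross-error tracings
star_landmarks <- function(K = 150) {
  t <- seq(0, 2 * pi, length.out = 181)[-181]
  r <- 1 + 0.9 * cos(5 * t)
  efa_inverse(efa_normalize(efa_forward(cbind(r * cos(t), r * sin(t)), 10)),
              K)
}

# strip the normalized flag so normalization can be re-applied
new_unnormalized <- function(e) {
  e$normalized <- FALSE
  e
}

# rasterized disk mask of radius r centered in an n x n image
disk_mask <- function(n = 201, r = 50) {
  cx <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), n), n)
  yy <- t(xx)
  binary_mask((xx - cx)^2 + (yy - cx)^2 <= r^2)
}
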