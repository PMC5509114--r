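#' Rasterize a closed outline to a binary tracing image
#'
#' Renders a simple closed polygon as the kind of filled black-and-white
#' image a tracing worker produces: the polygon is scaled and translated to
#' fit a square image with the given margin, and a pixel is foreground when
#' its center lies inside the polygon under the even-odd rule.
#' Self-intersecting polygons are refused so that "inside" stays
#' well-defined.
#'
#' @param landmarks n x 2 matrix: vertices of a simple closed polygon
#'   (closing edge implied).
#' @param image_size side length in pixels (>= 32).
#' @param margin fraction of the image side left blank around the shape.
#' @return a [binary_mask()] of size \code{image_size} x \code{image_size}.
#' @export
rasterize_landmarks <- function(landmarks, image_size = 512, margin = 0.05) {
  xy <- check_contour_matrix(landmarks)
  if (image_size < 32) stop("'image_size' must be at least 32")
  if (margin < 0 || margin >= 0.5) stop("'margin' must be in [0, 0.5)")
  if (!polygon_is_simple(xy))
    stop("polygon is self-intersecting; fill is not well-defined")

  rng <- apply(xy, 2, range)
  span <- max(rng[2, ] - rng[1, ])
  if (span <= 0) stop("degenerate polygon with zero extent")
  avail <- image_size * (1 - 2 * margin)
  sc <- avail / span
  ctr <- colMeans(rng)
  x <- (xy[, 1] - ctr[1]) * sc + (image_size + 1) / 2
  y <- (xy[, 2] - ctr[2]) * sc + (image_size + 1) / 2

  # even-odd crossing count per pixel center, vectorized over edges
  px <- seq_len(image_size)           # pixel-center coordinates
  inside <- matrix(0L, image_size, image_size)   # [row = y, col = x]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  for (e in seq_len(n)) {
    y1 <- y[j[e]]; y2 <- y[e]; x1 <- x[j[e]]; x2 <- x[e]
    if (y1 == y2) next
    rows <- which((px >= min(y1, y2)) & (px < max(y1, y2)))
    if (length(rows) == 0) next
    xc <- x1 + (px[rows] - y1) / (y2 - y1) * (x2 - x1)
    for (k in seq_along(rows)) {
      cols <- px > xc[k]
      inside[rows[k], cols] <- inside[rows[k], cols] + 1L
    }
  }
  fg <- inside %% 2L == 1L
  # matrix row 1 should be the top image row (largest Cartesian y)
  binary_mask(fg[rev(seq_len(image_size)), , drop = FALSE])
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Checks every pair of non-adjacent edges for proper or improper
#' intersection. O(n^2), adequate for outline-sized polygons.
#'
#' @param xy n x 2 vertex matrix (closing edge implied).
#' @return logical.
#' @export
polygon_is_simple <- function(xy) {
  xy <- check_contour_matrix(xy)
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
  (d1 == 0 && on_segment(p3, p4, p1)) ||
    (d2 == 0 && on_segment(p3, p4, p2)) ||
    (d3 == 0 && on_segment(p1, p2, p3)) ||
    (d4 == 0 && on_segment(p1, p2, p4))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

on_segment <- function(a, b, p) {
  min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
}
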