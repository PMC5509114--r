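#' Binary tracing mask
#'
#' Constructor for the normalized form of a tracing image: a logical pixel
#' grid where \code{TRUE} marks the tooth (foreground, rendered black in
#' image files) and \code{FALSE} the background (white). Row 1 is the top
#' image row, matching raster file order.
#'
#' @param pixels logical matrix, \code{TRUE} = foreground.
#' @return object of class \code{"binary_mask"} with elements
#'   \code{pixels}, \code{width} (columns), \code{height} (rows).
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("'pixels' must be a logical matrix")
  if (length(pixels) == 0) stop("zero-size mask")
  structure(list(pixels = pixels, width = ncol(pixels),
                 height = nrow(pixels)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask %d x %d px, %d foreground px (%.1f%%)%s\n",
              x$width, x$height, sum(x$pixels),
              100 * mean(x$pixels),
              if (!any(x$pixels)) " [empty: no tracing]" else ""))
  invisible(x)
}

#' Force a raster image to a strict binary mask
#'
#' Worker tracings come back as gray or color rasters that are only
#' approximately black-and-white; this forces them to two levels. Color
#' images are converted to luminance (0.2126 R + 0.7152 G + 0.0722 B)
#' first. Pixels darker than the threshold become foreground (the tooth is
#' the black region).
#'
#' @param image numeric matrix (grayscale) or array with 3+ channels (RGB,
#'   alpha ignored). Intensities may be on the 0..1 scale (as read by image
#'   readers) or 0..255; the threshold is interpreted on the 0..255 scale
#'   either way.
#' @param threshold luminance cutoff in 0..255 (default 128).
#' @return a [binary_mask()]. An all-white image yields a valid mask with
#'   zero foreground pixels.
#' @export
binarize <- function(image, threshold = 128) {
  if (length(image) == 0) stop("zero-size image")
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] < 3)
      image <- image[, , 1]
    else
      image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
        0.0722 * image[, , 3]
  }
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix or 3-channel array")
  thr <- threshold
  if (max(image) <= 1) thr <- threshold / 255
  binary_mask(image < thr)
}

#' Read a tracing image file as a binary mask
#'
#' Reads an 8-bit gray or RGB PNG/JPEG and binarizes it. Files that cannot
#' be parsed as a supported raster (e.g. GIMP project files uploaded
#' instead of an exported image) are rejected with an error.
#'
#' @param path image file path.
#' @param threshold passed to [binarize()].
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, threshold = 128) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file '", path,
                                           "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  # EBImage stores x (columns) in dim 1; transpose to rows = image rows
  a <- if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
  binarize(a, threshold = threshold)
}

#' Write a binary mask as a PNG file
#'
#' Foreground is written as 0 (black), background as 255 (white), matching
#' the convention of the tracing protocol.
#'
#' @param mask a [binary_mask()].
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(ifelse(mask$pixels, 0, 1), path)
  invisible(path)
}

#' Extract the outer boundary contour of a tracing
#'
#' Selects the largest 8-connected foreground component (stray specks are
#' discarded), and traces its outer boundary at the 0.5 iso-level between
#' foreground and background by marching squares, giving sub-pixel vertex
#' positions. The raw iso-contour cuts pixel corners at 45 degrees; a short
#' periodic moving average (window \code{smooth}) removes this stair-step
#' jaggedness, which would otherwise inflate perimeter estimates and inject
#' spurious high-order harmonics. Holes inside the component are ignored:
#' only the outer occlusal outline is analyzed. The y axis is flipped so
#' the contour lives in standard Cartesian orientation, and the contour is
#' returned counter-clockwise.
#'
#' @param mask a [binary_mask()].
#' @param smooth odd window length for periodic boundary smoothing;
#'   \code{0} or \code{1} disables it. Smoothing is skipped for tiny
#'   contours (fewer than 3 x window points).
#' @return an n x 2 numeric matrix (x, y), counter-clockwise, not closed
#'   (last point connects to first). A warning is issued when the
#'   foreground touches the image border (possible clipped tracing).
#' @export
extract_contour <- function(mask, smooth = 3) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  if (!any(px)) stop("no tracing found: mask has no foreground pixels")
  if (any(px[1, ]) || any(px[nrow(px), ]) || any(px[, 1]) ||
      any(px[, ncol(px)]))
    warning("foreground touches the image border; tracing may be clipped")

  lab <- label_components8(px)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- lab == keep

  # pad with background so the iso-contour always closes
  z <- matrix(0, nrow(comp) + 2, ncol(comp) + 2)
  z[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp * 1
  # contourLines wants z[i, j] at (x[i], y[j]); our rows are y
  cl <- grDevices::contourLines(x = seq_len(ncol(z)), y = seq_len(nrow(z)),
                                z = t(z), levels = 0.5)
  if (length(cl) == 0) stop("no tracing found: no iso-contour at level 0.5")
  areas <- vapply(cl, function(cc) abs(polygon_area(cc$x, cc$y)), 1)
  cc <- cl[[which.max(areas)]]   # outer boundary; holes enclose less area

  xs <- cc$x - 1                        # undo padding offset
  ys <- cc$y - 1
  n <- length(xs)
  if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n] }
  ys <- mask$height + 1 - ys            # Cartesian orientation

  if (smooth > 1 && length(xs) >= 3 * smooth) {
    xs <- smooth_periodic(xs, smooth)
    ys <- smooth_periodic(ys, smooth)
  }
  out <- cbind(x = xs, y = ys)
  if (polygon_area(out[, 1], out[, 2]) < 0) out <- out[rev(seq_len(nrow(out))), ]
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find over label ids.
label_components8 <- function(px) {
  lab <- EBImage::imageData(EBImage::bwlabel(px))
  nl <- max(lab)
  if (nl <= 1) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nr - 1), if (off[2] == 1) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr,       if (off[2] == 1) 2:nc       else 1:(nc - 1)]
    hit <- which(a > 0 & b > 0 & a != b)
    if (length(hit))
      for (k in hit) union(a[k], b[k])
  }
  roots <- vapply(seq_len(nl), find, 1L)
  matrix(c(0L, roots)[lab + 1L], nr, nc)
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  i2 <- c(2:n, 1)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

smooth_periodic <- function(v, w) {
  k <- (w - 1) %/% 2
  n <- length(v)
  ext <- c(v[(n - k + 1):n], v, v[1:k])
  as.numeric(stats::filter(ext, rep(1 / w, w), sides = 2))[(k + 1):(k + n)]
}
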