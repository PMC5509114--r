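#' Elliptical Fourier decomposition of a closed outline
#'
#' Fits the classical elliptical Fourier model to a closed polygonal contour,
#' \deqn{x(t) = A_0 + \sum_{j=1}^H a_j \cos(jt) + b_j \sin(jt), \qquad
#'       y(t) = C_0 + \sum_{j=1}^H c_j \cos(jt) + d_j \sin(jt),}
#' using the closed-form coefficient estimators for a chord-length
#' parameterized piecewise-linear contour. These estimators are exact for
#' polygonal input: each coefficient is the analytic Fourier integral of the
#' piecewise-linear coordinate functions. Because the fit is a Fourier
#' integral over the whole closed curve, the starting vertex of the listing
#' does not affect the described shape, only the phase of the coefficients
#' (removed by [efa_normalize()]).
#'
#' @param contour numeric matrix with two columns (x, y): vertices of a
#'   closed outline in order. The closing edge from the last vertex back to
#'   the first is implied; a repeated final vertex is tolerated and dropped.
#' @param H number of harmonics to fit (any positive integer: the
#'   estimators are exact integrals of the polygonal contour, so there is
#'   no sampling-theorem limit on \code{H}; harmonics beyond roughly half
#'   the vertex count describe the polygon's corners rather than the
#'   underlying smooth outline).
#' @return An object of class \code{"efa"}: a list with elements \code{A0},
#'   \code{C0} (the chord-length parameterization centroid), \code{an},
#'   \code{bn}, \code{cn}, \code{dn} (length-\code{H} coefficient vectors),
#'   \code{H}, and \code{normalized} (logical).
#' @seealso [efa_normalize()], [efa_inverse()], [efa_features()],
#'   [harmonic_power()]
#' @examples
#' t <- seq(0, 2 * pi, length.out = 361)[-361]
#' circ <- cbind(cos(t), sin(t))
#' ef <- efa_forward(circ, H = 2)
#' ef$an[1] # ~1
#' @export
efa_forward <- function(contour, H) {
  xy <- check_contour_matrix(contour)
  n <- nrow(xy)
  if (!is.numeric(H) || length(H) != 1L || H < 1 || H != round(H))
    stop("'H' must be a positive integer")

  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0))
    stop("contour has coincident consecutive vertices")
  Tp <- sum(dt)
  if (Tp <= 0) stop("degenerate contour: zero perimeter")
  t1 <- c(0, cumsum(dt))        # t_0 .. t_n, t_n = T

  # A0, C0: centroid of the chord-length parameterization (trapezoid over
  # each linear segment is exact).
  xmid <- (xy[, 1] + c(xy[-1, 1], xy[1, 1])) / 2
  ymid <- (xy[, 2] + c(xy[-1, 2], xy[1, 2])) / 2
  A0 <- sum(dt * xmid) / Tp
  C0 <- sum(dt * ymid) / Tp

  j <- seq_len(H)
  phi <- outer(t1, j) * (2 * pi / Tp)   # (n+1) x H
  dcos <- diff(cos(phi))                # cos(phi_i) - cos(phi_{i-1}), n x H
  dsin <- diff(sin(phi))
  const <- Tp / (2 * pi^2 * j^2)
  an <- const * colSums((dx / dt) * dcos)
  bn <- const * colSums((dx / dt) * dsin)
  cn <- const * colSums((dy / dt) * dcos)
  dn <- const * colSums((dy / dt) * dsin)

  new_efa(A0 = A0, C0 = C0, an = an, bn = bn, cn = cn, dn = dn,
          normalized = FALSE)
}

new_efa <- function(A0, C0, an, bn, cn, dn, normalized = FALSE,
                    start_convention = if (normalized) "first-harmonic-major-axis" else "contour-start") {
  stopifnot(length(an) == length(bn), length(bn) == length(cn),
            length(cn) == length(dn))
  if (!all(is.finite(c(A0, C0, an, bn, cn, dn))))
    stop("non-finite elliptical Fourier coefficients")
  structure(
    list(A0 = A0, C0 = C0, an = an, bn = bn, cn = cn, dn = dn,
         H = length(an), normalized = normalized,
         start_convention = start_convention),
    class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("Elliptical Fourier decomposition: %d harmonics (%s)\n",
              x$H, if (x$normalized) "normalized" else "unnormalized"))
  cat(sprintf("  centroid (A0, C0) = (%.4g, %.4g)\n", x$A0, x$C0))
  pw <- harmonic_power(x)
  cat(sprintf("  first-harmonic share of power: %.1f%%\n",
              100 * pw[1] / sum(pw)))
  invisible(x)
}

#' Canonical start-point and orientation normalization
#'
#' Applies the standard first-harmonic normalization: the curve parameter is
#' re-phased so that \eqn{t = 0} falls on the first harmonic ellipse's
#' semi-major axis, and the coordinate frame is rotated (about the outline
#' centroid) so that this major axis defines orientation zero. After
#' normalization \code{bn[1]} and \code{cn[1]} are zero and \code{an[1] > 0}
#' (the semi-major length). Reflection is deliberately not normalized: left
#' and right molars are genuinely different shapes.
#'
#' Landmarks regenerated from a normalized decomposition "begin in the same
#' location" for every tracing of a tooth, which is what makes them usable
#' as homologous landmarks.
#'
#' @param decomp an unnormalized \code{"efa"} object.
#' @return the normalized \code{"efa"} object (shape unchanged up to a
#'   rotation about its centroid).
#' @export
efa_normalize <- function(decomp) {
  stopifnot(inherits(decomp, "efa"))
  if (isTRUE(decomp$normalized)) return(decomp)
  a1 <- decomp$an[1]; b1 <- decomp$bn[1]
  c1 <- decomp$cn[1]; d1 <- decomp$dn[1]
  if (a1^2 + b1^2 + c1^2 + d1^2 <= 0)
    stop("degenerate first harmonic: cannot normalize")

  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  # The major axis crosses the first ellipse twice: theta and theta + pi
  # both give a1 > 0 with b1 = c1 = 0, but flip the sign of every even
  # harmonic. Resolve the ambiguity deterministically by taking the
  # lexicographically larger coefficient vector, which is invariant to the
  # contour's start vertex, rotation, translation, and (positive) scale.
  cand <- lapply(c(theta, theta + pi), function(th) {
    out <- apply_phase_rotation(decomp, th)
    psi <- atan2(out$cn[1], out$an[1])
    apply_frame_rotation(out, psi)
  })
  v1 <- coeff_vector(cand[[1]]); v2 <- coeff_vector(cand[[2]])
  sc <- sqrt(sum(v1^2))
  delta <- v1 - v2
  first <- which(abs(delta) > 1e-9 * sc)
  out <- if (length(first) == 0 || delta[first[1]] > 0)
    cand[[1]] else cand[[2]]
  out$bn[1] <- 0
  out$cn[1] <- 0
  out$normalized <- TRUE
  out$start_convention <- "first-harmonic-major-axis"
  out
}

coeff_vector <- function(ef) as.numeric(rbind(ef$an, ef$bn, ef$cn, ef$dn))

# re-phase the parameter: t -> t + theta (start-point shift)
apply_phase_rotation <- function(ef, theta) {
  j <- seq_len(ef$H)
  cj <- cos(j * theta); sj <- sin(j * theta)
  an <- ef$an * cj + ef$bn * sj
  bn <- -ef$an * sj + ef$bn * cj
  cn <- ef$cn * cj + ef$dn * sj
  dn <- -ef$cn * sj + ef$dn * cj
  new_efa(A0 = ef$A0, C0 = ef$C0, an = an, bn = bn, cn = cn, dn = dn,
          normalized = ef$normalized, start_convention = ef$start_convention)
}

# rotate the (x, y) frame by -psi about the centroid
apply_frame_rotation <- function(ef, psi) {
  cp <- cos(psi); sp <- sin(psi)
  an <- cp * ef$an + sp * ef$cn
  bn <- cp * ef$bn + sp * ef$dn
  cn <- -sp * ef$an + cp * ef$cn
  dn <- -sp * ef$bn + cp * ef$dn
  new_efa(A0 = ef$A0, C0 = ef$C0, an = an, bn = bn, cn = cn, dn = dn,
          normalized = ef$normalized, start_convention = ef$start_convention)
}

#' Regenerate canonical-start landmarks from a decomposition
#'
#' Evaluates the elliptical Fourier parametric curve at \code{K} equally
#' spaced parameter values \eqn{t_k = 2\pi k / K}, \eqn{k = 0, \dots, K-1}.
#' When the decomposition is normalized, point 1 is the canonical start
#' (the first-harmonic major-axis crossing), so the K points are homologous
#' across independent tracings of the same tooth.
#'
#' @param decomp an \code{"efa"} object; a warning is issued if it has not
#'   been normalized (landmarks are then not comparable across tracings).
#' @param K number of landmarks to generate (default 150).
#' @return a K x 2 numeric matrix of (x, y) landmark coordinates.
#' @export
efa_inverse <- function(decomp, K = 150) {
  stopifnot(inherits(decomp, "efa"))
  if (!is.numeric(K) || length(K) != 1L || K < 3 || K != round(K))
    stop("'K' must be an integer >= 3")
  if (!isTRUE(decomp$normalized))
    warning("decomposition is not normalized; landmarks will not be homologous across tracings")
  t <- 2 * pi * (seq_len(K) - 1) / K
  j <- seq_len(decomp$H)
  ct <- cos(outer(t, j))   # K x H
  st <- sin(outer(t, j))
  x <- decomp$A0 + ct %*% decomp$an + st %*% decomp$bn
  y <- decomp$C0 + ct %*% decomp$cn + st %*% decomp$dn
  cbind(x = as.numeric(x), y = as.numeric(y))
}

#' Harmonic amplitude feature vector
#'
#' Packs the coefficient quadruples \eqn{(a_j, b_j, c_j, d_j)}, j = 1..H,
#' into a named numeric vector for use as classifier input features. With
#' \code{drop_pinned = TRUE} the entries fixed by normalization
#' (\code{b1}, \code{c1}, both exactly zero) are omitted; with
#' \code{size_invariant = TRUE} all coefficients are additionally divided by
#' \code{a1} (the first semi-major length) and \code{a1} itself dropped,
#' giving a scale-free vector. Size is kept by default because specimens are
#' assumed pre-scaled to a common reference, making size a real signal.
#'
#' @param decomp a normalized \code{"efa"} object.
#' @param drop_pinned drop the normalization-pinned zero entries b1, c1.
#' @param size_invariant divide by a1 and drop it (implies
#'   \code{drop_pinned}).
#' @return named numeric vector of length 4H, 4H - 2, or 4H - 3.
#' @export
efa_features <- function(decomp, drop_pinned = FALSE, size_invariant = FALSE) {
  stopifnot(inherits(decomp, "efa"))
  if (!isTRUE(decomp$normalized))
    stop("features require a normalized decomposition")
  j <- seq_len(decomp$H)
  v <- as.numeric(rbind(decomp$an, decomp$bn, decomp$cn, decomp$dn))
  names(v) <- as.vector(rbind(paste0("a", j), paste0("b", j),
                              paste0("c", j), paste0("d", j)))
  if (size_invariant) {
    v <- v / decomp$an[1]
    v <- v[setdiff(names(v), c("a1", "b1", "c1"))]
  } else if (drop_pinned) {
    v <- v[setdiff(names(v), c("b1", "c1"))]
  }
  v
}

#' Per-harmonic power spectrum
#'
#' Power of harmonic j is \eqn{(a_j^2 + b_j^2 + c_j^2 + d_j^2) / 2}. The
#' cumulative share of total power is the usual guide for choosing the
#' number of harmonics (e.g. enough to capture 99%). Power is invariant to
#' the contour's start vertex even before normalization.
#'
#' @param decomp an \code{"efa"} object.
#' @return numeric vector of length H with the power of each harmonic.
#' @export
harmonic_power <- function(decomp) {
  stopifnot(inherits(decomp, "efa"))
  (decomp$an^2 + decomp$bn^2 + decomp$cn^2 + decomp$dn^2) / 2
}

# validate a 2-column contour matrix; drop a duplicated closing vertex
check_contour_matrix <- function(contour) {
  if (!is.matrix(contour) || ncol(contour) != 2L || !is.numeric(contour))
    stop("contour must be a numeric matrix with columns (x, y)")
  n <- nrow(contour)
  if (n >= 2 && all(contour[n, ] == contour[1, ]))
    contour <- contour[-n, , drop = FALSE]
  if (nrow(contour) < 3) stop("contour needs at least 3 distinct points")
  if (!all(is.finite(contour))) stop("contour has non-finite coordinates")
  contour
}
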