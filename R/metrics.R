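#' Center and scale a landmark configuration to a preshape
#'
#' Removes location (centroid to origin) and scale (unit centroid size,
#' i.e. unit root-sum-of-squares) from a K x 2 landmark configuration.
#' Rotation is retained; preshapes are the points of the preshape sphere on
#' which the Riemannian shape distance is defined.
#'
#' @param landmarks K x 2 numeric matrix.
#' @return K x 2 matrix with centroid (0, 0) and Frobenius norm 1.
#' @export
preshape <- function(landmarks) {
  z <- as_landmarks(landmarks)
  z <- sweep(z, 2, colMeans(z))
  s <- sqrt(sum(z^2))
  if (s <= 0) stop("degenerate configuration: all landmarks identical")
  z / s
}

#' Riemannian (Procrustes) shape distance between landmark sets
#'
#' The geodesic distance in Kendall's shape space for planar configurations:
#' both landmark sets are centered and scaled to unit centroid size, treated
#' as complex K-vectors, and the distance is
#' \eqn{\rho = \arccos |\langle z_1, z_2 \rangle|}. The modulus quotients
#' out rotation, so the distance is invariant to translation, rotation, and
#' scaling of either configuration; it is symmetric and lies in
#' \eqn{[0, \pi/2]}. Reflection is not quotiented: a mirrored outline is a
#' different shape.
#'
#' The two landmark sets must have the same number of points in homologous
#' order -- in this pipeline, both regenerated by [efa_inverse()] with the
#' same \code{K} from normalized decompositions.
#'
#' @param L1,L2 K x 2 numeric landmark matrices.
#' @return the distance, a scalar in \code{[0, pi/2]}.
#' @export
riemann_distance <- function(L1, L2) {
  z1 <- complex_preshape(L1)
  z2 <- complex_preshape(L2)
  if (length(z1) != length(z2))
    stop("landmark sets have different numbers of points")
  s <- sum(Conj(z1) * z2)
  # rotate z2 onto z1 and use the chordal form 2*asin(chord/2), which is
  # algebraically acos(|s|) but numerically accurate near zero (acos
  # quantizes tiny distances to ~1.5e-8)
  za <- if (Mod(s) > 0) z2 * Conj(s) / Mod(s) else z2
  chord <- sqrt(sum(Mod(z1 - za)^2))
  2 * asin(min(1, chord / 2))
}

complex_preshape <- function(L) {
  p <- preshape(L)
  complex(real = p[, 1], imaginary = p[, 2])
}

#' Full-Procrustes mean shape of landmark sets
#'
#' Computes the full Procrustes mean of planar landmark configurations:
#' every input is centered and scaled to unit centroid size, and the mean is
#' the unit vector maximizing the summed squared Procrustes correlations --
#' the dominant eigenvector of the complex sum-of-outer-products matrix,
#' computed here through the small n x n Gram matrix. This is equivalent to
#' iteratively rotating all sets to a common frame and averaging pointwise.
#' The result is rotated to best match the first input (for a deterministic,
#' interpretable orientation) and rescaled to the mean centroid size of the
#' inputs so that consensus shapes keep the size signal of their tracings.
#'
#' @param sets list of K x 2 landmark matrices (all the same K).
#' @return a K x 2 landmark matrix: the consensus (mean) shape, centered at
#'   the origin.
#' @export
mean_shape <- function(sets) {
  if (!is.list(sets) || length(sets) == 0)
    stop("'sets' must be a non-empty list of landmark matrices")
  if (length(unique(vapply(sets, nrow, 1L))) != 1L)
    stop("all landmark sets must have the same number of points")
  Z <- vapply(sets, complex_preshape, complex(nrow(as_landmarks(sets[[1]]))))
  Z <- matrix(Z, ncol = length(sets))
  sizes <- vapply(sets, function(L) {
    Lc <- sweep(as_landmarks(L), 2, colMeans(L))
    sqrt(sum(Lc^2))
  }, 1)

  if (length(sets) == 1L) {
    mu <- Z[, 1]
  } else {
    G <- Conj(t(Z)) %*% Z              # n x n Hermitian Gram matrix
    e <- eigen(G, symmetric = TRUE)
    v <- e$vectors[, 1]
    mu <- as.vector(Z %*% v)
    mu <- mu / sqrt(sum(Mod(mu)^2))
  }
  # align orientation to the first input
  rot <- sum(Conj(mu) * Z[, 1])
  if (Mod(rot) > 0) mu <- mu * rot / Mod(rot)
  mu <- mu * mean(sizes)
  cbind(x = Re(mu), y = Im(mu))
}

#' Bundle one specimen's gold-standard and worker tracings
#'
#' A tracing bundle collects, for a single specimen, the expert
#' (gold-standard) landmark outline and up to \code{n_replicates} worker
#' outlines, together with per-tracing distances and keep/reject flags once
#' [filter_tracings()] has been applied.
#'
#' @param specimen_id identifier of the specimen.
#' @param gold optional K x 2 gold-standard landmark matrix.
#' @param tracings list (possibly empty) of K x 2 worker landmark matrices.
#' @return an object of class \code{"tracing_bundle"}.
#' @export
tracing_bundle <- function(specimen_id, gold = NULL, tracings = list()) {
  if (!is.list(tracings)) stop("'tracings' must be a list")
  structure(
    list(specimen_id = specimen_id, gold = gold, tracings = tracings,
         distances = rep(NA_real_, length(tracings)),
         kept = rep(NA, length(tracings)),
         reference_mode = NA_character_, no_usable = NA),
    class = "tracing_bundle")
}

#' @export
print.tracing_bundle <- function(x, ...) {
  cat(sprintf("Tracing bundle '%s': %d worker tracing(s), gold %s\n",
              x$specimen_id, length(x$tracings),
              if (is.null(x$gold)) "absent" else "present"))
  if (!all(is.na(x$distances)))
    cat(sprintf("  distances: %s; kept: %s\n",
                paste(signif(x$distances, 4), collapse = ", "),
                paste(x$kept, collapse = ", ")))
  invisible(x)
}

#' Consensus / filtering configuration
#'
#' @param threshold Riemannian distance above which a tracing is rejected as
#'   obviously incorrect (default 0.2).
#' @param reference_mode \code{"gold_standard"} grades each tracing against
#'   the expert outline; \code{"worker_mean"} grades against the consensus
#'   of the workers themselves (two-pass: mean, exclude, re-mean), which
#'   needs no expert tracing.
#' @param include_expert_in_mean whether consensus shapes should average the
#'   expert outline in with the surviving worker tracings.
#' @return a list of class \code{"consensus_config"}.
#' @export
consensus_config <- function(threshold = 0.2,
                             reference_mode = c("gold_standard", "worker_mean"),
                             include_expert_in_mean = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be > 0")
  structure(list(threshold = threshold,
                 reference_mode = match.arg(reference_mode),
                 include_expert_in_mean = include_expert_in_mean),
            class = "consensus_config")
}

#' Grade and filter a specimen's worker tracings
#'
#' Computes the Riemannian distance of every worker tracing to the reference
#' outline and flags tracings beyond the threshold as rejected. In
#' \code{gold_standard} mode the reference is the expert outline. In
#' \code{worker_mean} mode the reference is the Procrustes mean of all the
#' specimen's tracings; after exclusion the mean is recomputed once from the
#' survivors and stored (two-pass consensus).
#'
#' @param bundle a [tracing_bundle()].
#' @param config a [consensus_config()].
#' @return the bundle with \code{distances}, \code{kept},
#'   \code{reference_mode}, \code{no_usable}, and (in worker-mean mode)
#'   \code{consensus} filled in.
#' @export
filter_tracings <- function(bundle, config = consensus_config()) {
  stopifnot(inherits(bundle, "tracing_bundle"),
            inherits(config, "consensus_config"))
  nt <- length(bundle$tracings)
  if (config$reference_mode == "gold_standard") {
    if (is.null(bundle$gold))
      stop("gold-standard filtering requires a gold tracing")
    ref <- bundle$gold
  } else {
    if (nt == 0) stop("worker-mean filtering requires at least one tracing")
    ref <- mean_shape(bundle$tracings)
  }
  d <- vapply(bundle$tracings, riemann_distance, 1, L2 = ref)
  kept <- d <= config$threshold
  bundle$distances <- d
  bundle$kept <- kept
  bundle$reference_mode <- config$reference_mode
  bundle$no_usable <- nt == 0 || !any(kept)
  if (config$reference_mode == "worker_mean" && any(kept))
    bundle$consensus <- mean_shape(bundle$tracings[kept])
  bundle
}

#' Consensus shape of a graded bundle
#'
#' Procrustes mean of the surviving (kept) worker tracings, optionally
#' averaging the expert outline in as one more configuration.
#'
#' @param bundle a bundle already graded by [filter_tracings()].
#' @param include_expert average the gold outline in with the survivors.
#' @return K x 2 consensus landmark matrix, or \code{NULL} when no tracing
#'   survived and the expert is not included.
#' @export
consensus_shape <- function(bundle, include_expert = FALSE) {
  stopifnot(inherits(bundle, "tracing_bundle"))
  if (length(bundle$kept) > 0 && all(is.na(bundle$kept)))
    stop("bundle has not been graded; call filter_tracings() first")
  sets <- bundle$tracings[which(bundle$kept)]
  if (include_expert) {
    if (is.null(bundle$gold)) stop("no gold tracing to include")
    sets <- c(sets, list(bundle$gold))
  }
  if (length(sets) == 0) return(NULL)
  mean_shape(sets)
}

#' Summarize tracing errors across bundles
#'
#' Five-number summaries of worker-to-reference Riemannian distances,
#' grouped by a specimen attribute (typically tooth position or tribe), plus
#' overall histogram counts at a fixed bin width -- the standard view of how
#' tracing error is distributed across a digitization campaign.
#'
#' @param bundles list of graded [tracing_bundle()]s.
#' @param groups character vector assigning each bundle to a group (e.g.
#'   tooth position); defaults to a single overall group.
#' @param bin_width histogram bin width on the distance axis.
#' @return a list with \code{summary} (data frame: group, n, min, q1,
#'   median, q3, max) and \code{histogram} (data frame: bin_low, bin_high,
#'   count).
#' @export
error_summary <- function(bundles, groups = NULL, bin_width = 0.05) {
  if (length(bundles) == 0) stop("no bundles supplied")
  dlist <- lapply(bundles, function(b) {
    if (all(is.na(b$distances)) && length(b$tracings) > 0)
      stop(sprintf("bundle '%s' has no computed distances", b$specimen_id))
    b$distances
  })
  if (is.null(groups)) groups <- rep("all", length(bundles))
  if (length(groups) != length(bundles))
    stop("'groups' must have one entry per bundle")
  gs <- rep(groups, lengths(dlist))
  d <- unlist(dlist)
  if (length(d) == 0) stop("no distances present in any bundle")
  summ <- do.call(rbind, lapply(split(d, gs), function(v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(n = length(v), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  }))
  summ <- cbind(group = rownames(summ), summ, row.names = NULL)
  breaks <- seq(0, max(ceiling(max(d) / bin_width), 1) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE,
                                  left.open = FALSE),
                     nbins = length(breaks) - 1)
  hist <- data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                     count = counts)
  list(summary = summ, histogram = hist)
}

as_landmarks <- function(L) {
  if (is.data.frame(L)) L <- as.matrix(L)
  if (!is.matrix(L) || ncol(L) != 2L || !is.numeric(L))
    stop("landmarks must be a numeric matrix with columns (x, y)")
  if (!all(is.finite(L))) stop("landmarks contain non-finite coordinates")
  L
}
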