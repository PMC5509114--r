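#' Shape-class template for the synthetic population generator
#'
#' A template describes one tribe-like class of tooth outlines: a mean shape
#' given directly as an elliptical Fourier decomposition, a relative
#' within-class dispersion, and a class size. Truth shapes are defined in
#' coefficient space because that is the feature space used downstream, so
#' class separation and dispersion are directly interpretable.
#'
#' @param class_label name of the class (e.g. a synthetic tribe).
#' @param mean_coeffs an \code{"efa"} object with at least 2 harmonics: the
#'   class mean shape.
#' @param coeff_sd_scale nonnegative relative dispersion: harmonic j of a
#'   specimen is perturbed with zero-mean Gaussian noise of standard
#'   deviation \code{coeff_sd_scale * size / j}, where \code{size} is the
#'   first-harmonic amplitude norm of the mean (dispersion decays with
#'   harmonic order).
#' @param n_specimens number of specimens to draw for this class.
#' @param tooth_position tooth position label carried into the metadata
#'   (default "LM2").
#' @return object of class \code{"shape_class_template"}.
#' @export
shape_class_template <- function(class_label, mean_coeffs, coeff_sd_scale,
                                 n_specimens, tooth_position = "LM2") {
  stopifnot(inherits(mean_coeffs, "efa"))
  if (mean_coeffs$H < 2) stop("mean_coeffs needs at least 2 harmonics")
  if (!all(is.finite(c(mean_coeffs$an, mean_coeffs$bn, mean_coeffs$cn,
                       mean_coeffs$dn))))
    stop("non-finite template coefficients")
  if (coeff_sd_scale < 0) stop("'coeff_sd_scale' must be nonnegative")
  if (n_specimens < 1) stop("'n_specimens' must be >= 1")
  structure(list(class_label = class_label, mean_coeffs = mean_coeffs,
                 coeff_sd_scale = coeff_sd_scale,
                 n_specimens = as.integer(n_specimens),
                 tooth_position = tooth_position),
            class = "shape_class_template")
}

#' Molar-like mean outline in coefficient space
#'
#' Builds a plausible occlusal-outline mean shape: a squarish superellipse
#' of the given length and width, with an optional mid-crown waist
#' (the indentation between mesial and distal lobes of a molar). The
#' outline polygon is fitted with [efa_forward()] and normalized, so the
#' template is returned directly in coefficient space.
#'
#' @param length2,width2 semi-length and semi-width of the crown outline
#'   (arbitrary units; specimens are assumed pre-scaled to each other, so
#'   relative sizes between classes are meaningful).
#' @param squareness superellipse exponent (2 = ellipse; larger = squarer).
#' @param waist relative depth of the mid-crown indentation (0 = none).
#' @param H harmonics kept in the template.
#' @return a normalized \code{"efa"} object.
#' @export
molar_mean_shape <- function(length2 = 1.0, width2 = 0.6, squareness = 3,
                             waist = 0.15, H = 10) {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  e <- 2 / squareness
  x <- length2 * sign(cos(th)) * abs(cos(th))^e
  y <- width2 * sign(sin(th)) * abs(sin(th))^e
  # waist: pinch the width near mid-length on both sides
  y <- y * (1 - waist * exp(-(x / (0.35 * length2))^2))
  efa_normalize(efa_forward(cbind(x, y), H = H))
}

#' Default synthetic tribe templates (full population)
#'
#' Four tribe-like classes with the class sizes of the reference
#' digitization campaign (33, 10, 35, 18; total 96). Alcelaphini-like and
#' Hippotragini-like means are deliberately similar (those tribes are the
#' classically confusable pair); the Bovini-like class is large and square,
#' the Neotragini-like class small and slender.
#'
#' @param coeff_sd_scale within-class dispersion applied to every class.
#' @return list of [shape_class_template()]s.
#' @export
default_templates <- function(coeff_sd_scale = 0.045) {
  list(
    shape_class_template("Alcelaphini",
      molar_mean_shape(1.00, 0.58, squareness = 3.0, waist = 0.18),
      coeff_sd_scale, 33),
    shape_class_template("Bovini",
      molar_mean_shape(1.25, 0.85, squareness = 3.6, waist = 0.10),
      coeff_sd_scale, 10),
    shape_class_template("Hippotragini",
      molar_mean_shape(1.05, 0.62, squareness = 2.8, waist = 0.13),
      coeff_sd_scale, 35),
    shape_class_template("Neotragini",
      molar_mean_shape(0.70, 0.38, squareness = 2.4, waist = 0.22),
      coeff_sd_scale, 18))
}

#' Synthetic LM2-like classification layout
#'
#' The three-class subset used for the classification experiment: 15
#' Alcelaphini-like, 15 Hippotragini-like, and 8 Neotragini-like specimens
#' (38 in total), mirroring the lower-second-molar composition of the
#' reference campaign, which contains no Bovini.
#'
#' @inheritParams default_templates
#' @return list of three [shape_class_template()]s.
#' @export
lm2_templates <- function(coeff_sd_scale = 0.045) {
  tp <- default_templates(coeff_sd_scale)
  tp <- tp[c(1, 3, 4)]
  tp[[1]]$n_specimens <- 15L
  tp[[2]]$n_specimens <- 15L
  tp[[3]]$n_specimens <- 8L
  tp
}

#' Worker tracing noise model
#'
#' Parameters of the simulated crowd worker. Tracing error is modeled as
#' smooth jitter along the outline (hand tracing errors are locally
#' correlated, not independent per point), an optional systematic
#' inside/outside bias, and two failure modes observed in real crowdsourced
#' tracing: gross errors ("clearly wrong" submissions such as tracing the
#' wrong tooth) and missing submissions.
#'
#' @param jitter_sd standard deviation of outline jitter, in units of the
#'   outline's RMS radius about its centroid.
#' @param jitter_correlation_length correlation length of the jitter as a
#'   fraction of the perimeter.
#' @param boundary_bias signed offset along the outward normal (same units
#'   as \code{jitter_sd}); positive = traces outside the true edge.
#' @param p_gross_error probability that a returned tracing is grossly
#'   wrong (constructed to exceed the 0.2 rejection distance).
#' @param p_missing probability that a tracing is not returned at all.
#' @param n_replicates tracings requested per specimen (default 3).
#' @return object of class \code{"worker_noise_model"}.
#' @export
worker_noise_model <- function(jitter_sd = 0.15,
                               jitter_correlation_length = 0.1,
                               boundary_bias = 0,
                               p_gross_error = 0.1,
                               p_missing = 0.1,
                               n_replicates = 3) {
  if (jitter_sd < 0) stop("'jitter_sd' must be nonnegative")
  if (jitter_correlation_length <= 0)
    stop("'jitter_correlation_length' must be positive")
  if (p_gross_error < 0 || p_gross_error > 1 || p_missing < 0 || p_missing > 1)
    stop("probabilities must lie in [0, 1]")
  if (n_replicates < 0) stop("'n_replicates' must be >= 0")
  structure(list(jitter_sd = jitter_sd,
                 jitter_correlation_length = jitter_correlation_length,
                 boundary_bias = boundary_bias,
                 p_gross_error = p_gross_error, p_missing = p_missing,
                 n_replicates = as.integer(n_replicates)),
            class = "worker_noise_model")
}

#' Generate a synthetic specimen population
#'
#' Draws \code{n_specimens} truth outlines per template by perturbing the
#' template's mean coefficients harmonic-wise with zero-mean Gaussian noise
#' (standard deviation \code{coeff_sd_scale * size / j} for harmonic j),
#' re-normalizing, and regenerating \code{K} canonical-start landmarks.
#' Fully deterministic given \code{seed}.
#'
#' @param templates non-empty list of [shape_class_template()]s with
#'   distinct class labels.
#' @param seed integer RNG seed.
#' @param K landmarks per outline (default 150).
#' @return object of class \code{"tooth_dataset"}: list with
#'   \code{specimens} (data frame: specimen_id, class_label,
#'   tooth_position), \code{landmarks} (named list of truth K x 2
#'   matrices), \code{tracings} (named list, empty until
#'   [simulate_worker_tracings()]), and \code{seed}.
#' @export
generate_population <- function(templates, seed, K = 150) {
  if (!is.list(templates) || length(templates) == 0)
    stop("'templates' must be a non-empty list")
  if (!all(vapply(templates, inherits, TRUE, "shape_class_template")))
    stop("all templates must be shape_class_template objects")
  labels <- vapply(templates, `[[`, "", "class_label")
  if (anyDuplicated(labels)) stop("class labels must be distinct")

  with_seed(seed, {
    rows <- list(); lms <- list(); k <- 0L
    for (tp in templates) {
      ef <- tp$mean_coeffs
      scale0 <- sqrt(ef$an[1]^2 + ef$bn[1]^2 + ef$cn[1]^2 + ef$dn[1]^2)
      sds <- tp$coeff_sd_scale * scale0 / seq_len(ef$H)
      for (i in seq_len(tp$n_specimens)) {
        k <- k + 1L
        id <- sprintf("S%03d", k)
        pert <- new_efa(
          A0 = 0, C0 = 0,
          an = ef$an + stats::rnorm(ef$H, 0, sds),
          bn = ef$bn + stats::rnorm(ef$H, 0, sds),
          cn = ef$cn + stats::rnorm(ef$H, 0, sds),
          dn = ef$dn + stats::rnorm(ef$H, 0, sds))
        lms[[id]] <- efa_inverse(efa_normalize(pert), K = K)
        rows[[k]] <- data.frame(specimen_id = id,
                                class_label = tp$class_label,
                                tooth_position = tp$tooth_position)
      }
    }
    structure(list(specimens = do.call(rbind, rows), landmarks = lms,
                   tracings = stats::setNames(vector("list", k),
                                              names(lms)),
                   seed = seed, K = K),
              class = "tooth_dataset")
  })
}

#' @export
print.tooth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic tooth dataset: %d specimens, %d classes (seed %d)\n",
              nrow(x$specimens), length(unique(x$specimens$class_label)),
              x$seed))
  nt <- sum(lengths(x$tracings))
  cat(sprintf("  worker tracings: %d\n", nt))
  invisible(x)
}

#' Simulate crowd-worker tracings for every specimen
#'
#' For each specimen, \code{n_replicates} candidate tracings are drawn.
#' Each candidate is independently missing with probability
#' \code{p_missing}; otherwise, with probability \code{p_gross_error} it is
#' a gross error -- a different random specimen's outline, inflated in
#' distortion until its Riemannian distance to the truth exceeds 0.2 -- and
#' otherwise it is the truth outline with smooth correlated jitter plus the
#' normal-direction bias. Deterministic given \code{seed}.
#'
#' @param dataset a [generate_population()] result.
#' @param noise a [worker_noise_model()].
#' @param seed integer RNG seed.
#' @return the dataset with \code{tracings} filled: per specimen a list of
#'   K x 2 matrices, each carrying attributes \code{gross} (logical) and
#'   \code{tracing_id}.
#' @export
simulate_worker_tracings <- function(dataset, noise, seed) {
  stopifnot(inherits(dataset, "tooth_dataset"),
            inherits(noise, "worker_noise_model"))
  if (nrow(dataset$specimens) == 0) stop("dataset has no specimens")
  ids <- dataset$specimens$specimen_id
  with_seed(seed, {
    for (id in ids) {
      truth <- dataset$landmarks[[id]]
      trs <- list()
      for (r in seq_len(noise$n_replicates)) {
        if (stats::runif(1) < noise$p_missing) next
        if (stats::runif(1) < noise$p_gross_error) {
          tr <- make_gross_error(dataset, id)
          attr(tr, "gross") <- TRUE
        } else {
          tr <- jitter_outline(truth, noise)
          attr(tr, "gross") <- FALSE
        }
        attr(tr, "tracing_id") <- sprintf("%s_T%d", id, r)
        trs[[length(trs) + 1L]] <- tr
      }
      dataset$tracings[[id]] <- trs
    }
    dataset
  })
}

# smooth correlated jitter + normal-direction bias, on the truth landmarks
jitter_outline <- function(truth, noise) {
  K <- nrow(truth)
  ctr <- colMeans(truth)
  rms <- sqrt(mean(rowSums(sweep(truth, 2, ctr)^2)))
  ell <- max(1, noise$jitter_correlation_length * K)
  nx <- smooth_noise(K, ell)
  ny <- smooth_noise(K, ell)
  out <- truth + cbind(nx, ny) * (noise$jitter_sd * rms)
  if (noise$boundary_bias != 0) {
    nrm <- outward_normals(truth, ctr)
    out <- out + nrm * (noise$boundary_bias * rms)
  }
  out
}

# unit-variance Gaussian noise smoothed with a circular Gaussian kernel
smooth_noise <- function(K, ell) {
  w <- stats::rnorm(K)
  d <- pmin(0:(K - 1), K - (0:(K - 1)))
  kern <- exp(-0.5 * (d / ell)^2)
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) / K
  s <- stats::sd(sm)
  if (s == 0) return(rep(0, K))
  sm / s
}

outward_normals <- function(xy, ctr) {
  K <- nrow(xy)
  nxt <- xy[c(2:K, 1), , drop = FALSE]
  prv <- xy[c(K, 1:(K - 1)), , drop = FALSE]
  tg <- nxt - prv
  nrm <- cbind(tg[, 2], -tg[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # orient outward (away from the centroid)
  flip <- rowSums(nrm * sweep(xy, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

# a "clearly wrong" tracing: another specimen's outline, distorted further
# if needed until its shape distance from the truth exceeds 0.2
make_gross_error <- function(dataset, id) {
  truth <- dataset$landmarks[[id]]
  others <- setdiff(names(dataset$landmarks), id)
  base <- if (length(others) > 0)
    dataset$landmarks[[sample(others, 1)]] else truth
  cand <- base
  amp <- 0.25
  # construct to clear the 0.2 rejection threshold with margin, so the
  # distance still exceeds 0.2 after the tracing is re-fit through EFA
  repeat {
    if (riemann_distance(cand, truth) > 0.3) return(cand)
    # amplify: stretch one axis and add a low-order bend
    ctr <- colMeans(base)
    b <- sweep(base, 2, ctr)
    th <- atan2(b[, 2], b[, 1])
    cand <- sweep(cbind(b[, 1] * (1 + amp),
                        b[, 2] * (1 - 0.6 * amp) + amp * b[, 1] * sin(th)),
                  2, ctr, "+")
    amp <- amp * 1.6
    if (amp > 1e3) stop("failed to construct a gross-error tracing")
  }
}

# run an expression with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
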