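#' Harmonic features from a landmark outline
#'
#' Convenience wrapper chaining [efa_forward()], [efa_normalize()], and
#' [efa_features()]: the standard route from any closed outline (truth,
#' worker tracing, or consensus shape) to a classifier feature vector.
#'
#' @param landmarks n x 2 closed-outline matrix.
#' @param H harmonics (default 10, i.e. 40 amplitude features).
#' @param ... passed to [efa_features()].
#' @return named numeric feature vector.
#' @export
outline_features <- function(landmarks, H = 10, ...) {
  efa_features(efa_normalize(efa_forward(landmarks, H = H)), ...)
}

#' Run the four tracing-condition classification experiments
#'
#' Reproduces the evaluation design of a crowdsourced digitization
#' campaign on a synthetic dataset with simulated worker tracings:
#' \describe{
#'   \item{expert}{leave-one-out classification from the truth outlines
#'     (the gold standard's own performance).}
#'   \item{single_worker_sample}{the sampling distribution of log-loss over
#'     \code{R} datasets, each built by sampling one of the at-most
#'     \code{n_replicates} tracings per specimen.}
#'   \item{worker_consensus}{each specimen represented by the Procrustes
#'     mean of its tracings after two-pass worker-mean filtering at the
#'     distance threshold (no expert needed).}
#'   \item{consensus_plus_expert}{tracings filtered against the expert at
#'     the threshold, then averaged together with the expert outline.}
#' }
#' Specimens with zero usable tracings are dropped from the worker
#' conditions and counted in the report.
#'
#' @param dataset a [generate_population()] result with tracings filled by
#'   [simulate_worker_tracings()].
#' @param seed integer seed governing resampling and forest training.
#' @param R number of single-worker resampled datasets (default 50).
#' @param H harmonics for the feature vectors.
#' @param ntree forest size.
#' @param threshold rejection distance for consensus filtering
#'   (default 0.2).
#' @param include_gross_in_sampling whether the single-worker sampling pool
#'   includes gross-error tracings (it does by default: an unscreened
#'   single worker is exactly that risk).
#' @return object of class \code{"condition_results"}: list with
#'   \code{reports} (named list of [evaluate()] reports for expert,
#'   worker_consensus, consensus_plus_expert), \code{single_worker_logloss}
#'   (length-R numeric), \code{single_worker_mean},
#'   \code{dropped} (named counts of specimens dropped per worker
#'   condition), and \code{seed}.
#' @export
run_conditions <- function(dataset, seed = 1, R = 50, H = 10, ntree = 500,
                           threshold = 0.2,
                           include_gross_in_sampling = TRUE) {
  stopifnot(inherits(dataset, "tooth_dataset"))
  ids <- dataset$specimens$specimen_id
  labels <- stats::setNames(dataset$specimens$class_label, ids)
  if (all(lengths(dataset$tracings) == 0))
    stop("dataset has no worker tracings; run simulate_worker_tracings() first")

  feat_truth <- t(vapply(ids, function(id)
    outline_features(dataset$landmarks[[id]], H = H), numeric(4 * H)))
  rownames(feat_truth) <- ids

  # per-tracing features, computed once and reused by every resample
  feat_tr <- lapply(ids, function(id)
    lapply(dataset$tracings[[id]], outline_features, H = H))
  names(feat_tr) <- ids

  reports <- list()
  reports$expert <- evaluate(
    loocv_predict(feat_truth, labels, ntree = ntree, seed = seed),
    labels, condition_label = "expert")

  # --- single-worker sampling distribution -------------------------------
  pool <- lapply(ids, function(id) {
    trs <- dataset$tracings[[id]]
    if (!include_gross_in_sampling && length(trs) > 0)
      trs <- trs[!vapply(trs, function(t) isTRUE(attr(t, "gross")), TRUE)]
    seq_along(trs)
  })
  names(pool) <- ids
  avail <- ids[lengths(pool) > 0]
  dropped_single <- length(ids) - length(avail)
  sw_loss <- rep(NA_real_, R)
  with_seed(seed, {
    for (r in seq_len(R)) {
      picks <- vapply(avail, function(id) sample(pool[[id]], 1), 1L)
      fr <- t(mapply(function(id, k) feat_tr[[id]][[k]], avail, picks))
      rownames(fr) <- avail
      pr <- loocv_predict(fr, labels[avail], ntree = ntree,
                          seed = seed + 7919 * r)
      sw_loss[r] <- log_loss(pr, labels[avail])
    }
  })

  # --- consensus conditions ----------------------------------------------
  cfg_wm <- consensus_config(threshold = threshold,
                             reference_mode = "worker_mean")
  cfg_gold <- consensus_config(threshold = threshold,
                               reference_mode = "gold_standard")
  cons <- list(); cons_exp <- list()
  for (id in ids) {
    b <- tracing_bundle(id, gold = dataset$landmarks[[id]],
                        tracings = dataset$tracings[[id]])
    if (length(b$tracings) > 0) {
      bw <- filter_tracings(b, cfg_wm)
      if (!bw$no_usable) cons[[id]] <- consensus_shape(bw)
    }
    bg <- if (length(b$tracings) > 0) filter_tracings(b, cfg_gold) else b
    if (length(b$tracings) > 0 || !is.null(b$gold)) {
      if (length(b$tracings) == 0) { bg$kept <- logical(0) }
      cons_exp[[id]] <- consensus_shape(bg, include_expert = TRUE)
    }
  }
  dropped_cons <- length(ids) - length(cons)

  fc <- t(vapply(names(cons), function(id)
    outline_features(cons[[id]], H = H), numeric(4 * H)))
  reports$worker_consensus <- evaluate(
    loocv_predict(fc, labels[names(cons)], ntree = ntree,
                  seed = seed + 104729),
    labels[names(cons)], condition_label = "worker_consensus")

  fce <- t(vapply(names(cons_exp), function(id)
    outline_features(cons_exp[[id]], H = H), numeric(4 * H)))
  reports$consensus_plus_expert <- evaluate(
    loocv_predict(fce, labels[names(cons_exp)], ntree = ntree,
                  seed = seed + 224737),
    labels[names(cons_exp)], condition_label = "consensus_plus_expert")

  structure(list(reports = reports,
                 single_worker_logloss = sw_loss,
                 single_worker_mean = mean(sw_loss),
                 dropped = c(single_worker_sample = dropped_single,
                             worker_consensus = dropped_cons,
                             consensus_plus_expert =
                               length(ids) - length(cons_exp)),
                 seed = seed),
            class = "condition_results")
}

#' @export
print.condition_results <- function(x, ...) {
  cat("Tracing-condition comparison (log-loss)\n")
  cat(sprintf("  expert:                %.4f\n", x$reports$expert$log_loss))
  cat(sprintf("  single worker (mean of %d samples): %.4f  [%.4f, %.4f]\n",
              length(x$single_worker_logloss), x$single_worker_mean,
              min(x$single_worker_logloss), max(x$single_worker_logloss)))
  cat(sprintf("  worker consensus:      %.4f\n",
              x$reports$worker_consensus$log_loss))
  cat(sprintf("  consensus + expert:    %.4f\n",
              x$reports$consensus_plus_expert$log_loss))
  if (any(x$dropped > 0))
    cat("  dropped specimens:",
        paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
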