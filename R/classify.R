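#' Leave-one-out random-forest class probabilities
#'
#' For each specimen, a random forest is trained on all other specimens and
#' the held-out specimen's class probabilities are the forest's vote
#' fractions. Each fold re-seeds the RNG at \code{seed + fold index}, so a
#' run is exactly reproducible and folds are independent of evaluation
#' order.
#'
#' @param x numeric feature matrix (rows = specimens), typically harmonic
#'   amplitudes from [efa_features()].
#' @param y factor (or coercible) of class labels; at least 2 classes with
#'   at least 2 specimens each.
#' @param ntree trees per forest (default 500).
#' @param mtry features tried per split (default \code{floor(sqrt(p))}).
#' @param seed integer base seed.
#' @return numeric matrix n x n_classes of probabilities (rows sum to 1),
#'   with row names from \code{rownames(x)} and columns the class levels in
#'   sorted order.
#' @export
loocv_predict <- function(x, y, ntree = 500, mtry = NULL, seed = 1) {
  x <- as.matrix(x)
  y <- factor(y, levels = sort(unique(as.character(y))))
  if (nrow(x) != length(y)) stop("feature rows and labels differ in length")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 specimens")
  if (anyNA(x)) stop("features contain missing values")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))

  n <- nrow(x)
  probs <- matrix(NA_real_, n, nlevels(y),
                  dimnames = list(rownames(x), levels(y)))
  with_seed(seed, {
    for (i in seq_len(n)) {
      set.seed(seed + i)
      fit <- randomForest::randomForest(x[-i, , drop = FALSE], y[-i],
                                        ntree = ntree, mtry = mtry)
      probs[i, ] <- stats::predict(fit, x[i, , drop = FALSE],
                                   type = "prob")[1, levels(y)]
    }
  })
  probs
}

#' Multiclass log-loss
#'
#' \eqn{-(1/N) \sum_i \ln \max(\epsilon, \hat p_i(\mathrm{actual}_i))},
#' natural logarithm. Zero for perfect one-hot prediction; \eqn{\ln(C)} for
#' uniform guessing over C classes. Probabilities are clipped at
#' \code{clip} so that a zero-probability vote for the true class gives a
#' finite (large) penalty.
#'
#' @param probs n x C probability matrix with class labels as column names.
#' @param actual length-n vector of true class labels.
#' @param clip lower clip for probabilities (default 1e-15).
#' @return scalar log-loss.
#' @export
log_loss <- function(probs, actual, clip = 1e-15) {
  probs <- as.matrix(probs)
  actual <- as.character(actual)
  if (nrow(probs) != length(actual))
    stop("each labeled specimen needs a prediction")
  if (!all(actual %in% colnames(probs)))
    stop("some actual labels have no prediction column")
  p <- probs[cbind(seq_along(actual), match(actual, colnames(probs)))]
  -mean(log(pmax(clip, p)))
}

#' Evaluate predictions: confusion matrix, rate, and log-loss
#'
#' The predicted class is the argmax of each probability row (ties broken
#' toward the lexicographically first label, with a message). The
#' classification rate is the confusion-matrix diagonal sum over the total.
#'
#' @param probs n x C probability matrix, columns named by class.
#' @param actual true labels.
#' @param condition_label optional tag describing which tracing condition
#'   produced the features (e.g. "expert", "worker_consensus").
#' @return object of class \code{"eval_report"}: list with
#'   \code{confusion} (actual rows x predicted columns),
#'   \code{classification_rate}, \code{log_loss}, \code{n},
#'   \code{condition_label}.
#' @export
evaluate <- function(probs, actual, condition_label = NA_character_) {
  probs <- as.matrix(probs)
  actual <- as.character(actual)
  if (nrow(probs) != length(actual))
    stop("each labeled specimen needs a prediction")
  classes <- sort(colnames(probs))
  probs <- probs[, classes, drop = FALSE]
  ties <- apply(probs, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    message(sum(ties), " tied prediction(s) broken toward the first label")
  pred <- classes[apply(probs, 1, which.max)]
  all_lab <- sort(unique(c(classes, actual)))
  conf <- table(factor(actual, levels = all_lab),
                factor(pred, levels = all_lab))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("actual", "predicted")
  structure(list(confusion = conf,
                 classification_rate = sum(diag(conf)) / sum(conf),
                 log_loss = log_loss(probs, actual),
                 n = length(actual),
                 condition_label = condition_label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (!is.na(x$condition_label))
    cat("Condition:", x$condition_label, "\n")
  cat(sprintf("Classification rate: %.0f%% (%d/%d)   log-loss: %.4f\n",
              100 * x$classification_rate,
              sum(diag(x$confusion)), x$n, x$log_loss))
  print(x$confusion)
  invisible(x)
}

#' Classification rate of a confusion matrix
#'
#' Diagonal sum divided by the total number of specimens scored.
#'
#' @param confusion square numeric matrix, rows = actual, columns =
#'   predicted, with matching dimension names.
#' @return fraction correct.
#' @export
classification_rate <- function(confusion) {
  confusion <- check_confusion(confusion)
  sum(diag(confusion)) / sum(confusion)
}

#' Share of misclassifications between one pair of classes
#'
#' Of all off-diagonal (misclassified) specimens, the fraction that are
#' either actually A but predicted B, or actually B but predicted A --
#' the usual way of asking how much of the error is one confusable pair.
#'
#' @param confusion square confusion matrix with named dimensions.
#' @param pair character vector of two class names.
#' @return fraction of misclassified specimens in \code{[0, 1]}.
#' @export
confusion_share <- function(confusion, pair) {
  confusion <- check_confusion(confusion)
  if (length(pair) != 2 || !all(pair %in% rownames(confusion)))
    stop("'pair' must name two classes present in the matrix")
  off <- sum(confusion) - sum(diag(confusion))
  if (off == 0) stop("no misclassifications: share is undefined")
  (confusion[pair[1], pair[2]] + confusion[pair[2], pair[1]]) / off
}

check_confusion <- function(confusion) {
  confusion <- as.matrix(unclass(confusion))
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion counts must be nonnegative")
  if (is.null(rownames(confusion)))
    rownames(confusion) <- colnames(confusion)
  if (is.null(colnames(confusion)))
    colnames(confusion) <- rownames(confusion)
  confusion
}

#' Confusion tables from the reference crowdsourcing campaign
#'
#' The three published leave-one-out confusion matrices of the reference
#' bovid-tooth digitization campaign (three tribes, 38 lower second
#' molars), one per tracing condition: the expert's own outlines, the
#' consensus (mean) of crowd-worker outlines after distance filtering, and
#' the consensus of workers averaged together with the expert. These serve
#' as fixed inputs for recomputing the campaign's summary statistics
#' (classification rates; the share of error between the confusable
#' Alcelaphini/Hippotragini pair).
#'
#' @return named list of three 3 x 3 matrices (\code{expert},
#'   \code{worker_consensus}, \code{consensus_plus_expert}), rows = actual,
#'   columns = predicted.
#' @export
study_confusion_tables <- function() {
  cls <- c("Alcelaphini", "Hippotragini", "Neotragini")
  mk <- function(v) matrix(v, 3, 3, byrow = TRUE,
                           dimnames = list(actual = cls, predicted = cls))
  list(
    expert = mk(c(11, 3, 1,
                  3, 11, 1,
                  0, 0, 8)),
    worker_consensus = mk(c(10, 2, 3,
                            4, 11, 0,
                            1, 0, 7)),
    consensus_plus_expert = mk(c(11, 3, 1,
                                 5, 8, 2,
                                 1, 0, 7)))
}
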