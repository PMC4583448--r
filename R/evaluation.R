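#' Randomly resolve tie labels
#'
#' Ensemble vote counts can tie, leaving a sample with label 0. Before
#' computing performance metrics each tie is assigned `-1` or `+1` with
#' probability 1/2, under a dedicated seed so the resolution is reproducible.
#'
#' @param labels integer labels over `{-1, 0, +1}`.
#' @param seed RNG seed for the resolution.
#' @return Labels over `{-1, +1}`; non-tie entries are returned unchanged.
#' @export
resolve_ties <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  ties <- labels == 0L
  if (!any(ties)) return(labels)
  set.seed(seed)
  labels[ties] <- sample(c(-1L, 1L), sum(ties), replace = TRUE)
  labels
}

#' Accuracy, sensitivity, and specificity against clinical labels
#'
#' Periodontitis (`+1`) is the positive class: sensitivity is the fraction of
#' periodontitis samples flagged as periodontitis, specificity the fraction
#' of gingivitis samples flagged as gingivitis.
#'
#' @param pred predicted labels over `{-1, +1}`.
#' @param truth clinical labels over `{-1, +1}`; both classes must be present.
#' @param positive which label counts as positive (default `+1`).
#' @return Named numeric vector `c(acc, sen, spc)`.
#' @export
performance <- function(pred, truth, positive = 1L) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (!all(pred %in% c(-1L, 1L)) || !all(truth %in% c(-1L, 1L)))
    stop("labels must be in {-1, +1}; resolve ties first")
  negative <- -positive
  if (!any(truth == positive) || !any(truth == negative))
    stop("both classes must be present in truth for sen/spc to be defined")
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred == negative & truth == negative)
  fp <- sum(pred == positive & truth == negative)
  fn <- sum(pred == negative & truth == positive)
  c(acc = (tp + tn) / length(truth),
    sen = tp / (tp + fn),
    spc = tn / (tn + fp))
}

#' Summarize per-realization metrics as mean and SD
#'
#' Computes accuracy, sensitivity and specificity independently for every
#' cross-validation realization (resolving tie labels per realization) and
#' reports the mean and standard deviation across realizations.
#'
#' @param per_realization_labels `Nb x n` matrix over `{-1, 0, +1}`.
#' @param truth clinical labels over `{-1, +1}`.
#' @param seed seed for tie resolution.
#' @return An object of class `performance_summary`: list with `mean`, `sd`
#'   (named vectors over acc/sen/spc) and the `Nb x 3` matrix
#'   `per_realization`.
#' @export
summarize_performance <- function(per_realization_labels, truth, seed = 1L) {
  Nb <- nrow(per_realization_labels)
  set.seed(seed)
  tie_seeds <- sample.int(.Machine$integer.max, Nb)
  per <- t(vapply(seq_len(Nb), function(r) {
    performance(resolve_ties(per_realization_labels[r, ], tie_seeds[r]), truth)
  }, numeric(3)))
  structure(list(mean = colMeans(per),
                 sd = apply(per, 2L, stats::sd),
                 per_realization = per),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  for (mtr in names(x$mean))
    cat(sprintf("  %s: %.3f +/- %.3f\n", mtr, x$mean[mtr], x$sd[mtr]))
  invisible(x)
}

#' Identify mismatch samples
#'
#' A mismatch sample is one whose ensemble classification label disagrees
#' with its clinical label in a strict majority of realizations — interpreted
#' as biological heterogeneity rather than misclassification. Tie
#' realizations carry no directional evidence and are excluded from the
#' majority denominator.
#'
#' @param result an [run_sva()] result.
#' @param truth clinical labels over `{-1, +1}`; defaults to the labels
#'   carried by `result`.
#' @return Character vector of mismatch sample IDs.
#' @export
identify_mismatch <- function(result, truth = result$labels) {
  stopifnot(inherits(result, "sva_result"))
  lab <- result$per_realization_labels
  n <- ncol(lab)
  stopifnot(length(truth) == n)
  mism <- vapply(seq_len(n), function(k) {
    votes <- lab[, k]
    votes <- votes[votes != 0L]
    sum(votes != truth[k]) > length(votes) / 2
  }, logical(1))
  result$sample_ids[mism]
}

#' Traditional single-classifier baseline
#'
#' The conventional alternative to pairwise voting: one classifier trained on
#' all `m` markers jointly, evaluated under exactly the same randomized
#' leave-`k1`-out scheme (`Nb` realizations, identical fold permutations
#' under the same seed). Reported as per-realization metrics summarized as
#' mean and SD, directly comparable to the ensemble run.
#'
#' @param table a normalized [biomarker_table()].
#' @param cfg an [sva_config()].
#' @return A `performance_summary` with an extra element
#'   `per_realization_labels` (`Nb x n` predicted labels).
#' @export
run_traditional <- function(table, cfg = sva_config()) {
  stopifnot(inherits(table, "biomarker_table"))
  if (!table$normalized)
    stop("run_traditional expects a normalized table")
  n <- ncol(table$X)
  set.seed(cfg$seed)
  lab_r <- matrix(0L, cfg$Nb, n)
  for (r in seq_len(cfg$Nb)) {
    folds <- draw_valid_folds(table$labels, cfg$k1, cfg$max_redraws)
    for (idx in folds) {
      clf <- train_pair_classifier(cfg$classifier,
                                   table$X[, -idx, drop = FALSE],
                                   table$labels[-idx],
                                   cost = cfg$cost)
      lab_r[r, idx] <- predict(clf, table$X[, idx, drop = FALSE])
    }
  }
  out <- summarize_performance(lab_r, table$labels, seed = cfg$seed)
  out$per_realization_labels <- lab_r
  out
}
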