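#' Configuration for a selective-voting ensemble run
#'
#' @param Nb number of independent cross-validation realizations. The study
#'   default is 1000; scaled-down values are appropriate for exploration.
#' @param k1 test-fold size for leave-`k1`-out cross-validation (default 10).
#'   Each realization permutes the samples and cuts them into disjoint folds
#'   of `k1` (plus one remainder fold of `n %% k1` when `k1` does not divide
#'   `n`); every sample is held out exactly once per realization.
#' @param classifier base classifier kind: `"lda"`, `"qda"`, `"nb"`, `"svm"`.
#' @param seed integer RNG seed driving all fold permutations (and recorded in
#'   the result for bit-reproducibility).
#' @param cost linear-SVM soft-margin cost (ignored by the other kinds).
#' @param max_redraws how many times a realization may be re-drawn when a
#'   permutation leaves a training fold without 2 members of each class.
#' @return An object of class `sva_config`.
#' @export
sva_config <- function(Nb = 1000L, k1 = 10L,
                       classifier = c("lda", "qda", "nb", "svm"),
                       seed = 1L, cost = 1, max_redraws = 100L) {
  classifier <- match.arg(classifier)
  Nb <- as.integer(Nb); k1 <- as.integer(k1)
  if (Nb < 1L) stop("Nb must be >= 1")
  if (k1 < 1L) stop("k1 must be >= 1")
  structure(list(Nb = Nb, k1 = k1, classifier = classifier,
                 seed = as.integer(seed), cost = cost,
                 max_redraws = as.integer(max_redraws)),
            class = "sva_config")
}

#' Cut a random permutation of samples into disjoint test folds
#'
#' Draws a fresh uniform permutation of `1:n` from the current RNG state and
#' cuts it into consecutive windows of `k1` — the "randomly permuting the
#' columns" step that makes each realization's fold assignment independent.
#'
#' @param n sample count.
#' @param k1 fold size; `1 <= k1 < n`. The last fold has `n %% k1` samples
#'   when `k1` does not divide `n`.
#' @return List of disjoint integer index vectors covering `1:n`.
#' @export
make_folds <- function(n, k1) {
  if (k1 >= n) stop("k1 must be smaller than the number of samples")
  if (k1 < 1L) stop("k1 must be >= 1")
  perm <- sample.int(n)
  split(perm, ceiling(seq_len(n) / k1))
}

#' Majority vote label from a gingivitis/periodontitis tally
#'
#' `-1` (gingivitis) when gingivitis votes exceed periodontitis votes, `+1`
#' (periodontitis) when they fall short, `0` for a tie. Vectorized.
#'
#' @param v_g,v_p non-negative integer vote counts.
#' @return Integer labels in `{-1, 0, +1}`.
#' @export
majority_label <- function(v_g, v_p) {
  if (any(v_g < 0) || any(v_p < 0)) stop("vote counts must be non-negative")
  as.integer(sign(v_p - v_g))
}

#' Per-sample proclivity scores from a vote tally
#'
#' Normalizes accumulated votes into the proclivity pair
#' `G_votes(k) = sum_r v_g(r,k) / (Nb * m(m-1)/2)` and likewise `P_votes`.
#' Votes are summed in integer arithmetic and divided once, so
#' `G_votes + P_votes == 1` holds exactly.
#'
#' @param v_g,v_p `Nb x n` integer vote matrices.
#' @param m number of markers.
#' @return A list with numeric vectors `G_votes` and `P_votes` in `[0, 1]`.
#' @export
proclivity <- function(v_g, v_p, m) {
  Nb <- nrow(v_g)
  denom <- Nb * m * (m - 1) / 2
  list(G_votes = colSums(v_g) / denom,
       P_votes = colSums(v_p) / denom)
}

# lexicographic enumeration of unordered marker pairs: 2 x m(m-1)/2 matrix
pair_index <- function(m) {
  if (m < 2L) stop("m >= 2 required")
  utils::combn(m, 2L)
}

# draw folds, re-drawing (capped) if any training complement lacks 2 of a class
draw_valid_folds <- function(labels, k1, max_redraws) {
  n <- length(labels)
  for (attempt in seq_len(max_redraws + 1L)) {
    folds <- make_folds(n, k1)
    ok <- all(vapply(folds, function(idx) {
      tr <- labels[-idx]
      sum(tr == -1L) >= 2L && sum(tr == 1L) >= 2L
    }, logical(1)))
    if (ok) return(folds)
    warning("degenerate training fold; re-drawing realization permutation",
            call. = FALSE)
  }
  stop("could not draw a valid fold partition in ", max_redraws, " redraws")
}

#' Run one cross-validation realization of pairwise voting
#'
#' For each test fold, trains one classifier per unordered marker pair on the
#' fold's complement and lets it vote on every held-out sample. Each sample
#' is tested exactly once, so it accrues exactly `m(m-1)/2` votes.
#'
#' Uses the current RNG state to draw the fold permutation; [run_sva()] calls
#' this `Nb` times under a single seeded generator.
#'
#' @param table a normalized [biomarker_table()].
#' @param cfg an [sva_config()].
#' @return A list with `v_g`, `v_p` (length-`n` integer vote counts) and
#'   `gmask` (length-`n` integer bitmask; bit `b - 1` set iff pair `b` in
#'   lexicographic order voted gingivitis for that sample).
#' @export
run_realization <- function(table, cfg) {
  stopifnot(inherits(table, "biomarker_table"), inherits(cfg, "sva_config"))
  n <- ncol(table$X)
  m <- nrow(table$X)
  pairs <- pair_index(m)
  folds <- draw_valid_folds(table$labels, cfg$k1, cfg$max_redraws)
  gmask <- integer(n)
  v_g <- integer(n)
  for (idx in folds) {
    X_tr <- table$X[, -idx, drop = FALSE]
    y_tr <- table$labels[-idx]
    X_te <- table$X[, idx, drop = FALSE]
    for (b in seq_len(ncol(pairs))) {
      fi <- pairs[, b]
      clf <- train_pair_classifier(cfg$classifier,
                                   X_tr[fi, , drop = FALSE], y_tr,
                                   feature_indices = fi, cost = cfg$cost)
      vote <- predict(clf, X_te[fi, , drop = FALSE])
      g <- vote == -1L
      v_g[idx[g]] <- v_g[idx[g]] + 1L
      gmask[idx[g]] <- bitwOr(gmask[idx[g]], bitwShiftL(1L, b - 1L))
    }
  }
  list(v_g = v_g, v_p = ncol(pairs) - v_g, gmask = gmask)
}

#' Run the full selective-voting ensemble analysis
#'
#' Executes `Nb` randomized leave-`k1`-out realizations of pairwise-feature
#' voting on a normalized biomarker table. Per realization, each of the
#' `m(m-1)/2` marker-pair classifiers votes once on every held-out sample;
#' the per-realization majority label, the accumulated vote tally, the
#' proclivity pair `(G_votes, P_votes)`, and the per-realization ensemble
#' sets are all retained.
#'
#' The aggregate label of a sample is the majority of its per-realization
#' labels (tie realizations contribute nothing; an overall tie yields 0).
#'
#' @param table a normalized [biomarker_table()].
#' @param cfg an [sva_config()].
#' @return An object of class `sva_result`: a list with
#'   \describe{
#'     \item{G_votes, P_votes}{length-`n` proclivity scores, summing to 1.}
#'     \item{per_realization_labels}{`Nb x n` matrix over `{-1, 0, +1}`.}
#'     \item{aggregate_labels}{length-`n` vector over `{-1, 0, +1}`.}
#'     \item{v_g, v_p}{`Nb x n` integer vote tallies.}
#'     \item{gmask}{`Nb x n` integer bitmasks encoding the per-realization
#'       gingivitis ensemble sets over the lexicographic pair order.}
#'     \item{pairs}{`2 x m(m-1)/2` marker-pair enumeration.}
#'     \item{sample_ids, labels, config}{bookkeeping echoes.}
#'   }
#' @export
run_sva <- function(table, cfg = sva_config()) {
  stopifnot(inherits(table, "biomarker_table"))
  if (!table$normalized)
    stop("run_sva expects a normalized table; call log_normalize() first")
  n <- ncol(table$X)
  m <- nrow(table$X)
  if (cfg$k1 >= n) stop("k1 must be smaller than n")
  if (cfg$k1 > n / 4)
    warning("k1 > n/4: the training set is not much larger than the test set",
            call. = FALSE)
  npair <- m * (m - 1) / 2
  if (npair > 30L) stop("at most 30 marker pairs supported (m <= 8)")
  set.seed(cfg$seed)
  v_g <- matrix(0L, cfg$Nb, n)
  gmask <- matrix(0L, cfg$Nb, n)
  for (r in seq_len(cfg$Nb)) {
    rr <- run_realization(table, cfg)
    stopifnot(all(rr$v_g + rr$v_p == npair))   # vote conservation
    v_g[r, ] <- rr$v_g
    gmask[r, ] <- rr$gmask
  }
  v_p <- npair - v_g
  lab_r <- matrix(majority_label(v_g, v_p), cfg$Nb, n)
  agg <- as.integer(sign(colSums(lab_r == 1L) - colSums(lab_r == -1L)))
  pr <- proclivity(v_g, v_p, m)
  structure(list(G_votes = pr$G_votes, P_votes = pr$P_votes,
                 per_realization_labels = lab_r,
                 aggregate_labels = agg,
                 v_g = v_g, v_p = v_p, gmask = gmask,
                 pairs = pair_index(m),
                 sample_ids = table$sample_ids,
                 marker_names = table$marker_names,
                 labels = table$labels,
                 config = cfg),
            class = "sva_result")
}

#' @export
print.sva_result <- function(x, ...) {
  cat(sprintf("sva_result: %d samples, %d marker pairs, Nb = %d (%s)\n",
              length(x$G_votes), ncol(x$pairs), x$config$Nb,
              toupper(x$config$classifier)))
  agg <- table(factor(x$aggregate_labels, levels = c(-1L, 0L, 1L),
                      labels = c("gingivitis", "tie", "periodontitis")))
  cat("  aggregate labels: ",
      paste(names(agg), agg, sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract the ensemble sets of one sample in one realization
#'
#' @param result an [run_sva()] result.
#' @param r realization index.
#' @param k sample index.
#' @return A list with `g` and `p`: integer matrices of marker-pair columns
#'   (rows `i < j`) that voted gingivitis resp. periodontitis.
#' @export
ensemble_sets <- function(result, r, k) {
  stopifnot(inherits(result, "sva_result"))
  np <- ncol(result$pairs)
  bits <- bitwAnd(bitwShiftR(result$gmask[r, k], 0:(np - 1L)), 1L) == 1L
  list(g = result$pairs[, bits, drop = FALSE],
       p = result$pairs[, !bits, drop = FALSE])
}

#' Proclivity table as a data frame
#'
#' @param result an [run_sva()] result.
#' @return Data frame with `sample_id`, clinical `label`, `G_votes`,
#'   `P_votes`, `aggregate_label`.
#' @export
proclivity_table <- function(result) {
  stopifnot(inherits(result, "sva_result"))
  data.frame(sample_id = result$sample_ids,
             label = result$labels,
             G_votes = result$G_votes,
             P_votes = result$P_votes,
             aggregate_label = result$aggregate_labels,
             stringsAsFactors = FALSE)
}
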