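#' Two-class base classifiers
#'
#' The voting ensemble delegates every vote to one of four standard two-class
#' classifiers: linear discriminant analysis (LDA), quadratic discriminant
#' analysis (QDA), Gaussian naive Bayes (NB), or a linear soft-margin support
#' vector machine (SVM). All four share one train/predict contract so they are
#' interchangeable both on marker pairs (ensemble mode) and on all `m` markers
#' (traditional single-classifier mode).
#'
#' LDA, QDA and NB are fitted from their closed-form Gaussian plug-in
#' estimates with class priors taken from training-fold proportions. QDA
#' covariances are shrunk toward their diagonal,
#' `S_c <- (1 - gamma) S_c + gamma diag(S_c)` with `gamma = 1e-4` escalated
#' tenfold until positive definite, because two-feature folds of ~35
#' z-scored samples can be near-singular. NB per-feature variances receive a
#' `1e-9` floor. The SVM is a linear-kernel soft-margin machine
#' (cost `C = 1` by default) fitted by [e1071::svm()].
#'
#' Decision ties (posteriors exactly equal, or an SVM decision value of
#' exactly 0) are resolved deterministically to `+1` (periodontitis).
#'
#' @param kind one of `"lda"`, `"qda"`, `"nb"`, `"svm"`.
#' @param X_train numeric `d x k` matrix, features in rows, training samples
#'   in columns.
#' @param y_train integer labels in `{-1, +1}`, one per training sample; both
#'   classes must have at least 2 members.
#' @param feature_indices optional integer vector recording which markers of
#'   the parent table the rows of `X_train` are (bookkeeping only).
#' @param cost SVM soft-margin cost parameter.
#'
#' @return An object of class `sva_classifier` with a [predict()] method.
#' @export
train_pair_classifier <- function(kind = c("lda", "qda", "nb", "svm"),
                                  X_train, y_train,
                                  feature_indices = seq_len(nrow(X_train)),
                                  cost = 1) {
  kind <- match.arg(kind)
  X_train <- as.matrix(X_train)
  y_train <- as.integer(y_train)
  if (ncol(X_train) != length(y_train))
    stop("ncol(X_train) must equal length(y_train)")
  if (!all(y_train %in% c(-1L, 1L)))
    stop("y_train must be in {-1, +1}")
  n_neg <- sum(y_train == -1L)
  n_pos <- sum(y_train == 1L)
  if (n_neg < 2L || n_pos < 2L)
    stop(sprintf(
      "degenerate training fold: class counts (-1: %d, +1: %d); >= 2 each required",
      n_neg, n_pos))
  d <- nrow(X_train)
  priors <- c(neg = n_neg, pos = n_pos) / (n_neg + n_pos)

  Xn <- X_train[, y_train == -1L, drop = FALSE]
  Xp <- X_train[, y_train == 1L, drop = FALSE]
  fit <- switch(kind,
    lda = {
      Sn <- stats::cov(t(Xn)); Sp <- stats::cov(t(Xp))
      pooled <- ((n_neg - 1) * Sn + (n_pos - 1) * Sp) / (n_neg + n_pos - 2)
      list(means = cbind(neg = rowMeans(Xn), pos = rowMeans(Xp)),
           cov_inv = solve_spd(pooled, "pooled covariance"))
    },
    qda = {
      list(means = cbind(neg = rowMeans(Xn), pos = rowMeans(Xp)),
           neg = shrunk_gaussian(stats::cov(t(Xn))),
           pos = shrunk_gaussian(stats::cov(t(Xp))))
    },
    nb = {
      vfloor <- 1e-9
      list(means = cbind(neg = rowMeans(Xn), pos = rowMeans(Xp)),
           vars = cbind(neg = apply(Xn, 1L, stats::var) + vfloor,
                        pos = apply(Xp, 1L, stats::var) + vfloor))
    },
    svm = {
      yf <- factor(y_train, levels = c(-1L, 1L))
      e1071::svm(x = t(X_train), y = yf, kernel = "linear", cost = cost,
                 scale = FALSE)
    })
  structure(list(kind = kind, d = d, feature_indices = feature_indices,
                 class_priors = priors, fit = fit, cost = cost),
            class = "sva_classifier")
}

# diagonal-target ridge shrinkage until positive definite; returns the
# inverse and log-determinant needed by the quadratic discriminant
shrunk_gaussian <- function(S, gamma = 1e-4) {
  repeat {
    Ss <- (1 - gamma) * S + gamma * diag(diag(S), nrow = nrow(S))
    ch <- tryCatch(chol(Ss), error = function(e) NULL)
    if (!is.null(ch) && all(diag(ch) > 0))
      return(list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch)))))
    if (gamma > 1) stop("covariance singular even after full shrinkage")
    gamma <- gamma * 10
  }
}

solve_spd <- function(S, what) {
  ch <- tryCatch(chol(S), error = function(e)
    stop("singular ", what, " in training fold"))
  chol2inv(ch)
}

#' Predict class labels with a trained base classifier
#'
#' Deterministic, abstention-free prediction: every column of `newdata`
#' receives exactly one label in `{-1, +1}`, with exact decision-boundary
#' ties going to `+1`.
#'
#' @param object an `sva_classifier` from [train_pair_classifier()].
#' @param newdata numeric `d x k` matrix with the same feature rows the
#'   classifier was trained on.
#' @param ... unused.
#' @return Integer vector of `k` labels in `{-1, +1}`.
#' @export
predict.sva_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != object$d)
    stop(sprintf("dimension mismatch: classifier expects %d features, got %d",
                 object$d, nrow(newdata)))
  pr <- log(object$class_priors)
  score <- switch(object$kind,   # score = log-posterior(+1) - log-posterior(-1)
    lda = {
      f <- object$fit
      w <- f$cov_inv %*% (f$means[, "pos"] - f$means[, "neg"])
      b <- -0.5 * (crossprod(f$means[, "pos"], f$cov_inv %*% f$means[, "pos"]) -
                   crossprod(f$means[, "neg"], f$cov_inv %*% f$means[, "neg"])) +
           pr["pos"] - pr["neg"]
      drop(crossprod(w, newdata)) + drop(b)
    },
    qda = {
      f <- object$fit
      qp <- mahalanobis_cols(newdata, f$means[, "pos"], f$pos$inv)
      qn <- mahalanobis_cols(newdata, f$means[, "neg"], f$neg$inv)
      (-0.5 * (f$pos$logdet + qp) + pr["pos"]) -
        (-0.5 * (f$neg$logdet + qn) + pr["neg"])
    },
    nb = {
      f <- object$fit
      ll <- function(cls) {
        colSums(stats::dnorm(newdata, mean = f$means[, cls],
                             sd = sqrt(f$vars[, cls]), log = TRUE))
      }
      ll("pos") - ll("neg") + pr["pos"] - pr["neg"]
    },
    svm = {
      dv <- attr(stats::predict(object$fit, t(newdata),
                                decision.values = TRUE), "decision.values")
      # e1071 orients decision values so positive favors the class named
      # first in the column header "a/b"
      if (colnames(dv)[1L] == "-1/1") -drop(dv) else drop(dv)
    })
  unname(ifelse(score >= 0, 1L, -1L))
}

mahalanobis_cols <- function(X, mu, inv) {
  D <- X - mu
  colSums(D * (inv %*% D))
}
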