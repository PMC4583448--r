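#' Target group moments for the synthetic salivary panel
#'
#' Per-marker, per-group target means and standard deviations on the raw
#' concentration (pg/mL) scale. The defaults reproduce the reported group
#' statistics of the four-marker salivary panel (IL-1beta, IL-6, MMP-8,
#' MIP-1alpha) in a gingivitis/periodontitis cohort: means well below the
#' SDs for some markers, i.e. strongly right-skewed marginals with heavy
#' between-group overlap.
#'
#' @param markers marker names.
#' @param gin_mean,gin_sd gingivitis-group means and SDs.
#' @param per_mean,per_sd periodontitis-group means and SDs.
#' @return An object of class `group_moments`: a data frame with one row per
#'   marker and columns `marker`, `gin_mean`, `gin_sd`, `per_mean`, `per_sd`.
#' @export
group_moments <- function(markers = c("IL-1beta", "IL-6", "MMP-8", "MIP-1alpha"),
                          gin_mean = c(29.6, 3.9, 208.2, 10.9),
                          gin_sd = c(49.5, 5.9, 194.2, 14.5),
                          per_mean = c(157.6, 12.1, 397.9, 24.4),
                          per_sd = c(217, 10.2, 302.1, 29.8)) {
  m <- length(markers)
  stopifnot(length(gin_mean) == m, length(gin_sd) == m,
            length(per_mean) == m, length(per_sd) == m)
  if (any(c(gin_mean, gin_sd, per_mean, per_sd) <= 0))
    stop("all target means and SDs must be positive")
  structure(data.frame(marker = markers,
                       gin_mean = gin_mean, gin_sd = gin_sd,
                       per_mean = per_mean, per_sd = per_sd,
                       stringsAsFactors = FALSE),
            class = c("group_moments", "data.frame"))
}

#' Log-normal parameters matching a target mean and SD
#'
#' Moment matching for the log-normal family: `sigma^2 = log(1 + S^2/M^2)`
#' and `mu = log(M) - sigma^2/2`, so that `exp(mu + sigma*Z)` with standard
#' normal `Z` has mean `M` and standard deviation `S` exactly.
#'
#' @param M target mean(s), > 0.
#' @param S target SD(s), > 0 (a 0 is tolerated as the degenerate
#'   point-mass limit `sigma = 0`).
#' @return A list with numeric vectors `mu` and `sigma`.
#' @export
lognormal_params_from_moments <- function(M, S) {
  if (any(M <= 0)) stop("target mean must be positive")
  if (any(S < 0)) stop("target SD must be non-negative")
  sigma2 <- log(1 + S^2 / M^2)
  list(mu = log(M) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_gin,n_per group sizes (defaults 40/40).
#' @param moments a [group_moments()] object.
#' @param correlation optional between-marker correlation matrix applied on
#'   the log scale (shared by both groups), or a list with elements `gin`
#'   and `per`; `NULL` means independent markers.
#' @param planted_swap_fraction fraction of each group drawn from the
#'   opposite group's distribution while keeping its nominal clinical label,
#'   in `[0, 0.5]`. Planted swaps emulate a biologically discordant
#'   subpopulation and give the mismatch analysis a known ground truth.
#' @param family marginal family: `"lognormal"` (default, matches the
#'   positive skew and log-scale analysis of salivary panels) or `"gamma"`
#'   (moment-matched alternative).
#' @param emit_clinical also draw BOP/PPD/CAL parameters uniformly inside
#'   each sample's nominal case definition (to exercise label derivation).
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_gin = 40L, n_per = 40L, moments = group_moments(),
                        correlation = NULL, planted_swap_fraction = 0,
                        family = c("lognormal", "gamma"),
                        emit_clinical = FALSE, seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(moments, "group_moments"))
  n_gin <- as.integer(n_gin); n_per <- as.integer(n_per)
  if (n_gin < 2L || n_per < 2L) stop("group sizes must be >= 2")
  if (planted_swap_fraction < 0 || planted_swap_fraction > 0.5)
    stop("planted_swap_fraction must be in [0, 0.5]")
  m <- nrow(moments)
  corr <- if (is.null(correlation)) {
    list(gin = diag(m), per = diag(m))
  } else if (is.list(correlation)) {
    correlation
  } else {
    list(gin = correlation, per = correlation)
  }
  for (R in corr) {
    if (!isSymmetric(unname(R)) || nrow(R) != m)
      stop("correlation must be a symmetric m x m matrix")
    if (inherits(tryCatch(chol(R), error = identity), "error"))
      stop("correlation matrix must be positive definite")
  }
  structure(list(n_gin = n_gin, n_per = n_per, moments = moments,
                 correlation = corr,
                 planted_swap_fraction = planted_swap_fraction,
                 family = family, emit_clinical = emit_clinical,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# raw-scale draws for n samples from one group's law (markers in rows)
draw_group <- function(n, moments, group, corr, family) {
  M <- if (group == "gin") moments$gin_mean else moments$per_mean
  S <- if (group == "gin") moments$gin_sd else moments$per_sd
  m <- nrow(moments)
  if (family == "lognormal") {
    p <- lognormal_params_from_moments(M, S)
    Z <- matrix(stats::rnorm(n * m), n, m) %*% chol(corr)
    t(exp(sweep(sweep(Z, 2L, p$sigma, `*`), 2L, p$mu, `+`)))
  } else {
    # gamma with matched mean/SD; correlation via a Gaussian copula
    Z <- matrix(stats::rnorm(n * m), n, m) %*% chol(corr)
    U <- stats::pnorm(Z)
    shape <- M^2 / S^2
    X <- vapply(seq_len(m), function(j)
      stats::qgamma(U[, j], shape = shape[j], rate = shape[j] / M[j]),
      numeric(n))
    t(X)
  }
}

#' Generate a synthetic two-group biomarker cohort
#'
#' Draws each sample's marker vector from its generating group's
#' moment-matched law (log-normal by default, optionally correlated on the
#' log scale via a joint-normal construction). A `planted_swap_fraction`
#' of each group keeps its nominal clinical label but is drawn from the
#' opposite group's distribution; those samples are the ground truth for
#' mismatch-recovery experiments.
#'
#' @param spec a [cohort_spec()].
#' @return A list with
#'   \describe{
#'     \item{table}{a raw-scale [biomarker_table()]; gingivitis samples
#'       (`G01`, `G02`, ...) first, then periodontitis (`P01`, ...).}
#'     \item{truth}{data frame with `sample_id`, nominal `label`,
#'       `generating_group` (`-1`/`+1`), and logical `swapped`.}
#'     \item{clinical}{data frame of BOP/PPD/CAL parameters consistent with
#'       each nominal label, or `NULL` unless `emit_clinical`.}
#'   }
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_gin + spec$n_per
  labels <- rep(c(-1L, 1L), c(spec$n_gin, spec$n_per))
  ids <- c(sprintf("G%02d", seq_len(spec$n_gin)),
           sprintf("P%02d", seq_len(spec$n_per)))
  n_swap_g <- round(spec$planted_swap_fraction * spec$n_gin)
  n_swap_p <- round(spec$planted_swap_fraction * spec$n_per)
  swapped <- rep(FALSE, n)
  if (n_swap_g > 0)
    swapped[sample(which(labels == -1L), n_swap_g)] <- TRUE
  if (n_swap_p > 0)
    swapped[sample(which(labels == 1L), n_swap_p)] <- TRUE
  gen <- ifelse(swapped, -labels, labels)
  m <- nrow(spec$moments)
  X <- matrix(NA_real_, m, n)
  from_gin <- gen == -1L
  if (any(from_gin))
    X[, from_gin] <- draw_group(sum(from_gin), spec$moments, "gin",
                                spec$correlation$gin, spec$family)
  if (any(!from_gin))
    X[, !from_gin] <- draw_group(sum(!from_gin), spec$moments, "per",
                                 spec$correlation$per, spec$family)
  clinical <- NULL
  if (spec$emit_clinical) {
    gin <- labels == -1L
    clinical <- data.frame(
      sample_id = ids,
      bop_pct = ifelse(gin, stats::runif(n, 20, 80),
                       stats::runif(n, 20.1, 80)),
      ppd4_pct = ifelse(gin, stats::runif(n, 0, 9.9),
                        stats::runif(n, 10.1, 60)),
      cal2_any = !gin,
      stringsAsFactors = FALSE)
  }
  list(table = biomarker_table(X, ids, spec$moments$marker, labels,
                               normalized = FALSE),
       truth = data.frame(sample_id = ids, label = labels,
                          generating_group = gen, swapped = swapped,
                          stringsAsFactors = FALSE),
       clinical = clinical)
}
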