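#' Persistent ensemble sets across realizations
#'
#' A marker pair belongs to a sample's persistent gingivitis set when it
#' voted gingivitis for that sample in every one of the `Nb` realizations
#' (strict intersection), and symmetrically for periodontitis. Pairs that
#' ever switched sides belong to neither set. A `consistency` fraction below
#' 1 relaxes the rule to "voted that way in at least `consistency * Nb`
#' realizations"; the strict behavior is the default and the reference
#' definition.
#'
#' @param result an [run_sva()] result.
#' @param consistency required vote-agreement fraction in `(0.5, 1]`;
#'   default 1 (strict intersection).
#' @return An object of class `persistent_sets`: a list with
#'   `g_star`/`p_star` (per-sample lists of pair-index vectors into
#'   `result$pairs`), the equivalent integer bitmasks `g_mask`/`p_mask`,
#'   `pairs`, `sample_ids`, and `labels`.
#' @export
persistent_sets <- function(result, consistency = 1) {
  stopifnot(inherits(result, "sva_result"))
  if (consistency <= 0.5 || consistency > 1)
    stop("consistency must be in (0.5, 1]")
  Nb <- nrow(result$gmask)
  np <- ncol(result$pairs)
  n <- ncol(result$gmask)
  need <- if (consistency == 1) Nb else ceiling(consistency * Nb)
  # per-(pair, sample) count of gingivitis votes across realizations
  cnt <- vapply(seq_len(np), function(b)
    colSums(matrix(bitwAnd(bitwShiftR(result$gmask, b - 1L), 1L), Nb, n)),
    numeric(n))                                   # n x np
  g_in <- cnt >= need
  p_in <- (Nb - cnt) >= need
  mask_of <- function(inmat) {
    as.integer(inmat %*% bitwShiftL(1L, 0:(np - 1L)))
  }
  structure(list(
    g_star = apply(g_in, 1L, which, simplify = FALSE),
    p_star = apply(p_in, 1L, which, simplify = FALSE),
    g_mask = mask_of(g_in),
    p_mask = mask_of(p_in),
    pairs = result$pairs,
    sample_ids = result$sample_ids,
    labels = result$labels,
    consistency = consistency),
    class = "persistent_sets")
}

popcount <- function(x, nbits) {
  out <- integer(length(x))
  for (b in 0:(nbits - 1L))
    out <- out + bitwAnd(bitwShiftR(x, b), 1L)
  out
}

#' Between-sample consensus map
#'
#' The consensus `tau(i, j)` counts the marker pairs shared by the persistent
#' ensemble sets of samples `i` and `j`: within the gingivitis group it
#' intersects the two gingivitis sets, within the periodontitis group the two
#' periodontitis sets, and between groups the gingivitis set of the
#' gingivitis-labeled sample with the periodontitis set of the
#' periodontitis-labeled sample. The matrix is symmetric with values in
#' `[0, m(m-1)/2]`. Diagonal cells (not part of the definition) are filled
#' with the size of the sample's own-group persistent set, for display only.
#'
#' @param psets a [persistent_sets()] object.
#' @param labels clinical labels over `{-1, +1}`; defaults to the labels
#'   carried by `psets`.
#' @return An object of class `consensus_map`: list with the `n x n` integer
#'   matrix `tau`, a same-shaped character `region` matrix
#'   (`"GxG"`/`"PxP"`/`"GxP"`), `sample_ids`, `labels`, and `n_pairs`.
#' @export
consensus_map <- function(psets, labels = psets$labels) {
  stopifnot(inherits(psets, "persistent_sets"))
  n <- length(psets$g_mask)
  np <- ncol(psets$pairs)
  stopifnot(length(labels) == n, all(labels %in% c(-1L, 1L)))
  # per-sample mask entering each region: own-group set within groups,
  # class-matched sets between groups
  own <- ifelse(labels == -1L, psets$g_mask, psets$p_mask)
  tau <- matrix(0L, n, n, dimnames = list(psets$sample_ids, psets$sample_ids))
  region <- matrix("", n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        tau[i, j] <- popcount(bitwAnd(own[i], own[j]), np)
        region[i, j] <- if (labels[i] == -1L) "GxG" else "PxP"
      } else {
        gi <- if (labels[i] == -1L) i else j   # gingivitis member of the pair
        pi_ <- if (labels[i] == -1L) j else i
        tau[i, j] <- popcount(bitwAnd(psets$g_mask[gi], psets$p_mask[pi_]), np)
        region[i, j] <- "GxP"
      }
    }
  }
  structure(list(tau = tau, region = region,
                 sample_ids = psets$sample_ids, labels = labels,
                 n_pairs = np),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("consensus_map: %d x %d, tau in [0, %d]\n",
              nrow(x$tau), ncol(x$tau), x$n_pairs))
  for (rg in c("GxG", "PxP", "GxP")) {
    cells <- x$tau[x$region == rg & upper.tri(x$tau)]
    if (length(cells))
      cat(sprintf("  mean tau %s: %.3f\n", rg, mean(cells)))
  }
  invisible(x)
}

#' Export a consensus map as heatmap image and TSV matrix
#'
#' Renders the upper triangle of `tau` (the map is symmetric) with gingivitis
#' samples ordered first, then periodontitis, so the three regions (GxG top
#' left, PxP bottom right, GxP between) form contiguous blocks. The color
#' scale is linear from 0 to `m(m-1)/2` so renders are comparable across
#' classifier kinds. The full symmetric matrix is also written as TSV with
#' sample IDs as row and column headers.
#'
#' @param cmap a [consensus_map()].
#' @param image_path output PNG path, or `NULL` to skip the image.
#' @param matrix_path output TSV path, or `NULL` to skip the matrix.
#' @return Invisibly, the reordered `tau` matrix.
#' @export
export_heatmap <- function(cmap, image_path = NULL, matrix_path = NULL) {
  stopifnot(inherits(cmap, "consensus_map"))
  ord <- order(cmap$labels)   # gingivitis (-1) first
  tau <- cmap$tau[ord, ord]
  n_gin <- sum(cmap$labels == -1L)
  n <- nrow(tau)
  if (!is.null(matrix_path)) {
    utils::write.table(
      data.frame(sample_id = rownames(tau), tau, check.names = FALSE),
      matrix_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(image_path)) {
    shown <- tau
    shown[lower.tri(shown)] <- NA   # symmetric: draw the upper triangle only
    grDevices::png(image_path, width = 900, height = 900)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(cmap$n_pairs + 1L, "inferno")
    graphics::par(mar = c(5, 5, 3, 6))
    graphics::image(seq_len(n), seq_len(n), t(shown[n:1, ]),
                    zlim = c(0, cmap$n_pairs), col = pal, axes = FALSE,
                    xlab = "sample", ylab = "sample",
                    main = "Consensus map (upper triangle)")
    graphics::abline(v = n_gin + 0.5, h = n - n_gin + 0.5, col = "white",
                     lwd = 2, lty = 2)
    graphics::mtext(c("G", "P"), side = 1,
                    at = c(n_gin / 2, n_gin + (n - n_gin) / 2), line = 1)
    graphics::box()
    legend_vals <- 0:cmap$n_pairs
    graphics::legend("topright", inset = c(-0.05, 0), xpd = TRUE,
                     legend = rev(legend_vals), fill = rev(pal),
                     title = "tau", bty = "n", cex = 0.9)
  }
  invisible(tau)
}

#' Per-sample mean consensus within and between groups
#'
#' Summarizes each sample's row of the consensus map: the mean `tau` against
#' the other members of its own clinical group and against the opposite
#' group. Samples at odds with their group (heterogeneous or mismatched)
#' show depressed within-group consensus.
#'
#' @param cmap a [consensus_map()].
#' @return Data frame with `sample_id`, `label`, `mean_within`, `mean_between`.
#' @export
consensus_profile <- function(cmap) {
  stopifnot(inherits(cmap, "consensus_map"))
  n <- nrow(cmap$tau)
  within <- between <- numeric(n)
  for (k in seq_len(n)) {
    same <- which(cmap$labels == cmap$labels[k])
    same <- setdiff(same, k)
    other <- which(cmap$labels != cmap$labels[k])
    within[k] <- mean(cmap$tau[k, same])
    between[k] <- mean(cmap$tau[k, other])
  }
  data.frame(sample_id = cmap$sample_ids, label = cmap$labels,
             mean_within = within, mean_between = between,
             stringsAsFactors = FALSE)
}
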