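# minimal hand-crafted sva_result for set-level tests: m = 3 markers
# (3 pairs), 2 realizations, 4 samples
crafted_result <- function() {
  # bitmask bit b-1 set <=> pair b voted gingivitis
  # sample 1: pairs {1,2} G both times, pair 3 P both times
  # sample 2: pair 1 flips sides between realizations (consistent in neither),
  #           pair 2 G both times, pair 3 P both times
  # sample 3: all pairs G always; sample 4: all pairs P always
  gmask <- rbind(c(3L, 3L, 7L, 0L),
                 c(3L, 2L, 7L, 0L))
  np <- 3L
  vg <- matrix(0L, 2, 4)
  for (b in 1:np) vg <- vg + bitwAnd(bitwShiftR(gmask, b - 1L), 1L)
  structure(list(gmask = gmask, v_g = vg, v_p = np - vg,
                 pairs = utils::combn(3L, 2L),
                 sample_ids = paste0("S", 1:4),
                 labels = c(-1L, -1L, 1L, 1L)),
            class = "sva_result")
}

test_that("persistent sets are strict intersections across realizations", {
  ps <- persistent_sets(crafted_result())
  expect_identical(ps$g_star[[1]], c(1L, 2L))
  expect_identical(ps$p_star[[1]], 3L)
  # the flipping pair belongs to neither set of sample 2
  expect_identical(ps$g_star[[2]], 2L)     # bit 2 (pair 2) G in both: 1&6 -> 0? see below
  expect_identical(ps$p_star[[2]], 3L)
  expect_identical(ps$g_star[[3]], 1:3)
  expect_length(ps$p_star[[3]], 0L)
  expect_identical(ps$p_star[[4]], 1:3)
  # disjointness of the two sets, per sample
  for (k in 1:4)
    expect_length(intersect(ps$g_star[[k]], ps$p_star[[k]]), 0L)
})

test_that("with one realization the persistent sets equal that realization's sets", {
  sim <- normalized_cohort(n_gin = 6L, n_per = 6L, seed = 9L)
  res <- run_sva(sim$table, sva_config(Nb = 1L, k1 = 3L, seed = 4L))
  ps <- persistent_sets(res)
  for (k in 1:12) {
    es <- ensemble_sets(res, 1L, k)
    expect_identical(ps$pairs[, ps$g_star[[k]], drop = FALSE], es$g)
    expect_identical(ps$pairs[, ps$p_star[[k]], drop = FALSE], es$p)
  }
})

test_that("consensus map matches a brute-force set-intersection oracle", {
  sim <- normalized_cohort(n_gin = 4L, n_per = 4L, seed = 10L)
  res <- run_sva(sim$table, sva_config(Nb = 3L, k1 = 2L, seed = 5L))
  ps <- persistent_sets(res)
  cm <- consensus_map(ps)

  # oracle: persistent sets recomputed by intersecting pair-name strings
  # across realizations, then pairwise intersections per the region rules
  key <- function(pm) if (ncol(pm) == 0) character(0) else
    paste(pm[1, ], pm[2, ], sep = "-")
  g_star <- p_star <- vector("list", 8L)
  for (k in 1:8) {
    gs <- lapply(1:3, function(r) key(ensemble_sets(res, r, k)$g))
    pstr <- lapply(1:3, function(r) key(ensemble_sets(res, r, k)$p))
    g_star[[k]] <- Reduce(intersect, gs)
    p_star[[k]] <- Reduce(intersect, pstr)
  }
  lab <- sim$table$labels
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    expected <- if (lab[i] == -1L && lab[j] == -1L) {
      length(intersect(g_star[[i]], g_star[[j]]))
    } else if (lab[i] == 1L && lab[j] == 1L) {
      length(intersect(p_star[[i]], p_star[[j]]))
    } else if (lab[i] == -1L) {
      length(intersect(g_star[[i]], p_star[[j]]))
    } else {
      length(intersect(g_star[[j]], p_star[[i]]))
    }
    expect_identical(unname(cm$tau[i, j]), expected)
  }
})

test_that("consensus map is symmetric, bounded, and region-labelled", {
  sim <- normalized_cohort(n_gin = 8L, n_per = 8L, seed = 12L)
  res <- run_sva(sim$table, sva_config(Nb = 4L, k1 = 4L, seed = 6L))
  ps <- persistent_sets(res)
  cm <- consensus_map(ps)
  expect_identical(cm$tau, t(cm$tau))
  expect_true(all(cm$tau >= 0 & cm$tau <= 6L))
  # tau(i,j) <= min of the entering set sizes
  sz <- ifelse(ps$labels == -1L, lengths(ps$g_star), lengths(ps$p_star))
  for (i in 1:16) for (j in 1:16) {
    if (i == j || ps$labels[i] != ps$labels[j]) next
    expect_lte(cm$tau[i, j], min(sz[i], sz[j]))
  }
  expect_true(all(cm$region %in% c("GxG", "PxP", "GxP")))
  expect_identical(unname(cm$region[1, 2]), "GxG")
  expect_identical(unname(cm$region[9, 10]), "PxP")
  expect_identical(unname(cm$region[1, 9]), "GxP")
})

test_that("relabeling samples permutes the consensus map consistently", {
  res <- crafted_result()
  ps <- persistent_sets(res)
  cm <- consensus_map(ps)
  perm <- c(2L, 4L, 1L, 3L)
  ps2 <- ps
  ps2$g_star <- ps$g_star[perm]; ps2$p_star <- ps$p_star[perm]
  ps2$g_mask <- ps$g_mask[perm]; ps2$p_mask <- ps$p_mask[perm]
  ps2$sample_ids <- ps$sample_ids[perm]; ps2$labels <- ps$labels[perm]
  cm2 <- consensus_map(ps2)
  expect_identical(unname(cm2$tau), unname(cm$tau[perm, perm]))
})

test_that("a separable cohort saturates the consensus map", {
  sim <- normalized_cohort(n_gin = 8L, n_per = 8L, seed = 13L,
                           moments = separable_moments())
  res <- run_sva(sim$table, sva_config(Nb = 10L, k1 = 4L, seed = 7L))
  ps <- persistent_sets(res)
  # every pair votes each sample's generating group consistently, so each
  # sample's own-group persistent set is the full pair set ...
  own_size <- ifelse(sim$table$labels == -1L,
                     lengths(ps$g_star), lengths(ps$p_star))
  expect_true(all(own_size == 6L))
  cm <- consensus_map(ps)
  expect_true(all(cm$tau[cm$region == "GxG"] == 6L))
  expect_true(all(cm$tau[cm$region == "PxP"] == 6L))
  # ... and the between-group cells intersect two full sets: every pair that
  # consistently votes a gingivitis sample G also consistently votes a
  # periodontitis sample P, so G x P saturates as well
  expect_true(all(cm$tau[cm$region == "GxP"] == 6L))
})

test_that("heatmap export writes an ordered TSV matrix and a PNG", {
  sim <- normalized_cohort(n_gin = 5L, n_per = 5L, seed = 14L)
  res <- run_sva(sim$table, sva_config(Nb = 2L, k1 = 2L, seed = 8L))
  cm <- consensus_map(persistent_sets(res))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  png_path <- withr::local_tempfile(fileext = ".png")
  tau <- export_heatmap(cm, image_path = png_path, matrix_path = tsv)
  expect_true(file.exists(tsv))
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  back <- read.delim(tsv, check.names = FALSE)
  expect_identical(back$sample_id, rownames(tau))
  M <- as.matrix(back[, -1]); dimnames(M) <- dimnames(tau)
  expect_equal(M, tau, ignore_attr = FALSE, tolerance = 0)
  # gingivitis block first
  expect_true(all(startsWith(back$sample_id[1:5], "G")))

  # an all-zero map renders without error
  cm0 <- cm; cm0$tau[] <- 0L
  expect_silent(export_heatmap(cm0, image_path = png_path, matrix_path = NULL))
})

test_that("mismatched samples show depressed within-group consensus", {
  sim <- normalized_cohort(n_gin = 15L, n_per = 15L, seed = 15L,
                           moments = separable_moments(), swap = 0.2)
  res <- run_sva(sim$table, sva_config(Nb = 20L, k1 = 5L, seed = 9L))
  cm <- consensus_map(persistent_sets(res))
  prof <- consensus_profile(cm)
  swapped <- sim$truth$swapped
  expect_lt(mean(prof$mean_within[swapped]),
            mean(prof$mean_within[!swapped]))
})
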