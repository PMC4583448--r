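# shared fixtures: cohorts are always generated in code

# widely separated groups: log-scale mean gap ~ln(50) ~= 3.9 at log-SD ~0.29,
# i.e. >> 4 pooled SDs -- every reasonable classifier should be near-perfect
separable_moments <- function(m = 4L) {
  base <- 10 * seq_len(m)
  group_moments(markers = paste0("M", seq_len(m)),
                gin_mean = base, gin_sd = 0.3 * base,
                per_mean = 50 * base, per_sd = 15 * base)
}

# overlapping groups of arbitrary width, loosely shaped like the salivary
# panel (SD comparable to the mean)
overlap_moments <- function(m = 4L) {
  base <- c(30, 4, 200, 11, 50, 8)[seq_len(m)]
  group_moments(markers = paste0("M", seq_len(m)),
                gin_mean = base, gin_sd = 1.2 * base,
                per_mean = 2.5 * base, per_sd = 1.5 * base)
}

make_cohort <- function(n_gin = 20L, n_per = 20L, m = 4L, seed = 1L,
                        moments = overlap_moments(m), swap = 0) {
  generate_cohort(cohort_spec(n_gin = n_gin, n_per = n_per, moments = moments,
                              planted_swap_fraction = swap, seed = seed))
}

normalized_cohort <- function(...) {
  sim <- make_cohort(...)
  sim$table <- log_normalize(sim$table)
  sim
}

# 2-D training clouds for classifier tests
gaussian_clouds <- function(n_per_class = 30L, shift = 3, seed = 1L) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(2 * n_per_class), 2L),
             matrix(rnorm(2 * n_per_class, mean = shift), 2L))
  list(X = X, y = rep(c(-1L, 1L), each = n_per_class))
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
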