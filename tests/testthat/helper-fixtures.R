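# Small populations and response matrices used across test files.

tiny_pop <- function(gain = "peaked", ...) {
  input_population(gain, retinal_range = c(-20, 20), eye_range = c(-10, 10),
                   spacing = 5, sigma = 6, rho = 6, seed = 42, ...)
}

# A synthetic E x T response matrix from a response-generating function
# rate(eye, target); eyes/targets follow the standard test geometry scaled
# down unless overridden.
synthetic_responses <- function(rate_fun,
                                eyes = c(-18, -6, 6, 18),
                                targets = seq(-39, 39, by = 2)) {
  R <- outer(eyes, targets, rate_fun)
  dimnames(R) <- list(eye = eyes, target = targets)
  R
}

# Gaussian bump helper for constructing perfectly head- or eye-centred cells.
bump <- function(x, centre, width = 8) exp(-(x - centre)^2 / (2 * width^2))

# Brute-force mean pairwise Pearson correlation over full rows.
oracle_mean_row_cor <- function(R) {
  E <- nrow(R)
  vals <- c()
  for (i in seq_len(E - 1)) {
    for (j in (i + 1):E) {
      if (stats::sd(R[i, ]) > 0 && stats::sd(R[j, ]) > 0)
        vals <- c(vals, stats::cor(R[i, ], R[j, ]))
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Brute-force windowed pairwise correlation (independent of the package's
# vectorised path).
oracle_windowed_cor <- function(R, f, V, eps = 0.01) {
  E <- nrow(R)
  subs <- lapply(seq_len(E), function(i) R[i, f[i]:(f[i] + V - 1)])
  ok <- vapply(subs, function(x) diff(range(x)) >= eps && stats::sd(x) > 0,
               logical(1))
  vals <- c()
  for (i in seq_len(E - 1)) {
    for (j in (i + 1):E) {
      if (ok[i] && ok[j]) vals <- c(vals, stats::cor(subs[[i]], subs[[j]]))
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}
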