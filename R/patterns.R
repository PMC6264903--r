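#' Static-pattern trajectory for Hebbian control training
#'
#' Presents a sequence of static input patterns: each pattern holds a random
#' eye position (uniform over `eye_range`) and a random retinal target
#' location (uniform over `retinal_range`, so the head-centred target sits
#' at their sum) fixed for `duration_ms`.  Used with a short activation time
#' constant and the Hebbian rule to probe what competitive learning alone
#' (without a temporal trace effect) extracts from the input statistics.
#'
#' @param n_patterns number of patterns.
#' @param eye_range,retinal_range sampling ranges (degrees).
#' @param duration_ms presentation time per pattern (ms).
#' @param seed integer seed.
#' @return a `gf_trajectory` tibble sampled at 1 kHz.
#' @export
pattern_trajectory <- function(n_patterns = 200, eye_range = c(-24, 24),
                               retinal_range = c(-63, 63),
                               duration_ms = 100, seed = NULL) {
  draw <- function() {
    e <- runif(n_patterns, eye_range[1], eye_range[2])
    r <- runif(n_patterns, retinal_range[1], retinal_range[2])
    tibble::tibble(
      time_ms = seq_len(n_patterns * duration_ms) - 1,
      eye = rep(e, each = duration_ms),
      target = rep(r + e, each = duration_ms),
      segment = "fixation")
  }
  traj <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(traj, class = c("gf_trajectory", class(traj)), kind = "training")
}

#' Train a model on a static-pattern sequence
#'
#' Integrates the dynamics along a [pattern_trajectory()] with the model's
#' learning rule active (state carries over between calls).
#'
#' @param model a `gf_model` with a rule.
#' @param trajectory a `gf_trajectory`.
#' @return the trained model.
#' @export
train_patterns <- function(model, trajectory) {
  stopifnot(inherits(model, "gf_model"), !is.null(model$rule))
  res <- run_engine(model, trajectory, learn = TRUE)
  model$synapses$weights <- res$W
  model$state <- list(h = res$h, q = res$q, v = res$v,
                      bufq = res$bufq, bufv = res$bufv,
                      buf_head = res$buf_head, buf_count = res$buf_count,
                      t = model$state$t + max(trajectory$time_ms))
  model
}
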