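#' Experiment recipes
#'
#' A recipe bundles the full configuration of one of the canonical
#' experiments: input gain form, output-layer dynamics, learning rule,
#' training protocol and network geometry.  `scale = "full"` echoes the
#' canonical parameter tables (900 output neurons, 20 training epochs, 10 for
#' the prewired-plasticity experiment); `scale = "reduced"` shrinks only the
#' output population and epoch count (200 neurons, 5 epochs) for quick runs,
#' never the rate equations or rule forms.
#'
#' Recipes:
#' * `peaked_standard`, `sigmoid_standard` — standard trace rule with pure
#'   peaked / sigmoidal gain fields.
#' * `hebbian_control` — Hebbian rule on 200 static patterns with a short
#'   (30 ms) activation time constant.
#' * `prewired_plasticity` — manually prewired sigmoidal model, then standard
#'   trace plasticity.
#' * `mixed` — standard trace rule with a mixed population (override
#'   `sigmoid_rate`).
#' * `delayed_trace_antihebb`, `delayed_rate_antihebb`,
#'   `current_trace_antihebb`, `delayed_trace_only` — modified rules with
#'   pure sigmoidal gain at their tuned delay / balance settings.
#' * `delayed_trace_only_mixed50` — pure delayed-trace rule on a 50:50 mixed
#'   population.
#'
#' @param name recipe name.
#' @param scale `"full"` or `"reduced"`.
#' @param ... overrides of individual config fields (e.g. `n_output`,
#'   `epochs`, `sigmoid_rate`).
#' @return a config list of class `gf_recipe`.
#' @export
gf_recipe <- function(name = c("peaked_standard", "sigmoid_standard",
                               "hebbian_control", "prewired_plasticity",
                               "mixed",
                               "delayed_trace_antihebb",
                               "delayed_rate_antihebb",
                               "current_trace_antihebb",
                               "delayed_trace_only",
                               "delayed_trace_only_mixed50"),
                      scale = c("full", "reduced"), ...) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  peaked_dyn <- list(tau_h = 100, tau_q = 400, phi = 4.5, theta = 0.4,
                     pi_pct = 80)
  sigmoid_dyn <- list(tau_h = 100, tau_q = 400, phi = 4.5, theta = 0,
                      pi_pct = 90)
  prewired_dyn <- list(tau_h = 100, tau_q = 400, phi = 4, theta = 0,
                       pi_pct = 90)
  base <- list(name = name, scale = scale,
               gain = "peaked", sigmoid_rate = 0,
               sigma = 6, rho = 6, kappa = 0.0625,
               n_output = 900, connectivity = 0.05,
               epochs = 20, n_periods = 8, n_fixations = 15,
               dynamics = peaked_dyn,
               rule = list(rule = "standard_trace", learning_rate = 0.05),
               prewired = FALSE)
  cfg <- switch(name,
    peaked_standard = base,
    sigmoid_standard = modifyList(base, list(gain = "sigmoid",
                                             dynamics = sigmoid_dyn)),
    hebbian_control = modifyList(base, list(
      dynamics = modifyList(peaked_dyn, list(tau_h = 30)),
      rule = list(rule = "hebbian", learning_rate = 0.05),
      n_patterns = 200, pattern_ms = 100)),
    prewired_plasticity = modifyList(base, list(
      gain = "sigmoid", prewired = TRUE, connectivity = 0.0816,
      dynamics = prewired_dyn, epochs = 10)),
    mixed = modifyList(base, list(gain = "mixed", sigmoid_rate = 0.5)),
    delayed_trace_antihebb = modifyList(base, list(
      gain = "sigmoid", dynamics = sigmoid_dyn,
      rule = list(rule = "delayed_trace_antihebb", learning_rate = 0.05,
                  beta = 2.2, delta_t = 50))),
    delayed_rate_antihebb = modifyList(base, list(
      gain = "sigmoid", dynamics = sigmoid_dyn,
      rule = list(rule = "delayed_rate_antihebb", learning_rate = 0.05,
                  beta = 2.4, delta_t = 500))),
    current_trace_antihebb = modifyList(base, list(
      gain = "sigmoid", dynamics = sigmoid_dyn,
      rule = list(rule = "current_trace_antihebb", learning_rate = 0.05,
                  beta = 2.2))),
    delayed_trace_only = modifyList(base, list(
      gain = "sigmoid", dynamics = sigmoid_dyn,
      rule = list(rule = "delayed_trace_only", learning_rate = 0.05,
                  delta_t = 30))),
    delayed_trace_only_mixed50 = modifyList(base, list(
      gain = "mixed", sigmoid_rate = 0.5, dynamics = sigmoid_dyn,
      rule = list(rule = "delayed_trace_only", learning_rate = 0.05,
                  delta_t = 30))))
  if (scale == "reduced")
    cfg <- modifyList(cfg, list(n_output = 200,
                                epochs = min(cfg$epochs, 5)))
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = "gf_recipe")
}

#' Run an experiment recipe end to end
#'
#' Builds the input population and network (or prewired network), tests the
#' untrained model, trains it, tests again, classifies every output neuron
#' and summarises both phases.  All randomness flows through `seed`.
#'
#' @param recipe a [gf_recipe()].
#' @param seed integer master seed.
#' @param schedule a [testing_schedule()].
#' @param test_untrained also test and classify before training.
#' @return list of class `gf_run` with elements `model`, `responses`,
#'   `classification`, `stats` (tibble with a `phase` column) and `manifest`.
#' @export
run_recipe <- function(recipe, seed = 1L, schedule = testing_schedule(),
                       test_untrained = TRUE) {
  stopifnot(inherits(recipe, "gf_recipe"))
  pop <- input_population(recipe$gain, sigmoid_rate = recipe$sigmoid_rate,
                          sigma = recipe$sigma, rho = recipe$rho,
                          kappa = recipe$kappa, seed = seed * 13L)
  dyn <- do.call(dynamics_params, recipe$dynamics)
  rule <- do.call(learning_rule, recipe$rule)
  model <- if (recipe$prewired) {
    prewire(pop, n_output = recipe$n_output,
            connectivity = recipe$connectivity, dynamics = dyn, rule = rule,
            seed = seed * 17L)
  } else {
    gf_network(pop, n_output = recipe$n_output,
               connectivity = recipe$connectivity, dynamics = dyn,
               rule = rule, seed = seed * 17L)
  }
  stats <- list()
  cls0 <- NULL
  if (test_untrained) {
    resp0 <- test_network(model, schedule)
    cls0 <- classify_responses(resp0)
    stats$untrained <- epoch_statistics(cls0, epoch = 0L)
  }
  if (identical(recipe$name, "hebbian_control")) {
    traj <- pattern_trajectory(n_patterns = recipe$n_patterns,
                               duration_ms = recipe$pattern_ms,
                               seed = seed * 19L)
    model <- train_patterns(model, traj)
  } else if (recipe$epochs > 0) {
    model <- train_network(model, epochs = recipe$epochs,
                           protocol = list(n_periods = recipe$n_periods,
                                           n_fixations = recipe$n_fixations),
                           seed = seed * 19L)
  }
  resp <- test_network(model, schedule)
  cls <- classify_responses(resp)
  stats$trained <- epoch_statistics(cls, epoch = model$epochs_trained)
  stats_tbl <- dplyr::bind_rows(stats, .id = "phase")
  structure(list(model = model, responses = resp,
                 classification = cls, untrained_classification = cls0,
                 stats = stats_tbl,
                 manifest = list(recipe = unclass(recipe), seed = seed)),
            class = "gf_run")
}

#' Sweep the sigmoid modulation rate of a mixed population
#'
#' For each rate p, builds a mixed input population (each neuron sigmoidal
#' with probability p), evaluates the untrained network and the network
#' trained with the standard trace rule, and records the population summary
#' statistics for both phases.
#'
#' @param p_values sigmoid modulation rates in \[0, 1\].
#' @param scale recipe scale.
#' @param seed integer master seed.
#' @param ... recipe overrides (e.g. `n_output`, `epochs`).
#' @return tibble with one row per (p, phase).
#' @export
sweep_sigmoid_rate <- function(p_values = c(0, 0.1, 0.2, 0.5),
                               scale = "reduced", seed = 1L, ...) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  purrr::map_dfr(p_values, function(p) {
    run <- run_recipe(gf_recipe("mixed", scale = scale, sigmoid_rate = p, ...),
                      seed = seed)
    dplyr::mutate(run$stats, sigmoid_rate = p, .before = 1)
  })
}

#' Reduced-scale fixture configuration
#'
#' A small model configuration (coarse preference grids, ~200 input neurons,
#' 50 output neurons, short training) plus a matching compact test schedule,
#' for fast end-to-end runs in examples and tests.
#'
#' @param gain input gain form.
#' @param seed integer seed.
#' @return list with elements `pop`, `model_args`, `protocol`, `schedule`,
#'   `epochs`.
#' @export
make_fixture <- function(gain = "peaked", seed = 1L) {
  pop <- input_population(gain, retinal_range = c(-40, 40),
                          eye_range = c(-24, 24), spacing = 4,
                          sigma = 6, rho = 6, seed = seed)
  list(pop = pop,
       model_args = list(n_output = 50, connectivity = 0.2),
       protocol = list(n_periods = 4, n_fixations = 5,
                       locations = c(-27, -9, 9, 27)),
       schedule = testing_schedule(n_targets = 40,
                                   target_range = c(-58.5, 58.5),
                                   dwell_ms = 330),
       epochs = 2)
}
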