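#' Assemble a gain-field network model
#'
#' Combines an input population, sparse random feedforward connectivity with
#' random unit-norm initial weights, the output-layer dynamics and
#' (optionally) a learning rule into a simulatable model object.
#'
#' @param pop an [input_population()].
#' @param n_output number of competitive output neurons.
#' @param connectivity connectivity fraction: each output neuron receives
#'   `round(connectivity * nrow(pop))` afferents.
#' @param dynamics a [dynamics_params()].
#' @param rule a [learning_rule()] or `NULL` (no plasticity).
#' @param seed integer seed governing connectivity and initial weights.
#' @return object of class `gf_model`.
#' @export
gf_network <- function(pop, n_output = 900, connectivity = 0.05,
                       dynamics = dynamics_params(), rule = learning_rule(),
                       seed = 1L) {
  stopifnot(inherits(pop, "gf_population"), n_output > 0)
  syn <- sample_connectivity(nrow(pop), n_output, connectivity, seed = seed)
  syn <- init_weights(syn, seed = seed + 1L)
  new_gf_model(pop, syn, dynamics, rule,
               seeds = list(connectivity = seed, weights = seed + 1L))
}

new_gf_model <- function(pop, synapses, dynamics, rule, seeds = list(),
                         assigned_locations = NULL) {
  depth <- delay_depth(rule, dynamics)
  structure(list(pop = pop, synapses = synapses, dynamics = dynamics,
                 rule = rule, seeds = seeds,
                 assigned_locations = assigned_locations,
                 state = init_state(ncol(synapses$pre), dynamics, depth),
                 epochs_trained = 0L),
            class = "gf_model")
}

delay_depth <- function(rule, dynamics) {
  if (is.null(rule)) return(1L)
  d <- rule$delta_t / dynamics$dt
  if (abs(d - round(d)) > 1e-9)
    stop("`delta_t` must be an integer multiple of the Euler step dt")
  max(1L, as.integer(round(d)))
}

#' @export
print.gf_model <- function(x, ...) {
  cat("<gf_model> ", ncol(x$synapses$pre), " output neurons, ",
      nrow(x$pop), " input neurons (", attr(x$pop, "gain"), " gain)\n",
      "  ", nrow(x$synapses$pre), " afferents per output neuron; rule: ",
      if (is.null(x$rule)) "none" else x$rule$rule,
      "; epochs trained: ", x$epochs_trained, "\n", sep = "")
  invisible(x)
}

# Resample a trajectory onto the Euler grid and run the compiled engine.
run_engine <- function(model, traj, learn, record_at = integer(0),
                       state = model$state) {
  dyn <- model$dynamics
  span <- max(traj$time_ms) - min(traj$time_ms) + 1
  n_steps <- floor(span / dyn$dt)
  tt <- min(traj$time_ms) + (seq_len(n_steps) - 1) * dyn$dt
  inp <- sample_trajectory(traj, tt)
  rule <- model$rule
  use_rule <- learn && !is.null(rule)
  res <- cpp_simulate(
    model$synapses$pre - 1L, model$synapses$weights,
    model$pop$alpha, model$pop$beta, model$pop$kappa,
    attr(model$pop, "sigma"), attr(model$pop, "rho"),
    inp$eye, inp$target,
    dyn$tau_h, dyn$tau_q, dyn$phi, dyn$theta, dyn$pi_pct, dyn$dt,
    if (use_rule) rule$id else 0L,
    if (use_rule) rule$learning_rate else 0,
    if (use_rule && !is.na(rule$beta)) rule$beta else 0,
    if (use_rule) as.integer(round(rule$delta_t / dyn$dt)) else 0L,
    as.integer(record_at),
    state$h, state$q, state$bufq, state$bufv,
    state$buf_head, state$buf_count)
  res
}

#' Train a network along visually guided saccade-and-fixation epochs
#'
#' Each epoch generates a fresh training trajectory (new random fixation
#' sequence), integrates the activation/trace dynamics along it at
#' `dt = tau_h / 10`, and applies the model's learning rule with weight
#' renormalisation at every step.  Dynamic state (activations, traces, delay
#' buffers) carries over between epochs.
#'
#' @param model a [gf_network()] model with a non-`NULL` rule.
#' @param epochs number of training epochs (0 leaves the model untouched).
#' @param protocol list of arguments passed to [training_trajectory()].
#' @param seed integer seed for the saccade draws (each epoch derives its own
#'   sub-seed).
#' @return the trained model.
#' @export
train_network <- function(model, epochs = 20, protocol = list(), seed = 1L) {
  stopifnot(inherits(model, "gf_model"), epochs >= 0)
  if (epochs == 0) return(model)
  if (is.null(model$rule)) stop("model has no learning rule")
  for (ep in seq_len(epochs)) {
    traj <- do.call(training_trajectory,
                    c(protocol, list(seed = seed * 1000L + model$epochs_trained + ep)))
    res <- run_engine(model, traj, learn = TRUE)
    model$synapses$weights <- res$W
    model$state <- list(h = res$h, q = res$q, v = res$v,
                        bufq = res$bufq, bufv = res$bufv,
                        buf_head = res$buf_head, buf_count = res$buf_count,
                        t = model$state$t + max(traj$time_ms))
    model$epochs_trained <- model$epochs_trained + 1L
    if (!all(is.finite(res$W))) stop("non-finite weights during training")
  }
  model
}

#' Test a network and collect per-neuron response matrices
#'
#' Integrates the dynamics along a testing schedule with learning disabled.
#' Dynamic state is reset to rest at the start of each eye-position sweep;
#' within a sweep the target shifts without reset.  The instantaneous firing
#' rates at the end of each dwell are stored, giving each output neuron an
#' E x T response matrix (rows: ascending eye positions, columns: ascending
#' head-centred target locations).
#'
#' @param model a `gf_model`.
#' @param schedule a [testing_schedule()].
#' @return object of class `gf_responses`: a 3-d array
#'   (neuron x eye position x target) plus metadata.
#' @export
test_network <- function(model, schedule = testing_schedule()) {
  stopifnot(inherits(model, "gf_model"),
            identical(attr(schedule, "kind"), "testing"))
  eyes <- attr(schedule, "eye_positions")
  targets <- attr(schedule, "targets")
  dt <- model$dynamics$dt
  record_at <- as.integer(round(attr(schedule, "record_ms") / dt))
  n <- ncol(model$synapses$pre)
  out <- array(NA_real_, c(n, length(eyes), length(targets)))
  depth <- delay_depth(model$rule, model$dynamics)
  for (s in seq_along(eyes)) {
    sw <- schedule[schedule$sweep == s, ]
    res <- run_engine(model, sw, learn = FALSE, record_at = record_at,
                      state = init_state(n, model$dynamics, depth))
    out[, s, ] <- res$records
  }
  ord_e <- order(eyes)
  ord_t <- order(targets)
  structure(list(values = out[, ord_e, ord_t, drop = FALSE],
                 eye_positions = eyes[ord_e], targets = targets[ord_t]),
            class = "gf_responses")
}

#' Extract one neuron's E x T response matrix
#'
#' @param responses a `gf_responses` object from [test_network()].
#' @param neuron output neuron index.
#' @export
response_matrix <- function(responses, neuron) {
  m <- responses$values[neuron, , ]
  dimnames(m) <- list(eye = responses$eye_positions,
                      target = responses$targets)
  m
}

#' @export
print.gf_responses <- function(x, ...) {
  cat("<gf_responses> ", dim(x$values)[1], " neurons x ",
      dim(x$values)[2], " eye positions x ", dim(x$values)[3],
      " targets\n", sep = "")
  invisible(x)
}

#' @describeIn test_network long-format tibble of all recorded test responses.
#' @param x a `gf_responses` object.
#' @param ... unused.
#' @method as_tibble gf_responses
#' @export
as_tibble.gf_responses <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    neuron = rep(seq_len(d[1]), times = d[2] * d[3]),
    eye = rep(rep(x$eye_positions, each = d[1]), times = d[3]),
    target = rep(x$targets, each = d[1] * d[2]),
    rate = as.vector(x$values))
}
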