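#' Synaptic learning-rule specification
#'
#' Defines which synaptic update rule drives training and its
#' hyperparameters.  The derivative of the weight from input neuron j to
#' output neuron i under each rule is:
#'
#' * `standard_trace`: `rate * q_i * v_j` — the postsynaptic factor is the
#'   activity trace, binding inputs that occur close together in time.
#' * `hebbian`: `rate * y_i * v_j` — the trace is replaced by the current
#'   postsynaptic rate (control rule without temporal binding).
#' * `delayed_trace_antihebb`: `rate * (beta * q_i(t - dT) - y_i) * v_j` —
#'   delayed trace term plus an anti-Hebbian term that weakens currently
#'   co-active synapses.
#' * `delayed_rate_antihebb`: `rate * (beta * y_i(t - dT) - y_i) * v_j`.
#' * `current_trace_antihebb`: `rate * (beta * q_i - y_i) * v_j`.
#' * `delayed_trace_only`: `rate * q_i(t - dT) * v_j`.
#'
#' Default `beta` / `delta_t` values are the tuned settings for each rule
#' (50 ms / 2.2 for the delayed trace anti-Hebbian rule, 500 ms / 2.4 for the
#' delayed rate rule, 2.2 for the current-trace rule, 30 ms for the pure
#' delayed-trace rule).
#'
#' @param rule rule name (see Details).
#' @param learning_rate positive learning rate in 1/s: one Euler step of
#'   `dt` ms adds `learning_rate * factor * v_j * dt / 1000` to a weight
#'   before renormalisation.
#' @param beta trace-versus-anti-Hebbian balance (rules with an anti-Hebbian
#'   term only).
#' @param delta_t delay in ms (delayed rules only); must be a nonnegative
#'   multiple of the Euler step.
#' @return an object of class `gf_rule`.
#' @export
learning_rule <- function(rule = c("standard_trace", "hebbian",
                                   "delayed_trace_antihebb",
                                   "delayed_rate_antihebb",
                                   "current_trace_antihebb",
                                   "delayed_trace_only"),
                          learning_rate = 0.05, beta = NULL, delta_t = NULL) {
  rule <- match.arg(rule)
  stopifnot(learning_rate > 0)
  needs_beta <- rule %in% c("delayed_trace_antihebb", "delayed_rate_antihebb",
                            "current_trace_antihebb")
  needs_delay <- rule %in% c("delayed_trace_antihebb", "delayed_rate_antihebb",
                             "delayed_trace_only")
  defaults <- list(delayed_trace_antihebb = list(beta = 2.2, delta_t = 50),
                   delayed_rate_antihebb = list(beta = 2.4, delta_t = 500),
                   current_trace_antihebb = list(beta = 2.2, delta_t = 0),
                   delayed_trace_only = list(beta = NULL, delta_t = 30))
  if (needs_beta && is.null(beta)) beta <- defaults[[rule]]$beta
  if (needs_delay && is.null(delta_t)) delta_t <- defaults[[rule]]$delta_t
  if (needs_beta && (is.null(beta) || beta <= 0))
    stop("rule '", rule, "' requires a positive `beta`")
  if (needs_delay && (is.null(delta_t) || delta_t < 0))
    stop("rule '", rule, "' requires a nonnegative `delta_t`")
  if (!needs_beta) beta <- NA_real_
  if (!needs_delay) delta_t <- 0
  structure(list(rule = rule, learning_rate = learning_rate,
                 beta = beta, delta_t = delta_t,
                 id = match(rule, c("standard_trace", "hebbian",
                                    "delayed_trace_antihebb",
                                    "delayed_rate_antihebb",
                                    "current_trace_antihebb",
                                    "delayed_trace_only"))),
            class = "gf_rule")
}

#' Per-synapse weight derivative (reference implementation)
#'
#' Evaluates the selected rule's weight derivative on the stored synapses
#' only.  This is the plain-R counterpart of the engine's update and is used
#' as its oracle in the tests.
#'
#' @param rule a [learning_rule()].
#' @param q,y current trace and firing-rate vectors (length N).
#' @param q_del,y_del delayed trace and rate vectors (length N).
#' @param v_in input firing rates (length of the input population).
#' @param synapses a [sample_connectivity()] synapse set.
#' @return K x N matrix of derivatives aligned with `synapses$weights`.
#' @export
weight_derivative <- function(rule, q, y, q_del = NULL, y_del = NULL,
                              v_in, synapses) {
  stopifnot(inherits(rule, "gf_rule"))
  a <- rule$learning_rate
  factor <- switch(rule$rule,
    standard_trace = a * q,
    hebbian = a * y,
    delayed_trace_antihebb = a * (rule$beta * q_del - y),
    delayed_rate_antihebb = a * (rule$beta * y_del - y),
    current_trace_antihebb = a * (rule$beta * q - y),
    delayed_trace_only = a * q_del)
  vin_pre <- matrix(v_in[synapses$pre], nrow(synapses$pre), ncol(synapses$pre))
  sweep(vin_pre, 2, factor, `*`)
}

#' Euler weight update with clipping and renormalisation
#'
#' `w <- w + dt/1000 * dw`; negative results are clipped to zero (synapses
#' remain excitatory), then each output neuron's weight vector is rescaled to
#' unit Euclidean norm.
#'
#' @param synapses synapse set.
#' @param derivative K x N derivative matrix.
#' @param dt Euler step (ms).
#' @export
apply_update <- function(synapses, derivative, dt) {
  w <- pmax(synapses$weights + dt / 1000 * derivative, 0)
  nrm <- sqrt(colSums(w^2))
  if (any(nrm == 0))
    stop("a weight vector collapsed to zero after clipping; ",
         "learning rate or beta is pathological")
  synapses$weights <- sweep(w, 2, nrm, `/`)
  synapses
}

#' Sample sparse feedforward connectivity
#'
#' Each output neuron receives `round(fraction * n_inputs)` afferents from
#' its own uniformly sampled (without replacement) subset of the input
#' population.
#'
#' @param n_inputs input population size.
#' @param n_outputs output population size.
#' @param fraction connectivity fraction in (0, 1\].
#' @param seed integer seed.
#' @return list of class `gf_synapses` with `pre` (K x N 1-based indices),
#'   `weights` (K x N, zero until [init_weights()]), and metadata.
#' @export
sample_connectivity <- function(n_inputs, n_outputs, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- round(fraction * n_inputs)
  stopifnot(k >= 1)
  draw <- function() vapply(seq_len(n_outputs),
                            function(i) sample.int(n_inputs, k),
                            integer(k))
  pre <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(pre = matrix(pre, nrow = k), weights = matrix(0, k, n_outputs),
                 n_inputs = n_inputs, fraction = fraction),
            class = "gf_synapses")
}

#' Random initial weights
#'
#' Weights are drawn i.i.d. uniform on \[0, 1\] and each output neuron's
#' weight vector is renormalised to unit Euclidean norm.
#'
#' @param synapses synapse set from [sample_connectivity()].
#' @param seed integer seed.
#' @export
init_weights <- function(synapses, seed = NULL) {
  draw <- function() matrix(runif(length(synapses$weights)),
                            nrow(synapses$weights))
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  synapses$weights <- sweep(w, 2, sqrt(colSums(w^2)), `/`)
  synapses
}
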