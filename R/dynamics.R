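#' Output-layer dynamics parameters
#'
#' Bundles the parameters of the competitive output layer: activation and
#' trace time constants (ms), the slope and threshold of the logistic
#' activation function, the sparseness percentile controlling competition, and
#' the Euler step (defaults to one tenth of `tau_h`).
#'
#' @param tau_h activation time constant (ms).
#' @param tau_q trace time constant (ms).
#' @param phi activation function slope.
#' @param theta activation function threshold.
#' @param pi_pct sparseness percentile in \[0, 100\]; the competition
#'   threshold is the `pi_pct`-th percentile of the current activations.
#' @param dt Euler step (ms).
#' @export
dynamics_params <- function(tau_h = 100, tau_q = 400, phi = 4.5, theta = 0.4,
                            pi_pct = 80, dt = tau_h / 10) {
  stopifnot(tau_h > 0, tau_q > 0, dt > 0, dt < tau_h, dt < tau_q,
            pi_pct >= 0, pi_pct <= 100)
  structure(list(tau_h = tau_h, tau_q = tau_q, phi = phi, theta = theta,
                 pi_pct = pi_pct, dt = dt),
            class = "gf_dynamics")
}

#' Percentile-based competition threshold
#'
#' The competition threshold is the `pi_pct`-th percentile of the activation
#' distribution, using linear interpolation between order statistics (the
#' default `stats::quantile` type-7 convention).
#'
#' @param h activation vector (non-empty).
#' @param pi_pct percentile in \[0, 100\].
#' @export
percentile_threshold <- function(h, pi_pct) {
  if (length(h) == 0) stop("empty activation vector")
  unname(quantile(h, probs = pi_pct / 100, type = 7, names = FALSE))
}

#' Logistic firing-rate function with competition
#'
#' Element-wise `1 / (1 + exp(-2 phi (h - p_pi - theta)))`; the exponent is
#' clamped to +/-700 so rates saturate to 0/1 instead of overflowing.
#'
#' @param h activation vector.
#' @param p_pi competition threshold (scalar).
#' @param phi slope.
#' @param theta threshold.
#' @export
firing_rates <- function(h, p_pi, phi, theta) {
  x <- pmin(700, pmax(-700, -2 * phi * (h - p_pi - theta)))
  1 / (1 + exp(x))
}

#' One Forward-Euler step of the activation equation
#'
#' `h <- h + (dt / tau_h) * (-h + drive)`, the leaky integration of the
#' summed synaptic drive.
#'
#' @param h activation vector.
#' @param drive summed weighted input rates, same length as `h`.
#' @param tau_h time constant (ms).
#' @param dt step (ms), must be `< tau_h`.
#' @export
step_activation <- function(h, drive, tau_h, dt) {
  stopifnot(dt < tau_h)
  h + dt / tau_h * (-h + drive)
}

#' One Forward-Euler step of the trace equation
#'
#' `q <- q + (dt / tau_q) * (-q + v)`: the trace is a low-pass filtered copy
#' of the firing rate, so it stays in \[0, 1\] whenever `v` and `q(0)` do.
#'
#' @param q trace vector.
#' @param v firing-rate vector.
#' @param tau_q time constant (ms).
#' @param dt step (ms), must be `< tau_q`.
#' @export
step_trace <- function(q, v, tau_q, dt) {
  stopifnot(dt < tau_q)
  q + dt / tau_q * (-q + v)
}

#' Delay ring buffer for trace / rate vectors
#'
#' Stores the last `depth` state vectors so learning rules can read values
#' from `delta_t` milliseconds in the past.  Reads before enough history has
#' accumulated return zeros (the prefill convention).
#'
#' @param n vector length.
#' @param depth number of past steps retained (>= 1).
#' @export
delay_buffer <- function(n, depth) {
  stopifnot(n > 0, depth >= 1)
  structure(list(data = matrix(0, n, depth), head = 0L, count = 0L,
                 n = n, depth = depth),
            class = "gf_delay_buffer")
}

#' @rdname delay_buffer
#' @param buf a `delay_buffer`.
#' @param x vector to push.
#' @export
buffer_push <- function(buf, x) {
  stopifnot(length(x) == buf$n)
  buf$data[, buf$head + 1L] <- x
  buf$head <- (buf$head + 1L) %% buf$depth
  buf$count <- min(buf$count + 1L, buf$depth)
  buf
}

#' @rdname delay_buffer
#' @param steps how many pushes ago to read (0 is invalid here: a zero delay
#'   means "use the current vector", which the caller already holds).
#' @export
buffer_read <- function(buf, steps) {
  stopifnot(steps >= 1)
  if (steps > buf$depth) stop("delay exceeds buffer capacity")
  if (steps > buf$count) return(rep(0, buf$n))
  pos <- (buf$head - as.integer(steps)) %% buf$depth
  buf$data[, pos + 1L]
}

#' Initial network state
#'
#' Zero rest state: activations and traces start at zero, rates follow from
#' the activation function, and the delay buffers are prefilled with zeros.
#'
#' @param n number of output neurons.
#' @param params a [dynamics_params()].
#' @param depth delay-buffer depth in steps (>= 1).
#' @export
init_state <- function(n, params, depth = 1L) {
  stopifnot(n > 0)
  h <- rep(0, n)
  p_pi <- percentile_threshold(h, params$pi_pct)
  list(h = h, q = rep(0, n),
       v = firing_rates(h, p_pi, params$phi, params$theta),
       bufq = matrix(0, n, depth), bufv = matrix(0, n, depth),
       buf_head = 0L, buf_count = 0L, t = 0)
}
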