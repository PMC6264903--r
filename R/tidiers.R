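#' Tidy a gain-field network model
#'
#' One row per output neuron: synapse count, weight-vector norm, weight
#' concentration (fraction of total squared weight in the top 5% of
#' synapses), and — for prewired models — the assigned head-centred location.
#'
#' @param x a `gf_model`.
#' @param ... unused.
#' @method tidy gf_model
#' @export
tidy.gf_model <- function(x, ...) {
  w <- x$synapses$weights
  k <- nrow(w)
  top <- max(1L, ceiling(0.05 * k))
  conc <- apply(w, 2, function(col) {
    s <- sort(col^2, decreasing = TRUE)
    sum(s[seq_len(top)]) / sum(s)
  })
  out <- tibble::tibble(neuron = seq_len(ncol(w)), n_synapses = k,
                        weight_norm = sqrt(colSums(w^2)),
                        weight_concentration = conc)
  if (!is.null(x$assigned_locations))
    out$assigned_location <- x$assigned_locations
  out
}

#' Model-level summary of a gain-field network
#'
#' @param x a `gf_model`.
#' @param ... unused.
#' @method glance gf_model
#' @export
glance.gf_model <- function(x, ...) {
  tibble::tibble(
    n_output = ncol(x$synapses$pre),
    n_input = nrow(x$pop),
    gain = attr(x$pop, "gain"),
    connectivity = x$synapses$fraction,
    rule = if (is.null(x$rule)) NA_character_ else x$rule$rule,
    epochs_trained = x$epochs_trained,
    tau_h = x$dynamics$tau_h, tau_q = x$dynamics$tau_q,
    pi_pct = x$dynamics$pi_pct)
}

#' @method tidy gf_run
#' @export
tidy.gf_run <- function(x, ...) x$classification

#' @method glance gf_run
#' @export
glance.gf_run <- function(x, ...) x$stats
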