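#' Mean input-neuron response over the stimulus space
#'
#' Discrete-grid mean of a gain-modulated input neuron's response over the
#' retinal-location x eye-position stimulus space, normalised by the number
#' of grid cells.  Because the response factorises into a retinal and an
#' eye-position component, the mean is the product of the two marginal means.
#'
#' @param alpha,beta,kappa neuron preferences (`kappa = 0` selects the peaked
#'   gain).
#' @param sigma,rho tuning widths (degrees).
#' @param r_grid,e_grid stimulus grids (degrees); default the full
#'   \[-90, 90\] x \[-30, 30\] space at 1-degree resolution.
#' @export
input_mean_response <- function(alpha, beta, kappa = 0, sigma = 6, rho = 6,
                                r_grid = seq(-90, 90), e_grid = seq(-30, 30)) {
  if (length(r_grid) == 0 || length(e_grid) == 0) stop("empty stimulus grid")
  fr <- exp(-(r_grid - alpha)^2 / (2 * sigma^2))
  ge <- if (kappa == 0) exp(-(e_grid - beta)^2 / (2 * rho^2)) else
    1 / (1 + exp(kappa * (e_grid - beta)))
  mean(fr) * mean(ge)
}

#' Input covariance map
#'
#' Covariance (over the discretised stimulus space, normalised by cell
#' count) between a reference input neuron and every neuron of the
#' population, arranged by the probe neurons' preferences.  The response
#' factorisation `resp(r, e) = f(r) g(e)` makes each entry
#' `mean(f f*) mean(g g*) - mean(f) mean(g) mean(f*) mean(g*)`, which is
#' computed from marginal cross-products instead of a full double loop.
#'
#' For sigmoidal and mixed populations the map splits by gain direction
#' (column `kappa_sign`), matching the topographic weight-map conventions.
#'
#' @param pop an [input_population()].
#' @param reference row index of the reference neuron in `pop`.
#' @param r_grid,e_grid stimulus grids (degrees).
#' @return tibble with columns `alpha`, `beta`, `gain_form`, `kappa_sign`,
#'   `covariance`.
#' @export
covariance_map <- function(pop, reference,
                           r_grid = seq(-90, 90), e_grid = seq(-30, 30)) {
  stopifnot(inherits(pop, "gf_population"),
            reference >= 1, reference <= nrow(pop))
  sigma <- attr(pop, "sigma")
  rho <- attr(pop, "rho")
  fmat <- function(alpha) exp(-(outer(r_grid, alpha, "-"))^2 / (2 * sigma^2))
  gvec <- function(beta, kappa) {
    if (kappa == 0) exp(-(e_grid - beta)^2 / (2 * rho^2)) else
      1 / (1 + exp(kappa * (e_grid - beta)))
  }
  f_ref <- fmat(pop$alpha[reference])[, 1]
  g_ref <- gvec(pop$beta[reference], pop$kappa[reference])

  # marginal cross-moments with the reference, per unique preference value
  ua <- unique(pop$alpha)
  fa <- fmat(ua)
  cross_f <- colMeans(fa * f_ref)
  mean_f <- colMeans(fa)
  gkey <- paste(pop$beta, pop$kappa)
  ug <- !duplicated(gkey)
  gtab <- purrr::map2(pop$beta[ug], pop$kappa[ug], gvec)
  cross_g <- vapply(gtab, function(g) mean(g * g_ref), numeric(1))
  mean_g <- vapply(gtab, mean, numeric(1))
  ia <- match(pop$alpha, ua)
  ig <- match(gkey, gkey[ug])

  tibble::tibble(
    alpha = pop$alpha, beta = pop$beta, gain_form = pop$gain_form,
    kappa_sign = sign(pop$kappa),
    covariance = cross_f[ia] * cross_g[ig] -
      (mean_f[ia] * mean_g[ig]) * (mean(f_ref) * mean(g_ref)))
}

#' Topographic weight map of one output neuron
#'
#' Arranges an output neuron's afferent synaptic weights on the input
#' population's preference grid.  Cells without a stored synapse carry `NA`.
#' Sigmoidal (and mixed) populations are split by gain direction.
#'
#' @param model a `gf_model`.
#' @param neuron output neuron index.
#' @return tibble with columns `alpha`, `beta`, `gain_form`, `kappa_sign`,
#'   `weight` (`NA` where unconnected), one row per input neuron.
#' @export
weight_map <- function(model, neuron) {
  stopifnot(inherits(model, "gf_model"))
  pre <- model$synapses$pre[, neuron]
  w <- rep(NA_real_, nrow(model$pop))
  w[pre] <- model$synapses$weights[, neuron]
  tibble::tibble(alpha = model$pop$alpha, beta = model$pop$beta,
                 gain_form = model$pop$gain_form,
                 kappa_sign = sign(model$pop$kappa), weight = w)
}

#' Write a weight map to CSV
#'
#' @param model a `gf_model`.
#' @param neuron output neuron index.
#' @param path output file.
#' @export
write_weight_map <- function(model, neuron, path) {
  utils::write.csv(weight_map(model, neuron), path, row.names = FALSE)
  invisible(path)
}

#' Manually prewired head-centred network
#'
#' Builds a network whose weights are set analytically rather than learned,
#' demonstrating that a head-centred solution exists for sigmoidal gain
#' fields.  Each output neuron is assigned one of the given head-centred
#' locations (balanced assignment).  A sampled synapse is *elevated* when the
#' presynaptic neuron's preferences make it respond maximally near the
#' assigned location h: for positive gain when `h - beta <= alpha <= h + W/2`,
#' for negative gain when `h - W/2 <= alpha <= h - beta` (closed intervals,
#' `W` the size of the eye-position dimension).  All other synapses are
#' *depressed*.  Weight vectors are then renormalised to unit norm.
#'
#' @param pop a sigmoidal [input_population()].
#' @param n_output number of output neurons.
#' @param locations assigned head-centred locations (degrees).
#' @param elevated,depressed the two weight values before renormalisation.
#' @param W size of the eye-position dimension (degrees).
#' @param connectivity connectivity fraction.
#' @param dynamics a [dynamics_params()]; defaults to the prewired-model
#'   settings (slope 4, threshold 0, percentile 90).
#' @param rule optional [learning_rule()] for subsequent plasticity.
#' @param seed integer seed for assignment and connectivity.
#' @return a `gf_model` with an `assigned_locations` field.
#' @export
prewire <- function(pop, n_output = 900,
                    locations = seq(-68, 68, by = 17),
                    elevated = 10, depressed = 1, W = 60,
                    connectivity = 0.0816,
                    dynamics = dynamics_params(phi = 4, theta = 0, pi_pct = 90),
                    rule = NULL, seed = 1L) {
  stopifnot(inherits(pop, "gf_population"))
  if (!all(pop$gain_form == "sigmoid"))
    stop("prewiring requires a pure sigmoidal input population")
  stopifnot(elevated > depressed, depressed > 0)
  syn <- sample_connectivity(nrow(pop), n_output, connectivity, seed = seed)
  assigned <- withr::with_seed(seed + 1L, {
    sample(rep_len(locations, n_output))
  })
  for (i in seq_len(n_output)) {
    idx <- syn$pre[, i]
    syn$weights[, i] <- prewired_weight(
      assigned[i], pop$alpha[idx], pop$beta[idx], pop$kappa[idx],
      elevated, depressed, W)
  }
  syn$weights <- sweep(syn$weights, 2, sqrt(colSums(syn$weights^2)), `/`)
  new_gf_model(pop, syn, dynamics, rule,
               seeds = list(connectivity = seed, assignment = seed + 1L),
               assigned_locations = assigned)
}

#' Prewired weight of a single synapse (vectorised membership rule)
#'
#' @param h assigned head-centred location of the output neuron.
#' @param alpha,beta,kappa presynaptic preferences.
#' @param elevated,depressed weight values.
#' @param W eye-position dimension size (degrees).
#' @export
prewired_weight <- function(h, alpha, beta, kappa,
                            elevated = 10, depressed = 1, W = 60) {
  elev <- ifelse(kappa > 0,
                 h - beta <= alpha & alpha <= h + W / 2,
                 h - W / 2 <= alpha & alpha <= h - beta)
  ifelse(elev, elevated, depressed)
}
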