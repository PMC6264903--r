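#' Build a gain-modulated input population
#'
#' Constructs the population of retinotopic visual input neurons whose
#' responses are gain modulated by eye position.  Each neuron has a preferred
#' retinal location `alpha` and a preferred eye position (or sigmoid inflection
#' point) `beta`.  Peaked neurons carry a Gaussian eye-position gain of width
#' `rho`; sigmoidal neurons carry a monotonic gain of signed slope parameter
#' `kappa` (positive gain direction responds for eye positions left of `beta`).
#' Preferences tile the retinal and eye-position preference ranges in even
#' steps, so a peaked population has `G_r * G_e` neurons and a pure sigmoid
#' population `2 * G_r * G_e` (one neuron of each gain direction per grid
#' point).
#'
#' The retinal preference range defaults to \[-100, 100\] degrees: with
#' 1-degree spacing this gives the canonical 201 x 61 = 12,261 peaked neurons
#' (24,522 sigmoidal), and the 10 degrees beyond the nominal +/-90-degree
#' retinal space only add neurons that are essentially silent during training.
#'
#' @param gain `"peaked"`, `"sigmoid"`, or `"mixed"`.  A mixed population
#'   starts from the peaked grid and converts each neuron independently to
#'   sigmoidal with probability `sigmoid_rate` (gain direction then drawn +/-
#'   with equal probability), keeping the population size fixed.
#' @param sigmoid_rate probability in \[0, 1\] that a grid neuron is sigmoidal
#'   (mixed populations only).
#' @param retinal_range,eye_range preference ranges in degrees.
#' @param spacing preference grid spacing in degrees.
#' @param sigma retinal tuning width (degrees, Gaussian sd), shared.
#' @param rho peaked eye-position tuning width (degrees, Gaussian sd), shared.
#' @param kappa absolute sigmoid gain parameter, shared across the population.
#' @param seed integer seed for the mixed-population draws (ignored for pure
#'   populations, which are deterministic).
#'
#' @return A tibble of class `gf_population` with one row per input neuron and
#'   columns `neuron`, `alpha`, `beta`, `gain_form`, `kappa` (0 for peaked
#'   neurons); `sigma` and `rho` are stored as attributes.
#' @export
#' @examples
#' pop <- input_population("peaked", retinal_range = c(-10, 10),
#'                         eye_range = c(-5, 5))
#' nrow(pop) # 21 * 11
input_population <- function(gain = c("peaked", "sigmoid", "mixed"),
                             sigmoid_rate = 0,
                             retinal_range = c(-100, 100),
                             eye_range = c(-30, 30),
                             spacing = 1,
                             sigma = 6, rho = 6, kappa = 0.0625,
                             seed = NULL) {
  gain <- match.arg(gain)
  stopifnot(sigma > 0, spacing > 0)
  if (gain != "sigmoid" && rho <= 0) stop("`rho` must be positive for peaked neurons")
  if (gain != "peaked" && kappa == 0) stop("`kappa` must be nonzero for sigmoid neurons")
  if (sigmoid_rate < 0 || sigmoid_rate > 1) stop("`sigmoid_rate` must lie in [0, 1]")

  alphas <- seq(retinal_range[1], retinal_range[2], by = spacing)
  betas <- seq(eye_range[1], eye_range[2], by = spacing)
  grid <- tidyr::expand_grid(alpha = alphas, beta = betas)

  pop <- switch(gain,
    peaked = dplyr::mutate(grid, gain_form = "peaked", kappa = 0),
    sigmoid = tidyr::expand_grid(grid, sign = c(1, -1)) |>
      dplyr::transmute(.data$alpha, .data$beta, gain_form = "sigmoid",
                       kappa = .data$sign * abs(kappa)),
    mixed = {
      draw <- function() {
        is_sig <- runif(nrow(grid)) < sigmoid_rate
        sgn <- ifelse(runif(nrow(grid)) < 0.5, 1, -1)
        dplyr::mutate(grid,
          gain_form = ifelse(is_sig, "sigmoid", "peaked"),
          kappa = ifelse(is_sig, sgn * abs(kappa), 0))
      }
      if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    }
  )
  pop <- dplyr::mutate(pop, neuron = dplyr::row_number(), .before = 1)
  structure(tibble::as_tibble(pop),
            sigma = sigma, rho = rho, gain = gain,
            sigmoid_rate = if (gain == "mixed") sigmoid_rate else
              if (gain == "sigmoid") 1 else 0,
            class = c("gf_population", class(pop)))
}

#' Peaked-gain input response
#'
#' Response of a retinotopic neuron with a Gaussian (peaked) eye-position gain
#' field: `exp(-(e - beta)^2 / 2 rho^2) * exp(-(r - alpha)^2 / 2 sigma^2)`.
#' All arguments are in degrees; the result lies in \[0, 1\].
#'
#' @param alpha,beta retinal and eye-position preferences.
#' @param r,e retinal target location and eye position (vectorised).
#' @param sigma,rho tuning widths (degrees).
#' @export
peaked_response <- function(alpha, beta, r, e, sigma = 6, rho = 6) {
  exp(-(e - beta)^2 / (2 * rho^2)) * exp(-(r - alpha)^2 / (2 * sigma^2))
}

#' Sigmoidal-gain input response
#'
#' Response of a retinotopic neuron with a monotonic (sigmoidal) eye-position
#' gain field: `1 / (1 + exp(kappa (e - beta))) * exp(-(r - alpha)^2 / 2 sigma^2)`.
#' For `kappa > 0` the gain exceeds one half for eye positions left of `beta`,
#' for `kappa < 0` right of `beta`.
#'
#' @inheritParams peaked_response
#' @param kappa signed gain parameter (nonzero).
#' @export
sigmoid_response <- function(alpha, beta, kappa, r, e, sigma = 6) {
  1 / (1 + exp(pmin(700, pmax(-700, kappa * (e - beta))))) *
    exp(-(r - alpha)^2 / (2 * sigma^2))
}

#' Evaluate all input-population firing rates at one (r, e)
#'
#' @param pop a [input_population()] tibble.
#' @param r retinal target location (degrees).
#' @param e eye position (degrees).
#' @return numeric vector of rates in \[0, 1\], one per neuron in `pop` order.
#' @export
population_rates <- function(pop, r, e) {
  stopifnot(inherits(pop, "gf_population"), length(r) == 1, length(e) == 1)
  cpp_input_rates(pop$alpha, pop$beta, pop$kappa,
                  attr(pop, "sigma"), attr(pop, "rho"), r, e)
}
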