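#' Training gaze trajectory (one epoch)
#'
#' One training epoch consists of `n_periods` periods, one per head-centred
#' target location (in the listed order).  Within a period the target stays
#' fixed while the eyes perform `n_fixations` fixations of `fixation_ms` each
#' at eye positions drawn uniformly from `eye_range`, joined by
#' `n_fixations - 1` constant-velocity saccades.  The trajectory is sampled
#' at 1 kHz; since fixations are constant and saccades linear in time, linear
#' interpolation off this sampling is exact.
#'
#' @param n_periods number of head-centred target locations per epoch (M).
#' @param n_fixations fixations per period (P).
#' @param locations head-centred target locations (degrees), one per period.
#' @param eye_range eye-position sampling range (degrees).
#' @param fixation_ms fixation duration (ms).
#' @param velocity saccade speed (degrees per second).
#' @param seed integer seed for the eye-position draws.
#' @return tibble of class `gf_trajectory` with columns `time_ms`, `eye`,
#'   `target` and `segment` (`"fixation"` / `"saccade"`), sampled at 1 kHz.
#' @export
training_trajectory <- function(n_periods = 8, n_fixations = 15,
                                locations = seq(-63, 63,
                                                length.out = n_periods),
                                eye_range = c(-24, 24),
                                fixation_ms = 300, velocity = 400,
                                seed = NULL) {
  if (length(locations) == 0) stop("empty location list")
  stopifnot(length(locations) == n_periods, n_fixations >= 1)
  build <- function() {
    pieces <- vector("list", n_periods)
    t0 <- 0
    for (m in seq_len(n_periods)) {
      fix <- runif(n_fixations, eye_range[1], eye_range[2])
      # knots: (time, eye) breakpoints of the piecewise-linear eye trajectory
      kt <- t0
      ke <- fix[1]
      tcur <- t0
      for (p in seq_len(n_fixations)) {
        tcur <- tcur + fixation_ms
        kt <- c(kt, tcur)
        ke <- c(ke, fix[p])
        if (p < n_fixations) {
          dur <- abs(fix[p + 1] - fix[p]) / velocity * 1000
          tcur <- tcur + dur
          kt <- c(kt, tcur)
          ke <- c(ke, fix[p + 1])
        }
      }
      times <- seq(ceiling(t0), floor(tcur), by = 1)
      eye <- approx(kt, ke, xout = times, rule = 2)$y
      # fixation samples are those within [fix start, fix end] of some fixation
      fstart <- kt[seq(1, length(kt) - 1, by = 2)]
      fend <- kt[seq(2, length(kt), by = 2)]
      in_fix <- vapply(times, function(tt) any(tt >= fstart & tt <= fend),
                       logical(1))
      pieces[[m]] <- tibble::tibble(
        time_ms = times, eye = eye, target = locations[m],
        segment = ifelse(in_fix, "fixation", "saccade"))
      t0 <- tcur
    }
    dplyr::bind_rows(pieces)
  }
  traj <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  traj <- dplyr::distinct(traj, .data$time_ms, .keep_all = TRUE)
  structure(traj, class = c("gf_trajectory", class(traj)),
            kind = "training")
}

#' Testing presentation schedule
#'
#' For each eye position (held fixed for a whole sweep) the head-centred
#' target visits `n_targets` evenly spaced locations in ascending order,
#' dwelling `dwell_ms` at each; output rates are recorded at the end of each
#' dwell, giving `E x T` record marks in total.  The schedule is
#' deterministic.
#'
#' @param eye_positions test eye positions (degrees).
#' @param n_targets number of head-centred target locations (T).
#' @param target_range span of target locations (degrees).
#' @param dwell_ms presentation duration per target (ms).
#' @return tibble of class `gf_trajectory` with columns `time_ms`, `eye`,
#'   `target`, `sweep`, sampled at 1 kHz; record times per sweep are stored
#'   in the `record_ms` attribute.
#' @export
testing_schedule <- function(eye_positions = c(-18, -6, 6, 18),
                             n_targets = 80, target_range = c(-79, 79),
                             dwell_ms = 330) {
  targets <- seq(target_range[1], target_range[2], length.out = n_targets)
  sweep_ms <- n_targets * dwell_ms
  one <- function(e, s) {
    times <- seq(0, sweep_ms - 1)
    tibble::tibble(time_ms = times, eye = e,
                   target = targets[pmin(n_targets, times %/% dwell_ms + 1)],
                   sweep = s)
  }
  sched <- dplyr::bind_rows(purrr::imap(eye_positions, one))
  structure(sched, class = c("gf_trajectory", class(sched)),
            kind = "testing",
            eye_positions = eye_positions, targets = targets,
            dwell_ms = dwell_ms,
            record_ms = seq_len(n_targets) * dwell_ms)
}

#' Retinal location of a head-centred target
#'
#' The head-centred location decomposes as h = r + e, so the retinal
#' location is r = h - e.
#'
#' @param target_h head-centred target location (degrees).
#' @param eye eye position (degrees).
#' @export
retinal_location <- function(target_h, eye) target_h - eye

#' Sample a trajectory at arbitrary times
#'
#' Eye position is linearly interpolated between the 1 kHz samples; the
#' head-centred target is piecewise constant (left-continuous).
#'
#' @param traj a `gf_trajectory`.
#' @param t times (ms) within the trajectory span (single sweep for testing
#'   schedules).
#' @return tibble with columns `time_ms`, `eye`, `target`.
#' @export
sample_trajectory <- function(traj, t) {
  tm <- traj$time_ms
  if (any(t < min(tm) | t > max(tm) + 1)) stop("time out of trajectory range")
  tibble::tibble(
    time_ms = t,
    eye = approx(tm, traj$eye, xout = t, rule = 2)$y,
    target = approx(tm, traj$target, xout = t, method = "constant",
                    rule = 2)$y)
}
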