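#' Head-centredness of a response matrix
#'
#' The head-centredness of an output neuron is the mean Pearson correlation
#' between its full head-centred response vectors (rows of the E x T response
#' matrix) over all pairs of eye positions.  Rows with zero variance are
#' dropped from the pair average (their correlation is undefined); if no
#' valid pair remains the metric is undefined (`NA`).
#'
#' @param R an E x T response matrix (rows: ascending eye positions, columns:
#'   ascending head-centred target locations).
#' @return scalar in \[-1, 1\], or `NA` if undefined.
#' @export
head_centredness <- function(R) {
  stopifnot(is.matrix(R), nrow(R) >= 2)
  mean_pairwise_cor(R)
}

mean_pairwise_cor <- function(rows) {
  # pairs involving a zero-variance row are dropped from the average
  ok <- which(apply(rows, 1, function(x) stats::sd(x) > 0))
  if (length(ok) < 2) return(NA_real_)
  cc <- cor(t(rows[ok, , drop = FALSE]))
  mean(cc[upper.tri(cc)])
}

#' Retinal-intersection windows for the eye-centredness analysis
#'
#' During testing, each eye position samples the same head-centred target
#' locations and therefore a shifted range of retinal locations.  The
#' eye-centredness analysis correlates only the portions of each response
#' vector that fall in the intersection of those retinal ranges.  With
#' targets spaced `delta_h` and eye positions spaced `delta_e`
#' (`delta_e` an integer multiple of `delta_h`), the first included column
#' for eye position i is `f_i = (delta_e / delta_h) (i - 1) + 1` and the
#' window length is `V = T - (delta_e / delta_h) (E - 1)`, which makes the
#' windowed subvectors cover exactly the common retinal range: the alignment
#' identities `t[f_i] - e_i = t[1] - e_1` and
#' `t[f_i + V - 1] - e_i = t[T] - e_E` hold for every i.
#'
#' `printed = TRUE` instead uses the shorter window
#' `V = T - (delta_e / delta_h) (E + 1)` that appears in some derivations of
#' this analysis; it violates the alignment identities and is provided only
#' for comparison.
#'
#' @param n_targets number of target locations (T).
#' @param n_eyes number of eye positions (E).
#' @param delta_e eye-position spacing (degrees).
#' @param delta_h target spacing (degrees).
#' @param printed use the shorter printed closed form for V.
#' @return list of class `gf_window` with 1-based `f` (first column per eye
#'   position), `l` (last column), and window length `V`.
#' @export
window_indices <- function(n_targets, n_eyes, delta_e, delta_h,
                           printed = FALSE) {
  if (delta_e == 0) {
    step <- 0
  } else {
    step <- delta_e / delta_h
    if (abs(step - round(step)) > 1e-9 || step < 0)
      stop("`delta_e` must be a nonnegative integer multiple of `delta_h`")
    step <- as.integer(round(step))
  }
  f <- step * (seq_len(n_eyes) - 1L) + 1L
  V <- n_targets - step * (if (printed) n_eyes + 1L else n_eyes - 1L)
  if (V < 2) stop("window length V < 2; test protocol too narrow")
  structure(list(f = f, l = f + V - 1L, V = as.integer(V),
                 step = step, printed = printed),
            class = "gf_window")
}

windowed_rows <- function(R, w) {
  t(vapply(seq_len(nrow(R)),
           function(i) R[i, w$f[i]:(w$f[i] + w$V - 1)],
           numeric(w$V)))
}

#' Eye-centredness of a response matrix
#'
#' Mean Pearson correlation between the retinally aligned windowed subvectors
#' of the response matrix over all pairs of eye positions (see
#' [window_indices()]).  Windowed subvectors with no response (within-window
#' range below `eps`) are excluded from the pair average, as are zero-variance
#' subvectors; with fewer than two usable rows the metric is undefined.
#'
#' @inheritParams head_centredness
#' @param w a [window_indices()] window specification.
#' @param eps no-response threshold on the within-window response range.
#' @export
eye_centredness <- function(R, w, eps = 0.01) {
  stopifnot(is.matrix(R), length(w$f) == nrow(R),
            max(w$f + w$V - 1) <= ncol(R))
  sub <- windowed_rows(R, w)
  rng <- apply(sub, 1, function(x) diff(range(x)))
  sub[rng < eps, ] <- NA_real_
  ok <- which(rng >= eps)
  if (length(ok) < 2) return(NA_real_)
  mean_pairwise_cor(sub[ok, , drop = FALSE])
}

#' Response-presence filter
#'
#' A neuron enters the reference-frame analysis only if it responds within
#' the common retinal range at every eye position: a neuron whose windowed
#' subvector shows no response (range, i.e. maximum deviation from the row
#' minimum, below `eps`) at one or more eye positions is excluded.
#'
#' @inheritParams eye_centredness
#' @return `TRUE` to keep the neuron, `FALSE` to exclude it.
#' @export
presence_filter <- function(R, w, eps = 0.01) {
  sub <- windowed_rows(R, w)
  all(apply(sub, 1, function(x) diff(range(x)) >= eps))
}

#' Reference-frame classification rule
#'
#' A neuron is head-centred if its head-centredness is positive and exceeds
#' its eye-centredness, eye-centred if the reverse strict inequalities hold,
#' and unclassified otherwise (including undefined metrics).
#'
#' @param pi head-centredness.
#' @param omega eye-centredness.
#' @param excluded did the neuron fail the presence criterion?
#' @return one of `"head_centred"`, `"eye_centred"`, `"unclassified"`,
#'   `"excluded"` (vectorised).
#' @export
classify <- function(pi, omega, excluded = FALSE) {
  out <- rep("unclassified", length(pi))
  head <- !is.na(pi) & pi > 0 & (!is.na(omega) & pi > omega)
  eye <- !is.na(omega) & omega > 0 & (!is.na(pi) & omega > pi)
  out[head] <- "head_centred"
  out[eye] <- "eye_centred"
  out[rep_len(excluded, length(pi))] <- "excluded"
  out
}

#' Classify every output neuron of a test run
#'
#' Computes head-centredness, eye-centredness (with the retinal-intersection
#' windowing derived from the schedule geometry), the presence filter and the
#' classification label for every output neuron.
#'
#' @param responses a `gf_responses` object from [test_network()].
#' @param eps no-response threshold.
#' @param printed use the printed (shorter) window length, see
#'   [window_indices()].
#' @return tibble with columns `neuron`, `head_centredness`,
#'   `eye_centredness`, `label`.
#' @export
classify_responses <- function(responses, eps = 0.01, printed = FALSE) {
  eyes <- responses$eye_positions
  targs <- responses$targets
  de <- unique(round(diff(eyes), 9))
  dh <- unique(round(diff(targs), 9))
  if (length(de) != 1 || length(dh) != 1)
    stop("eye positions and targets must be evenly spaced")
  w <- window_indices(length(targs), length(eyes), de, dh, printed = printed)
  n <- dim(responses$values)[1]
  res <- purrr::map(seq_len(n), function(i) {
    R <- responses$values[i, , ]
    keep <- presence_filter(R, w, eps)
    pi_v <- head_centredness(R)
    om_v <- eye_centredness(R, w, eps)
    tibble::tibble(neuron = i, head_centredness = pi_v,
                   eye_centredness = om_v,
                   label = classify(pi_v, om_v, excluded = !keep))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("gf_classification", class(out))
  out
}

#' Population summary statistics of a classification table
#'
#' Three summary statistics over the output population: the head-centredness
#' rate (fraction of head-centred neurons among all output neurons), the mean
#' head-centredness among head-centred neurons (`NA` when none exist), and
#' the mean eye-centredness among all analysed (non-excluded) neurons with a
#' defined eye-centredness.
#'
#' @param classification tibble from [classify_responses()].
#' @param epoch optional epoch index recorded in the output.
#' @return one-row tibble.
#' @export
epoch_statistics <- function(classification, epoch = NA_integer_) {
  head <- classification$label == "head_centred"
  analysed <- classification$label != "excluded" &
    !is.na(classification$eye_centredness)
  tibble::tibble(
    epoch = epoch,
    n_neurons = nrow(classification),
    n_head_centred = sum(head),
    head_centred_rate = mean(head),
    mean_head_centredness = if (any(head))
      mean(classification$head_centredness[head]) else NA_real_,
    mean_eye_centredness = if (any(analysed))
      mean(classification$eye_centredness[analysed]) else NA_real_)
}
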