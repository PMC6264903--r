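test_that("head-centredness handles perfect, anti-, and random correlation", {
  # identical non-constant rows correlate perfectly
  R <- matrix(rep(bump(seq(-39, 39, 2), 5), 4), nrow = 4, byrow = TRUE)
  expect_equal(head_centredness(R), 1)
  # two mean-centred, sign-flipped rows anti-correlate
  row <- sin(seq(0, 6 * pi, length.out = 40))
  expect_equal(head_centredness(rbind(row, -row)), -1)
  # random matrices match the brute-force pairwise oracle
  set.seed(11)
  for (k in 1:20) {
    R <- matrix(runif(4 * 80), 4)
    expect_equal(head_centredness(R), oracle_mean_row_cor(R))
  }
  # zero-variance rows are dropped from the pair average
  R <- rbind(row, row, 0 * row)
  expect_equal(head_centredness(R), 1)
  expect_true(is.na(head_centredness(rbind(0 * row, 0 * row))))
})

test_that("window indices solve the retinal-alignment constraints", {
  w <- window_indices(80, 4, delta_e = 12, delta_h = 2)
  expect_equal(w$f, c(1, 7, 13, 19))
  expect_equal(w$V, 62)
  expect_equal(w$l, c(62, 68, 74, 80))
  # degenerate geometries
  expect_equal(window_indices(50, 1, 12, 2)$V, 50)
  w0 <- window_indices(50, 4, 0, 2)
  expect_equal(w0$f, rep(1, 4))
  expect_equal(w0$V, 50)
  expect_error(window_indices(80, 4, delta_e = 5, delta_h = 2), "multiple")
  expect_error(window_indices(4, 4, delta_e = 2, delta_h = 2), "V < 2")
  # the printed shorter form is available but misaligned
  wp <- window_indices(80, 4, 12, 2, printed = TRUE)
  expect_equal(wp$V, 80 - 6 * 5)
})

test_that("alignment identities hold for every generated window spec", {
  set.seed(12)
  for (k in 1:30) {
    E <- sample(2:6, 1)
    step <- sample(0:6, 1)
    dh <- sample(c(1, 2, 3), 1)
    Tn <- step * (E - 1) + sample(5:40, 1)
    w <- window_indices(Tn, E, delta_e = step * dh, delta_h = dh)
    t1 <- 0; targets <- t1 + dh * (seq_len(Tn) - 1)
    eyes <- 3 + step * dh * (seq_len(E) - 1)
    # first and last windowed column hit the common retinal range ends
    expect_equal(targets[w$f] - eyes, rep(targets[1] - eyes[1], E))
    expect_equal(targets[w$f + w$V - 1] - eyes,
                 rep(targets[Tn] - eyes[E], E))
  }
})

test_that("eye-centredness is exact on constructed reference frames", {
  eyes <- c(-18, -6, 6, 18)
  targets <- seq(-39, 39, by = 2)
  w <- window_indices(length(targets), length(eyes), 12, 2)
  # perfectly eye-centred: rate depends only on the retinal location t - e
  R_eye <- synthetic_responses(function(e, t) bump(t - e, 4), eyes, targets)
  expect_equal(eye_centredness(R_eye, w), 1)
  # perfectly head-centred: rate depends only on t
  R_head <- synthetic_responses(function(e, t) bump(t, -10), eyes, targets)
  expect_equal(head_centredness(R_head), 1)
  # its eye-centredness equals the mean pairwise correlation of shifted copies
  f <- bump(targets, -10)
  shift <- w$step
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    a <- f[(w$f[i]):(w$f[i] + w$V - 1)]
    b <- f[(w$f[j]):(w$f[j] + w$V - 1)]
    vals <- c(vals, cor(a, b))
  }
  expect_equal(eye_centredness(R_head, w), mean(vals))
  expect_lt(eye_centredness(R_head, w), 1)
  # random matrices match the windowed brute-force oracle
  set.seed(13)
  for (k in 1:20) {
    R <- matrix(runif(4 * 40), 4)
    expect_equal(eye_centredness(R, w), oracle_windowed_cor(R, w$f, w$V))
  }
})

test_that("metrics are invariant to common affine rescaling", {
  set.seed(14)
  R <- matrix(runif(4 * 40), 4)
  w <- window_indices(40, 4, 12, 2)
  expect_equal(head_centredness(2.5 * R + 0.3), head_centredness(R))
  expect_equal(eye_centredness(0.6 * R + 0.1, w), eye_centredness(R, w),
               tolerance = 1e-10)
})

test_that("with two eye positions and full windows the metrics coincide", {
  set.seed(15)
  R <- matrix(runif(2 * 30), 2)
  w <- window_indices(30, 2, 0, 2)
  expect_equal(head_centredness(R), eye_centredness(R, w))
})

test_that("classification applies the strict comparison rule", {
  expect_equal(classify(0.5, 0.2), "head_centred")
  expect_equal(classify(0.2, 0.5), "eye_centred")
  expect_equal(classify(0.4, 0.4), "unclassified")
  expect_equal(classify(-0.1, -0.1), "unclassified")
  expect_equal(classify(-0.2, -0.5), "unclassified")  # head > eye but not > 0
  expect_equal(classify(NA, 0.5), "unclassified")
  expect_equal(classify(0.5, 0.2, excluded = TRUE), "excluded")
  # vectorised, exactly one label each
  labs <- classify(c(0.5, 0.2, 0.4), c(0.2, 0.5, 0.4))
  expect_equal(labs, c("head_centred", "eye_centred", "unclassified"))
})

test_that("presence filter requires a response at every eye position", {
  eyes <- c(-18, -6, 6, 18)
  targets <- seq(-39, 39, by = 2)
  w <- window_indices(length(targets), length(eyes), 12, 2)
  # constant matrix: no response anywhere
  expect_false(presence_filter(matrix(0.3, 4, 40), w))
  # responsive at all eye positions: kept
  R <- synthetic_responses(function(e, t) bump(t, 0), eyes, targets)
  expect_true(presence_filter(R, w))
  # silent at one eye position: excluded
  R[2, ] <- 0.01
  expect_false(presence_filter(R, w))
  # strictly positive but flat floor: kept only with eps = 0
  Rf <- matrix(0.2, 4, 40) + 1e-6 * matrix(runif(160), 4)
  expect_false(presence_filter(Rf, w, eps = 0.01))
  expect_true(presence_filter(Rf, w, eps = 0))
})

test_that("epoch statistics match a hand computation on synthetic tables", {
  cls <- tibble::tibble(
    neuron = 1:5,
    head_centredness = c(0.8, 0.6, -0.1, 0.2, NA),
    eye_centredness = c(0.1, 0.2, 0.4, 0.9, NA),
    label = c("head_centred", "head_centred", "unclassified",
              "eye_centred", "excluded"))
  st <- epoch_statistics(cls, epoch = 3L)
  expect_equal(st$epoch, 3L)
  expect_equal(st$n_head_centred, 2)
  expect_equal(st$head_centred_rate, 2 / 5)
  expect_equal(st$mean_head_centredness, 0.7)
  expect_equal(st$mean_eye_centredness, mean(c(0.1, 0.2, 0.4, 0.9)))
  # no head-centred neurons: rate 0, mean undefined
  cls2 <- dplyr::mutate(cls, label = "unclassified")
  st2 <- epoch_statistics(cls2)
  expect_equal(st2$head_centred_rate, 0)
  expect_true(is.na(st2$mean_head_centredness))
  # degenerate all-head-centred, perfectly head-centred population
  cls3 <- tibble::tibble(neuron = 1:3, head_centredness = 1,
                         eye_centredness = 0, label = "head_centred")
  st3 <- epoch_statistics(cls3)
  expect_equal(st3$head_centred_rate, 1)
  expect_equal(st3$mean_head_centredness, 1)
})

test_that("classify_responses reproduces per-neuron hand classification", {
  eyes <- c(-18, -6, 6, 18)
  targets <- seq(-39, 39, by = 2)
  funs <- list(
    function(e, t) bump(t, 0),             # head-centred
    function(e, t) bump(t - e, 10),        # eye-centred
    function(e, t) 0 * t,                  # silent -> excluded
    function(e, t) bump(t, 20) * bump(e, 0, 20),  # gain-modulated head
    function(e, t) 0.5 + 0 * t)            # flat floor -> excluded
  vals <- array(0, c(5, 4, 40))
  for (i in 1:5) vals[i, , ] <- synthetic_responses(funs[[i]], eyes, targets)
  resp <- structure(list(values = vals, eye_positions = eyes,
                         targets = targets), class = "gf_responses")
  cls <- classify_responses(resp)
  expect_equal(cls$label,
               c("head_centred", "eye_centred", "excluded",
                 "head_centred", "excluded"))
  w <- window_indices(40, 4, 12, 2)
  for (i in c(1, 2, 4)) {
    expect_equal(cls$head_centredness[i],
                 oracle_mean_row_cor(vals[i, , ]))
    expect_equal(cls$eye_centredness[i],
                 oracle_windowed_cor(vals[i, , ], w$f, w$V))
  }
})
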