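test_that("input mean response matches a brute-force grid loop", {
  r_grid <- seq(-20, 20, by = 2)
  e_grid <- seq(-10, 10, by = 2)
  loop_mean <- function(alpha, beta, kappa) {
    tot <- 0
    for (r in r_grid) for (e in e_grid) {
      tot <- tot + if (kappa == 0) peaked_response(alpha, beta, r, e)
      else sigmoid_response(alpha, beta, kappa, r, e)
    }
    tot / (length(r_grid) * length(e_grid))
  }
  for (spec in list(c(0, 0, 0), c(5, -4, 0), c(-10, 2, 0.0625),
                    c(8, 8, -0.0625))) {
    m <- input_mean_response(spec[1], spec[2], spec[3],
                             r_grid = r_grid, e_grid = e_grid)
    expect_equal(m, loop_mean(spec[1], spec[2], spec[3]), tolerance = 1e-12)
    expect_gte(m, 0); expect_lte(m, 1)
  }
  expect_error(input_mean_response(0, 0, r_grid = numeric(0)), "empty")
})

test_that("covariance map matches brute-force summation on a coarse grid", {
  pop <- tiny_pop("peaked")
  r_grid <- seq(-25, 25, by = 5)
  e_grid <- seq(-10, 10, by = 5)
  ref <- which(pop$alpha == 0 & pop$beta == 0)
  cm <- covariance_map(pop, ref, r_grid = r_grid, e_grid = e_grid)
  resp <- function(j) {
    outer(r_grid, e_grid, function(r, e)
      peaked_response(pop$alpha[j], pop$beta[j], r, e))
  }
  Rref <- resp(ref)
  for (j in sample(seq_len(nrow(pop)), 10)) {
    Rj <- resp(j)
    expect_equal(cm$covariance[j],
                 mean(Rref * Rj) - mean(Rref) * mean(Rj), tolerance = 1e-12)
  }
  # self entry is the reference variance, the map maximum at the preferences
  self_cov <- cm$covariance[ref]
  expect_equal(self_cov, mean(Rref^2) - mean(Rref)^2)
  expect_gt(self_cov, 0)
  expect_equal(which.max(cm$covariance), ref)
  # decays away from the reference in both preference dimensions
  along_a <- cm$covariance[cm$beta == 0][order(abs(unique(cm$alpha)))]
  expect_true(all(diff(along_a) <= 1e-12))
})

test_that("covariance is symmetric between reference and probe", {
  pop <- tiny_pop("sigmoid")
  r_grid <- seq(-25, 25, by = 5)
  e_grid <- seq(-10, 10, by = 5)
  set.seed(16)
  pairs <- matrix(sample(nrow(pop), 10), ncol = 2)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ca <- covariance_map(pop, a, r_grid = r_grid, e_grid = e_grid)
    cb <- covariance_map(pop, b, r_grid = r_grid, e_grid = e_grid)
    expect_equal(ca$covariance[b], cb$covariance[a], tolerance = 1e-12)
  }
})

test_that("sigmoid covariance is elongated along the eye-preference axis", {
  pop <- input_population("sigmoid", retinal_range = c(-60, 60),
                          eye_range = c(-30, 30), spacing = 3)
  ref <- which(pop$alpha == 0 & pop$beta == 0 & pop$kappa > 0)
  cm <- covariance_map(pop, ref, r_grid = seq(-60, 60, by = 3),
                       e_grid = seq(-30, 30, by = 3))
  pos <- dplyr::filter(cm, .data$kappa_sign > 0)
  half <- max(pos$covariance) / 2
  span_beta <- diff(range(pos$beta[pos$alpha == 0 & pos$covariance > half]))
  span_alpha <- diff(range(pos$alpha[pos$beta == 0 & pos$covariance > half]))
  expect_gt(span_beta, span_alpha)
})

test_that("weight maps round-trip the stored synapses", {
  pop <- tiny_pop("sigmoid")
  m <- gf_network(pop, n_output = 5, connectivity = 0.3, seed = 17)
  wm <- weight_map(m, 3)
  expect_equal(nrow(wm), nrow(pop))
  pre <- m$synapses$pre[, 3]
  expect_equal(wm$weight[pre], m$synapses$weights[, 3])
  expect_true(all(is.na(wm$weight[-pre])))
  # uniform weights show up constant at connected cells
  m$synapses$weights[, 3] <- 0.5
  expect_equal(unique(stats::na.omit(weight_map(m, 3)$weight)), 0.5)
})

test_that("prewiring applies the interval membership rule exactly", {
  # hand-checked memberships at h = 0, W = 60
  expect_equal(prewired_weight(0, alpha = 15, beta = 0, kappa = 0.0625), 10)
  expect_equal(prewired_weight(0, alpha = 40, beta = 0, kappa = 0.0625), 1)
  expect_equal(prewired_weight(0, alpha = -15, beta = 0, kappa = -0.0625), 10)
  expect_equal(prewired_weight(0, alpha = -40, beta = 0, kappa = -0.0625), 1)
  # closed interval boundaries
  expect_equal(prewired_weight(0, 30, 0, 0.0625), 10)
  expect_equal(prewired_weight(0, -30, 30, 0.0625), 10)
  # brute-force check against the interval definition on a random sample
  pop <- tiny_pop("sigmoid")
  m <- prewire(pop, n_output = 6, connectivity = 0.5,
               locations = rep(c(-17, 0, 17), 2), seed = 18)
  for (i in 1:6) {
    h <- m$assigned_locations[i]
    idx <- m$synapses$pre[, i]
    a <- pop$alpha[idx]; b <- pop$beta[idx]; k <- pop$kappa[idx]
    expected_elev <- ifelse(k > 0, h - b <= a & a <= h + 30,
                            h - 30 <= a & a <= h - b)
    w <- m$synapses$weights[, i]
    # after renormalisation the two weight levels keep their 10:1 ratio
    expect_equal(length(unique(round(w, 12))), 2)
    expect_equal(max(w) / min(w), 10, tolerance = 1e-9)
    expect_equal(w == max(w), expected_elev)
    expect_equal(sum(w^2), 1, tolerance = 1e-9)
  }
  # balanced assignment over the listed locations
  expect_equal(as.integer(table(m$assigned_locations)), rep(2L, 3))
  expect_error(prewire(tiny_pop("peaked"), 5), "sigmoid")
})

test_that("Hebbian-trained weights align with the input covariance structure", {
  pop <- input_population("peaked", retinal_range = c(-40, 40),
                          eye_range = c(-20, 20), spacing = 4)
  dyn <- dynamics_params(tau_h = 30, phi = 4.5, theta = 0.4, pi_pct = 80)
  m <- gf_network(pop, n_output = 30, connectivity = 0.5, dynamics = dyn,
                  rule = learning_rule("hebbian", 0.05), seed = 19)
  for (rep in 1:5)
    m <- train_patterns(m, pattern_trajectory(n_patterns = 200,
                                              duration_ms = 100,
                                              seed = 20 + rep))
  r_grid <- seq(-40, 40, by = 4)
  e_grid <- seq(-20, 20, by = 4)
  cors <- vapply(1:30, function(i) {
    wm <- weight_map(m, i)
    top <- which.max(wm$weight)
    cm <- covariance_map(pop, top, r_grid = r_grid, e_grid = e_grid)
    keep <- !is.na(wm$weight)
    stats::cor(wm$weight[keep], cm$covariance[keep])
  }, numeric(1))
  # weight vectors resemble the covariance maps around their strongest input
  expect_gt(mean(cors > 0), 0.8)
  expect_gt(mean(cors), 0.05)
})
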