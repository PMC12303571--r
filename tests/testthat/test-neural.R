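# Binary-neuron mapping, PCA embeddings and the synthetic recording
# fixture.

test_that("neuron sampling respects the firing probability", {
  units <- matrix(c(1, 1, 0, 0, 1, 0), 2, 3)
  full <- sample_neural_activity(units, N = 5, p = 1, seed = 1)
  expect_equal(full$activity[1:5, 1], rep(1L, 5))   # unit 1 active at t1
  expect_true(all(full$activity[6:10, 2:3] == 0))   # unit 2 silent there
  none <- sample_neural_activity(units, N = 5, p = 0, seed = 1)
  expect_true(all(none$activity == 0))
  expect_error(sample_neural_activity(units, N = 5, p = 1.4), "domain")
  # expected fraction active = p x fraction of active units, within
  # binomial bounds, across seeds
  big <- matrix(1, 40, 6); big[1:20, 4:6] <- 0
  for (sd in 1:5) {
    na <- sample_neural_activity(big, N = 20, p = 0.5, seed = sd)
    frac <- na$fraction_active
    se <- sqrt(0.5 * 0.5 / (40 * 20))
    expect_lt(abs(frac[1] - 0.5), 4 * se)
    expect_lt(abs(frac[5] - 0.25), 4 * se)
  }
})

test_that("PCA embedding has the exact eigenstructure on designed inputs", {
  # rank-1 input: one component explains everything
  act <- outer(runif(30, 0.5, 2), c(sin(1:50)^2))
  emb <- pca_embedding(act, 2)
  expect_gt(emb$explained_variance[1], 1 - 1e-10)
  # orthogonal two-block design: two components recover the blocks
  blocks <- rbind(matrix(rep(c(1, 0), each = 25), 10, 50, byrow = TRUE),
                  matrix(rep(c(0, 1), each = 25), 10, 50, byrow = TRUE))
  emb2 <- pca_embedding(blocks, 3)
  expect_gt(emb2$explained_variance[1], 1 - 1e-10)
  # constant matrix is degenerate
  expect_error(pca_embedding(matrix(1, 5, 8)), "degenerate")
  # invariance (up to sign) under neuron permutation
  set.seed(2)
  noisy <- act + matrix(rnorm(30 * 50, sd = 0.1), 30, 50)
  e1 <- pca_embedding(noisy, 2)
  e2 <- pca_embedding(noisy[sample(30), ], 2)
  for (k in 1:2)
    expect_lt(min(sum(abs(e1$scores[, k] - e2$scores[, k])),
                  sum(abs(e1$scores[, k] + e2$scores[, k]))), 1e-8)
})

test_that("the synthetic fixture is reproducible and habituates", {
  f1 <- generate_fixture(seed = 7)
  f2 <- generate_fixture(seed = 7)
  expect_identical(f1$activity, f2$activity)
  p1 <- file.path(tempdir(), "fx1.csv"); p2 <- file.path(tempdir(), "fx2.csv")
  write_activity_csv(f1$activity, f1$times, p1)
  write_activity_csv(f2$activity, f2$times, p2)
  expect_identical(readLines(p1), readLines(p2))
  rt <- read_activity_csv(p1)
  expect_equal(rt$activity, f1$activity, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(rt$times, as.numeric(f1$times))
  # no habituation: every stimulus evokes the same response
  flat <- generate_fixture(noise = 0, habituation_rate = Inf, seed = 1)
  per <- diff(flat$stimulus_onsets)[1]
  w1 <- flat$activity[, flat$stimulus_onsets[2] + 0:(per - 1)]
  w2 <- flat$activity[, flat$stimulus_onsets[5] + 0:(per - 1)]
  expect_equal(w1, w2)
})

test_that("the fixture's second component encodes the habituation axis", {
  fx <- generate_fixture(noise = 0)
  emb <- pca_embedding(fx$activity, 2)
  m2 <- vapply(seq_along(fx$stimulus_onsets), function(k) {
    win <- fx$times >= fx$stimulus_onsets[k] &
           fx$times <= fx$stimulus_onsets[k] + fx$stim_len
    mean(emb$scores[win, 2])
  }, 0.0)
  expect_gte(abs(cor(seq_along(m2), m2, method = "spearman")), 0.8)
})

test_that("model-driven units habituate; feedback off keeps them active", {
  p <- model_params(beta = 4.5, sigma = 0.15)
  pr <- looming_protocol(n_stimuli = 8)
  one <- unit_activations_from_model(p, pr, n_units = 1, seed = 1)
  expect_equal(nrow(one$active), 1)
  ua <- unit_activations_from_model(p, pr, n_units = 80, seed = 1)
  expect_gt(ua$activation_fraction[1], mean(ua$activation_fraction[7:8]))
  # with the feedback disabled the activation fraction stays flat
  p0 <- model_params(beta = 4.5, sigma = 0.15, kappa = 0)
  ua0 <- unit_activations_from_model(p0, pr, n_units = 80, seed = 1)
  expect_lt(diff(range(ua0$activation_fraction)), 0.11)
})
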