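# Conditional stationary laws, the spectral storage propagator and the
# Chapman-Kolmogorov iteration.

test_that("conditional readout law is the renormalized Poisson", {
  p <- fig_params()
  for (r in 0:1) {
    q <- readout_stationary_given_r(p, r)
    mu <- if (r == 0) p$U_mean_passive else p$U_mean_active
    expect_close(sum(q), 1, 1e-12)
    expect_lt(abs(sum(q * (0:(length(q) - 1))) - mu) / mu, 1e-6)
    m2 <- sum(q * (0:(length(q) - 1))^2)
    m1 <- sum(q * (0:(length(q) - 1)))
    expect_lt(abs((m2 - m1^2) / m1 - 1), 1e-5)    # Poisson: var = mean
  }
  # term-by-term recurrence oracle p(u+1) = p(u) mu/(u+1), normalized
  mu <- 30; U_max <- 250
  po <- numeric(U_max + 1); po[1] <- 1
  for (u in 0:(U_max - 1)) po[u + 2] <- po[u + 1] * mu / (u + 1)
  po <- po / sum(po)
  q <- readout_stationary_given_r(p, 0, U_max)
  expect_close(q[31], po[31], 1e-12)
  expect_error(readout_stationary_given_r(p, 0, U_max = 40), "grid-too-small")
})

test_that("receptor activation matches the two-state null-space oracle", {
  p <- model_params(beta = 3, sigma = 0.6, DeltaE = 0)
  expect_equal(receptor_stationary_given_sh(p, 0, 0), 0.5)
  p2 <- fig_params()
  # oracle: null space of the 2x2 generator assembled from the raw rates
  r <- receptor_rates(p2, s = 20, h = 10)
  k_on <- r[["sense_PA"]] + r[["int_PA"]]
  k_off <- r[["sense_AP"]] + r[["int_AP"]]
  G <- matrix(c(-k_on, k_on, k_off, -k_off), 2, 2)
  ns <- eigen(G)$vectors[, which.min(abs(eigen(G)$values))]
  ns <- ns / sum(ns)
  pa <- receptor_stationary_given_sh(p2, 20, 10)
  expect_close(pa, ns[2], 1e-12)
  expect_close(pa, 1 / (1 + exp(3)), 1e-4)
  # strong signals saturate the sensing pathway without overflow
  expect_gt(receptor_stationary_given_sh(p2, 20, 1e4), 1 - 1e-10)
})

test_that("truncated spectral propagator matches the dense matrix exponential", {
  skip_if_not_installed("Matrix")
  p <- small_params()
  # dense oracle: exp(G dt) on the full 6-state chain, no truncation
  G <- matrix(0, 6, 6)
  b <- 3 * exp(-p$beta * p$sigma) * p$Gamma_S0
  for (s in 0:5) {
    if (s < 5) G[s + 2, s + 1] <- b
    if (s > 0) G[s, s + 1] <- s * p$Gamma_S0
  }
  diag(G) <- -colSums(G)
  for (dt in c(0.01, 0.04)) {
    dense <- as.matrix(Matrix::expm(G * dt))
    tol <- if (dt == 0.01) 5e-5 else 1e-3   # ~(rate dt)^(n+1) truncation
    for (s0 in c(0, 2, 5)) {
      tv <- 0.5 * sum(abs(storage_propagator(p, 3, s0, dt) -
                          dense[, s0 + 1]))
      expect_lt(tv, tol)
    }
  }
  expect_equal(storage_propagator(p, 3, 2, 0), c(0, 0, 1, 0, 0, 0))
  expect_error(storage_propagator(p, 3, 2, dt = 1), "step-too-large")
})

test_that("compiled propagator bands agree with the reference implementation", {
  p <- fig_params()
  dt <- max_step(p)
  U_max <- 40   # a band subset is enough to compare implementations
  bands <- habinfo:::.propagator_bands(p, dt, U_max)
  for (u0 in c(0, 17, 40)) for (s0 in c(0, 1, 15, 29, 30)) {
    ref <- storage_propagator(p, u0, s0, dt)
    got <- vapply(-2:2, function(k) {
      if (s0 + k < 0 || s0 + k > p$N_S) return(0)
      bands[[as.character(k)]][u0 + 1, s0 + 1]
    }, 0.0)
    ref_band <- vapply(-2:2, function(k) {
      if (s0 + k < 0 || s0 + k > p$N_S) return(0)
      ref[s0 + k + 1]
    }, 0.0)
    expect_close(got, ref_band, 1e-12)
  }
})

test_that("one Chapman-Kolmogorov step conserves probability", {
  p <- fig_params()
  st <- stationary_solve(p, 0.1)
  stepped <- step_joint(p, st, mean_signal_next = 10, dt = max_step(p))
  expect_close(sum(stepped$values), 1, 1e-12)
  expect_lt(attr(stepped, "norm_defect"), 1e-8)
  expect_true(all(stepped$values >= 0))
})

test_that("stationary state is a fixed point and init-independent", {
  p <- reduced_params()
  st <- stationary_solve(p, 1.5)
  expect_lt(attr(st, "residual"), 1e-9)
  expect_close(sum(st$values), 1, 1e-10)
  expect_lte(joint_means(st)[["S"]], p$N_S)
  # long step_joint iteration from two very different starts converges to
  # the same law
  dt <- max_step(p)
  mk <- function(vals) joint_distribution(vals / sum(vals))
  u0 <- matrix(0, nrow(st$values), ncol(st$values)); u0[] <- 1
  d0 <- matrix(0, nrow(st$values), ncol(st$values)); d0[1, 1] <- 1
  outs <- lapply(list(mk(u0), mk(d0)), function(pp) {
    for (i in seq_len(4000)) pp <- step_joint(p, pp, 1.5, dt)
    pp
  })
  tv12 <- 0.5 * sum(abs(outs[[1]]$values - outs[[2]]$values))
  tv1s <- 0.5 * sum(abs(outs[[1]]$values - st$values))
  expect_lt(tv12, 1e-8)
  expect_lt(tv1s, 1e-6)
})

test_that("a flat protocol leaves the stationary state unchanged", {
  p <- reduced_params()
  pr <- signal_protocol(H_min = 0.5, H_max = 0.5, T_s = 10, Delta_T = 10,
                        n_stimuli = 1, t_start = 10)
  # a step that divides the protocol segments exactly keeps the
  # iteration at the very fixed point the initial condition solved
  tr <- evolve(p, pr, t_end = 40, dt = 0.08)
  expect_lt(diff(range(tr$U_mean)) / mean(tr$U_mean), 1e-6)
  expect_lt(diff(range(tr$S_mean)) / mean(tr$S_mean), 1e-6)
})

test_that("responses decrease and storage grows under repeated stimulation", {
  p <- fig_params()
  pr <- short_protocol(10)
  tr <- evolve(p, pr, t_end = protocol_end(pr))
  resp <- peak_responses(tr, pr)
  expect_true(all(diff(resp) < 0))
  ends <- stimulus_onsets(pr) + pr$T_s
  s_at <- tr$S_mean[match(ends, tr$times)]
  expect_true(all(diff(s_at) > 0))
})

test_that("without feedback the response does not habituate", {
  p0 <- model_params(beta = 3, sigma = 0.6, kappa = 0)
  pr <- short_protocol(6)
  tr <- evolve(p0, pr, t_end = protocol_end(pr))
  resp <- peak_responses(tr, pr)
  expect_lt(diff(range(resp)) / mean(resp), 1e-8)
})

test_that("halving the step size leaves the solution unchanged", {
  p <- reduced_params()
  pr <- reduced_protocol(2)
  dt <- max_step(p, pr) / 4
  tt <- seq(5, 60, by = 5)
  tr1 <- evolve(p, pr, t_end = 60, dt = dt, sample_times = tt)
  tr2 <- evolve(p, pr, t_end = 60, dt = dt / 2, sample_times = tt)
  u1 <- vapply(tt, function(x) joint_means(get_snapshot(tr1, x))[["U"]], 0)
  u2 <- vapply(tt, function(x) joint_means(get_snapshot(tr2, x))[["U"]], 0)
  expect_lt(max(abs(u1 - u2) / u1), 1e-4)
})

test_that("readout and storage means collapse onto a mean-field curve", {
  # the normalized readout depression is a single monotone function of
  # the occupied storage fraction, across times and protocols
  p <- fig_params()
  xs <- c(); ys <- c()
  for (DT in c(100, 300)) {
    pr <- signal_protocol(Delta_T = DT, n_stimuli = 12)
    ends <- stimulus_onsets(pr) + pr$T_s
    tr <- evolve(p, pr, t_end = protocol_end(pr), sample_times = ends)
    for (s in tr$snapshots) {
      m <- joint_means(s)
      xs <- c(xs, m[["S"]] / p$N_S)
      ys <- c(ys, (m[["U"]] - p$U_mean_active) /
                    (p$U_mean_active - p$U_mean_passive))
    }
  }
  fit <- stats::lowess(xs, ys, f = 1 / 3)
  resid <- ys[order(xs)] - fit$y
  expect_lt(max(abs(resid)) / diff(range(ys)), 0.05)
  # strong monotone association along the curve
  expect_lt(cor(xs, ys, method = "spearman"), -0.995)
})
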