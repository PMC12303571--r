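# Exact stochastic simulation: reproducibility, stationary moments and the
# event-count flux estimator.

test_that("ensembles are bit-reproducible and seed-sensitive", {
  p <- reduced_params()
  pr <- reduced_protocol(2)
  tt <- c(10, 30, 50)
  a <- gillespie_simulate(p, pr, 50, seed = 42, tt, burn_in = 10)
  b <- gillespie_simulate(p, pr, 50, seed = 42, tt, burn_in = 10)
  expect_identical(a$u, b$u)
  expect_identical(a$s, b$s)
  d <- gillespie_simulate(p, pr, 50, seed = 43, tt, burn_in = 10)
  expect_false(identical(a$u, d$u))
})

test_that("states stay inside their domains", {
  p <- reduced_params()
  ens <- gillespie_simulate(p, reduced_protocol(2), 200, seed = 3,
                            seq(5, 75, by = 10), burn_in = 20)
  expect_true(all(ens$r %in% c(0, 1)))
  expect_true(all(ens$s >= 0 & ens$s <= p$N_S))
  expect_true(all(ens$u >= 0))
  expect_true(all(ens$h >= 0))
})

test_that("stationary readout mean matches the conditional-mixture value", {
  p <- reduced_params()
  H <- 0.8
  pr <- signal_protocol(H_min = H, H_max = H, T_s = 10, Delta_T = 10,
                        n_stimuli = 1, t_start = 1e5)  # constant background
  ens <- gillespie_simulate(p, pr, 3000, seed = 9, c(50, 60, 70),
                            burn_in = 8 * p$tau_S)
  mom <- ensemble_moments(ens)
  st <- stationary_solve(p, H)
  for (j in 1:3) {
    z_u <- (mom$mean["u", j] - joint_means(st)[["U"]]) / mom$se["u", j]
    z_s <- (mom$mean["s", j] - joint_means(st)[["S"]]) / mom$se["s", j]
    expect_lt(abs(z_u), 4)
    expect_lt(abs(z_s), 4)
  }
})

test_that("ensemble moments reproduce closed-form Poisson statistics", {
  # machinery check on synthetic draws with a known law
  set.seed(1)
  fake <- structure(list(u = matrix(rpois(2000, 30), 1000, 2),
                         r = matrix(0, 1000, 2), s = matrix(0, 1000, 2),
                         h = matrix(0, 1000, 2),
                         n_traj = 1000L, sample_times = c(1, 2),
                         params = reduced_params()),
                    class = "habinfo_ensemble")
  mom <- ensemble_moments(fake)
  expect_lt(abs(mom$mean["u", 1] - 30), 3 * mom$se["u", 1])
  expect_equal(mom$se["u", 1], sd(fake$u[, 1]) / sqrt(1000))
  mom2 <- ensemble_moments(fake, joint_at = 1)
  expect_close(sum(mom2$p_US), 1, 1e-12)
})

test_that("standard errors shrink like one over root n", {
  p <- reduced_params()
  pr <- reduced_protocol(2)
  e1 <- gillespie_simulate(p, pr, 400, seed = 5, c(40, 60), burn_in = 40)
  e2 <- gillespie_simulate(p, pr, 1600, seed = 5, c(40, 60), burn_in = 40)
  r <- ensemble_moments(e1)$se["u", ] / ensemble_moments(e2)$se["u", ]
  expect_true(all(r > 1.4 & r < 2.9))   # ideal ratio 2
})

test_that("event-count flux estimate agrees with the solver flux", {
  p <- reduced_params()
  pr <- reduced_protocol(3)
  # window inside the first stimulus, where the storage is being charged
  ens <- gillespie_simulate(p, pr, 4000, seed = 11, c(21, 29),
                            burn_in = 5 * p$tau_S)
  est <- flux_from_counts(ens, 1, 2)
  tr <- evolve(p, pr, t_end = 30, sample_times = 25)
  J <- internal_flux(p, get_snapshot(tr, 25))
  expect_lt(abs(est[["J_int"]] - J), 4 * est[["se"]])
  expect_gt(J, 0)   # charging: positive internal flux
})

test_that("diverging signal exponents raise an overflow error", {
  p <- reduced_params(beta = 2)
  pr <- signal_protocol(H_min = 600, H_max = 600, T_s = 10, Delta_T = 0,
                        n_stimuli = 1, t_start = 5)
  expect_error(
    gillespie_simulate(p, pr, 5, seed = 1, c(1, 2), burn_in = 1),
    "overflow")
})
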