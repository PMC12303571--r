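# Parameter derivation and the elementary transition rates.

test_that("energy derivation inverts the stationary readout means", {
  p <- fig_params()
  expect_equal(p$kappa, 25)                       # 10 / ((2/3) * 0.6)
  expect_equal(p$V, -log(30) / 3)
  expect_equal(p$c, log(5) / 3)
  # round-trip identities hold to machine precision
  expect_equal(exp(-p$beta * p$V), p$U_mean_passive)
  expect_equal(exp(-p$beta * (p$V - p$c)), p$U_mean_active)
  # idempotence
  p2 <- derive_energies(p)
  expect_identical(unclass(p2), unclass(p))
})

test_that("invalid parameter combinations are rejected", {
  expect_error(model_params(beta = 3, sigma = 0), "kappa")
  expect_error(model_params(beta = -1, sigma = 0.5), "beta")
  expect_error(model_params(beta = 3, sigma = 0.5, U_mean_passive = -2),
               "positive")
  expect_error(model_params(beta = 3, sigma = 0.5, U_mean_passive = 150,
                            U_mean_active = 30), "exceed")
  expect_error(model_params(beta = 3, sigma = 0.5, tau_U = 10), "timescales")
  expect_error(model_params(beta = 3, sigma = 0.5, tau_H = 10),
               "comparable")
  expect_error(model_params(beta = 3, sigma = 0.5, alpha = 1.2), "alpha")
  # sigma = 0 is allowed with an explicit inhibition strength
  p0 <- model_params(beta = 3, sigma = 0, kappa = 0)
  expect_equal(p0$kappa, 0)
})

test_that("receptor rates follow the Arrhenius form on both pathways", {
  p <- model_params(beta = 3, sigma = 0.6, DeltaE = 0)
  r <- receptor_rates(p, s = 0, h = 0)
  expect_equal(unname(r), rep(1 / p$tau_R, 4))    # all exponents vanish
  p2 <- fig_params()
  r2 <- receptor_rates(p2, s = 0, h = 10)
  expect_equal(r2[["sense_PA"]], exp(27) / p2$tau_R)
  expect_equal(r2[["sense_AP"]], 1 / p2$tau_R)
  expect_error(receptor_rates(p2, s = -1, h = 1), "domain")
  expect_error(receptor_rates(p2, s = 0, h = -1), "domain")
})

test_that("reference-signal drive cancels the feedback at the balance point", {
  # at h = H_ref and s = alpha N_S the two driving exponents cancel: the
  # log-ratio of sensing activation to feedback deactivation reduces to
  # the barrier and pathway-ratio terms only
  p <- fig_params()
  r <- receptor_rates(p, s = p$alpha * p$N_S, h = p$H_ref)
  expect_equal(log(r[["sense_PA"]] / r[["int_AP"]]),
               -p$beta * p$DeltaE + log(p$g))
})

test_that("readout and storage rates implement the controlled birth-death", {
  p <- fig_params()
  expect_equal(readout_rates(p, 0, 7)[["birth"]],
               p$U_mean_passive * p$Gamma_U0)
  expect_equal(readout_rates(p, 1, 7)[["birth"]],
               p$U_mean_active * p$Gamma_U0)
  expect_equal(readout_rates(p, 1, 0)[["death"]], 0)
  p_flat <- p; p_flat$c <- 0
  expect_equal(readout_rates(p_flat, 0, 3)[["birth"]],
               readout_rates(p_flat, 1, 3)[["birth"]])
  expect_error(readout_rates(p, 2, 1), "domain")

  expect_equal(storage_rates(p, u = 0, s = 3)[["birth"]], 0)
  p10 <- model_params(beta = 2, sigma = 0.5, tau_S = 2000, tau_H = 2000)
  expect_equal(storage_rates(p10, u = 10, s = 3)[["birth"]],
               10 * exp(-1) * p10$Gamma_S0)
  expect_equal(storage_rates(p, u = 10, s = p$N_S)[["birth"]], 0)
  expect_equal(storage_rates(p, u = 10, s = 4)[["death"]],
               4 * p$Gamma_S0)
  expect_error(storage_rates(p, u = 1, s = p$N_S + 1), "domain")
})

test_that("rates are finite and positive across the (beta, sigma) domain", {
  for (b in c(0.5, 2, 5)) for (sg in c(0.05, 0.6, 1.5)) {
    p <- model_params(beta = b, sigma = sg)
    for (s in c(0, 10, 30)) for (h in c(0, 1, 30)) {
      r <- receptor_rates(p, s, h)
      expect_true(all(r > 0) && all(is.finite(r)))
    }
    expect_true(all(is.finite(readout_rates(p, 1, 500))))
    expect_true(all(is.finite(storage_rates(p, 500, 15))))
  }
})

test_that("storage enters the receptor only through the occupied fraction", {
  p1 <- model_params(beta = 2.5, sigma = 0.7, N_S = 30)
  p2 <- model_params(beta = 2.5, sigma = 0.7, N_S = 60)
  for (s in c(0, 7, 30))
    expect_identical(receptor_rates(p1, s, 3), receptor_rates(p2, 2 * s, 3))
})

test_that("square-wave protocol exposes onsets and windows", {
  pr <- signal_protocol(H_min = 0.1, H_max = 10, T_s = 100, Delta_T = 100,
                        n_stimuli = 3, t_start = 100)
  expect_equal(stimulus_onsets(pr), c(100, 300, 500))
  expect_equal(protocol_end(pr), 600)
  expect_equal(mean_signal(pr, c(0, 100, 199.9, 200, 350, 599.9, 600)),
               c(0.1, 10, 10, 0.1, 10, 10, 0.1))
  expect_error(signal_protocol(H_min = 0), "H_min")
  expect_error(signal_protocol(H_min = 2, H_max = 1))
})

test_that("adaptive inhibition retunes kappa to the stimulus strength", {
  p <- fig_params()
  pr <- signal_protocol(H_max = 20, adaptive_kappa = TRUE)
  p2 <- protocol_params(p, pr)
  expect_equal(p2$kappa, 20 / (p$alpha * p$sigma))
  pr_fix <- signal_protocol(H_max = 20)
  expect_equal(protocol_params(p, pr_fix)$kappa, p$kappa)
})
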