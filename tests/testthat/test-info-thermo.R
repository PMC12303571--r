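# Mutual information, feedback information and the thermodynamic
# observables, cross-checked against independent integration and
# summation routes.

test_that("storage carries no information on the signal under the TSS laws", {
  p <- fig_params()
  st <- stationary_solve(p, 10)
  expect_lt(abs(mutual_information_SH(p, storage_marginal(st), 1 / 10)),
            1e-10)
  # also on a transient state and at another parameter point
  pr <- short_protocol(5)
  tr <- evolve(p, pr, t_end = protocol_end(pr),
               sample_times = stimulus_onsets(pr)[3] + pr$T_s)
  pS <- storage_marginal(tr$snapshots[[1]])
  expect_lt(abs(mutual_information_SH(p, pS, 1 / 10)), 1e-10)
  p2 <- model_params(beta = 2, sigma = 1)
  st2 <- stationary_solve(p2, 5)
  expect_lt(abs(mutual_information_SH(p2, storage_marginal(st2), 1 / 5)),
            1e-10)
})

test_that("readout-signal information matches a dense Riemann-sum oracle", {
  p <- fig_params()
  st <- stationary_solve(p, 10)
  pS <- storage_marginal(st)
  I <- mutual_information_UH(p, pS, lambda_t = 1 / 10)
  # oracle: trapezoidal integration over an explicit h grid
  hg <- seq(1e-4, 150, length.out = 50000)
  w <- stats::dexp(hg, rate = 1 / 10)
  U_max <- u_grid_max(p)
  p0 <- readout_stationary_given_r(p, 0, U_max)
  p1 <- readout_stationary_given_r(p, 1, U_max)
  a_h <- vapply(hg, function(h)
    sum(pS * receptor_stationary_given_sh(p, 0:p$N_S, h)), 0.0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  condH <- vapply(a_h, function(a) ent((1 - a) * p0 + a * p1), 0.0)
  trap <- function(y) sum(diff(hg) * (head(y * w, -1) + tail(y * w, -1)) / 2)
  abar <- trap(a_h)
  I_oracle <- ent((1 - abar) * p0 + abar * p1) - trap(condH)
  expect_lt(abs(I - I_oracle), 1e-4)
  # quadrature refinement leaves the value unchanged
  I2 <- mutual_information_UH(p, pS, 1 / 10, quad_n = 1024)
  expect_lt(abs(I - I2), 1e-6)
  # degenerate signal law: no information
  expect_lt(mutual_information_UH(p, pS, lambda_t = 1e6), 1e-6)
})

test_that("information equals the readout entropy change (dual route)", {
  # the entropy-difference route must agree with the direct
  # Kullback-Leibler route sum_h w(h) KL(p(u|h) || p(u))
  p <- fig_params()
  st <- stationary_solve(p, 10)
  pS <- storage_marginal(st)
  I <- mutual_information_UH(p, pS, 1 / 10)
  quad <- signal_quadrature(1 / 10, 512)
  U_max <- u_grid_max(p)
  p0 <- readout_stationary_given_r(p, 0, U_max)
  p1 <- readout_stationary_given_r(p, 1, U_max)
  a_h <- vapply(quad$h, function(h)
    sum(pS * receptor_stationary_given_sh(p, 0:p$N_S, h)), 0.0)
  abar <- sum(quad$w * a_h)
  pU <- (1 - abar) * p0 + abar * p1
  kl <- vapply(a_h, function(a) {
    q <- (1 - a) * p0 + a * p1
    ok <- q > 0
    sum(q[ok] * log(q[ok] / pU[ok]))
  }, 0.0)
  expect_lt(abs(I - sum(quad$w * kl)), 1e-10)
})

test_that("feedback information is nonnegative and vanishes without feedback", {
  p <- fig_params()
  pr <- short_protocol(6)
  ends <- stimulus_onsets(pr) + pr$T_s
  tr <- evolve(p, pr, t_end = protocol_end(pr), sample_times = ends)
  for (s in tr$snapshots) {
    fi <- feedback_information(p, s, 1 / 10)
    expect_gte(fi[["DeltaI_f"]], -1e-10)
    expect_gte(fi[["I_USH"]], fi[["I_UH"]] - 1e-10)
  }
  p0 <- model_params(beta = 3, sigma = 0.6, kappa = 0)
  st0 <- stationary_solve(p0, 10)
  fi0 <- feedback_information(p0, st0, 1 / 10)
  expect_lt(abs(fi0[["DeltaI_f"]]), 1e-10)
})

test_that("joint information matches a brute-force sum on the reduced model", {
  p <- reduced_params()
  st <- stationary_solve(p, 1.5)
  fi <- feedback_information(p, st, 1 / 1.5)
  # brute force: assemble the full (u, s, h-node) joint table and apply
  # the generic mutual-information formula
  quad <- signal_quadrature(1 / 1.5, 64)
  U_max <- max(st$grid_u)
  p0 <- readout_stationary_given_r(p, 0, U_max)
  p1 <- readout_stationary_given_r(p, 1, U_max)
  pS <- storage_marginal(st)
  I_bf <- 0
  p_us_marg <- matrix(0, U_max + 1, p$N_S + 1)
  tabs <- vector("list", length(quad$h))
  for (j in seq_along(quad$h)) {
    a <- receptor_stationary_given_sh(p, 0:p$N_S, quad$h[j])
    tab <- (outer(p0, 1 - a) + outer(p1, a)) * rep(pS, each = U_max + 1)
    tabs[[j]] <- tab
    p_us_marg <- p_us_marg + quad$w[j] * tab
  }
  for (j in seq_along(quad$h)) {
    ok <- tabs[[j]] > 0
    I_bf <- I_bf +
      quad$w[j] * sum(tabs[[j]][ok] * log(tabs[[j]][ok] / p_us_marg[ok]))
  }
  expect_lt(abs(fi[["I_USH"]] - I_bf), 1e-10)
})

test_that("internal flux follows the storage currents", {
  p <- fig_params()
  U_max <- u_grid_max(p)
  # all mass at (u = 5, s = 0): single production term
  vals <- matrix(0, U_max + 1, p$N_S + 1)
  vals[6, 1] <- 1
  j <- internal_flux(p, joint_distribution(vals))
  expect_equal(j, p$sigma * 5 * exp(-p$beta * p$sigma) * p$Gamma_S0)
  # exact 1-D birth-death stationarity: zero net current across every
  # storage edge (detailed balance of the effective chain)
  U_max <- u_grid_max(p)
  phi <- habinfo:::.phi_bar(p, 1 / 10, U_max)
  b_bar <- exp(-p$beta * p$sigma) * p$Gamma_S0 *
    colSums(phi * (0:U_max))
  q <- numeric(p$N_S + 1); q[1] <- 1
  for (s in 1:p$N_S)
    q[s + 1] <- q[s] * b_bar[s] / (s * p$Gamma_S0)
  q <- q / sum(q)
  p_eq <- joint_distribution(phi * rep(q, each = U_max + 1) /
                             sum(phi * rep(q, each = U_max + 1)))
  expect_lt(abs(internal_flux(p, p_eq)),
            1e-8 * internal_flux(p, p_eq, mode = "production"))
  # the solver's discrete-time fixed point carries only an O(dt) residual
  st <- stationary_solve(p, 10)
  expect_lt(abs(internal_flux(p, st)),
            5e-3 * internal_flux(p, st, mode = "production"))
  expect_gt(internal_flux(p, st, mode = "production"), 0)
  # degenerate empty readout: no production at all
  vals0 <- matrix(0, U_max + 1, p$N_S + 1)
  vals0[1, 3] <- 1
  expect_equal(internal_flux(p, joint_distribution(vals0),
                             mode = "production"), 0)
})

test_that("receptor dissipation equals the log cycle affinity", {
  p <- fig_params()
  expect_equal(receptor_dissipation(p, p$H_ref, p$alpha * p$N_S),
               2 * p$beta * p$H_ref)
  expect_equal(receptor_dissipation(p, 0, 0), 0)
  # oracle: direct rate-ratio evaluation around the two-pathway cycle
  for (h in c(0.5, 10)) for (s in c(3, 20)) {
    r <- receptor_rates(p, s, h)
    aff <- log((r[["sense_PA"]] * r[["int_AP"]]) /
               (r[["sense_AP"]] * r[["int_PA"]]))
    expect_close(receptor_dissipation(p, h, s), aff, 1e-9)
  }
  expect_error(receptor_dissipation(p, -1, 0), "domain")
})

test_that("habituation raises information and lowers the energy flux", {
  p <- fig_params()
  ig <- info_gain(p, signal_protocol(n_stimuli = 30))
  expect_gt(ig$DeltaI_UH, 0)
  expect_lt(ig$DeltaJ_int, 0)
  expect_lt(ig$DeltaU, 0)
  # identical first/habituated states give null gains by construction
  v <- ig$at_first
  expect_equal(v[["I_UH"]] - v[["I_UH"]], 0)
})
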