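# Shared fixtures: the standard habituating parameter point, a small model
# on which dense linear-algebra oracles are affordable, and short
# protocols.

fig_params <- function(...) model_params(beta = 3, sigma = 0.6, ...)

# Small chain with order-one storage rates, for propagator oracles.
small_params <- function(beta = 2, sigma = 0.5) {
  model_params(beta = beta, sigma = sigma, N_S = 5,
               U_mean_passive = 5, U_mean_active = 20, H_ref = 1.5,
               tau_U = 1e-3, tau_R = 1e-2, tau_S = 1, tau_H = 1)
}

short_protocol <- function(n_stimuli = 8, ...) {
  signal_protocol(n_stimuli = n_stimuli, ...)
}

reduced_protocol <- function(n_stimuli = 3) {
  signal_protocol(H_min = 0.1, H_max = 1.5, T_s = 10, Delta_T = 10,
                  n_stimuli = n_stimuli, t_start = 20)
}

expect_close <- function(x, y, tol = 1e-10) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max deviation %.3g (tol %.3g)",
                              max(abs(x - y)), tol))
}
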