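#' Model parameters for the receptor-readout-storage habituation model
#'
#' Builds and validates the full parameter set of the minimal sensing model:
#' a two-state receptor driven by an external signal along a sensing pathway
#' and inhibited along an internal pathway by a slow storage population that
#' is produced catalytically by the readout population.  Energies are
#' measured in units of the signal energy, times in arbitrary units with the
#' storage relaxation time \code{tau_S} as the slow scale.
#'
#' Rather than specifying the readout production energy \code{V} and the
#' receptor-driven reduction \code{c} directly, the target readout means with
#' a passive (\code{U_mean_passive = exp(-beta V)}) and an active
#' (\code{U_mean_active = exp(-beta (V - c))}) receptor are supplied and the
#' energies are derived; see \code{\link{derive_energies}}.  The inhibition
#' strength defaults to \code{kappa = H_ref / (alpha * sigma)} so that the
#' sensing drive of a reference signal \code{H_ref} is balanced by the
#' feedback of a fraction \code{alpha} of the storage capacity.
#'
#' @param beta inverse temperature (1/energy), > 0.
#' @param sigma energetic cost of one storage molecule (energy), >= 0.  A
#'   value of 0 is only admissible together with an explicit \code{kappa}.
#' @param DeltaE receptor energy barrier (energy).
#' @param N_S storage capacity (maximum number of storage molecules).
#' @param U_mean_passive,U_mean_active target mean readout with a passive /
#'   active receptor.  The active mean must exceed the passive one (an active
#'   receptor pumps the readout population up).
#' @param g ratio between the timescales of the sensing and internal
#'   receptor pathways.
#' @param alpha inhibiting storage fraction in (0, 1].
#' @param H_ref reference signal strength (energy).
#' @param tau_U,tau_R,tau_S,tau_H timescales of readout, receptor, storage
#'   and environment.  The ordering \code{tau_U < tau_R < tau_S} is enforced;
#'   \code{tau_S} and \code{tau_H} must agree within a factor
#'   \code{tau_ratio_max}.
#' @param kappa inhibition strength.  \code{NULL} (default) derives it from
#'   Eq. \code{kappa = H_ref/(alpha sigma)}; supply a number (e.g. 0) to
#'   override, which is the only way to use \code{sigma = 0}.
#' @param tau_ratio_max largest admissible \code{tau_S/tau_H} ratio (and its
#'   inverse).  The storage and environment evolve on comparable scales; the
#'   reduced validation model relaxes this to let the signal decorrelate
#'   faster than the storage.
#'
#' @return An object of class \code{"habinfo_params"}: a list with all
#'   supplied fields plus the derived \code{V}, \code{c}, \code{kappa} and
#'   \code{Gamma_S0 = 1/tau_S}, \code{Gamma_U0 = 1/tau_U}.
#' @seealso \code{\link{derive_energies}}, \code{\link{signal_protocol}},
#'   \code{\link{reduced_params}}
#' @export
#' @examples
#' p <- model_params(beta = 3, sigma = 0.6)
#' p$kappa                    # 10 / ((2/3) * 0.6) = 25
#' exp(-p$beta * p$V)         # recovers U_mean_passive
model_params <- function(beta, sigma,
                         DeltaE = 1,
                         N_S = 30,
                         U_mean_passive = 30,
                         U_mean_active = 150,
                         g = 1,
                         alpha = 2 / 3,
                         H_ref = 10,
                         tau_U = 0.01,
                         tau_R = 1,
                         tau_S = 2000,
                         tau_H = 2000,
                         kappa = NULL,
                         tau_ratio_max = 1.5) {
  p <- list(beta = beta, sigma = sigma, DeltaE = DeltaE, N_S = N_S,
            U_mean_passive = U_mean_passive, U_mean_active = U_mean_active,
            g = g, alpha = alpha, H_ref = H_ref,
            tau_U = tau_U, tau_R = tau_R, tau_S = tau_S, tau_H = tau_H,
            kappa = kappa, tau_ratio_max = tau_ratio_max)
  class(p) <- "habinfo_params"
  derive_energies(p)
}

#' Derive the energetic parameters V, c and kappa
#'
#' Inverts the stationary readout means to the production energies,
#' \code{V = -log(U_mean_passive)/beta} and
#' \code{c = log(U_mean_active/U_mean_passive)/beta}, and derives the
#' inhibition strength \code{kappa = H_ref/(alpha sigma)} unless an explicit
#' override was supplied.  Idempotent.
#'
#' @param params a \code{habinfo_params} object (possibly with energies
#'   already filled in).
#' @return the validated parameter object with \code{V}, \code{c},
#'   \code{kappa}, \code{Gamma_S0} and \code{Gamma_U0} filled in.
#' @export
derive_energies <- function(params) {
  p <- unclass(params)
  stopifnot(is.numeric(p$beta), is.numeric(p$sigma))
  if (!is.finite(p$beta) || p$beta <= 0)
    stop("invalid parameter: beta must be > 0")
  if (!is.finite(p$sigma) || p$sigma < 0)
    stop("invalid parameter: sigma must be >= 0")
  if (p$N_S < 1 || p$N_S != round(p$N_S))
    stop("invalid parameter: N_S must be a positive integer")
  if (p$g <= 0) stop("invalid parameter: g must be > 0")
  if (p$alpha <= 0 || p$alpha > 1)
    stop("invalid parameter: alpha must be in (0, 1]")
  if (p$H_ref <= 0) stop("invalid parameter: H_ref must be > 0")
  if (p$U_mean_passive <= 0 || p$U_mean_active <= 0)
    stop("invalid parameter: readout means must be positive")
  if (p$U_mean_active <= p$U_mean_passive)
    stop("invalid parameter: U_mean_active must exceed U_mean_passive ",
         "(an active receptor pumps the readout up)")
  if (!(p$tau_U < p$tau_R && p$tau_R < p$tau_S))
    stop("invalid parameter: timescales must satisfy tau_U < tau_R < tau_S")
  ratio <- p$tau_S / p$tau_H
  if (ratio > p$tau_ratio_max || ratio < 1 / p$tau_ratio_max)
    stop("invalid parameter: tau_S and tau_H must be comparable ",
         "(tau_S/tau_H = ", signif(ratio, 3), ", allowed factor ",
         p$tau_ratio_max, ")")

  p$V <- -log(p$U_mean_passive) / p$beta
  p$c <- log(p$U_mean_active / p$U_mean_passive) / p$beta
  if (is.null(p$kappa)) {
    if (p$sigma == 0)
      stop("invalid parameter: sigma = 0 makes kappa singular; ",
           "supply kappa explicitly")
    p$kappa <- p$H_ref / (p$alpha * p$sigma)
  }
  p$Gamma_S0 <- 1 / p$tau_S
  p$Gamma_U0 <- 1 / p$tau_U
  class(p) <- "habinfo_params"
  p
}

#' @export
print.habinfo_params <- function(x, ...) {
  cat("Habituation model parameters\n")
  cat(sprintf("  beta = %g, sigma = %g, DeltaE = %g, N_S = %d\n",
              x$beta, x$sigma, x$DeltaE, x$N_S))
  cat(sprintf("  readout means (passive/active) = %g / %g  (V = %.4f, c = %.4f)\n",
              x$U_mean_passive, x$U_mean_active, x$V, x$c))
  cat(sprintf("  kappa = %g (alpha = %g, H_ref = %g), g = %g\n",
              x$kappa, x$alpha, x$H_ref, x$g))
  cat(sprintf("  timescales: tau_U = %g, tau_R = %g, tau_S = %g, tau_H = %g\n",
              x$tau_U, x$tau_R, x$tau_S, x$tau_H))
  invisible(x)
}

#' Reduced model parameterization for cross-validation
#'
#' A scaled-down parameter set (storage capacity 5, readout means 5/20,
#' moderate inverse temperature and signal strength) on which the exact
#' Gillespie simulation is computationally light and well posed, used to
#' cross-validate the timescale-separation solver.  The signal redraw time is
#' set ten times shorter than the storage relaxation so that the stochastic
#' signal decorrelates on the scale on which the deterministic solver assumes
#' it uncorrelated.
#'
#' @param beta,sigma free energetic parameters of the reduced model.
#' @param ... overrides passed to \code{\link{model_params}}.
#' @return a \code{habinfo_params} object.
#' @export
reduced_params <- function(beta = 0.5, sigma = 0.5, ...) {
  args <- list(beta = beta, sigma = sigma,
               DeltaE = 0.5, N_S = 5,
               U_mean_passive = 5, U_mean_active = 20,
               H_ref = 1.5,
               tau_U = 0.02, tau_R = 0.1, tau_S = 20, tau_H = 1,
               tau_ratio_max = 25)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_params, args)
}

#' Square-wave stimulation protocol
#'
#' Describes the schedule of the exponentially distributed external signal:
#' its mean switches between a background value \code{H_min} and a stimulus
#' value \code{H_max}.  Stimulus k occupies the window
#' \code{[t_k, t_k + T_s)} with onsets
#' \code{t_k = t_start + (k-1) (T_s + Delta_T)}.
#'
#' @param H_min background mean signal (> 0).
#' @param H_max stimulus mean signal (>= H_min).
#' @param T_s stimulus duration.
#' @param Delta_T inter-stimulus pause.
#' @param n_stimuli number of stimuli.
#' @param t_start onset time of the first stimulus.
#' @param adaptive_kappa if \code{TRUE}, runs built from this protocol tune
#'   the inhibition strength to the stimulus, \code{kappa = H_max/(alpha
#'   sigma)}, instead of the reference-signal value.
#' @return an object of class \code{"habinfo_protocol"}.
#' @export
#' @examples
#' pr <- signal_protocol()              # the standard hallmark protocol
#' mean_signal(pr, c(50, 150, 250))     # background, stimulus, background
signal_protocol <- function(H_min = 0.1, H_max = 10,
                            T_s = 100, Delta_T = 100,
                            n_stimuli = 40, t_start = 100,
                            adaptive_kappa = FALSE) {
  stopifnot(H_min > 0, H_max >= H_min, T_s > 0, Delta_T >= 0, n_stimuli >= 1)
  pr <- list(H_min = H_min, H_max = H_max, T_s = T_s, Delta_T = Delta_T,
             n_stimuli = as.integer(n_stimuli), t_start = t_start,
             adaptive_kappa = isTRUE(adaptive_kappa))
  class(pr) <- "habinfo_protocol"
  pr
}

#' @export
print.habinfo_protocol <- function(x, ...) {
  cat(sprintf(
    "Square-wave protocol: H %g -> %g, T_s = %g, Delta_T = %g, %d stimuli from t = %g%s\n",
    x$H_min, x$H_max, x$T_s, x$Delta_T, x$n_stimuli, x$t_start,
    if (x$adaptive_kappa) " (adaptive kappa)" else ""))
  invisible(x)
}

#' Stimulus onset times of a protocol
#' @param protocol a \code{habinfo_protocol}.
#' @return numeric vector of onset times, one per stimulus.
#' @export
stimulus_onsets <- function(protocol) {
  protocol$t_start +
    (seq_len(protocol$n_stimuli) - 1) * (protocol$T_s + protocol$Delta_T)
}

#' End of the last stimulus window
#' @param protocol a \code{habinfo_protocol}.
#' @return time at which the final stimulus window closes.
#' @export
protocol_end <- function(protocol) {
  max(stimulus_onsets(protocol)) + protocol$T_s
}

#' Mean signal at given times
#'
#' The signal law at any time is exponential with density
#' \code{lambda(t) exp(-lambda(t) h)}, \code{lambda(t) = 1/mean_signal(t)};
#' this returns the mean, \code{H_max} inside stimulus windows
#' \code{[t_k, t_k + T_s)} and \code{H_min} elsewhere.
#'
#' @param protocol a \code{habinfo_protocol}.
#' @param t numeric vector of times.
#' @return numeric vector of mean signal values.
#' @export
mean_signal <- function(protocol, t) {
  period <- protocol$T_s + protocol$Delta_T
  rel <- t - protocol$t_start
  k <- floor(rel / period)
  inside <- k >= 0 & k < protocol$n_stimuli & (rel - k * period) < protocol$T_s
  ifelse(inside, protocol$H_max, protocol$H_min)
}

#' Effective parameters for a run of a protocol
#'
#' Applies the protocol's adaptive-inhibition flag: with
#' \code{adaptive_kappa}, the inhibition strength is retuned to the stimulus
#' strength, \code{kappa = H_max/(alpha sigma)}.
#'
#' @param params a \code{habinfo_params}.
#' @param protocol a \code{habinfo_protocol}.
#' @return a \code{habinfo_params} object to be used for the run.
#' @export
protocol_params <- function(params, protocol) {
  if (isTRUE(protocol$adaptive_kappa)) {
    params$kappa <- protocol$H_max / (params$alpha * params$sigma)
  }
  params
}
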