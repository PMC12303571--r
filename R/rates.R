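# Transition rates of the model.  All rates follow an effective Arrhenius
# form; the receptor has two pathways (sensing, driven by the signal h, and
# internal, inhibited by the storage level s), the readout and storage are
# controlled birth-death processes.

#' Receptor transition rates
#'
#' The four passive/active transition rates of the two-state receptor at
#' storage level \code{s} and signal value \code{h}:
#' sensing pathway \code{P->A = exp(beta (h - DeltaE))/tau_R},
#' \code{A->P = 1/tau_R}; internal pathway
#' \code{P->A = exp(-beta DeltaE)/(g tau_R)},
#' \code{A->P = exp(beta kappa sigma s / N_S)/(g tau_R)}.
#' The storage enters only through the occupied fraction \code{s/N_S}.
#'
#' @param params a \code{habinfo_params}.
#' @param s storage count in \code{[0, N_S]} (need not be integer; the
#'   conditional laws evaluate it on the integer grid).
#' @param h signal value, >= 0.
#' @return named numeric vector with components \code{sense_PA},
#'   \code{sense_AP}, \code{int_PA}, \code{int_AP}.
#' @export
receptor_rates <- function(params, s, h) {
  if (any(s < 0) || any(s > params$N_S))
    stop("domain error: s must lie in [0, N_S]")
  if (any(h < 0)) stop("domain error: h must be >= 0")
  b <- params$beta
  c(sense_PA = exp(b * (h - params$DeltaE)) / params$tau_R,
    sense_AP = 1 / params$tau_R,
    int_PA   = exp(-b * params$DeltaE) / (params$g * params$tau_R),
    int_AP   = exp(b * params$kappa * params$sigma * s / params$N_S) /
               (params$g * params$tau_R))
}

#' Readout birth and death rates
#'
#' Birth \code{exp(-beta (V - c r)) Gamma_U0} (independent of the current
#' count) and death \code{u Gamma_U0} of the readout birth-death process,
#' given the receptor state.
#'
#' @param params a \code{habinfo_params}.
#' @param r receptor state, 0 (passive) or 1 (active).
#' @param u readout count, >= 0.
#' @return named numeric vector \code{c(birth, death)}.
#' @export
readout_rates <- function(params, r, u) {
  if (!all(r %in% c(0, 1))) stop("domain error: r must be 0 or 1")
  if (any(u < 0)) stop("domain error: u must be >= 0")
  c(birth = exp(-params$beta * (params$V - params$c * r)) * params$Gamma_U0,
    death = u * params$Gamma_U0)
}

#' Storage birth and death rates
#'
#' Catalytic production \code{u exp(-beta sigma) Gamma_S0} (forbidden at the
#' capacity \code{s = N_S}) and decay \code{s Gamma_S0}.
#'
#' @param params a \code{habinfo_params}.
#' @param u readout count, >= 0.
#' @param s storage count in \code{[0, N_S]}.
#' @return named numeric vector \code{c(birth, death)}.
#' @export
storage_rates <- function(params, u, s) {
  if (any(s < 0) || any(s > params$N_S))
    stop("domain error: s must lie in [0, N_S]")
  if (any(u < 0)) stop("domain error: u must be >= 0")
  birth <- ifelse(s < params$N_S,
                  u * exp(-params$beta * params$sigma) * params$Gamma_S0, 0)
  c(birth = unname(birth), death = unname(s * params$Gamma_S0))
}

# Stable log on/off rates of the receptor, vectorized over s and h.
# Returns log k_on = log(sense_PA + int_PA), log k_off = log(sense_AP +
# int_AP), each minus log tau_R which cancels in the activation probability.
.receptor_log_onoff <- function(params, s, h) {
  b <- params$beta
  lon1 <- b * (h - params$DeltaE)             # sensing P->A
  lon2 <- -b * params$DeltaE - log(params$g)  # internal P->A
  loff1 <- 0                                  # sensing A->P
  loff2 <- b * params$kappa * params$sigma * s / params$N_S - log(params$g)
  logsum2 <- function(a, b) {
    m <- pmax(a, b)
    m + log1p(exp(pmin(a, b) - m))
  }
  list(log_on = logsum2(lon1, lon2 + 0 * lon1),
       log_off = logsum2(loff1 + 0 * loff2, loff2))
}

#' Stationary activation probability of the receptor
#'
#' Probability that the receptor is active in its conditional stationary
#' state at fixed storage level and signal,
#' \code{p_A = k_on/(k_on + k_off)}, with \code{k_on} (\code{k_off}) the sum
#' of the two activation (deactivation) rates.  Evaluated in log space so
#' that arbitrarily strong signals are handled without overflow.
#'
#' @param params a \code{habinfo_params}.
#' @param s storage count(s) in \code{[0, N_S]}.
#' @param h signal value(s), >= 0.  \code{s} and \code{h} are recycled.
#' @return activation probabilities in (0, 1).
#' @export
#' @examples
#' p <- model_params(beta = 3, sigma = 0.6, DeltaE = 0)
#' receptor_stationary_given_sh(p, s = 0, h = 0)  # symmetric rates: 1/2
receptor_stationary_given_sh <- function(params, s, h) {
  if (any(s < 0) || any(s > params$N_S))
    stop("domain error: s must lie in [0, N_S]")
  if (any(h < 0)) stop("domain error: h must be >= 0")
  lr <- .receptor_log_onoff(params, s, h)
  stats::plogis(lr$log_on - lr$log_off)
}
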