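# Exact stochastic simulation of the full four-variable model (r, u, s, h),
# the brute-force oracle for the timescale-separation solver.

#' Exact Gillespie simulation of the full model
#'
#' Continuous-time stochastic simulation of receptor, readout, storage and
#' signal.  The signal is a jump process: it is redrawn from the
#' exponential law of the current protocol epoch at exponential waiting
#' times of mean \code{tau_H}, and at every protocol switch, which makes
#' successive values uncorrelated while matching the prescribed marginals.
#' All other reaction channels use the model rates; rates are piecewise
#' constant between events so the simulation is exact.  Each trajectory has
#' its own counter-derived random stream, so results are bit-reproducible
#' given \code{(seed, n_traj, params)}.
#'
#' @param params a \code{habinfo_params}.  Note that exact simulation
#'   requires \code{beta < 1/H} for every signal mean \code{H} in the
#'   protocol, otherwise the expected receptor flip count diverges (the
#'   reduced model of \code{\link{reduced_params}} is designed for this).
#' @param protocol a \code{habinfo_protocol}.
#' @param n_traj number of trajectories, >= 1.
#' @param seed integer seed.
#' @param sample_times increasing times at which states are recorded.
#' @param init named list with elements \code{r}, \code{u}, \code{s}
#'   (scalars or length-\code{n_traj} vectors) giving initial states;
#'   defaults to \code{r = 0}, \code{u} and \code{s} at their background
#'   stationary scale.
#' @param burn_in time simulated before the first sample under the
#'   background signal, to relax the initial condition.
#' @return an object of class \code{"habinfo_ensemble"}: matrices
#'   \code{r, u, s, h} and cumulative storage event counts
#'   \code{s_births, s_deaths}, each \code{n_traj x length(sample_times)},
#'   plus the call metadata.
#' @export
#' @examples
#' p <- reduced_params()
#' pr <- signal_protocol(H_min = 0.1, H_max = 1.5, T_s = 10, Delta_T = 10,
#'                       n_stimuli = 2, t_start = 10)
#' ens <- gillespie_simulate(p, pr, n_traj = 50, seed = 1,
#'                           sample_times = c(5, 15, 25, 35))
#' ensemble_moments(ens)$mean
gillespie_simulate <- function(params, protocol, n_traj, seed, sample_times,
                               init = NULL, burn_in = 3 * params$tau_S) {
  stopifnot(n_traj >= 1, length(sample_times) >= 1,
            !is.unsorted(sample_times))
  params <- protocol_params(params, protocol)
  if (is.null(init)) {
    init <- list(r = 0L,
                 u = as.integer(round(params$U_mean_passive)),
                 s = as.integer(round(min(params$N_S,
                   params$U_mean_passive * exp(-params$beta * params$sigma)))))
  }
  res <- hab_ssa(params, protocol, as.integer(n_traj), as.double(seed),
                 as.numeric(sample_times),
                 as.integer(init$r), as.integer(init$u), as.integer(init$s),
                 as.double(burn_in))
  res$n_traj <- as.integer(n_traj)
  res$seed <- seed
  res$sample_times <- as.numeric(sample_times)
  res$params <- params
  res$protocol <- protocol
  class(res) <- "habinfo_ensemble"
  res
}

#' @export
print.habinfo_ensemble <- function(x, ...) {
  cat(sprintf("Gillespie ensemble: %d trajectories, %d sample times, seed %s\n",
              x$n_traj, length(x$sample_times), format(x$seed)))
  invisible(x)
}

#' Ensemble moments of a Gillespie ensemble
#'
#' Means, variances and standard errors (sample sd / sqrt(n)) of each
#' variable at every sample time, plus (optionally) the empirical joint
#' readout-storage histogram at one sample time.
#'
#' @param ens a \code{habinfo_ensemble} with at least 2 trajectories.
#' @param joint_at optional index into \code{sample_times} at which the
#'   empirical normalized joint \code{(u, s)} histogram is computed.
#' @return list with matrices \code{mean}, \code{var}, \code{se} (rows
#'   \code{r, u, s, h}, columns sample times) and, if requested,
#'   \code{p_US} (matrix over \code{0:max(u)} x \code{0:N_S}).
#' @export
ensemble_moments <- function(ens, joint_at = NULL) {
  if (ens$n_traj < 2) stop("need at least 2 trajectories for moments")
  vars <- c("r", "u", "s", "h")
  mean_m <- t(vapply(vars, function(v) colMeans(ens[[v]]),
                     numeric(length(ens$sample_times))))
  var_m <- t(vapply(vars, function(v) apply(ens[[v]], 2, stats::var),
                    numeric(length(ens$sample_times))))
  se_m <- sqrt(var_m / ens$n_traj)
  rownames(mean_m) <- rownames(var_m) <- rownames(se_m) <- vars
  colnames(mean_m) <- colnames(var_m) <- colnames(se_m) <-
    format(ens$sample_times)
  out <- list(mean = mean_m, var = var_m, se = se_m)
  if (!is.null(joint_at)) {
    u <- ens$u[, joint_at]; s <- ens$s[, joint_at]
    NS <- ens$params$N_S
    tab <- table(factor(u, levels = 0:max(u)), factor(s, levels = 0:NS))
    out$p_US <- unclass(tab) / length(u)
  }
  out
}

#' Event-count estimate of the internal energy flux
#'
#' Estimates \code{J_int} between two sample times from the cumulative
#' storage birth/death counters:
#' \code{sigma * (births - deaths) / elapsed}, averaged over trajectories,
#' with its standard error.
#'
#' @param ens a \code{habinfo_ensemble}.
#' @param i,j indices into \code{sample_times} delimiting the window.
#' @return named vector \code{c(J_int, se)}.
#' @export
flux_from_counts <- function(ens, i, j) {
  stopifnot(j > i)
  dt <- ens$sample_times[j] - ens$sample_times[i]
  net <- (ens$s_births[, j] - ens$s_births[, i]) -
         (ens$s_deaths[, j] - ens$s_deaths[, i])
  x <- ens$params$sigma * net / dt
  c(J_int = mean(x), se = stats::sd(x) / sqrt(length(x)))
}
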