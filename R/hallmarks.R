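# Habituation metrics and the five hallmark experiments: potentiation,
# spontaneous recovery, subliminal accumulation, intensity sensitivity and
# frequency sensitivity.  The "response" to a stimulus is the mean readout
# sampled at a fixed phase within the stimulus window (default: the end of
# the window), since the observable is evaluated once per stimulus.

#' Snapshot of a trajectory at a given time
#' @param traj a \code{habinfo_trajectory}.
#' @param t requested snapshot time (must be one of the sample times).
#' @return the stored \code{habinfo_joint}.
#' @export
get_snapshot <- function(traj, t) {
  k <- which(abs(traj$sample_times - t) < 1e-9)
  if (length(k) != 1) stop("no snapshot stored at t = ", t)
  traj$snapshots[[k]]
}

#' Per-stimulus responses of a trajectory
#'
#' Extracts one mean-readout value per stimulus, sampled at a fixed phase
#' of the stimulus window.
#'
#' @param traj a \code{habinfo_trajectory} covering all stimuli of
#'   \code{protocol}.
#' @param protocol the protocol the trajectory was run under.
#' @param phase sampling phase within the window, in (0, 1]; 1 = end of the
#'   stimulus window.
#' @return numeric vector of responses, one per stimulus.
#' @export
peak_responses <- function(traj, protocol, phase = 1) {
  stopifnot(phase > 0, phase <= 1)
  targets <- stimulus_onsets(protocol) + phase * protocol$T_s
  if (max(targets) > max(traj$times) + 1e-9)
    stop("trajectory does not cover all stimuli of the protocol")
  idx <- vapply(targets, function(tt) which.min(abs(traj$times - tt)), 0L)
  if (any(abs(traj$times[idx] - targets) > traj$dt + 1e-9))
    stop("protocol/trajectory mismatch: no recorded step near a sampling phase")
  traj$U_mean[idx]
}

#' Habituation time and stimulus count
#'
#' The system counts as habituated at the first stimulus \code{n} whose
#' response decrement relative to the previous stimulus,
#' \code{(U[n-1] - U[n]) / U[n]}, is a nonnegative value not exceeding the
#' threshold (default 0.5\%).  Reaching the criterion requires an actual
#' habituation phase: some earlier decrement must have exceeded the
#' threshold, otherwise a response that never changes (e.g. with the
#' feedback disabled) would count as instantly habituated.
#'
#' @param responses per-stimulus responses (see
#'   \code{\link{peak_responses}}).
#' @param protocol the protocol that produced them.
#' @param threshold relative-decrement criterion.
#' @return list with \code{n_hab} (stimulus index) and \code{t_hab} (onset
#'   time of that stimulus); both \code{NA} if the criterion is never met.
#' @export
habituation_time <- function(responses, protocol, threshold = 0.005) {
  if (length(responses) < 2) stop("need at least 2 responses")
  rel <- (responses[-length(responses)] - responses[-1]) / responses[-1]
  started <- c(FALSE, cumsum(rel > threshold) > 0)[seq_along(rel)]
  hit <- which(rel >= 0 & rel <= threshold & started)
  if (length(hit) == 0) return(list(n_hab = NA_integer_, t_hab = NA_real_))
  n <- hit[1] + 1L
  list(n_hab = n, t_hab = stimulus_onsets(protocol)[n])
}

# Evolve a joint law under a constant mean signal for a given duration,
# reusing a solver cache.  Returns the final state (time advanced).
.evolve_const <- function(params, p, H, duration, dt, cache) {
  if (duration <= 0) return(p)
  nsub <- max(1L, ceiling(duration / dt))
  h <- duration / nsub
  for (j in seq_len(nsub)) p <- step_joint(params, p, H, h, cache)
  p
}

# Response of a single probe stimulus applied to state p: evolve one
# stimulus window under H_max and return the mean readout at its end.
.probe_response <- function(params, p, protocol, dt, cache, phase = 1) {
  p2 <- .evolve_const(params, p, protocol$H_max, phase * protocol$T_s, dt,
                      cache)
  unname(joint_means(p2)["U"])
}

#' Train the model to habituation
#'
#' Runs the protocol for exactly \code{n_stimuli} stimuli (default: until
#' the habituation criterion is met) and returns the responses, the
#' habituation metrics and the final state at the end of the last stimulus
#' window.
#'
#' @param params a \code{habinfo_params}.
#' @param protocol a \code{habinfo_protocol}; its \code{n_stimuli} is the
#'   maximum train length considered.
#' @param n_stimuli optional explicit train length.
#' @param phase response sampling phase.
#' @return list with \code{responses}, \code{n_hab}, \code{t_hab},
#'   \code{U_in} (initial response), \code{final} (joint law at the end of
#'   stimulus \code{n_stimuli}), \code{traj}.
#' @export
train_to_habituation <- function(params, protocol, n_stimuli = NULL,
                                 phase = 1) {
  params <- protocol_params(params, protocol)
  full <- evolve(params, protocol,
                 t_end = protocol_end(protocol),
                 sample_times = stimulus_onsets(protocol) + protocol$T_s)
  resp <- peak_responses(full, protocol, phase)
  hab <- habituation_time(resp, protocol)
  if (is.null(n_stimuli)) {
    if (is.na(hab$n_hab))
      stop("precondition error: no habituation within ", protocol$n_stimuli,
           " stimuli")
    n_stimuli <- hab$n_hab
  }
  end_t <- stimulus_onsets(protocol)[n_stimuli] + protocol$T_s
  list(responses = resp[seq_len(n_stimuli)], n_hab = hab$n_hab,
       t_hab = hab$t_hab, U_in = resp[1],
       final = get_snapshot(full, end_t), traj = full)
}

#' Recovery time after a stimulation train
#'
#' Time needed, after the end of a stimulation train, for the response to a
#' probe stimulus to return to within \code{threshold} (default 1\%) of the
#' response at the first stimulus of the train.  The background relaxation
#' is computed once; probe stimuli are applied counterfactually from states
#' along it, and the first passage is resolved by bisection on the pause
#' duration.  The returned time is the pause plus the probe window (the
#' probe response is realized at the end of its window).
#'
#' @param params a \code{habinfo_params}.
#' @param state joint law at the end of the train
#'   (\code{train_to_habituation(...)$final}).
#' @param U_ref reference response (the train's first-stimulus response).
#' @param protocol the protocol (probe stimulus strength and duration are
#'   taken from it).
#' @param threshold relative-deficit criterion.
#' @param pause_max probing horizon; \code{NA} is returned if the response
#'   has not recovered within it.
#' @param phase probe sampling phase.
#' @param tol_t absolute time resolution of the bisection.
#' @return recovery time (scalar), or \code{NA} if not reached within
#'   \code{pause_max}.
#' @export
recovery_time <- function(params, state, U_ref, protocol, threshold = 0.01,
                          pause_max = 12 * params$tau_S, phase = 1,
                          tol_t = NULL) {
  params <- protocol_params(params, protocol)
  dt <- max_step(params, protocol)
  if (is.null(tol_t)) tol_t <- dt / 8
  cache <- .solver_cache(params)
  deficit_of <- function(p) {
    (U_ref - .probe_response(params, p, protocol, dt, cache, phase)) / U_ref
  }
  coarse <- max(protocol$Delta_T, params$tau_S / 10)
  p <- state
  pause <- 0
  d0 <- deficit_of(p)
  if (d0 <= threshold) return(phase * protocol$T_s)
  repeat {
    if (pause >= pause_max) return(NA_real_)
    step <- min(coarse, pause_max - pause)
    p_next <- .evolve_const(params, p, protocol$H_min, step, dt, cache)
    d_next <- deficit_of(p_next)
    if (d_next <= threshold) break
    p <- p_next; pause <- pause + step; d0 <- d_next
  }
  lo <- 0; hi <- step  # bracket within [pause, pause + step]
  while (hi - lo > tol_t) {
    mid <- (lo + hi) / 2
    pm <- .evolve_const(params, p, protocol$H_min, mid, dt, cache)
    if (deficit_of(pm) <= threshold) hi <- mid else lo <- mid
  }
  pause + hi + phase * protocol$T_s
}

#' The five hallmark experiments
#'
#' Runs the paired experiments probing the classical hallmarks of
#' habituation on a square-wave protocol:
#' \enumerate{
#'   \item potentiation: after a train and a short pause, a second train
#'     habituates in fewer stimuli;
#'   \item spontaneous recovery: after a sufficiently long pause the
#'     response recovers;
#'   \item subliminal accumulation: continuing the stimulation beyond the
#'     habituation time lengthens the recovery period by \code{delta_t};
#'   \item intensity sensitivity: weaker stimuli give a larger normalized
#'     response decrement;
#'   \item frequency sensitivity: more frequent stimuli give a larger
#'     normalized decrement.
#' }
#'
#' @param params a \code{habinfo_params} in a habituating regime.
#' @param base_protocol the reference protocol.
#' @param pause_potentiation pause inserted between the two trains of the
#'   potentiation experiment; default twice the inter-stimulus pause.
#' @param n_extra stimuli applied beyond the habituation time in the
#'   subliminal-accumulation experiment; default: as many as were needed to
#'   habituate.
#' @param H_max_grid stimulus strengths for the intensity experiment.
#' @param Delta_T_grid pauses for the frequency experiment.
#' @param phase response sampling phase.
#' @return an object of class \code{"habinfo_hallmarks"}: per-hallmark pass
#'   flags and effect sizes (\code{n_hab}, \code{t_hab}, \code{t_recovery},
#'   \code{delta_t_recovery}, \code{DeltaU}, sweep tables).
#' @export
hallmark_suite <- function(params, base_protocol = signal_protocol(),
                           pause_potentiation = 2 * base_protocol$Delta_T,
                           n_extra = NULL,
                           H_max_grid = c(5, 10, 20, 40),
                           Delta_T_grid = c(400, 200, 100, 50),
                           phase = 1) {
  params <- protocol_params(params, base_protocol)
  base <- train_to_habituation(params, base_protocol, phase = phase)
  if (is.na(base$n_hab))
    stop("precondition error: parameters are not in a habituating regime")
  DeltaU <- base$responses[base$n_hab] - base$U_in

  # (1) potentiation: second train after a short pause
  dt <- max_step(params, base_protocol)
  cache <- .solver_cache(params)
  p_rest <- .evolve_const(params, base$final, base_protocol$H_min,
                          pause_potentiation, dt, cache)
  pr2 <- base_protocol
  pr2$t_start <- base_protocol$Delta_T
  tr2 <- evolve(params, pr2, t_end = protocol_end(pr2), init = p_rest)
  resp2 <- peak_responses(tr2, pr2, phase)
  hab2 <- habituation_time(resp2, pr2)
  pot_pass <- !is.na(hab2$n_hab) && hab2$n_hab < base$n_hab

  # (2) spontaneous recovery
  t_rec <- recovery_time(params, base$final, base$U_in, base_protocol,
                         phase = phase)
  rec_pass <- is.finite(t_rec)

  # (3) subliminal accumulation
  if (is.null(n_extra)) n_extra <- base$n_hab
  ext <- train_to_habituation(params, base_protocol,
                              n_stimuli = min(base$n_hab + n_extra,
                                              base_protocol$n_stimuli),
                              phase = phase)
  t_rec_ext <- recovery_time(params, ext$final, base$U_in, base_protocol,
                             phase = phase)
  delta_t <- t_rec_ext - t_rec
  sub_pass <- is.finite(delta_t) && delta_t > 0

  # (4) intensity sensitivity: normalized decrement shrinks with H_max
  intensity <- do.call(rbind, lapply(H_max_grid, function(Hm) {
    pr <- base_protocol; pr$H_max <- Hm
    tr <- train_to_habituation(params, pr,
                               n_stimuli = base_protocol$n_stimuli,
                               phase = phase)
    hab_n <- if (is.na(tr$n_hab)) length(tr$responses) else tr$n_hab
    data.frame(H_max = Hm, U_in = tr$U_in,
               norm_decrement = (tr$U_in - tr$responses[hab_n]) / tr$U_in,
               n_hab = tr$n_hab)
  }))
  int_pass <- !is.unsorted(rev(intensity$norm_decrement)) &&
    !is.unsorted(intensity$U_in)

  # (5) frequency sensitivity: faster/deeper decrement at smaller Delta_T
  frequency <- do.call(rbind, lapply(Delta_T_grid, function(DT) {
    pr <- base_protocol; pr$Delta_T <- DT
    tr <- train_to_habituation(params, pr,
                               n_stimuli = base_protocol$n_stimuli,
                               phase = phase)
    hab_n <- if (is.na(tr$n_hab)) length(tr$responses) else tr$n_hab
    data.frame(Delta_T = DT,
               norm_decrement = (tr$U_in - tr$responses[hab_n]) / tr$U_in,
               n_hab = tr$n_hab, t_hab = tr$t_hab)
  }))
  # more frequent stimulation habituates more deeply and earlier in time
  # (the stimulus count n_hab grows as Delta_T shrinks: each stimulus then
  # moves the slow storage less, but stimuli come more often)
  freq_pass <- !is.unsorted(frequency$norm_decrement) &&
    !is.unsorted(rev(frequency$t_hab))

  structure(list(
    n_hab = base$n_hab, t_hab = base$t_hab, U_in = base$U_in,
    DeltaU = DeltaU,
    n_hab_potentiated = hab2$n_hab,
    t_recovery = t_rec, t_recovery_extended = t_rec_ext,
    delta_t_recovery = delta_t,
    subliminal_rel_increase = delta_t / t_rec,
    intensity = intensity, frequency = frequency,
    pass = c(potentiation = pot_pass, spontaneous_recovery = rec_pass,
             subliminal_accumulation = sub_pass,
             intensity_sensitivity = int_pass,
             frequency_sensitivity = freq_pass)),
    class = "habinfo_hallmarks")
}

#' @export
print.habinfo_hallmarks <- function(x, ...) {
  cat("Habituation hallmark report\n")
  cat(sprintf("  n_hab = %d (t_hab = %g), initial response %.2f, DeltaU = %.2f\n",
              x$n_hab, x$t_hab, x$U_in, x$DeltaU))
  cat(sprintf("  potentiated n_hab = %s, t_recovery = %.1f (+%.1f after extended train, +%.1f%%)\n",
              format(x$n_hab_potentiated), x$t_recovery,
              x$delta_t_recovery, 100 * x$subliminal_rel_increase))
  cat("  hallmark flags:\n")
  for (nm in names(x$pass))
    cat(sprintf("    %-24s %s\n", nm, if (x$pass[nm]) "pass" else "FAIL"))
  invisible(x)
}

#' Subliminal accumulation of the recovery period
#'
#' The third hallmark in isolation: relative increase of the recovery
#' period when stimulation is continued beyond the habituation time,
#' \code{(t_recovery_extended - t_recovery)/t_recovery}.
#'
#' @inheritParams hallmark_suite
#' @return list with \code{t_recovery}, \code{t_recovery_extended},
#'   \code{delta_t}, \code{rel_increase} and the training metadata.
#' @export
subliminal_accumulation <- function(params,
                                    base_protocol = signal_protocol(),
                                    n_extra = NULL, phase = 1) {
  params <- protocol_params(params, base_protocol)
  base <- train_to_habituation(params, base_protocol, phase = phase)
  if (is.na(base$n_hab))
    stop("precondition error: parameters are not in a habituating regime")
  if (is.null(n_extra)) n_extra <- base$n_hab
  t_rec <- recovery_time(params, base$final, base$U_in, base_protocol,
                         phase = phase)
  ext <- train_to_habituation(params, base_protocol,
                              n_stimuli = min(base$n_hab + n_extra,
                                              base_protocol$n_stimuli),
                              phase = phase)
  t_rec_ext <- recovery_time(params, ext$final, base$U_in, base_protocol,
                             phase = phase)
  list(n_hab = base$n_hab, n_extra = n_extra,
       t_recovery = t_rec, t_recovery_extended = t_rec_ext,
       delta_t = t_rec_ext - t_rec,
       rel_increase = (t_rec_ext - t_rec) / t_rec)
}
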