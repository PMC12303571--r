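# Mapping of the model readout dynamics to binary-neuron population
# activity: each readout unit stands for a subpopulation of N neurons,
# each of which fires with probability p whenever its unit is active.
# PCA embeddings of the resulting activity expose the habituation axis,
# as in population recordings of repeated visual stimulation.

#' Looming-like stimulation protocol
#'
#' Default protocol for the neural comparison: one stimulus every 150
#' time units (interpreted as the inter-onset interval of the repeated
#' looming presentations), with a 50-unit stimulus window.
#'
#' @param n_stimuli number of stimuli.
#' @param H_max stimulus strength.
#' @return a \code{habinfo_protocol}.
#' @export
looming_protocol <- function(n_stimuli = 20, H_max = 10) {
  signal_protocol(H_min = 0.1, H_max = H_max, T_s = 50, Delta_T = 100,
                  n_stimuli = n_stimuli, t_start = 100)
}

#' Stochastic readout-unit activations under a protocol
#'
#' Simulates \code{n_units} independent stochastic readout units with the
#' receptor-equilibrated jump simulator (the receptor is kept at its
#' conditional stationary activation probability; readout, storage and
#' signal evolve as an exact jump process) and thresholds them into a
#' binary units-by-time activation table.  A unit counts as activated by a
#' stimulus when its readout count, averaged over the stimulus window,
#' exceeds the midpoint between the passive and active means; an
#' activated unit is marked active for all time bins of that window.  The
#' signal fluctuates several times within each presentation
#' (\code{tau_H_units}), so the window-averaged readout is a graded
#' function of the unit's storage level and dropout under habituation is
#' a sharp, ordered threshold crossing rather than a coin flip.
#'
#' @param params a \code{habinfo_params} in a habituating regime.  For
#'   these stochastic units the readout timescale may be chosen slower
#'   than the solver default (it only needs to stay well below
#'   \code{tau_S}); see \code{tau_U_units}.
#' @param protocol a \code{habinfo_protocol}.
#' @param n_units number of readout units.
#' @param seed integer seed (one independent stream per unit).
#' @param dt_sample sampling resolution of the activity table.
#' @param tau_U_units readout timescale used for the unit simulations;
#'   default \code{tau_S / 1000} (slower than the solver default, it only
#'   needs to stay far below \code{tau_S}; larger values keep the event
#'   count of the jump simulation moderate).
#' @param tau_H_units signal redraw time during the unit simulations;
#'   default \code{T_s / 16}, so each presentation contains many
#'   independent signal fluctuations that the readout integrates.
#' @param threshold activation threshold on the readout count; default
#'   one third of the way from the passive to the active mean.  With the
#'   default excitability dispersion the midpoint would leave only a
#'   small minority of units active at the first stimulus; the lower
#'   threshold yields an initially responsive population that thins out
#'   as habituation proceeds.
#' @param DeltaE_spread half-width of the uniform per-unit jitter applied
#'   to the receptor barrier (energy units).  Sensing units in a real
#'   population differ in excitability; this dispersion makes unit dropout
#'   under habituation persistent and ordered (the least excitable units
#'   stop responding first), which is what lets a principal component
#'   encode the habituation axis.  Set to 0 for identical units.
#' @return an object of class \code{"habinfo_unit_activity"}: list with
#'   binary matrix \code{active} (units x time), numeric matrix \code{u}
#'   (readout counts), \code{times}, \code{protocol}, \code{threshold},
#'   and \code{activation_fraction} (per-stimulus fraction of units active
#'   at any time within each stimulus window).
#' @export
unit_activations_from_model <- function(params, protocol, n_units = 120,
                                        seed = 1, dt_sample = 5,
                                        tau_U_units = params$tau_S / 1000,
                                        tau_H_units = protocol$T_s / 32,
                                        threshold = NULL,
                                        DeltaE_spread = 4) {
  params <- protocol_params(params, protocol)
  params$tau_U <- tau_U_units
  # the receptor is conditionally equilibrated in this simulator; its
  # timescale only participates in the ordering check
  params$tau_R <- max(params$tau_R, 2 * tau_U_units)
  params$tau_H <- tau_H_units
  params$tau_ratio_max <- max(params$tau_ratio_max,
                              2 * params$tau_S / tau_H_units)
  params <- derive_energies(params)
  if (is.null(threshold))
    threshold <- params$U_mean_passive +
      (params$U_mean_active - params$U_mean_passive) / 3
  times <- seq(0, protocol_end(protocol) + protocol$Delta_T, by = dt_sample)
  u0 <- as.integer(round(params$U_mean_passive))
  s0 <- as.integer(round(min(params$N_S,
        params$U_mean_passive * exp(-params$beta * params$sigma))))
  set.seed(seed)
  dE <- params$DeltaE +
    stats::runif(n_units, -DeltaE_spread, DeltaE_spread)
  u <- hab_hybrid_ssa(params, protocol, as.integer(n_units),
                      as.double(seed), times, u0, s0,
                      burn_in = 3 * params$tau_S, dE)
  onsets <- stimulus_onsets(protocol)
  active <- matrix(0L, n_units, length(times))
  act_win <- matrix(0L, n_units, length(onsets))
  for (k in seq_along(onsets)) {
    win <- which(times >= onsets[k] & times < onsets[k] + protocol$T_s)
    mu <- rowMeans(u[, win, drop = FALSE])
    act_win[, k] <- (mu > threshold) * 1L
    active[, win] <- act_win[, k]
  }
  structure(list(active = active, window_active = act_win, u = u,
                 times = times, protocol = protocol, threshold = threshold,
                 activation_fraction = colMeans(act_win), seed = seed),
            class = "habinfo_unit_activity")
}

#' @export
print.habinfo_unit_activity <- function(x, ...) {
  cat(sprintf("Unit activity: %d units x %d time points, threshold %g\n",
              nrow(x$active), ncol(x$active), x$threshold))
  cat("  per-stimulus activation fraction:",
      paste(sprintf("%.2f", x$activation_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Sample binary neural activity from unit activations
#'
#' Expands each readout unit into \code{N} binary neurons: whenever a
#' unit is activated, each of its \code{N} neurons fires independently
#' with probability \code{p}; neurons of inactive units are silent.  An
#' activation is one contiguous run of active time bins (one stimulus
#' presentation), and a neuron that fires stays on for that whole run;
#' set \code{per_bin = TRUE} to redraw the firing at every time bin
#' instead.
#'
#' @param unit_activations binary units-by-time matrix (e.g. the
#'   \code{active} element of \code{\link{unit_activations_from_model}}).
#' @param N neurons per unit.
#' @param p firing probability per activation, in \code{[0, 1]}.
#' @param seed integer seed.
#' @param per_bin draw firing independently at every time bin rather than
#'   once per activation run.
#' @return an object of class \code{"habinfo_neural"}: list with binary
#'   matrix \code{activity} (\code{N * n_units} neurons x time),
#'   \code{fraction_active} (per-time fraction of firing neurons),
#'   \code{N}, \code{p}, \code{seed}.
#' @export
sample_neural_activity <- function(unit_activations, N = 20, p = 0.5,
                                   seed = 1, per_bin = FALSE) {
  if (p < 0 || p > 1) stop("domain error: p must lie in [0, 1]")
  stopifnot(N >= 1)
  n_units <- nrow(unit_activations)
  nt <- ncol(unit_activations)
  set.seed(seed)
  act <- matrix(0L, n_units * N, nt)
  for (i in seq_len(n_units)) {
    on <- which(unit_activations[i, ] > 0)
    if (!length(on)) next
    rows <- (i - 1) * N + seq_len(N)
    if (per_bin) {
      act[rows, on] <- matrix(rbinom(N * length(on), 1, p), N, length(on))
    } else {
      run_id <- cumsum(c(1L, diff(on) != 1L))
      for (rr in unique(run_id)) {
        cols <- on[run_id == rr]
        act[rows, cols] <- rbinom(N, 1, p)  # recycled across the run
      }
    }
  }
  structure(list(activity = act, fraction_active = colMeans(act),
                 N = N, p = p, seed = seed),
            class = "habinfo_neural")
}

#' @export
print.habinfo_neural <- function(x, ...) {
  cat(sprintf("Neural activity: %d neurons x %d time points (N = %d, p = %g)\n",
              nrow(x$activity), ncol(x$activity), x$N, x$p))
  invisible(x)
}

#' PCA embedding of a neurons-by-time activity matrix
#'
#' Mean-centered principal component analysis of the time samples (time
#' points are observations, neurons are features).
#'
#' @param activity numeric neurons-by-time matrix.
#' @param n_components number of components to return.
#' @return list with \code{scores} (time x components),
#'   \code{explained_variance} (ratios, summing to <= 1) and the component
#'   \code{loadings}.
#' @export
pca_embedding <- function(activity, n_components = 2) {
  stopifnot(ncol(activity) >= 2)
  X <- t(activity)
  if (all(apply(X, 2, stats::sd) == 0))
    stop("degenerate input: activity matrix is constant")
  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE])
}

#' Per-stimulus means of a principal-component score
#'
#' Averages a PCA score trace within each stimulus window; the rank
#' correlation of these means with the stimulus index quantifies how well
#' the component encodes the habituation axis.
#'
#' @param scores time-by-component score matrix from
#'   \code{\link{pca_embedding}}.
#' @param times time stamps of the score rows.
#' @param protocol the stimulation protocol.
#' @param component which component to summarize.
#' @return list with \code{means} (one per stimulus) and
#'   \code{rank_correlation} (Spearman correlation with stimulus index).
#' @export
pc_stimulus_means <- function(scores, times, protocol, component = 2) {
  onsets <- stimulus_onsets(protocol)
  m <- vapply(onsets, function(o) {
    win <- times >= o & times <= o + protocol$T_s
    mean(scores[win, component])
  }, 0.0)
  list(means = m,
       rank_correlation = cor(seq_along(m), m, method = "spearman"))
}

#' Synthetic stimulus-locked activity fixture
#'
#' Generates a reproducible normalized-fluorescence-like neurons-by-time
#' matrix standing in for a processed population recording: every neuron
#' responds to each stimulus with a transient (square pulse convolved
#' with an exponential-decay kernel) whose amplitude decays across
#' stimuli as \code{A_k = A0 exp(-(k-1)/r_i)}, where the per-neuron
#' habituation scale \code{r_i} is spread around \code{habituation_rate}
#' (in real populations some cells habituate faster than others; this
#' heterogeneity is what lets a second principal component encode the
#' habituation axis), plus optional Gaussian noise.  This synthetic
#' stand-in emulates only the stimulus-locked, habituating structure of
#' such recordings.
#'
#' @param n_neurons number of neurons.
#' @param n_stimuli number of stimuli.
#' @param habituation_rate e-folding scale (in stimuli) of the amplitude
#'   decay; \code{Inf} for no habituation.
#' @param noise standard deviation of the additive noise.
#' @param seed integer seed.
#' @param n_time time points; stimuli are evenly spaced.
#' @param kernel_tau decay time of the response kernel, in time bins.
#' @param stim_len stimulus duration in time bins.
#' @return list with matrix \code{activity}, \code{times},
#'   \code{stimulus_onsets}, \code{protocol_like} metadata.
#' @export
generate_fixture <- function(n_neurons = 60, n_stimuli = 8,
                             habituation_rate = 5, noise = 0.05, seed = 1,
                             n_time = 40 * n_stimuli, kernel_tau = 8,
                             stim_len = 10) {
  stopifnot(n_neurons >= 1, n_stimuli >= 1, n_time >= n_stimuli)
  set.seed(seed)
  period <- floor(n_time / n_stimuli)
  onsets <- (seq_len(n_stimuli) - 1) * period + 1
  kern <- exp(-(0:(4 * kernel_tau)) / kernel_tau)
  gains <- stats::runif(n_neurons, 0.5, 1.5)
  # heterogeneous habituation: per-neuron e-folding scale spread around the
  # population value (log-uniform within a factor 3)
  rates <- habituation_rate * exp(stats::runif(n_neurons, -log(3), log(3)))
  act <- matrix(0, n_neurons, n_time)
  for (i in seq_len(n_neurons)) {
    amp_k <- exp(-(seq_len(n_stimuli) - 1) / rates[i])
    drive <- numeric(n_time)
    for (k in seq_len(n_stimuli)) {
      idx <- onsets[k]:min(n_time, onsets[k] + stim_len - 1)
      drive[idx] <- drive[idx] + amp_k[k]
    }
    resp <- stats::filter(drive, kern, method = "convolution", sides = 1)
    resp[is.na(resp)] <- 0
    act[i, ] <- gains[i] * as.numeric(resp)
  }
  act <- act +
    matrix(stats::rnorm(n_neurons * n_time, sd = noise), n_neurons, n_time)
  list(activity = act, times = seq_len(n_time), stimulus_onsets = onsets,
       stim_len = stim_len, n_stimuli = n_stimuli, seed = seed)
}

#' Write / read a neurons-by-time activity matrix as CSV
#'
#' Plain-text interchange format: a header row of time stamps, then one
#' row per neuron.
#'
#' @param activity neurons-by-time matrix.
#' @param times time stamps (column names).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_activity_csv <- function(activity, times, path) {
  stopifnot(ncol(activity) == length(times))
  df <- as.data.frame(activity)
  names(df) <- as.character(times)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @return \code{read_activity_csv}: list with \code{activity} matrix and
#'   numeric \code{times}.
#' @export
read_activity_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  list(activity = as.matrix(df), times = as.numeric(names(df)))
}
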