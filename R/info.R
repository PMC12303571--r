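# Information-theoretic and thermodynamic observables.  Under the
# timescale separation the conditional law of the fast variables given the
# signal is p_{U,S|H}(u, s | h) = phi_h(u | s) p_S(s) with
# phi_h(u|s) = sum_r p^st_{U|R}(u|r) p^st_{R|S,H}(r|s,h); all mutual
# informations with the signal are built from this channel and the
# exponential signal law, integrated with the shared Gauss-Laguerre
# quadrature.  Information is reported in nats.

# 0 log 0 = 0 entropy of a probability vector (any shape).
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Conditional channel phi_h(u | s) at one signal value, as a matrix
# (U_max+1) x (N_S+1); p0/p1 are the conditional readout laws.
.phi_at_h <- function(params, h, p0, p1) {
  a <- receptor_stationary_given_sh(params, 0:params$N_S, h)
  outer(p0, 1 - a) + outer(p1, a)
}

# Entropies of the two-component Poisson mixtures (1-a) p0 + a p1 for a
# vector of weights, vectorized (chunked to bound memory).
.mix_entropy <- function(a, p0, p1) {
  a <- pmin(1, pmax(0, a))   # guard roundoff from convex combinations
  out <- numeric(length(a))
  chunk <- 4096L
  for (i0 in seq(1, length(a), by = chunk)) {
    idx <- i0:min(length(a), i0 + chunk - 1L)
    M <- outer(p0, 1 - a[idx]) + outer(p1, a[idx])
    L <- M * log(M)
    L[M == 0] <- 0
    out[idx] <- -colSums(L)
  }
  out
}

# Per-(params, lambda) information kernel: quadrature, activation table
# a(s, h_j), and the channel entropies H[phi_h(.|s)] and H[phi_bar(.|s)],
# none of which depend on the system state.  info_record() and
# info_scan() cache it across snapshots.
.info_kernel <- function(params, lambda, U_max = u_grid_max(params),
                         quad_n = 512) {
  quad <- signal_quadrature(lambda, quad_n)
  p0 <- readout_stationary_given_r(params, 0, U_max)
  p1 <- readout_stationary_given_r(params, 1, U_max)
  s_grid <- 0:params$N_S
  a_mat <- vapply(quad$h, function(h)
    receptor_stationary_given_sh(params, s_grid, h),
    numeric(length(s_grid)))                     # (N_S+1) x nodes
  ent_sh <- matrix(.mix_entropy(as.vector(a_mat), p0, p1),
                   nrow = length(s_grid))
  abar_s <- as.vector(a_mat %*% quad$w)
  ent_sbar <- .mix_entropy(abar_s, p0, p1)
  list(quad = quad, p0 = p0, p1 = p1, a_mat = a_mat,
       ent_sh = ent_sh, ent_sbar = ent_sbar, lambda = lambda)
}

#' Mutual information between readout and signal
#'
#' \code{I_{U,H} = H[p_U] - E_h H[p_{U|H=h}]} in nats, with
#' \code{p_{U|H=h}(u) = sum_s p_S(s) phi_h(u|s)} the readout law
#' conditioned on the signal, built from the timescale-separation
#' conditionals, and \code{p_U} its average under the exponential signal
#' law of rate \code{lambda_t}.
#'
#' @param params a \code{habinfo_params}.
#' @param p_S storage marginal (probabilities over \code{0:N_S}).
#' @param lambda_t rate of the exponential signal law (1 / mean signal).
#' @param U_max readout grid bound.
#' @param quad_n quadrature order.
#' @param quad_check verify convergence under node doubling.
#' @return mutual information in nats (clipped at 0 from below).
#' @export
mutual_information_UH <- function(params, p_S, lambda_t,
                                  U_max = u_grid_max(params), quad_n = 512,
                                  quad_check = FALSE) {
  stopifnot(lambda_t > 0, abs(sum(p_S) - 1) < 1e-8)
  p0 <- readout_stationary_given_r(params, 0, U_max)
  p1 <- readout_stationary_given_r(params, 1, U_max)
  val <- function(quad) {
    a_h <- vapply(quad$h, function(h)
      sum(p_S * receptor_stationary_given_sh(params, 0:params$N_S, h)),
      0.0)
    # p(u | h) is a two-component Poisson mixture with weight a_h
    cond_H <- .mix_entropy(a_h, p0, p1)
    abar <- sum(quad$w * a_h)
    H_marg <- .mix_entropy(abar, p0, p1)
    max(0, H_marg - sum(quad$w * cond_H))
  }
  if (quad_check)
    .quad_converged(val, lambda_t, quad_n)
  else
    val(signal_quadrature(lambda_t, quad_n))
}

#' Mutual information between storage and signal
#'
#' Computed by the same marginalization that defines the
#' timescale-separation channel: \code{p_{S|H}(s|h) = sum_u sum_r
#' p^st_{U|R}(u|r) p^st_{R|S,H}(r|s,h) p_S(s)}.  Because the conditional
#' laws of the fast variables sum out of the marginalization, the storage
#' is independent of the signal in this limit and the value vanishes
#' identically (up to grid truncation roundoff); the function evaluates
#' the sums explicitly rather than using that shortcut, so it serves as a
#' numerical certificate.
#'
#' @inheritParams mutual_information_UH
#' @return mutual information in nats (on the order of the truncation
#'   roundoff, i.e. numerically zero).
#' @export
mutual_information_SH <- function(params, p_S, lambda_t,
                                  U_max = u_grid_max(params), quad_n = 512) {
  stopifnot(lambda_t > 0)
  p0 <- readout_stationary_given_r(params, 0, U_max)
  p1 <- readout_stationary_given_r(params, 1, U_max)
  quad <- signal_quadrature(lambda_t, quad_n)
  # p_{S|h}(s) via the full (u, r) marginalization, then renormalized
  cond <- vapply(quad$h, function(h) {
    joint_ush <- .phi_at_h(params, h, p0, p1) *
      rep(p_S, each = U_max + 1L)      # p_{U,S|h}
    colSums(joint_ush)
  }, numeric(params$N_S + 1L))         # (N_S+1) x n_nodes
  cond <- sweep(cond, 2, colSums(cond), "/")
  marg <- as.vector(cond %*% quad$w)
  cond_H <- apply(cond, 2, .entropy)
  .entropy(marg) - sum(quad$w * cond_H)
}

#' Joint readout-storage information on the signal and feedback information
#'
#' \code{I_{(U,S),H}} computed from the timescale-separation channel
#' \code{p_{U,S|H}(u,s|h) = phi_h(u|s) p_S(s)}, and the feedback
#' information \code{DeltaI_f = I_{(U,S),H} - I_{U,H}}, the extra signal
#' information carried by the storage jointly with the readout (always
#' nonnegative).
#'
#' @param params a \code{habinfo_params}.
#' @param p_US a \code{habinfo_joint} (its storage marginal and grid are
#'   used; the readout conditionals are the stationary laws).
#' @param lambda_t signal rate.
#' @param quad_n quadrature order.
#' @param kernel optional precomputed information kernel (internal
#'   caching across snapshots with a shared signal law).
#' @return named vector \code{c(I_USH, DeltaI_f, I_UH)} in nats.
#' @export
feedback_information <- function(params, p_US, lambda_t, quad_n = 512,
                                 kernel = NULL) {
  U_max <- max(p_US$grid_u)
  p_S <- storage_marginal(p_US)
  if (is.null(kernel))
    kernel <- .info_kernel(params, lambda_t, U_max, quad_n)
  quad <- kernel$quad
  # H[p_{U,S|h}] = H[p_S] + sum_s p_S(s) H[phi_h(.|s)], so the state
  # enters only through p_S-weighted sums of the cached channel entropies
  H_cond_part <- sum(p_S * as.vector(kernel$ent_sh %*% quad$w))
  H_joint_part <- sum(p_S * kernel$ent_sbar)
  I_USH <- max(0, H_joint_part - H_cond_part)
  # readout-only information from the same kernel
  a_h <- as.vector(p_S %*% kernel$a_mat)
  cond_H <- .mix_entropy(a_h, kernel$p0, kernel$p1)
  abar <- sum(quad$w * a_h)
  I_UH <- max(0, .mix_entropy(abar, kernel$p0, kernel$p1) -
                 sum(quad$w * cond_H))
  c(I_USH = I_USH, DeltaI_f = I_USH - I_UH, I_UH = I_UH)
}

#' Internal energy flux of the storage
#'
#' \code{J_int = sigma sum_{u, s < N_S} [ birth(u) p(u,s) -
#' death(s+1) p(u,s+1) ]}: the net rate of energy change due to driven
#' storage production (positive while the storage is being charged,
#' negative while it relaxes; zero at a stationary state of the
#' birth-death chain).
#'
#' @param params a \code{habinfo_params}.
#' @param p_US a \code{habinfo_joint}.
#' @param mode \code{"net"} (the flux as defined) or \code{"production"}
#'   (one-way production flux \code{sigma sum birth(u) p(u,s)}, the
#'   energy consumption rate used by the stationary Pareto objectives).
#' @return energy per unit time.
#' @export
internal_flux <- function(params, p_US, mode = c("net", "production")) {
  mode <- match.arg(mode)
  vals <- p_US$values
  NS1 <- ncol(vals)
  birth_u <- p_US$grid_u * exp(-params$beta * params$sigma) * params$Gamma_S0
  prod_flux <- sum(birth_u * rowSums(vals[, -NS1, drop = FALSE]))
  if (mode == "production") return(params$sigma * prod_flux)
  death_s <- p_US$grid_s * params$Gamma_S0
  decay_flux <- sum(colSums(vals[, -1, drop = FALSE]) * death_s[-1])
  params$sigma * (prod_flux - decay_flux)
}

#' Receptor dissipation per unit temperature
#'
#' Average log cycle affinity of the two-pathway receptor cycle,
#' \code{delta Q_R = beta (H + kappa sigma <S>/N_S)} (the barrier cancels
#' around the cycle).
#'
#' @param params a \code{habinfo_params}.
#' @param H_st mean signal, >= 0.
#' @param mean_S mean storage occupation in \code{[0, N_S]}.
#' @return dimensionless dissipation per unit temperature.
#' @export
receptor_dissipation <- function(params, H_st, mean_S) {
  if (H_st < 0) stop("domain error: H_st must be >= 0")
  if (mean_S < 0 || mean_S > params$N_S)
    stop("domain error: mean_S must lie in [0, N_S]")
  params$beta * (H_st + params$kappa * params$sigma * mean_S / params$N_S)
}

#' Information observables along a trajectory
#'
#' Evaluates \code{I_{U,H}}, \code{I_{(U,S),H}}, \code{DeltaI_f} and
#' \code{J_int} at each stored snapshot of a trajectory, using the signal
#' law in force at the snapshot time.
#'
#' @param traj a \code{habinfo_trajectory} with snapshots.
#' @param quad_n quadrature order.
#' @return data frame with one row per snapshot: \code{time},
#'   \code{H_mean}, \code{I_UH}, \code{I_USH}, \code{DeltaI_f},
#'   \code{J_int}, \code{U_mean}, \code{S_mean}.
#' @export
info_record <- function(traj, quad_n = 512) {
  params <- traj$params
  kernels <- new.env(parent = emptyenv())
  get_kernel <- function(lambda) {
    key <- sprintf("%.12g", lambda)
    k <- kernels[[key]]
    if (is.null(k)) {
      k <- .info_kernel(params, lambda, quad_n = quad_n)
      kernels[[key]] <- k
    }
    k
  }
  rows <- lapply(traj$snapshots, function(p) {
    # snapshots at window ends carry the law computed under the window's
    # signal; classify by the epoch of the step that produced them
    tm <- p$time
    H <- mean_signal(traj$protocol, tm - 1e-9)
    fi <- feedback_information(params, p, 1 / H, quad_n,
                               kernel = get_kernel(1 / H))
    m <- joint_means(p)
    data.frame(time = tm, H_mean = H, I_UH = fi[["I_UH"]],
               I_USH = fi[["I_USH"]], DeltaI_f = fi[["DeltaI_f"]],
               J_int = internal_flux(params, p),
               U_mean = m[["U"]], S_mean = m[["S"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$time), , drop = FALSE]
}

#' Information gain and flux change through habituation
#'
#' Differences of the information and flux observables between the first
#' stimulus (the initial response) and the stimulus at which the system
#' has habituated, both evaluated at the same phase of the stimulus
#' window: \code{DeltaI_UH = I^{(hab)} - I^{(in)}},
#' \code{DeltaDeltaI_f}, \code{DeltaJ_int}, and the habituation strength
#' \code{DeltaU}.
#'
#' @param params a \code{habinfo_params}.
#' @param protocol a \code{habinfo_protocol} long enough to habituate.
#' @param phase evaluation phase within the stimulus window.
#' @param quad_n quadrature order.
#' @return list with the four differences, the in/hab values and
#'   \code{n_hab}.
#' @export
info_gain <- function(params, protocol, phase = 1, quad_n = 512) {
  params <- protocol_params(params, protocol)
  onsets <- stimulus_onsets(protocol)
  sample_t <- onsets + phase * protocol$T_s
  traj <- evolve(params, protocol, t_end = protocol_end(protocol),
                 sample_times = sample_t)
  resp <- peak_responses(traj, protocol, phase)
  hab <- habituation_time(resp, protocol)
  if (is.na(hab$n_hab))
    stop("precondition error: no habituation under this protocol")
  lam <- 1 / protocol$H_max
  at <- function(k) {
    p <- get_snapshot(traj, sample_t[k])
    fi <- feedback_information(params, p, lam, quad_n)
    c(fi, J_int = internal_flux(params, p), U = joint_means(p)[["U"]])
  }
  v_in <- at(1); v_hab <- at(hab$n_hab)
  list(DeltaI_UH = v_hab[["I_UH"]] - v_in[["I_UH"]],
       DeltaDeltaI_f = v_hab[["DeltaI_f"]] - v_in[["DeltaI_f"]],
       DeltaJ_int = v_hab[["J_int"]] - v_in[["J_int"]],
       DeltaU = v_hab[["U"]] - v_in[["U"]],
       at_first = v_in, at_habituated = v_hab, n_hab = hab$n_hab)
}

#' Scan information observables over the (beta, sigma) plane
#'
#' For each grid point, runs the switching protocol to habituation and
#' records the information gain, feedback-information change, flux change
#' and habituation strength, together with the smallest feedback
#' information encountered at any sampled time (a certificate for
#' \code{DeltaI_f >= 0}).
#'
#' @param beta_grid,sigma_grid numeric grids.
#' @param protocol the switching protocol.
#' @param base_params template parameter set whose energetic fields are
#'   overridden at each grid point.
#' @param phase evaluation phase.
#' @param quad_n quadrature order.
#' @return data frame with one row per (beta, sigma).
#' @export
info_scan <- function(beta_grid, sigma_grid,
                      protocol = signal_protocol(),
                      base_params = NULL, phase = 1, quad_n = 512) {
  make_p <- function(b, s) {
    if (is.null(base_params)) model_params(beta = b, sigma = s)
    else { bp <- base_params; bp$beta <- b; bp$sigma <- s; bp$kappa <- NULL
           derive_energies(bp) }
  }
  grid <- expand.grid(beta = beta_grid, sigma = sigma_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- make_p(grid$beta[i], grid$sigma[i])
    onsets <- stimulus_onsets(protocol)
    sample_t <- sort(unique(c(onsets + phase * protocol$T_s,
                              onsets)))  # stimulus phases and pause ends
    traj <- evolve(p, protocol, t_end = protocol_end(protocol),
                   sample_times = sample_t)
    rec <- info_record(traj, quad_n)
    resp <- peak_responses(traj, protocol, phase)
    hab <- habituation_time(resp, protocol)
    n_hab <- if (is.na(hab$n_hab)) length(resp) else hab$n_hab
    stim_rows <- rec[match(onsets + phase * protocol$T_s, rec$time), ]
    v_in <- stim_rows[1, ]; v_hab <- stim_rows[n_hab, ]
    data.frame(beta = grid$beta[i], sigma = grid$sigma[i],
               I_in = v_in$I_UH, I_hab = v_hab$I_UH,
               dI = v_hab$I_UH - v_in$I_UH,
               dIf_in = v_in$DeltaI_f, dIf_hab = v_hab$DeltaI_f,
               ddIf = v_hab$DeltaI_f - v_in$DeltaI_f,
               J_in = v_in$J_int, J_hab = v_hab$J_int,
               dJ = v_hab$J_int - v_in$J_int,
               dU = v_hab$U_mean - v_in$U_mean,
               dIf_min = min(rec$DeltaI_f),
               n_hab = if (is.na(hab$n_hab)) NA_integer_ else hab$n_hab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
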