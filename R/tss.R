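# Timescale-separation (TSS) solution of the master equation.
#
# With tau_U << tau_R << tau_S ~ tau_H, the readout relaxes to its
# conditional stationary law given the receptor, the receptor to its
# conditional stationary law given storage and signal, and the slow joint
# law p_{U,S}(u, s, t) obeys a Chapman-Kolmogorov recursion: one step
# propagates the storage at frozen readout and then redresses (u, r) with
# the conditional stationary laws under the signal law of the new time.

#' Readout grid upper bound
#'
#' Truncation rule for the readout axis:
#' \code{ceil(m + 8 sqrt(m))} with \code{m} the largest conditional mean.
#' @param params a \code{habinfo_params}.
#' @return integer upper bound of the u grid.
#' @export
u_grid_max <- function(params) {
  m <- max(params$U_mean_passive, params$U_mean_active)
  as.integer(ceiling(m + 8 * sqrt(m)))
}

#' Stationary readout law given the receptor state
#'
#' The readout birth-death process at fixed receptor state has a Poisson
#' stationary law with mean \code{exp(-beta (V - c r))}; this returns it
#' renormalized on the truncated grid \code{0:U_max}.
#'
#' @param params a \code{habinfo_params}.
#' @param r receptor state, 0 or 1.
#' @param U_max grid upper bound; defaults to \code{\link{u_grid_max}}.
#' @param max_truncated largest admissible probability mass beyond the grid.
#' @return numeric vector of probabilities over \code{0:U_max}.
#' @export
readout_stationary_given_r <- function(params, r, U_max = u_grid_max(params),
                                       max_truncated = 1e-8) {
  if (!r %in% c(0, 1)) stop("domain error: r must be 0 or 1")
  mu <- exp(-params$beta * (params$V - params$c * r))
  lost <- stats::ppois(U_max, mu, lower.tail = FALSE)
  if (lost > max_truncated)
    stop("grid-too-small error: truncated readout mass ", signif(lost, 3),
         " exceeds ", max_truncated, " (increase U_max)")
  p <- stats::dpois(0:U_max, mu)
  p / sum(p)
}

#' Storage propagator over a short interval
#'
#' Conditional law of the storage after a time \code{dt} at frozen readout
#' \code{u0}, starting from \code{s0}.  The generator (birth
#' \code{u0 exp(-beta sigma) Gamma_S0}, death \code{s Gamma_S0}, capacity
#' cap at \code{N_S}, diagonal set to minus the column sums so probability
#' is conserved) is restricted to the \code{n}-nearest neighbors of
#' \code{s0} and solved by eigendecomposition, the expansion coefficients
#' matching the delta initial condition.
#'
#' @param params a \code{habinfo_params}.
#' @param u0 frozen readout count, >= 0.
#' @param s0 initial storage count in \code{[0, N_S]}.
#' @param dt time step, >= 0.  Must satisfy the jump rule
#'   (largest single-jump rate) * dt <= 0.2; larger steps must be
#'   subdivided by the caller.
#' @param n neighborhood truncation radius.
#' @return numeric vector of probabilities over \code{0:N_S}, supported on
#'   \code{|s - s0| <= n}.
#' @export
storage_propagator <- function(params, u0, s0, dt, n = 2) {
  if (u0 < 0) stop("domain error: u0 must be >= 0")
  if (s0 < 0 || s0 > params$N_S) stop("domain error: s0 must lie in [0, N_S]")
  if (dt < 0) stop("domain error: dt must be >= 0")
  NS <- params$N_S
  out <- numeric(NS + 1)
  if (dt == 0) {
    out[s0 + 1] <- 1
    return(out)
  }
  lo <- max(0L, s0 - n); hi <- min(NS, s0 + n)
  states <- lo:hi
  b <- u0 * exp(-params$beta * params$sigma) * params$Gamma_S0
  death <- states * params$Gamma_S0
  birth <- ifelse(states < NS, b, 0)
  max_rate <- max(birth, death)
  if (max_rate * dt > 0.2 + 1e-12)
    stop("step-too-large error: max jump rate * dt = ",
         signif(max_rate * dt, 3), " > 0.2; subdivide the step")
  m <- length(states)
  G <- matrix(0, m, m)
  for (i in seq_len(m)) {
    if (i < m && birth[i] > 0) G[i + 1, i] <- birth[i]
    if (i > 1) G[i - 1, i] <- death[i]
  }
  diag(G) <- -colSums(G)
  eg <- eigen(G)
  e0 <- numeric(m); e0[s0 - lo + 1] <- 1
  a <- solve(eg$vectors, e0)
  pw <- Re(eg$vectors %*% (exp(eg$values * dt) * a))
  pw[pw < 0 & pw > -1e-12] <- 0
  if (any(pw < 0))
    stop("propagator produced a negative probability: ", min(pw))
  if (abs(sum(pw) - 1) > 1e-8)
    stop("propagator mass defect ", signif(abs(sum(pw) - 1), 3))
  out[states + 1] <- pw
  out
}

# Banded propagator tables P(s0 -> s0 + k | u) for all u on the grid and all
# s0, computed in compiled code; band k runs over -n..n.  Keyed caches are
# held in a solver cache environment (see .solver_cache).
.propagator_bands <- function(params, dt, U_max, n = 2) {
  b_of_u <- (0:U_max) * exp(-params$beta * params$sigma) * params$Gamma_S0
  max_rate <- max(max(b_of_u), params$N_S * params$Gamma_S0)
  if (max_rate * dt > 0.2 + 1e-9)
    stop("step-too-large error: max jump rate * dt = ",
         signif(max_rate * dt, 3), " > 0.2; subdivide the step")
  bands <- hab_prop_bands(b_of_u, params$N_S, params$Gamma_S0, dt, n)
  names(bands) <- as.character(seq(-n, n))
  bands
}

#' Largest admissible Chapman-Kolmogorov step
#'
#' Step-size policy: the largest storage jump rate on the grid times the
#' step must not exceed 0.2 (so the n-neighbor propagator truncation is
#' accurate), and the step must resolve the protocol windows.
#'
#' @param params a \code{habinfo_params}.
#' @param protocol optional \code{habinfo_protocol} whose windows must be
#'   resolved (at least 10 steps per stimulus and pause).
#' @return a positive time step.
#' @export
max_step <- function(params, protocol = NULL) {
  U_max <- u_grid_max(params)
  max_rate <- max(U_max * exp(-params$beta * params$sigma),
                  params$N_S) * params$Gamma_S0
  dt <- 0.2 / max_rate
  if (!is.null(protocol)) {
    dt <- min(dt, protocol$T_s / 10,
              if (protocol$Delta_T > 0) protocol$Delta_T / 10 else Inf)
  }
  dt
}

#' Joint readout-storage distribution
#'
#' Container for the solver state \code{p_{U,S}(u, s, t)} on the truncated
#' grid.
#'
#' @param values matrix of probabilities, rows indexed by \code{u = 0:U_max},
#'   columns by \code{s = 0:N_S}; must be nonnegative and sum to 1 within
#'   1e-10.
#' @param time current time.
#' @return an object of class \code{"habinfo_joint"}.
#' @export
joint_distribution <- function(values, time = 0) {
  stopifnot(is.matrix(values), all(values >= 0))
  if (abs(sum(values) - 1) > 1e-10)
    stop("joint distribution must sum to 1 (defect ",
         signif(abs(sum(values) - 1), 3), ")")
  structure(list(values = values,
                 grid_u = 0:(nrow(values) - 1L),
                 grid_s = 0:(ncol(values) - 1L),
                 time = time),
            class = "habinfo_joint")
}

#' @export
print.habinfo_joint <- function(x, ...) {
  m <- joint_means(x)
  cat(sprintf(
    "Joint p(U,S) on [0,%d] x [0,%d] at t = %g:  <U> = %.3f, <S> = %.3f\n",
    max(x$grid_u), max(x$grid_s), x$time, m["U"], m["S"]))
  invisible(x)
}

#' Means of a joint distribution
#' @param p a \code{habinfo_joint}.
#' @return named vector with components \code{U} and \code{S}.
#' @export
joint_means <- function(p) {
  c(U = sum(rowSums(p$values) * p$grid_u),
    S = sum(colSums(p$values) * p$grid_s))
}

#' Storage marginal of a joint distribution
#' @param p a \code{habinfo_joint}.
#' @return numeric vector of probabilities over \code{0:N_S}.
#' @export
storage_marginal <- function(p) colSums(p$values)

# Signal-averaged activation profile a(s) = E_h[p_A(s, h)] for s = 0..N_S.
.activation_profile <- function(params, lambda, quad_n = 512) {
  quad <- signal_quadrature(lambda, quad_n)
  s <- 0:params$N_S
  pa <- outer(s, quad$h, function(ss, hh)
    receptor_stationary_given_sh(params, ss, hh))
  as.vector(pa %*% quad$w)
}

# Conditional readout law given storage, averaged over the signal law:
# phi(u | s) = (1 - a(s)) Pois_passive(u) + a(s) Pois_active(u).
.phi_bar <- function(params, lambda, U_max, quad_n = 512) {
  a <- .activation_profile(params, lambda, quad_n)
  p0 <- readout_stationary_given_r(params, 0, U_max)
  p1 <- readout_stationary_given_r(params, 1, U_max)
  outer(p0, 1 - a) + outer(p1, a)
}

# Solver cache: propagator bands keyed by dt, conditional laws keyed by
# lambda, all for one parameter set and grid.
.solver_cache <- function(params, U_max = u_grid_max(params), quad_n = 512,
                          n_band = 2) {
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$U_max <- U_max
  env$quad_n <- quad_n
  env$n_band <- n_band
  env$bands <- list()
  env$phi <- list()
  env
}

.cache_bands <- function(cache, dt) {
  key <- sprintf("%.12g", dt)
  b <- cache$bands[[key]]
  if (is.null(b)) {
    b <- .propagator_bands(cache$params, dt, cache$U_max, cache$n_band)
    cache$bands[[key]] <- b
  }
  b
}

.cache_phi <- function(cache, lambda) {
  key <- sprintf("%.12g", lambda)
  f <- cache$phi[[key]]
  if (is.null(f)) {
    f <- .phi_bar(cache$params, lambda, cache$U_max, cache$quad_n)
    cache$phi[[key]] <- f
  }
  f
}

# One storage-propagation sweep: q(s) = sum_{s', u'} P(s' -> s | u') p(u', s').
.propagate_storage <- function(P, bands, n_band) {
  NS1 <- ncol(P)
  q <- numeric(NS1)
  for (k in -n_band:n_band) {
    tmp <- colSums(bands[[as.character(k)]] * P)
    src <- seq_len(NS1)
    dst <- src + k
    ok <- dst >= 1 & dst <= NS1
    q[dst[ok]] <- q[dst[ok]] + tmp[src[ok]]
  }
  q
}

#' One Chapman-Kolmogorov step of the joint law
#'
#' Propagates the storage at frozen readout over \code{dt} and redresses
#' the fast variables with their conditional stationary laws under the
#' signal law of the new time:
#' \deqn{p'(u, s) = \sum_r \int dh\, p^{st}_{U|R}(u|r)\,
#'   p^{st}_{R|S,H}(r|s,h)\, p_H(h) \sum_{s', u'} P(s' \to s | u')\,
#'   p(u', s').}
#' The signal integral uses the shared Gauss-Laguerre quadrature.  The
#' output is renormalized; a mass defect beyond 1e-8 is an error.
#'
#' @param params a \code{habinfo_params}.
#' @param p a \code{habinfo_joint}.
#' @param mean_signal_next mean of the exponential signal law at the end of
#'   the step.
#' @param dt step size obeying the jump rule (see \code{\link{max_step}}).
#' @param cache optional solver cache (created internally when omitted;
#'   reuse across steps for speed).
#' @return the advanced \code{habinfo_joint}.
#' @export
step_joint <- function(params, p, mean_signal_next, dt, cache = NULL) {
  if (is.null(cache))
    cache <- .solver_cache(params, U_max = nrow(p$values) - 1L)
  bands <- .cache_bands(cache, dt)
  phi <- .cache_phi(cache, 1 / mean_signal_next)
  q <- .propagate_storage(p$values, bands, cache$n_band)
  vals <- phi * rep(q, each = nrow(phi))
  tot <- sum(vals)
  if (abs(tot - 1) > 1e-8)
    stop("normalization defect ", signif(abs(tot - 1), 3),
         " after step (grid too small or step too large)")
  attr_defect <- abs(tot - 1)
  out <- joint_distribution(vals / tot, time = p$time + dt)
  attr(out, "norm_defect") <- attr_defect
  out
}

#' Evolve the joint law through a stimulation protocol
#'
#' Iterates \code{\link{step_joint}} from the stationary state under the
#' background signal through the square-wave protocol, recording the mean
#' readout and storage at every step and full distribution snapshots at
#' requested times.  Stimulus onsets and window ends are always resolved
#' exactly; within a segment of constant signal the step size is the
#' largest admissible one (see \code{\link{max_step}}).
#'
#' @param params a \code{habinfo_params}.
#' @param protocol a \code{habinfo_protocol}.
#' @param t_end final time; defaults to the end of the last stimulus plus
#'   one pause.
#' @param dt target step size; defaults to \code{max_step(params, protocol)}.
#' @param sample_times times at which full joint snapshots are stored
#'   (rounded onto step boundaries; stimulus onsets and ends are included
#'   automatically).
#' @param init optional initial \code{habinfo_joint}; defaults to the
#'   stationary state under \code{H_min}.
#' @param quad_check if \code{TRUE}, verify quadrature convergence for each
#'   distinct signal level before running.
#' @return an object of class \code{"habinfo_trajectory"}: a list with
#'   \code{times}, \code{U_mean}, \code{S_mean}, \code{snapshots} (named by
#'   time), the protocol, the effective parameters and the step policy.
#' @export
#' @examples
#' \donttest{
#' p <- model_params(beta = 3, sigma = 0.6)
#' pr <- signal_protocol(n_stimuli = 5)
#' tr <- evolve(p, pr)
#' peak_responses(tr, pr)
#' }
evolve <- function(params, protocol, t_end = NULL, dt = NULL,
                   sample_times = NULL, init = NULL, quad_check = FALSE) {
  params <- protocol_params(params, protocol)
  if (is.null(dt)) dt <- max_step(params, protocol)
  onsets <- stimulus_onsets(protocol)
  if (is.null(t_end)) t_end <- protocol_end(protocol) + protocol$Delta_T
  if (!is.null(sample_times) &&
      (any(sample_times < 0) || any(sample_times > t_end)))
    stop("sample_times must lie in [0, t_end]")
  breaks <- sort(unique(c(0, onsets, onsets + protocol$T_s, sample_times,
                          t_end)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]
  cache <- .solver_cache(params)
  if (quad_check) {
    for (H in unique(c(protocol$H_min, protocol$H_max))) {
      lam <- 1 / H
      .quad_converged(function(q) {
        pa <- outer(0:params$N_S, q$h, function(ss, hh)
          receptor_stationary_given_sh(params, ss, hh))
        as.vector(pa %*% q$w)
      }, lam, cache$quad_n)
    }
  }
  # initial condition computed with the same step the iteration uses, so
  # a flat protocol stays exactly at its fixed point
  if (is.null(init)) init <- stationary_solve(params, protocol$H_min,
                                              dt = dt)
  p <- init
  p$time <- 0
  n_rec <- 1L
  times <- numeric(0); Us <- numeric(0); Ss <- numeric(0)
  m <- joint_means(p)
  times <- 0; Us <- m["U"]; Ss <- m["S"]
  snapshots <- list()
  want_snap <- if (is.null(sample_times)) numeric(0) else sort(sample_times)
  if (0 %in% want_snap) snapshots[["0"]] <- p
  max_defect <- 0
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    if (b <= a) next
    lam <- 1 / mean_signal(protocol, a)  # signal law on [a, b)
    nsub <- max(1L, ceiling((b - a) / dt))
    h <- (b - a) / nsub
    for (j in seq_len(nsub)) {
      p <- step_joint(params, p, 1 / lam, h, cache)
      max_defect <- max(max_defect, attr(p, "norm_defect"))
      m <- joint_means(p)
      times <- c(times, p$time); Us <- c(Us, m[["U"]]); Ss <- c(Ss, m[["S"]])
    }
    p$time <- b  # guard against float drift at segment boundaries
    times[length(times)] <- b
    if (any(abs(want_snap - b) < 1e-9)) snapshots[[sprintf("%.6g", b)]] <- p
  }
  structure(list(times = as.numeric(times), U_mean = as.numeric(Us),
                 S_mean = as.numeric(Ss),
                 snapshots = snapshots, sample_times = want_snap,
                 protocol = protocol, params = params, dt = dt,
                 U_max = cache$U_max, norm_defect_max = max_defect,
                 final = p),
            class = "habinfo_trajectory")
}

#' @export
print.habinfo_trajectory <- function(x, ...) {
  cat(sprintf(
    "TSS trajectory: %d steps to t = %g, %d snapshots, dt = %.4g\n",
    length(x$times) - 1, max(x$times), length(x$snapshots), x$dt))
  invisible(x)
}

#' Stationary joint law under a constant signal
#'
#' Fixed point of the Chapman-Kolmogorov step under a constant mean signal.
#' Within a constant-signal segment the storage marginal evolves linearly,
#' \code{q <- A q} with a column-stochastic kernel \code{A}; the fixed point
#' is the Perron eigenvector of \code{A}, refined by power iteration, and
#' the joint law is the eigenvector dressed with the conditional readout
#' law.
#'
#' @param params a \code{habinfo_params}.
#' @param H_st constant mean signal, > 0.
#' @param dt step used to build the kernel; defaults to
#'   \code{max_step(params)}.
#' @param tol residual tolerance: the one-step total-variation change of
#'   the returned state must be below this.
#' @param max_iter power-iteration budget after the eigensolve.
#' @return a \code{habinfo_joint} with attributes \code{residual} (one-step
#'   total-variation change) and \code{lambda} (signal rate).
#' @export
stationary_solve <- function(params, H_st, dt = NULL, tol = 1e-9,
                             max_iter = 256) {
  stopifnot(H_st > 0)
  if (is.null(dt)) dt <- max_step(params)
  cache <- .solver_cache(params)
  bands <- .cache_bands(cache, dt)
  phi <- .cache_phi(cache, 1 / H_st)
  NS1 <- params$N_S + 1L
  A <- matrix(0, NS1, NS1)
  for (k in -cache$n_band:cache$n_band) {
    tmp <- colSums(bands[[as.character(k)]] * phi)  # per source column s'
    src <- seq_len(NS1); dst <- src + k
    ok <- dst >= 1 & dst <= NS1
    A[cbind(dst[ok], src[ok])] <- A[cbind(dst[ok], src[ok])] + tmp[src[ok]]
  }
  # Perron eigenvector of the (column-substochastic up to truncation) kernel
  eg <- eigen(A)
  i <- which.max(Re(eg$values))
  q <- Re(eg$vectors[, i])
  if (sum(q) < 0) q <- -q
  q[q < 0] <- 0
  q <- q / sum(q)
  res <- Inf
  for (it in seq_len(max_iter)) {
    q2 <- as.vector(A %*% q)
    q2 <- q2 / sum(q2)
    res <- 0.5 * sum(abs(q2 - q))
    q <- q2
    if (res < tol / 4) break
  }
  if (res > tol)
    stop("convergence error: stationary solve residual ", signif(res, 3),
         " > ", tol)
  vals <- phi * rep(q, each = nrow(phi))
  out <- joint_distribution(vals / sum(vals), time = 0)
  attr(out, "residual") <- res
  attr(out, "lambda") <- 1 / H_st
  out
}
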