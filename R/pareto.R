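# Stationary information-dissipation Pareto optimization over the inverse
# temperature beta and the storage cost sigma.  For a prolonged constant
# signal the objectives are the stationary readout-signal information
# I_st and the total energy consumption per unit energy
# E_tot = deltaQ_R + E_int, with E_int the storage-production energy
# consumption rate times tau_S.

#' Stationary information and dissipation objectives
#'
#' Solves the stationary state under a constant mean signal and returns
#' the stationary mutual information \code{I_st} (nats), the receptor
#' dissipation \code{dQ_R_st}, the storage energy consumption
#' \code{E_int_st = tau_S * J_prod / sigma} with \code{J_prod} the one-way
#' production flux (see \code{\link{internal_flux}}; the net flux vanishes
#' identically at a one-dimensional birth-death stationary state), and
#' their sum \code{E_tot_st}.
#'
#' @param params a \code{habinfo_params}.
#' @param H_st constant mean signal.
#' @param flux_mode \code{"production"} (default) or \code{"net"} for the
#'   storage term.
#' @param quad_n quadrature order.
#' @return named vector \code{c(I_st, dQ_R_st, E_int_st, E_tot_st,
#'   S_mean)}.
#' @export
stationary_objectives <- function(params, H_st,
                                  flux_mode = c("production", "net"),
                                  quad_n = 512) {
  flux_mode <- match.arg(flux_mode)
  st <- stationary_solve(params, H_st)
  I_st <- mutual_information_UH(params, storage_marginal(st), 1 / H_st,
                                U_max = max(st$grid_u), quad_n = quad_n)
  mS <- joint_means(st)[["S"]]
  dQ <- receptor_dissipation(params, H_st, mS)
  J <- internal_flux(params, st, mode = flux_mode)
  E_int <- params$tau_S * J / params$sigma
  c(I_st = I_st, dQ_R_st = dQ, E_int_st = E_int,
    E_tot_st = dQ + E_int, S_mean = mS)
}

# Evaluate the objectives over a (beta, sigma) grid; kappa follows the
# reference signal unless kappa_of_H gives the adaptive rule target.
.objective_grid <- function(beta_grid, sigma_grid, H_st, base_params = NULL,
                            kappa_H = NULL, flux_mode = "production",
                            quad_n = 512) {
  grid <- expand.grid(beta = beta_grid, sigma = sigma_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$beta[i]; s <- grid$sigma[i]
    p <- if (is.null(base_params)) model_params(beta = b, sigma = s) else {
      bp <- base_params; bp$beta <- b; bp$sigma <- s; bp$kappa <- NULL
      derive_energies(bp)
    }
    if (!is.null(kappa_H)) p$kappa <- kappa_H / (p$alpha * p$sigma)
    obj <- tryCatch(
      stationary_objectives(p, H_st, flux_mode, quad_n),
      error = function(e) c(I_st = NA_real_, dQ_R_st = NA_real_,
                            E_int_st = NA_real_, E_tot_st = NA_real_,
                            S_mean = NA_real_))
    data.frame(beta = b, sigma = s, t(obj))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logit-spaced trade-off weights
#'
#' Weights in (0, 1), plus the exact endpoints 0 and 1, spaced uniformly
#' in \code{log(gamma/(1 - gamma))}; see \code{\link{pareto_front}} for
#' why uniform spacing is uninformative here.
#'
#' @param n number of weights.
#' @param ratio_range range of \code{gamma/(1 - gamma)} covered
#'   (log10 units).
#' @return increasing numeric vector of weights in \code{[0, 1]}.
#' @export
gamma_grid_logit <- function(n = 101, ratio_range = c(-3, 4)) {
  r <- 10^seq(ratio_range[1], ratio_range[2], length.out = n - 2L)
  c(0, r / (1 + r), 1)
}

#' Non-dominated subset in the (energy, information) plane
#'
#' A point dominates another if it has no larger energy consumption and
#' no smaller information, with at least one strict inequality.  The
#' subset is found by an energy-sorted sweep; points with \code{NA}
#' objectives are never selected.
#'
#' @param E,I numeric vectors of energy consumption and information.
#' @return logical vector: \code{TRUE} for non-dominated points.
#' @export
nondominated <- function(E, I) {
  n <- length(E)
  keep <- rep(FALSE, n)
  ok <- which(is.finite(E) & is.finite(I))
  ord <- ok[order(E[ok], -I[ok])]
  best <- -Inf
  prev_E <- NA_real_; prev_I <- NA_real_
  for (i in ord) {
    if (I[i] > best ||
        (identical(I[i], prev_I) && identical(E[i], prev_E))) {
      keep[i] <- TRUE
      best <- max(best, I[i])
      prev_E <- E[i]; prev_I <- I[i]
    }
  }
  keep
}

#' Pareto front of the information-dissipation trade-off
#'
#' For every trade-off weight \code{gamma} in \code{[0, 1]}, finds the
#' grid maximizer of the Pareto functional
#' \code{L(beta, sigma) = gamma I_st - (1 - gamma) E_tot_st}; the
#' de-duplicated maximizers, with their \code{(E_tot_st, I_st)}
#' coordinates, form the optimal front.  At \code{gamma = 1} (0) this
#' recovers the global information maximizer (energy minimizer).
#'
#' @param beta_grid,sigma_grid parameter grids.
#' @param gamma_grid trade-off weights in \code{[0, 1]}.  The default is
#'   logit-spaced: the energy objective is one to two orders of magnitude
#'   larger than the information, so uniformly spaced weights place almost
#'   every maximizer at one of the two extreme points; spacing the weights
#'   uniformly in \code{log(gamma/(1-gamma))} resolves the whole front.
#' @param H_st constant mean signal.
#' @param base_params optional template parameter set.
#' @param kappa_H if non-\code{NULL}, the inhibition strength is tuned to
#'   this signal value, \code{kappa = kappa_H/(alpha sigma)} (the adaptive
#'   rule); default keeps the reference-signal value.
#' @param flux_mode storage energy term convention.
#' @param quad_n quadrature order.
#' @return an object of class \code{"habinfo_pareto"}: list with
#'   \code{front} (one row per gamma: gamma, beta, sigma, I_st, E_tot_st,
#'   L), \code{objectives} (the full grid table) and the call settings.
#' @export
pareto_front <- function(beta_grid = seq(1, 5, by = 0.125),
                         sigma_grid = seq(0.05, 1.5, by = 0.025),
                         gamma_grid = gamma_grid_logit(),
                         H_st = 10, base_params = NULL, kappa_H = NULL,
                         flux_mode = "production", quad_n = 512) {
  stopifnot(length(beta_grid) > 0, length(sigma_grid) > 0,
            length(gamma_grid) > 0, all(gamma_grid >= 0 & gamma_grid <= 1))
  obj <- .objective_grid(beta_grid, sigma_grid, H_st, base_params, kappa_H,
                         flux_mode, quad_n)
  if (all(is.na(obj$I_st))) stop("all objectives are NaN on the grid")
  # objective scaled so gamma weighs comparable magnitudes, as printed:
  # both terms are already per unit energy / temperature
  front <- do.call(rbind, lapply(gamma_grid, function(g) {
    L <- g * obj$I_st - (1 - g) * obj$E_tot_st
    k <- which.max(L)
    data.frame(gamma = g, beta = obj$beta[k], sigma = obj$sigma[k],
               I_st = obj$I_st[k], E_tot_st = obj$E_tot_st[k], L = L[k])
  }))
  nd <- nondominated(obj$E_tot_st, obj$I_st)
  front_nd <- obj[nd, c("beta", "sigma", "I_st", "E_tot_st")]
  front_nd <- front_nd[order(front_nd$E_tot_st), , drop = FALSE]
  rownames(front_nd) <- NULL
  structure(list(front = front, front_nd = front_nd, objectives = obj,
                 H_st = H_st, kappa_H = kappa_H, flux_mode = flux_mode),
            class = "habinfo_pareto")
}

#' @export
print.habinfo_pareto <- function(x, ...) {
  u <- x$front_nd
  cat(sprintf("Pareto front at H_st = %g (%s kappa): %d points\n",
              x$H_st, if (is.null(x$kappa_H)) "reference" else "adaptive",
              nrow(u)))
  print(utils::head(u, 10))
  invisible(x)
}

#' Front points of a Pareto front
#'
#' The non-dominated set of the objective scatter (the Pareto front
#' proper), ordered by energy consumption.  The per-gamma maximizers of
#' the scalarized functional (\code{pf$front}) are the convex-hull subset
#' of these points.
#'
#' @param pf a \code{habinfo_pareto}.
#' @return data frame with columns beta, sigma, I_st, E_tot_st.
#' @export
front_points <- function(pf) pf$front_nd

#' Optimal storage cost at fixed inverse temperature
#'
#' For every beta represented on the front, the storage cost(s) sigma the
#' system should tune to: beta is set by the thermal environment, so the
#' front is naturally read as a map beta -> sigma.
#'
#' @param pf a \code{habinfo_pareto}.
#' @return data frame with columns beta, sigma_opt (mean of front sigmas
#'   at that beta), sigma_min, sigma_max.
#' @export
front_sigma_profile <- function(pf) {
  fp <- front_points(pf)
  out <- do.call(rbind, lapply(split(fp, fp$beta), function(d)
    data.frame(beta = d$beta[1], sigma_opt = mean(d$sigma),
               sigma_min = min(d$sigma), sigma_max = max(d$sigma))))
  rownames(out) <- NULL
  out[order(out$beta), , drop = FALSE]
}

#' Pareto fronts with signal-adapted inhibition
#'
#' Recomputes the Pareto front for several stimulus strengths with the
#' inhibition strength tuned to the signal,
#' \code{kappa = H_max/(alpha sigma)}, and reports collapse statistics.
#' The primary statistic compares the fronts where they live, in the
#' \code{(beta, sigma)} plane: the mean absolute difference of the
#' per-beta optimal sigma between fronts, averaged over the beta values
#' the fronts share.  A secondary statistic interpolates the fronts in
#' the \code{(E_tot, I)} plane and takes the maximum pairwise vertical
#' distance over the shared energy range; it is reported for reference
#' but is dominated by the curve endpoints on finite grids (a front that
#' reaches its grid boundary plunges at the edge of the overlap).
#'
#' @param H_max_list stimulus strengths.
#' @param beta_grid,sigma_grid,gamma_grid grids as in
#'   \code{\link{pareto_front}}.
#' @param base_params optional template parameters.
#' @param adaptive if \code{FALSE}, keeps the reference-signal inhibition
#'   (used to quantify the spread the adaptive rule removes).
#' @param flux_mode,quad_n as in \code{\link{pareto_front}}.
#' @return list with \code{fronts} (one \code{habinfo_pareto} per
#'   \code{H_max}), \code{collapse} (mean pairwise distance of the
#'   per-beta optimal sigma), \code{collapse_EI} (max pairwise
#'   interpolated information distance at matched energy) and
#'   \code{H_max_list}.
#' @export
adaptive_kappa_front <- function(H_max_list, beta_grid = seq(1, 5, by = 0.25),
                                 sigma_grid = seq(0.05, 1.5, by = 0.05),
                                 gamma_grid = gamma_grid_logit(51),
                                 base_params = NULL, adaptive = TRUE,
                                 flux_mode = "production", quad_n = 512) {
  stopifnot(length(H_max_list) >= 1)
  fronts <- lapply(H_max_list, function(H) {
    pareto_front(beta_grid, sigma_grid, gamma_grid, H_st = H,
                 base_params = base_params,
                 kappa_H = if (adaptive) H else NULL,
                 flux_mode = flux_mode, quad_n = quad_n)
  })
  names(fronts) <- as.character(H_max_list)
  collapse <- 0
  collapse_EI <- 0
  if (length(fronts) > 1) {
    profiles <- lapply(fronts, front_sigma_profile)
    curves <- lapply(fronts, function(pf) {
      u <- front_points(pf)
      u[!duplicated(u$E_tot_st), , drop = FALSE]
    })
    dsig <- numeric(0)
    for (i in seq_along(curves)) for (j in seq_along(curves)) {
      if (j <= i) next
      pa <- profiles[[i]]; pb <- profiles[[j]]
      common <- intersect(pa$beta, pb$beta)
      if (length(common)) {
        da <- pa$sigma_opt[match(common, pa$beta)]
        db <- pb$sigma_opt[match(common, pb$beta)]
        dsig <- c(dsig, abs(da - db))
      }
      a <- curves[[i]]; b <- curves[[j]]
      lo <- max(min(a$E_tot_st), min(b$E_tot_st))
      hi <- min(max(a$E_tot_st), max(b$E_tot_st))
      if (hi <= lo) next
      Eg <- seq(lo, hi, length.out = 50)
      Ia <- stats::approx(a$E_tot_st, a$I_st, Eg)$y
      Ib <- stats::approx(b$E_tot_st, b$I_st, Eg)$y
      collapse_EI <- max(collapse_EI, max(abs(Ia - Ib), na.rm = TRUE))
    }
    collapse <- if (length(dsig)) mean(dsig) else 0
  }
  list(fronts = fronts, collapse = collapse, collapse_EI = collapse_EI,
       H_max_list = H_max_list)
}
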