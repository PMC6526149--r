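#' Economic profit parameters
#'
#' @param w four cost weights (aniline, LiHMDS, o-FNB feeds; product), in
#'   cost units kg-1; defaults 10000, 25000, 12000, 450000.
#' @param M_LiNDPA molar mass of the product Li-NDPA, kg mol-1 (0.2202,
#'   C12H9LiN2O2).
#' @param rho_mixture reaction-mixture density, kg m-3.
#' @return list of class `profit_params`.
#' @export
profit_params <- function(w = c(10000, 25000, 12000, 450000),
                          M_LiNDPA = 0.2202, rho_mixture = 900) {
  stopifnot(length(w) == 4L, all(w > 0), rho_mixture > 0)
  structure(list(w = w, M_LiNDPA = M_LiNDPA, rho_mixture = rho_mixture),
            class = "profit_params")
}

#' Plant profit in cost units per hour
#'
#' `profit = w4 * M_LiNDPA * c_LiNDPA / rho_mixture * sum(u) - sum(w_i u_i)`
#' with the feed flowrates `u = (aniline, LiHMDS, oFNB)` in kg h-1 and the
#' measured product concentration in mol m-3.
#'
#' @param u length-3 feed flowrates, kg h-1, non-negative.
#' @param c_LiNDPA product concentration, mol m-3.
#' @param pp a [profit_params()].
#' @return profit, cost units h-1.
#' @export
profit <- function(u, c_LiNDPA, pp = profit_params()) {
  if (any(u < 0)) stop("negative feed flowrate", call. = FALSE)
  pp$w[4] * pp$M_LiNDPA * c_LiNDPA / pp$rho_mixture * sum(u) -
    sum(pp$w[1:3] * u)
}

#' RTO constraint set
#'
#' Box bounds on the three feed flowrates and the stoichiometric
#' requirement of at least 2 mol LiHMDS per mol aniline, expressed with
#' the configured (nominal) feed concentrations and densities.
#'
#' @param lower,upper box bounds on `u`, kg h-1.
#' @param ratio_min minimum LiHMDS:aniline molar feed ratio (default 2).
#' @param conc_aniline,conc_LiHMDS nominal feed concentrations, mol L-1.
#' @param dens_aniline,dens_LiHMDS feed densities, kg L-1.
#' @return list of class `rto_constraints`; `ratio_coef` is the molar
#'   ratio per unit `u2/u1`.
#' @export
rto_constraints <- function(lower = rep(0.5, 3), upper = rep(12, 3),
                            ratio_min = 2, conc_aniline = 0.96,
                            conc_LiHMDS = 1.10, dens_aniline = 0.90,
                            dens_LiHMDS = 0.90) {
  structure(list(lower = lower, upper = upper, ratio_min = ratio_min,
                 ratio_coef = (conc_LiHMDS / dens_LiHMDS) /
                   (conc_aniline / dens_aniline)),
            class = "rto_constraints")
}

molar_ratio <- function(u, cons) cons$ratio_coef * u[2] / u[1]

#' Solve the modified nominal optimization problem
#'
#' Maximizes `profit_model(u) + eps + lambda . (u - u_ref)` over the box
#' bounds intersected with an infinity-norm trust region around `u_ref`,
#' subject to the LiHMDS:aniline molar-ratio constraint.  The interior
#' problem is solved with L-BFGS-B; if its solution violates the ratio
#' constraint the problem is re-solved exactly on the constraint boundary
#' (`u2 = ratio_min / ratio_coef * u1`), so an active constraint holds
#' with equality.
#'
#' @param model_fn function `u -> c_LiNDPA` (mol m-3), the nominal model.
#' @param modifiers list with `eps` (profit bias) and `lambda`
#'   (length-3 gradient correction); zeros for plain model optimization.
#' @param u_ref current operating point (trust-region center and modifier
#'   anchor), kg h-1.
#' @param pp a [profit_params()].
#' @param cons an [rto_constraints()].
#' @param trust_radius infinity-norm trust radius, kg h-1.
#' @return list with `u` (the feasible maximizer), `value` (modified
#'   profit) and `active_ratio` (logical).
#' @export
nominal_optimize <- function(model_fn, modifiers = list(eps = 0, lambda = rep(0, 3)),
                             u_ref, pp = profit_params(),
                             cons = rto_constraints(), trust_radius = Inf) {
  lo <- pmax(cons$lower, u_ref - trust_radius)
  hi <- pmin(cons$upper, u_ref + trust_radius)
  if (any(lo > hi)) stop("infeasible trust region / box intersection",
                         call. = FALSE)
  obj <- function(u) {
    -(profit(u, model_fn(u), pp) + modifiers$eps +
        sum(modifiers$lambda * (u - u_ref)))
  }
  u0 <- pmin(pmax(u_ref, lo), hi)
  # the stoichiometric min() terms make the model profit piecewise smooth;
  # multi-start keeps L-BFGS-B from stalling on a kink at the start point
  starts <- list(u0, (lo + hi) / 2, lo + 0.8 * (hi - lo), lo + 0.2 * (hi - lo))
  sol <- NULL
  for (s in starts) {
    cand <- stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                         control = list(factr = 1e4, maxit = 500))
    if (is.null(sol) || cand$value < sol$value) sol <- cand
  }
  u_star <- sol$par
  if (molar_ratio(u_star, cons) >= cons$ratio_min - 1e-9)
    return(list(u = u_star, value = -sol$value, active_ratio = FALSE))
  # re-solve on the active ratio boundary: u2 = r0 * u1
  r0 <- cons$ratio_min / cons$ratio_coef
  if (cons$lower[1] * r0 > cons$upper[2])
    stop("infeasible constraint set: molar-ratio bound cannot be met ",
         "inside the box (active: ratio, u1 lower, u2 upper)", call. = FALSE)
  lo1 <- max(lo[1], lo[2] / r0); hi1 <- min(hi[1], hi[2] / r0)
  if (lo1 > hi1) {
    # the ratio boundary is outside the trust region (e.g. start-up from a
    # sub-stoichiometric point): take the step that restores feasibility
    # fastest, optimizing the remaining free flowrate
    u1r <- lo[1]; u2r <- hi[2]
    o3 <- stats::optimize(function(z) obj(c(u1r, u2r, z)), c(lo[3], hi[3]))
    return(list(u = c(u1r, u2r, o3$minimum), value = -o3$objective,
                active_ratio = NA, restoration = TRUE))
  }
  obj2 <- function(v) obj(c(v[1], r0 * v[1], v[2]))
  lo2d <- c(lo1, lo[3]); hi2d <- c(hi1, hi[3])
  starts2 <- list(c(min(max(u0[1], lo1), hi1), u0[3]), (lo2d + hi2d) / 2,
                  lo2d + 0.8 * (hi2d - lo2d), lo2d + 0.2 * (hi2d - lo2d))
  sol2 <- NULL
  for (s in starts2) {
    cand <- stats::optim(s, obj2, method = "L-BFGS-B",
                         lower = lo2d, upper = hi2d,
                         control = list(factr = 1e4, maxit = 500))
    if (is.null(sol2) || cand$value < sol2$value) sol2 <- cand
  }
  u2 <- c(sol2$par[1], r0 * sol2$par[1], sol2$par[2])
  list(u = u2, value = -sol2$value, active_ratio = TRUE)
}

# Quadratic monomial design in 3 variables: 1, z1..z3, z1^2.., cross terms.
quad_design <- function(Z) {
  cbind(1, Z,
        Z[, 1]^2, Z[, 2]^2, Z[, 3]^2,
        Z[, 1] * Z[, 2], Z[, 1] * Z[, 3], Z[, 2] * Z[, 3])
}

#' Plant-gradient estimate from a quadratic surrogate
#'
#' Fits a full quadratic model of the measured profit to the history
#' points inside `regression_radius` of the current point (screened for
#' poisedness: pairwise spacing and the condition number of the scaled
#' design matrix) and returns its analytic gradient at `u_current`.  With
#' fewer than 10 usable points or an ill-conditioned design it instead
#' requests probing moves.
#'
#' @param history `data.frame`/matrix with columns `u1,u2,u3,profit`.
#' @param u_current length-3 evaluation point.
#' @param regression_radius inclusion radius around `u_current`, kg h-1.
#' @param probe_step suggested probe step (per axis) if probing is
#'   needed.
#' @param max_condition largest accepted condition number of the design.
#' @return list: `need_probe` logical; if `FALSE`, `gradient`; if
#'   `TRUE`, `probe_points` (6 axis steps around `u_current`).
#' @export
estimate_gradient_quadratic <- function(history, u_current,
                                        regression_radius,
                                        probe_step = 0.15,
                                        max_condition = 1e8) {
  H <- as.matrix(history[, c("u1", "u2", "u3")])
  p <- history$profit
  d <- sqrt(colSums((t(H) - u_current)^2))
  keep <- which(d <= regression_radius)
  # drop near-duplicate points (closer than 1e-8 of the radius)
  if (length(keep) > 1L) {
    Hk <- H[keep, , drop = FALSE]
    dup <- rep(FALSE, length(keep))
    for (i in seq_along(keep)[-1L]) {
      dd <- sqrt(rowSums((Hk[seq_len(i - 1L), , drop = FALSE] -
                            matrix(Hk[i, ], i - 1L, 3L, byrow = TRUE))^2))
      if (min(dd) < 1e-8 * regression_radius) dup[i] <- TRUE
    }
    keep <- keep[!dup]
  }
  probes <- function() {
    # 6 axis steps + 3 up- and 3 down-diagonal steps: with the center this
    # over-determines a quadratic in 3 variables, so the design stays
    # poised even when probes at an active bound reflect onto each other
    pts <- matrix(rep(u_current, 12L), ncol = 3L, byrow = TRUE)
    for (i in 1:3) {
      pts[2 * i - 1L, i] <- u_current[i] + probe_step
      pts[2 * i, i] <- u_current[i] - probe_step
    }
    diags <- list(c(1, 2), c(1, 3), c(2, 3))
    for (j in 1:3) {
      pts[6L + j, diags[[j]]] <- u_current[diags[[j]]] + probe_step
      pts[9L + j, diags[[j]]] <- u_current[diags[[j]]] - probe_step
    }
    list(need_probe = TRUE, probe_points = pts)
  }
  if (length(keep) < 10L) return(probes())
  Z <- sweep(H[keep, , drop = FALSE], 2L, u_current) / regression_radius
  X <- quad_design(Z)
  qr_x <- qr(X)
  if (qr_x$rank < 10L || kappa(X, exact = FALSE) > max_condition)
    return(probes())
  beta <- qr.coef(qr_x, p[keep])
  list(need_probe = FALSE,
       gradient = unname(beta[2:4]) / regression_radius,
       coefficients = beta, n_points = length(keep))
}

# Central-difference gradient of the nominal-model profit.
model_gradient <- function(model_fn, u, pp, h = 1e-4) {
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h * (1 + abs(u[i]))
    (profit(u + e, model_fn(u + e), pp) -
       profit(u - e, model_fn(u - e), pp)) / (2 * e[i])
  }, 0)
}

#' Modifier adaptation with quadratic approximation (MAWQA)
#'
#' Iterative economic optimization of a plant through a mismatched
#' nominal model.  Each iteration measures the plant at the current
#' point, estimates the plant profit gradient from a quadratic surrogate
#' over the operating-point history, corrects the nominal optimization
#' problem with a zeroth-order bias and a first-order gradient modifier,
#' and steps to the corrected optimum inside a trust region.  Probing
#' moves are performed at start-up (and whenever the surrogate is not
#' poised).  A persistent shift in the measured profit at the current
#' point (e.g. a feed-batch change) flushes the history, re-probes and
#' re-converges.
#'
#' @param plant function `(u, iteration) -> c_LiNDPA` (mol m-3): the
#'   measured plant response.
#' @param model_fn function `u -> c_LiNDPA`: the nominal model.
#' @param u0 starting flowrates, kg h-1 (default `c(3.58, 3.58, 3.58)`).
#' @param pp a [profit_params()].
#' @param cons an [rto_constraints()].
#' @param max_iter maximum MAWQA iterations after probing.
#' @param tol convergence tolerance on the step norm, kg h-1.
#' @param probe_frac probe step as a fraction of `u0` per axis.
#' @param trust_frac initial trust radius as a fraction of `||u0||`.
#' @param trust_min smallest trust radius.
#' @param disturb_tol relative profit shift at the current point that is
#'   treated as a plant disturbance.
#' @return `data.frame` trajectory (class `mawqa_trajectory`): iteration,
#'   `u1..u3`, `c_measured`, `profit_plant`, `profit_model`, `phase`;
#'   attributes `converged`, `u_final`, `profit_final`.
#' @export
run_mawqa <- function(plant, model_fn, u0 = c(3.58, 3.58, 3.58),
                      pp = profit_params(), cons = rto_constraints(),
                      max_iter = 30L, tol = 1e-3, probe_frac = 0.05,
                      trust_frac = 0.10, trust_min = 0.05,
                      disturb_tol = 0.01) {
  # u0 must lie in the box; it may violate the molar-ratio bound (the
  # plant is typically started sub-stoichiometric, far from the optimum)
  # and the optimizer then restores feasibility over the first steps
  if (any(u0 < cons$lower) || any(u0 > cons$upper))
    stop("u0 outside box bounds", call. = FALSE)
  trust0 <- trust_frac * sqrt(sum(u0^2))
  probe_step <- probe_frac * mean(u0)
  history <- data.frame(u1 = numeric(0), u2 = numeric(0), u3 = numeric(0),
                        c = numeric(0), profit = numeric(0))
  traj <- list()
  iter_global <- 0L
  measure <- function(u, phase) {
    iter_global <<- iter_global + 1L
    cc <- tryCatch(plant(u, iter_global), error = function(e)
      tryCatch(plant(u, iter_global), error = function(e2) NA_real_))
    if (!is.finite(cc))
      stop("plant evaluation failed twice at u = ",
           paste(signif(u, 4), collapse = ", "), call. = FALSE)
    pr <- profit(u, cc, pp)
    history[nrow(history) + 1L, ] <<- c(u, cc, pr)
    traj[[length(traj) + 1L]] <<- data.frame(
      iteration = iter_global, u1 = u[1], u2 = u[2], u3 = u[3],
      c_measured = cc, profit_plant = pr,
      profit_model = profit(u, model_fn(u), pp), phase = phase)
    pr
  }
  probe_around <- function(u) {
    feas <- function(v) all(v >= cons$lower) && all(v <= cons$upper) &&
      molar_ratio(v, cons) >= cons$ratio_min - 1e-9
    pts <- list()
    for (i in 1:3) for (s in c(1, -1)) {
      v <- u; v[i] <- v[i] + s * probe_step
      if (!feas(v)) { v <- u; v[i] <- v[i] - s * probe_step }
      pts[[length(pts) + 1L]] <- v
    }
    # three diagonal points for a poised quadratic design
    for (d in list(c(1, 2), c(1, 3), c(2, 3))) {
      v <- u; v[d] <- v[d] + probe_step
      if (!feas(v)) { v <- u; v[d] <- v[d] - probe_step }
      pts[[length(pts) + 1L]] <- v
    }
    for (v in pts) measure(v, "probe")
  }

  u_k <- u0
  p_k <- measure(u_k, "probe")
  probe_around(u_k)
  trust <- trust0
  converged <- FALSE
  rejected_run <- 0L
  for (k in seq_len(max_iter)) {
    # re-measure the current point: tracks disturbances, averages noise
    p_new <- measure(u_k, "recheck")
    if (abs(p_new - p_k) > disturb_tol * max(abs(p_k), 1)) {
      keep <- nrow(history)          # plant changed: discard stale history
      history <- history[keep, , drop = FALSE]
      trust <- trust0
      p_k <- p_new
      rejected_run <- 0L
      probe_around(u_k)
    } else p_k <- (p_k + p_new) / 2
    # keep the surrogate local: points much farther than the probe scale
    # belong to a different region of the (piecewise-smooth) profit surface
    radius <- max(min(2 * trust, 3 * probe_step), 2.2 * probe_step)
    g_est <- estimate_gradient_quadratic(history, u_k, radius,
                                         probe_step = probe_step)
    if (g_est$need_probe) {
      for (i in seq_len(nrow(g_est$probe_points))) {
        v <- g_est$probe_points[i, ]
        # reflect probes that leave the box (active bound at the center)
        out <- v > cons$upper | v < cons$lower
        v[out] <- 2 * u_k[out] - v[out]
        measure(pmin(pmax(v, cons$lower), cons$upper), "probe")
      }
      g_est <- estimate_gradient_quadratic(history, u_k, radius,
                                           probe_step = probe_step)
      if (g_est$need_probe) next
    }
    lambda <- g_est$gradient - model_gradient(model_fn, u_k, pp)
    eps <- p_k - profit(u_k, model_fn(u_k), pp)
    step <- nominal_optimize(model_fn, list(eps = eps, lambda = lambda),
                             u_k, pp, cons, trust_radius = trust)
    u_next <- step$u
    if (sqrt(sum((u_next - u_k)^2)) < tol) { converged <- TRUE; break }
    p_next <- measure(u_next, "optimize")
    if (isTRUE(step$restoration)) {
      u_k <- u_next; p_k <- p_next     # feasibility first, whatever the profit
      rejected_run <- 0L
    } else if (p_next >= p_k) {
      gain <- (p_next - p_k) / max(abs(p_k), 1)
      trust <- min(1.3 * trust, 2 * trust0)
      u_k <- u_next; p_k <- p_next
      # accepted but not improving measurably: cycling on a plateau
      rejected_run <- if (gain < 1e-6) rejected_run + 1L else 0L
    } else {
      trust <- max(0.5 * trust, trust_min)   # regression: shrink, stay
      rejected_run <- rejected_run + 1L
    }
    if (rejected_run >= 4L) {
      converged <- TRUE                # no measurable progress: plateau
      break
    }
  }
  out <- do.call(rbind, traj)
  attr(out, "converged") <- converged
  attr(out, "u_final") <- u_k
  attr(out, "profit_final") <- p_k
  attr(out, "molar_ratio_final") <- molar_ratio(u_k, cons)
  class(out) <- c("mawqa_trajectory", "data.frame")
  out
}

#' @export
print.mawqa_trajectory <- function(x, ...) {
  cat(sprintf("<MAWQA trajectory> %d plant evaluations, converged: %s\n",
              nrow(x), attr(x, "converged")))
  uf <- attr(x, "u_final")
  cat(sprintf("final u = (%.3f, %.3f, %.3f) kg/h, profit %.0f, molar ratio %.3f\n",
              uf[1], uf[2], uf[3], attr(x, "profit_final"),
              attr(x, "molar_ratio_final")))
  invisible(x)
}

#' Build a concentration-response function from the reactor model
#'
#' Returns `function(u, iteration)` mapping feed flowrates to the product
#' concentration in mol m-3 under the given plant parameters, optionally
#' with measurement noise and a feed-batch disturbance (the LiHMDS feed
#' concentration changing at a given evaluation index).
#'
#' @param params [plant_params()] of the responding plant.
#' @param noise_sd SD of multiplicative measurement noise on the
#'   concentration (0 = noiseless oracle mode).
#' @param batch_change optional `list(at = <evaluation index>,
#'   conc_LiHMDS = <new mol L-1>)`.
#' @param conc_LiHMDS initial LiHMDS feed concentration.
#' @return a plant/model response function.
#' @export
make_response_fn <- function(params = plant_params(), noise_sd = 0,
                             batch_change = NULL, conc_LiHMDS = 1.10) {
  function(u, iteration = NULL) {
    cl <- conc_LiHMDS
    if (!is.null(batch_change) && !is.null(iteration) &&
        iteration >= batch_change$at)
      cl <- batch_change$conc_LiHMDS
    feeds <- default_feeds(u = u, conc_LiHMDS = cl)
    cc <- reactor_steady_state(feeds, params)$concentrations[["LiNDPA"]]
    if (noise_sd > 0) cc <- cc * (1 + stats::rnorm(1, 0, noise_sd))
    cc
  }
}

#' Brute-force grid optimum of a plant response
#'
#' Evaluates the profit on a regular `n^3` grid over the feasible box
#' (points violating the molar-ratio constraint are skipped) and polishes
#' the best grid point with a bounded local search.  Used as the
#' independent reference optimum for MAWQA runs.
#'
#' @param response_fn function `u -> c_LiNDPA` (mol m-3), noiseless.
#' @param pp a [profit_params()].
#' @param cons an [rto_constraints()].
#' @param n grid points per axis (default 51).
#' @param polish logical: refine the best grid point locally.
#' @return list with `u`, `profit`.
#' @export
grid_search_optimum <- function(response_fn, pp = profit_params(),
                                cons = rto_constraints(), n = 51L,
                                polish = TRUE) {
  g1 <- seq(cons$lower[1], cons$upper[1], length.out = n)
  g2 <- seq(cons$lower[2], cons$upper[2], length.out = n)
  g3 <- seq(cons$lower[3], cons$upper[3], length.out = n)
  best <- list(profit = -Inf, u = NULL)
  for (a in g1) {
    u2min <- cons$ratio_min / cons$ratio_coef * a
    for (b in g2[g2 >= u2min - 1e-12]) {
      for (d in g3) {
        u <- c(a, b, d)
        pr <- profit(u, response_fn(u), pp)
        if (pr > best$profit) best <- list(profit = pr, u = u)
      }
    }
  }
  if (is.null(best$u)) stop("no feasible grid point", call. = FALSE)
  if (polish) {
    step <- nominal_optimize(response_fn, u_ref = best$u, pp = pp,
                             cons = cons, trust_radius = Inf)
    if (step$value > best$profit) best <- list(profit = step$value, u = step$u)
  }
  best
}
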