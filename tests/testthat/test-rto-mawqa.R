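test_that("profit evaluates the economic objective exactly", {
  pp <- profit_params()
  # direct arithmetic oracle at the start-up recipe with c = 500 mol/m3
  u <- c(3.68, 6.89, 5.60)
  revenue <- 450000 * 0.2202 * 500 / 900 * sum(u)
  cost <- sum(c(10000, 25000, 12000) * u)
  expect_equal(profit(u, 500, pp), revenue - cost, tolerance = 1e-12)
  expect_equal(profit(u, 500, pp), 613908.5, tolerance = 1e-4)
  # zero product: pure feed cost
  expect_equal(profit(u, 0, pp), -cost)
  # degree-1 homogeneity in u at fixed concentration
  expect_equal(profit(2 * u, 500, pp), 2 * profit(u, 500, pp),
               tolerance = 1e-9)
  expect_error(profit(c(-1, 2, 3), 500, pp), "negative")
})

test_that("nominal_optimize matches a grid oracle and lands on active constraints", {
  model_fn <- make_response_fn(plant_params())
  pp <- profit_params()
  cons <- rto_constraints()
  u_ref <- c(6, 11, 9)
  r <- 1.5
  step <- nominal_optimize(model_fn, u_ref = u_ref, pp = pp, cons = cons,
                           trust_radius = r)
  # brute-force oracle over the same trust box (with ratio filter)
  g <- expand.grid(u1 = seq(u_ref[1] - r, u_ref[1] + r, length.out = 21),
                   u2 = seq(u_ref[2] - r, min(u_ref[2] + r, 12), length.out = 21),
                   u3 = seq(u_ref[3] - r, u_ref[3] + r, length.out = 21))
  g <- g[cons$ratio_coef * g$u2 / g$u1 >= cons$ratio_min, ]
  pg <- apply(g, 1, function(u) profit(u, model_fn(u), pp))
  expect_gte(step$value, max(pg) - 1e-6 * abs(max(pg)))
  # unconstrained optimum below ratio 2: returned point sits at 2 exactly
  cheap <- function(u) 320 * sum(u)   # flat response: cost structure rules
  step2 <- nominal_optimize(cheap, u_ref = c(4, 4, 4), pp = pp, cons = cons,
                            trust_radius = 3)
  if (isTRUE(step2$active_ratio))
    expect_equal(molar_ratio <- cons$ratio_coef * step2$u[2] / step2$u[1],
                 2, tolerance = 1e-6)
  # globally infeasible set errors with an active-set report
  bad <- rto_constraints(lower = c(8, 0.5, 0.5), upper = c(12, 5, 12))
  expect_error(nominal_optimize(model_fn, u_ref = c(9, 4, 4), pp = pp,
                                cons = bad, trust_radius = 1),
               "active")
})

test_that("quadratic surrogate gradients are exact on quadratics", {
  set.seed(30)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  b <- rnorm(3)
  f <- function(u) -0.5 * drop(t(u) %*% A %*% u) + sum(b * u) + 7
  u0 <- c(4, 8, 6)
  pts <- t(replicate(14, u0 + runif(3, -0.5, 0.5)))
  hist <- data.frame(u1 = pts[, 1], u2 = pts[, 2], u3 = pts[, 3],
                     profit = apply(pts, 1, f))
  g <- estimate_gradient_quadratic(hist, u0, regression_radius = 1.5)
  expect_false(g$need_probe)
  expect_equal(g$gradient, drop(-A %*% u0 + b), tolerance = 1e-8)
  # degenerate history on a line requests probing moves
  line <- t(sapply(seq(0, 1, length.out = 12), function(a) u0 + a * c(1, 1, 1)))
  hist_l <- data.frame(u1 = line[, 1], u2 = line[, 2], u3 = line[, 3],
                       profit = apply(line, 1, f))
  gl <- estimate_gradient_quadratic(hist_l, u0, regression_radius = 3)
  expect_true(gl$need_probe)
  expect_gte(nrow(gl$probe_points), 9L)
})

test_that("gradient error shrinks with more noisy observations", {
  set.seed(31)
  A <- diag(c(2, 1, 3)); b <- c(1, -2, 0.5)
  f <- function(u) -0.5 * drop(t(u) %*% A %*% u) + sum(b * u)
  u0 <- c(1, 1, 1)
  g_true <- drop(-A %*% u0 + b)
  err <- function(n_pts) {
    mean(replicate(20, {
      pts <- t(replicate(n_pts, u0 + runif(3, -0.6, 0.6)))
      hist <- data.frame(u1 = pts[, 1], u2 = pts[, 2], u3 = pts[, 3],
                         profit = apply(pts, 1, f) + rnorm(n_pts, 0, 0.01))
      g <- estimate_gradient_quadratic(hist, u0, regression_radius = 1.5)
      if (g$need_probe) NA else sqrt(sum((g$gradient - g_true)^2))
    }), na.rm = TRUE)
  }
  e <- c(err(12), err(40), err(150))
  expect_true(all(diff(e) < 0))
})

test_that("modifiers transfer plant optimality onto the model", {
  # constructed smooth pair: with lambda equal to the exact gradient gap
  # at the plant optimum, the modified problem is stationary there
  pp <- profit_params()
  cons <- rto_constraints()
  plant_c <- function(u) 400 - 3 * (u[1] - 5)^2 - 2 * (u[2] - 10)^2 -
    2.5 * (u[3] - 7)^2
  model_c <- function(u) 380 - 2 * (u[1] - 4)^2 - 1.5 * (u[2] - 9)^2 -
    2 * (u[3] - 8)^2
  pf <- function(u) profit(u, plant_c(u), pp)
  # plant optimum by direct search (interior, ratio satisfied)
  opt <- optim(c(5, 10, 7), function(u) -pf(u), method = "L-BFGS-B",
               lower = cons$lower, upper = cons$upper)
  u_star <- opt$par
  num_grad <- function(f, u) vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- 1e-5
    (f(u + e) - f(u - e)) / 2e-5
  }, 0)
  lambda <- num_grad(pf, u_star) -
    num_grad(function(u) profit(u, model_c(u), pp), u_star)
  # u_star is a stationary point of the modified problem; within a small
  # trust region (where the modified objective is locally concave) the
  # corrected optimum must stay there
  step <- nominal_optimize(model_c, list(eps = 0, lambda = lambda),
                           u_ref = u_star, pp = pp, cons = cons,
                           trust_radius = 0.1)
  expect_equal(step$u, u_star, tolerance = 0.02)
})

test_that("run_mawqa finds the model optimum when plant equals model", {
  plant_fn <- make_response_fn(plant_params())
  opt <- grid_search_optimum(plant_fn, n = 21L)
  # start near the optimum: convergence in a few corrected steps
  u0 <- pmin(pmax(opt$u * 0.95, rto_constraints()$lower),
             rto_constraints()$upper)
  traj <- run_mawqa(function(u, k) plant_fn(u), plant_fn, u0 = u0,
                    max_iter = 10L)
  expect_equal(attr(traj, "profit_final"), opt$profit,
               tolerance = 0.01 * abs(opt$profit))
  n_opt_steps <- sum(traj$phase == "optimize")
  expect_lte(n_opt_steps, 5L)
})

test_that("mawqa closes the gap to the true plant optimum under mismatch", {
  plant_fn <- make_response_fn(true_plant_params())
  model_fn <- make_response_fn(plant_params())
  opt <- grid_search_optimum(plant_fn, n = 31L)
  traj <- run_mawqa(function(u, k) plant_fn(u), model_fn)
  expect_lt(abs(opt$profit - attr(traj, "profit_final")),
            0.01 * abs(opt$profit))
  expect_gte(attr(traj, "molar_ratio_final"), 2.0 - 1e-6)
  # every visited point honors the box
  expect_true(all(traj$u1 >= 0.5 & traj$u2 <= 12 & traj$u3 <= 12))
})

test_that("final profit never falls below the start across noisy seeds", {
  model_fn <- make_response_fn(plant_params())
  pp <- profit_params()
  for (s in 1:10) {
    set.seed(s)
    plant_fn <- make_response_fn(true_plant_params(), noise_sd = 0.01)
    traj <- run_mawqa(plant_fn, model_fn, max_iter = 12L)
    expect_gte(attr(traj, "profit_final"), traj$profit_plant[1])
  }
})
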