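test_that("reactor mole balances close to 1e-9 over random feeds", {
  set.seed(20)
  for (r in 1:25) {
    u <- runif(3, 0.5, 12)
    feeds <- default_feeds(u = u, conc_LiHMDS = runif(1, 0.9, 1.2))
    out <- reactor_steady_state(feeds, plant_params(
      k_sat = runif(1, 0.01, 0.3), moisture_sink = runif(1, 0, 0.8),
      mixing_eff = runif(1, 0.7, 1)))
    f <- out$molar_flows
    aryl <- f[["aniline"]] + f[["LiAniline"]] + f[["LiNDPA"]]
    expect_equal(aryl, feeds$aniline$molar_flow, tolerance = 1e-9)
    fluoro <- f[["oFNB"]] + f[["LiNDPA"]]
    expect_equal(fluoro, feeds$oFNB$molar_flow, tolerance = 1e-9)
    expect_true(all(out$concentrations >= 0))
  }
})

test_that("conversion saturates toward the stoichiometric limit", {
  # vast LiHMDS excess: conversion -> 1, product -> min(n_an, n_oFNB)
  feeds <- default_feeds(u = c(3.0, 500, 4.0))
  out <- reactor_steady_state(feeds, plant_params(moisture_sink = 0))
  pairmin <- min(feeds$aniline$molar_flow, feeds$oFNB$molar_flow)
  expect_equal(out$molar_flows[["LiNDPA"]], pairmin, tolerance = 0.01)
  # zero aniline: no product, no intermediate
  feeds0 <- default_feeds(u = c(0, 6.89, 5.60))
  out0 <- reactor_steady_state(feeds0)
  expect_equal(out0$molar_flows[["LiNDPA"]], 0, tolerance = 1e-6)
  expect_equal(out0$molar_flows[["LiAniline"]], 0, tolerance = 1e-12)
  expect_error(reactor_steady_state(default_feeds(u = c(0, 0, 0))), "zero")
})

test_that("start-up feeds reproduce a hand mole balance", {
  # independent spreadsheet-style oracle at the start-up recipe
  pars <- plant_params(k_sat = 0.05, moisture_sink = 0.3, smoothing = 0)
  out <- reactor_steady_state(default_feeds(), pars)
  n_an <- 3.68 / 0.90 * 0.96      # 3.9253 mol/h
  n_of <- 5.60 / 0.90 * 0.63      # 3.9200
  n_li <- 6.89 / 0.90 * 1.10      # 8.4211
  n_eff <- n_li - 0.3
  excess <- n_eff / (2 * min(n_an, n_of))
  eta <- excess / (excess + 0.05)
  extent <- min(n_an, n_of, n_eff / 2) * eta
  vol <- (3.68 + 6.89 + 5.60) / 900
  expect_equal(out$concentrations[["LiNDPA"]], extent / vol, tolerance = 1e-12)
  expect_equal(out$concentrations[["oFNB"]], (n_of - extent) / vol,
               tolerance = 1e-12)
  un <- n_an - extent
  expect_equal(out$concentrations[["LiAniline"]], 0.35 * un / vol,
               tolerance = 1e-12)
  # the stoichiometric excess of the recipe is 2.14
  expect_equal(n_li / n_an, 2.145, tolerance = 0.002)
})

test_that("product flow is monotone in the LiHMDS feed", {
  # molar flow: more base never destroys product (the outlet
  # concentration itself eventually falls again through dilution)
  u2 <- seq(2, 12, by = 0.5)
  prod <- vapply(u2, function(b)
    reactor_steady_state(default_feeds(u = c(3.68, b, 5.60)),
                         true_plant_params())$molar_flows[["LiNDPA"]], 0)
  expect_true(all(diff(prod) > -1e-12))
})

test_that("true plant differs from the nominal model in its optimum", {
  same <- reactor_steady_state(default_feeds(), plant_params())
  same2 <- true_plant(default_feeds(), plant_params())
  expect_identical(same$concentrations, same2$concentrations)
  # coarse grid: profit-optimal u differs between model and plant
  plant_fn <- make_response_fn(true_plant_params())
  model_fn <- make_response_fn(plant_params())
  opt_p <- grid_search_optimum(plant_fn, n = 11L, polish = FALSE)
  opt_m <- grid_search_optimum(model_fn, n = 11L, polish = FALSE)
  expect_gt(abs(opt_p$profit - opt_m$profit), 1)
})

test_that("synthetic NMR spectra are linear in concentration", {
  x <- seq(-1, 11, length.out = 1024)
  zero <- synth_nmr_spectrum(c(oFNB = 0), axis = x, noise_sd = 0.1)
  expect_lt(max(abs(zero$intensity)), 0.6)    # pure noise
  c1 <- c(aniline = 0.2, LiNDPA = 0.4)
  s1 <- synth_nmr_spectrum(c1, axis = x)
  s2 <- synth_nmr_spectrum(2 * c1, axis = x)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-9)
})

test_that("synthetic NMR round trip recovers concentrations", {
  set.seed(21)
  conc <- c(aniline = 0.35, oFNB = 0.5, LiHMDS = 0.9, LiAniline = 0.1,
            LiNDPA = 0.25)
  sp <- synth_nmr_spectrum(conc, noise_sd = 0.12,
                           shift_error = 0.004, phase_error = 2)
  sp <- baseline_correct(auto_phase(sp), 1L)
  q <- quantify(fit_mixture(sp, models5), 1, numap5)
  expect_equal(unname(q[names(conc)]), unname(conc), tolerance = 0.02)
})

test_that("synthetic NIR spectra behave like absorbance data", {
  zero <- synth_nir_spectrum(c(LiNDPA = 0), noise_sd = 0, scatter = FALSE)
  # background only: smooth, small
  expect_lt(max(zero$intensity), 0.1)
  one <- synth_nir_spectrum(c(LiNDPA = 0.2), noise_sd = 0, scatter = FALSE)
  two <- synth_nir_spectrum(c(LiNDPA = 0.4), noise_sd = 0, scatter = FALSE)
  expect_equal(two$intensity - zero$intensity,
               2 * (one$intensity - zero$intensity), tolerance = 1e-9)
  expect_length(one$intensity, 2074L)
  # multiplicative gain is removed by SNV
  gained <- one
  gained$intensity <- 1.3 * one$intensity
  expect_equal(snv(gained)$intensity, snv(one)$intensity, tolerance = 1e-9)
})

test_that("campaign bundles are deterministic in the seed", {
  sched <- default_schedule(hold = 300, seed = 3)
  b1 <- run_campaign(sched, duration = 900, seed = 3, run_id = 1)
  b2 <- run_campaign(sched, duration = 900, seed = 3, run_id = 1)
  expect_identical(b1$nmr$truth, b2$nmr$truth)
  expect_identical(b1$nmr$spectra[[5]]$intensity,
                   b2$nmr$spectra[[5]]$intensity)
  expect_identical(b1$nir$X, b2$nir$X)
  b3 <- run_campaign(sched, duration = 900, seed = 4, run_id = 1)
  expect_false(identical(b1$nir$X, b3$nir$X))
})

test_that("holds are classified steady once concentrations settle", {
  sched <- default_schedule(seed = 2)
  b <- run_campaign(sched, params = true_plant_params(), seed = 2, run_id = 1)
  cs <- classify_steady(quantify_campaign(b))
  # judge the final 5 minutes of each hold, excluding points whose
  # centered 11-point window (+/- 75 s) crosses the next set-point
  # change or the series edge — those see the neighboring transient by
  # construction of the moving window
  ends <- c(sched$time[-1], max(b$nmr$times))
  for (h in seq_len(nrow(sched))) {
    win <- cs$timestamps > ends[h] - 300 & cs$timestamps <= ends[h] - 90
    expect_gte(mean(cs$steady[win]), 0.8)
  }
  # and a step change is flagged transient around it
  around <- abs(cs$timestamps - sched$time[3]) <= 60
  expect_lt(mean(cs$steady[around]), 0.5)
})
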