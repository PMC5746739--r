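toy_data <- function(net, param, n, tracer = tracer_pos1(), sd = 0.001) {
  fs <- complete_fluxes(param, n)
  simulate_iso_measurements(net, fs, tracer, c("A", "B", "C"),
                            sd = function(v) rep(sd, length(v)))
}

test_that("ssr follows its definition", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  data <- toy_data(net, param, 0.4)
  expect_equal(ssr(net, param, 0.4, data, tracer_pos1()), 0, tolerance = 1e-18)
  # one measurement moved by +1 sd gives SSR = 1
  data2 <- data
  data2$value[3] <- data2$value[3] + data2$sd[3]
  expect_equal(ssr(net, param, 0.4, data2, tracer_pos1()), 1, tolerance = 1e-9)
  data3 <- data
  data3$sd[1] <- 0
  expect_error(ssr(net, param, 0.4, data3, tracer_pos1()))
  # grid-search oracle: the generating flux minimises the SSR
  at_gen <- ssr(net, param, 0.4, data, tracer_pos1())
  probes <- setdiff(seq(0, 1, 0.05), 0.4)
  expect_true(all(vapply(probes, function(n) {
    ssr(net, param, n, data, tracer_pos1())
  }, 0) > at_gen))
})

test_that("fitting recovers generating fluxes from noise-free toy data", {
  net <- build_fig2_network()
  param <- free_flux_basis(net)
  truth <- c(0.35, 0.6)
  fs <- complete_fluxes(param, truth)
  data <- simulate_iso_measurements(net, fs, tracer_pos1(), c("A", "B", "C"),
                                    sd = function(v) rep(0.001, length(v)))
  fit <- fit_fluxes(net, param, data, tracer_pos1(),
                    fit_settings(multistart = 8, seed = 2))
  expect_equal(unname(fit$par), truth, tolerance = 1e-6)
  expect_equal(fit$ssr, 0, tolerance = 1e-12)
  # reported SSR equals an exact re-evaluation of the objective
  expect_equal(ssr(net, param, fit$par, data, tracer_pos1(), plan = fit$plan),
               fit$ssr, tolerance = 1e-12)
  expect_error(fit_fluxes(net, param, data[1:2, ], tracer_pos1()),
               "degrees of freedom")
})

test_that("averaged single-flux datasets fit to the weighted flux exactly", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  sc <- mixture_scenario(list(complete_fluxes(param, 0),
                              complete_fluxes(param, 1)), c(0.5, 0.5))
  data <- simulate_mixture_dataset(net, sc, tracer_pos1(),
                                   metabolites = c("A", "B", "C"),
                                   sd = function(v) rep(0.001, length(v)))
  fit <- fit_fluxes(net, param, data, tracer_pos1(),
                    fit_settings(multistart = 5))
  expect_equal(unname(fit$par), 0.5, tolerance = 1e-6)
})

test_that("Monte Carlo fitting is reproducible and follows the noise rule", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  data <- toy_data(net, param, 0.3)
  mc <- mc_settings(replicates = 100, seed = 42)
  expect_equal(mc$rel, 0.01)
  expect_equal(mc$floor, 0.001)
  f1 <- monte_carlo_fit(net, param, data, tracer_pos1(), mc,
                        fit_settings(multistart = 2))
  f2 <- monte_carlo_fit(net, param, data, tracer_pos1(), mc,
                        fit_settings(multistart = 2))
  expect_identical(f1$mc$estimates, f2$mc$estimates)
  expect_equal(nrow(f1$mc$estimates), 100)
  # sampling-theory check: MC mean close to the point estimate
  expect_lt(abs(f1$mc$mean - f1$par),
            4 * max(f1$mc$sd, 1e-4) / sqrt(100) + 1e-4)
  # different seed, different replicates
  f3 <- monte_carlo_fit(net, param, data, tracer_pos1(),
                        mc_settings(replicates = 100, seed = 43),
                        fit_settings(multistart = 2))
  expect_false(identical(f1$mc$estimates, f3$mc$estimates))
})

test_that("continuation CI matches the analytic linear least-squares interval", {
  # on the one-flux toy every simulated abundance is linear in the flux, so
  # the profile SSR is an exact parabola and the chi-square crossing has a
  # closed form
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  tr <- tracer_pos1()
  data <- toy_data(net, param, 0.37)
  fit <- fit_fluxes(net, param, data, tr, fit_settings(multistart = 3))
  civ <- continuation_ci(fit, ci_settings(nominal_sd = 0.001))
  eps <- 1e-6
  g <- (simulate_iso_measurements(net, complete_fluxes(param, 0.37 + eps), tr,
                                  c("A", "B", "C"))$value - data$value) / eps
  halfwidth <- sqrt(stats::qchisq(0.95, 1)) * 0.001 / sqrt(sum(g^2))
  expect_equal((civ$hi - civ$lo) / 2, halfwidth, tolerance = 0.01)
  expect_true(civ$lo <= 0.37 && civ$hi >= 0.37)
})

test_that("95% continuation CIs cover the generating flux at the nominal rate", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  tr <- tracer_pos1()
  truth <- 0.45
  clean <- toy_data(net, param, truth)
  sds <- pmax(0.01 * abs(clean$value), 0.001)
  set.seed(77)
  covered <- logical(200)
  for (r in seq_len(200)) {
    noisy <- clean
    noisy$value <- clean$value + rnorm(nrow(clean), 0, sds)
    noisy$sd <- sds
    fit <- fit_fluxes(net, param, noisy, tr, fit_settings(multistart = 2))
    civ <- continuation_ci(fit, refit_sd = FALSE)
    covered[r] <- civ$lo <= truth && truth <= civ$hi
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("anaplerotic fluxes are the least precise canonical estimates", {
  net <- build_canonical_network()
  param <- free_flux_basis(net)
  fs <- canonical_reference_state(param)
  tr <- glucose_tracer(frac_1 = 0.8, frac_u = 0.2)
  data <- bind_measurements(
    simulate_panel_measurements(net, fs, tr, default_fragment_panel(),
                                sd = function(v) rep(0.001, length(v))),
    flux_measurements("upt", 100))
  fit <- fit_fluxes(net, param, data, tr, fit_settings(multistart = 4, seed = 5))
  expect_lt(max(abs(fit$par - free_values(param, fs)) /
                  free_values(param, fs)), 0.001)
  civ <- continuation_ci(fit)
  w <- civ$hi - civ$lo
  names(w) <- civ$flux
  # relative CI width of PEPCase (anaplerosis) exceeds that of glucose input
  expect_gt(w[["ppc.net"]] / 80, w[["upt.net"]] / 100)
  # the generating value sits inside every interval
  truth <- free_values(param, fs)
  expect_true(all(civ$lo <= truth + 1e-6 & truth - 1e-6 <= civ$hi))
})
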