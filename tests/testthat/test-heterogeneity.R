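test_that("weighted-average flux is linear and stays balanced", {
  net <- build_canonical_network()
  param <- free_flux_basis(net)
  m1 <- complete_fluxes(param, c(100, 30, 60, 10, 7.56))
  m2 <- complete_fluxes(param, c(100, 70, 100, 40, 7.56))
  sc <- mixture_scenario(list(m1, m2), c(0.5, 0.5))
  avg <- weighted_average_flux(sc)
  expect_lt(balance_residual(net, avg), 1e-9)
  expect_equal(unname(avg$net[["g6pdh"]]), 50)
  ident <- weighted_average_flux(mixture_scenario(list(m1, m2), c(1 - 1e-12, 1e-12)))
  expect_equal(ident$net, m1$net, tolerance = 1e-9)
  # toy: members 0 and 1 average to 0.5
  p1 <- free_flux_basis(build_fig1_network())
  sct <- mixture_scenario(list(complete_fluxes(p1, 0), complete_fluxes(p1, 1)),
                          c(0.5, 0.5))
  expect_equal(unname(weighted_average_flux(sct)$net[["R1"]]), 0.5)
})

test_that("mixture datasets differ from the dataset of the averaged flux", {
  # the paper's central phenomenon: labelling is non-linear in the fluxes,
  # so the average of datasets is not the dataset of the average
  net <- build_fig2_network()
  param <- free_flux_basis(net)
  tr <- tracer_pos1()
  sc <- mixture_scenario(list(complete_fluxes(param, c(0.1, 0.8)),
                              complete_fluxes(param, c(0.9, 0.2))),
                         c(0.5, 0.5))
  mixed <- simulate_mixture_dataset(net, sc, tr, metabolites = c("A", "B", "C"))
  at_avg <- simulate_iso_measurements(net, weighted_average_flux(sc), tr,
                                      c("A", "B", "C"))
  expect_gt(max(abs(mixed$value - at_avg$value)), 0.01)
  # degenerate mixtures collapse to the member dataset
  fs <- complete_fluxes(param, c(0.4, 0.3))
  sc0 <- mixture_scenario(list(fs, fs), c(0.5, 0.5))
  same <- simulate_mixture_dataset(net, sc0, tr, metabolites = c("A", "B", "C"))
  single <- simulate_iso_measurements(net, fs, tr, c("A", "B", "C"))
  expect_equal(same$value, single$value, tolerance = 1e-12)
})

test_that("single-free-flux mixtures always fit to the weighted flux", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  tr <- tracer_pos1()
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (w in c(0.25, 0.5, 0.75)) {
    for (i in 1:4) {
      n1 <- grid[i]; n2 <- grid[i + 1]
      sc <- mixture_scenario(list(complete_fluxes(param, n1),
                                  complete_fluxes(param, n2)), c(w, 1 - w))
      data <- simulate_mixture_dataset(net, sc, tr,
                                       metabolites = c("A", "B", "C"),
                                       sd = function(v) rep(0.001, length(v)))
      fit <- fit_fluxes(net, param, data, tr, fit_settings(multistart = 2))
      expect_lt(abs(fit$par - (w * n1 + (1 - w) * n2)), 1e-6)
    }
  }
})

test_that("physiology summary reports the Table-1 arithmetic", {
  expect_equal(round(respiratory_quotient(300, 283), 2), 1.06)
  expect_equal(carbon_conversion_efficiency(300, 600), 0.50)
  expect_equal(respiratory_quotient(0, 100), 0)
  expect_true(is.na(respiratory_quotient(10, 0)))
  expect_equal(carbon_conversion_efficiency(0, 600), 1)
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  phys <- physiology_summary(net, fs)
  expect_equal(phys$co2, 300, tolerance = 1e-6)
  expect_equal(phys$cce, 0.5, tolerance = 1e-6)
  expect_equal(phys$biomass, 7.56)
  expect_equal(phys$carbon_in, 600)
})

test_that("linear physiology components commute with mixture averaging", {
  net <- build_canonical_network()
  param <- free_flux_basis(net)
  m1 <- complete_fluxes(param, c(100, 30, 60, 10, 6))
  m2 <- complete_fluxes(param, c(100, 70, 100, 40, 9.12))
  sc <- mixture_scenario(list(m1, m2), c(0.4, 0.6))
  avg <- physiology_summary(net, weighted_average_flux(sc))
  p1 <- physiology_summary(net, m1); p2 <- physiology_summary(net, m2)
  expect_equal(avg$co2, 0.4 * p1$co2 + 0.6 * p2$co2, tolerance = 1e-9)
  expect_equal(avg$o2, 0.4 * p1$o2 + 0.6 * p2$o2, tolerance = 1e-9)
  expect_equal(avg$biomass, 0.4 * p1$biomass + 0.6 * p2$biomass,
               tolerance = 1e-9)
})

test_that("the comparison report's percent column is exact", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  sc <- mixture_scenario(list(complete_fluxes(param, 0.2),
                              complete_fluxes(param, 0.8)), c(0.5, 0.5))
  rep1 <- run_mixture_experiment(net, sc, tracer_pos1(), param,
                                 metabolites = c("A", "B", "C"),
                                 settings = fit_settings(multistart = 2))
  expect_equal(rep1$percent,
               ifelse(rep1$expected != 0, 100 * rep1$estimate / rep1$expected,
                      NA_real_))
  # single free flux: estimated equals expected (Fig 1B identity)
  expect_equal(rep1$percent[1], 100, tolerance = 0.1)
})

test_that("balanced scenarios average to their reference and reject infeasible members", {
  param <- free_flux_basis(build_canonical_network())
  ref <- c(100, 50, 80, 25, 7.56)
  sc <- make_balanced_scenario(param, ref, c(100, 30, 60, 10, 7.56))
  avg <- weighted_average_flux(sc)
  expect_equal(unname(avg$net[c("upt", "g6pdh", "ppc", "icl", "biomass")]),
               ref, tolerance = 1e-9)
  expect_error(make_balanced_scenario(param, ref, c(100, 120, 60, 10, 7.56)),
               "bounds|negative")
})

test_that("reporter equivalence testing behaves under null and alternative", {
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  tr <- glucose_tracer(frac_u = 0.2, natural_abundance = 0.011)
  truth <- simulate_panel_measurements(net, fs, tr, default_fragment_panel())
  # identical sets: slope 1, intercept 0, p = 1
  res0 <- reporter_equivalence_test(truth, truth)
  expect_equal(res0$slope, 1, tolerance = 1e-12)
  expect_equal(res0$intercept, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  expect_equal(res0$df, nrow(truth) - 1L)
  # synthetic null pair: regression of one on the other has slope ~1
  pair <- generate_reporter_null_dataset(truth, sd = 0.001, seed = 8)
  res <- reporter_equivalence_test(pair$reporter, pair$total)
  expect_gt(res$slope, 0.99); expect_lt(res$slope, 1.01)
  expect_gt(res$p, 0.05)
  expect_gt(res$r_squared, 0.99)
  # a perturbed alternative is detected: a systematic abundance offset in
  # one dataset (e.g. a baseline artefact) rejects the null
  shifted <- pair$total
  shifted$value <- shifted$value + 0.005
  res_alt <- reporter_equivalence_test(pair$reporter, shifted)
  expect_lt(res_alt$p, 0.05)
  expect_error(reporter_equivalence_test(truth[1:2, ], truth[1:2, ]),
               "too small")
})
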