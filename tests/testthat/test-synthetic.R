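test_that("all shipped networks pass validation with the advertised freedoms", {
  net1 <- build_fig1_network()
  expect_equal(nrow(net1$free), 1)  # a single variable flux
  net2 <- build_fig2_network()
  expect_equal(nrow(net2$free), 2)  # R1net and R1xch
  expect_true(net2$reactions$R1$reversible)
  cn <- build_canonical_network()
  param <- free_flux_basis(cn)
  expect_equal(length(param$free_names), 5)
  expect_setequal(param$free_names, c("upt", "g6pdh", "ppc", "icl", "biomass"))
})

test_that("toy extremes put all label in one product", {
  net <- build_fig1_network()
  param <- free_flux_basis(net)
  tr <- tracer_pos1()
  at0 <- simulate_mids(net, complete_fluxes(param, 0), tr,
                       list("B[1]", "C[1]"))
  expect_equal(at0[["B[1]"]], c(1, 0), tolerance = 1e-12)   # B unlabelled
  expect_equal(at0[["C[1]"]], c(0, 1), tolerance = 1e-12)   # C fully labelled
  # the exchange toy at xch = 0 reduces to the one-flux toy
  net2 <- build_fig2_network()
  p2 <- free_flux_basis(net2)
  for (n in c(0.2, 0.7)) {
    a <- simulate_mids(net, complete_fluxes(param, n), tr, list("B[1]"))
    b <- simulate_mids(net2, complete_fluxes(p2, c(n, 0)), tr, list("B[1]"))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("default panel covers 27 fragments from 12 amino acids correctly", {
  panel <- default_fragment_panel()
  expect_length(panel, 27)
  aas <- vapply(panel, `[[`, "", "amino_acid")
  expect_length(unique(aas), 12)
  net <- build_canonical_network()
  for (frag in panel) {
    nc <- net$metabolites$n_carbons[net$metabolites$name == frag$amino_acid]
    expect_true(all(frag$carbons <= nc))  # backbone within the amino acid
    expect_true(all(frag$composition >= 0))
  }
  # every panel fragment is reachable from glucose
  targets <- lapply(panel, function(f) {
    paste0(f$amino_acid, "[", paste(f$carbons, collapse = ","), "]")
  })
  expect_silent(decompose_emus(net, targets))
})

test_that("Ala backbone is pure M3 under fully labelled glucose", {
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  mid <- simulate_mids(net, fs, glucose_tracer(frac_u = 1),
                       list("Ala[1-3]"))[["Ala[1-3]"]]
  expect_equal(mid, c(0, 0, 0, 1), tolerance = 1e-9)
})

test_that("GC-MS noise is seeded, mean-unbiased, and count-dependent", {
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  tr <- glucose_tracer(frac_1 = 0, frac_u = 0, natural_abundance = 0.011)
  truth <- simulate_panel_measurements(net, fs, tr, default_fragment_panel())
  n1 <- generate_gcms_noise(truth, noise_model(seed = 5), ion_counts = 1e4)
  n2 <- generate_gcms_noise(truth, noise_model(seed = 5), ion_counts = 1e4)
  expect_identical(n1$value, n2$value)
  # noiseless limit
  n0 <- generate_gcms_noise(truth, noise_model(a = 0, b = 0, seed = 5),
                            ion_counts = 1e6)
  expect_equal(n0$value, truth$value, tolerance = 1e-12)
  # unbiased: mean over many draws approaches truth within 3 standard errors
  row1 <- truth[truth$fragment_id == "Ala_M57" & truth$index == "M0", ]
  draws <- vapply(1:2000, function(s) {
    generate_gcms_noise(row1, noise_model(seed = s), ion_counts = 1e4)$value
  }, 0)
  sd_theory <- 2 / sqrt(1e4) + 1e-4
  expect_lt(abs(mean(draws) - row1$value), 3 * sd_theory / sqrt(2000))
  expect_equal(sd(draws), sd_theory, tolerance = 0.1)
})

test_that("low ion counts scatter enrichments wildly, high counts converge", {
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  tr <- glucose_tracer(frac_1 = 0, frac_u = 0, natural_abundance = 0.011)
  truth <- simulate_panel_measurements(net, fs, tr, default_fragment_panel())
  reps <- 15
  big <- do.call(rbind, replicate(reps, as.data.frame(truth), simplify = FALSE))
  big$fragment_id <- paste0(big$fragment_id, "_", rep(seq_len(reps),
                                                      each = nrow(truth)))
  big <- measurement_set(big)
  set.seed(99)
  counts <- stats::setNames(10^runif(27 * reps, 3, 7),
                            unique(big$fragment_id))
  noisy <- generate_gcms_noise(big, noise_model(seed = 17), counts)
  enr <- vapply(unique(noisy$fragment_id), function(f) {
    fractional_enrichment(noisy$value[noisy$fragment_id == f])
  }, 0)
  cnt <- counts[unique(noisy$fragment_id)]
  hi <- cnt >= 1e5; lo <- cnt <= 1e4
  expect_gte(mean(abs(enr[hi] - 0.011) <= 0.02), 0.95)
  expect_true(any(noisy$value[noisy$fragment_id %in% names(cnt)[lo]] < 0))
  expect_gt(stats::sd(enr[lo]), 5 * stats::sd(enr[hi]))
})

test_that("reporter null generator collapses to the truth as sd goes to 0", {
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  truth <- simulate_panel_measurements(net, fs, glucose_tracer(frac_u = 0.2),
                                       default_fragment_panel())
  pair <- generate_reporter_null_dataset(truth, sd = 0, seed = 1)
  expect_equal(pair$reporter$value, pair$total$value)
  expect_equal(pair$reporter$value, truth$value)
})
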