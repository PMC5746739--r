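test_that("EMU decomposition finds the needed units and flags bad fragments", {
  net <- build_fig1_network()
  sys <- decompose_emus(net, list("B[1]", "C[1]"))
  sizes <- vapply(sys$emus, `[[`, 0L, "size")
  expect_true(all(sizes == 1))
  expect_error(parse_fragment("B[4]", net), "carbon outside")
  # unreachable fragment: an isolated cycle never fed from any substrate
  isolated <- parse_network(c(
    "METABOLITES", "S 1 substrate", "A 1 internal", "Aout 1 sink",
    "Q 1 internal", "W 1 internal", "Qout 1 sink",
    "REACTIONS", "R0: S (a) -> A (a)", "R1: A (a) -> Aout (a)",
    "Q1: Q (a) -> W (a)", "Q2: W (a) -> Q (a)", "Q3: Q (a) -> Qout (a)"))
  expect_error(decompose_emus(isolated, list("Q[1]")), "unreachable")
  expect_silent(decompose_emus(isolated, list("A[1]")))
})

test_that("simulated MIDs match the closed-form solution of the exchange toy", {
  net <- build_fig2_network()
  param <- free_flux_basis(net)
  tr <- tracer_pos1()
  for (n in c(0, 0.25, 0.5, 0.8, 1)) {
    for (x in c(0, 0.3, 0.5, 0.9, 0.99)) {
      fs <- complete_fluxes(param, c(n, x))
      mids <- simulate_mids(net, fs, tr, list("B[1]", "C[1]"))
      expect_equal(mids[["B[1]"]][2], toy_b_fraction(n, x), tolerance = 1e-9)
      # label conservation: fractions of B and C sum to 1
      expect_equal(mids[["B[1]"]][2] + mids[["C[1]"]][2], 1, tolerance = 1e-9)
      expect_mid_sums_to_one(mids)
    }
  }
})

test_that("isotopomer reconstruction matches hand-derived values at n=0.5, xch=0.5", {
  net <- build_fig2_network()
  fs <- complete_fluxes(free_flux_basis(net), c(0.5, 0.5))
  iso <- simulate_isotopomers(net, fs, tracer_pos1(), "A")$A
  expect_equal(unname(iso[c("10", "01", "11", "00")]),
               c(13 / 18, 1 / 18, 1 / 9, 1 / 9), tolerance = 1e-9)
  expect_equal(positional_abundances(iso), c(5 / 6, 1 / 6), tolerance = 1e-9)
})

test_that("abundances of 00 and 11 in A are identical for any flux state", {
  net <- build_fig2_network()
  param <- free_flux_basis(net)
  set.seed(42)
  for (k in 1:20) {
    fs <- complete_fluxes(param, c(runif(1), runif(1, 0, 0.99)))
    iso <- simulate_isotopomers(net, fs, tracer_pos1(), "A")$A
    expect_equal(unname(iso[["00"]]), unname(iso[["11"]]), tolerance = 1e-9)
  }
})

test_that("a pass-through pool reproduces the substrate distribution", {
  net <- passthrough_network()
  fs <- complete_fluxes(free_flux_basis(net), 1)
  tr <- substrate_labelling(list(S = c("10" = 0.6, "01" = 0.1, "11" = 0.3)))
  iso <- simulate_isotopomers(net, fs, tr, "A")$A
  expect_equal(unname(iso[c("10", "01", "11", "00")]), c(0.6, 0.1, 0.3, 0),
               tolerance = 1e-12)
  orc <- simulate_isotopomers_oracle(net, fs, tr, "A")$A
  expect_equal(orc, iso, tolerance = 1e-10)
})

test_that("positional abundances marginalize simple distributions", {
  d <- c("10" = 1.0, "01" = 0, "11" = 0, "00" = 0)
  expect_equal(positional_abundances(d), c(1, 0))
  u <- c("00" = 0.25, "10" = 0.25, "01" = 0.25, "11" = 0.25)
  expect_equal(positional_abundances(u), c(0.5, 0.5))
})

test_that("every fragment is enriched to the tracer fraction on the canonical network", {
  # with glucose molecules either fully labelled (20%) or fully unlabelled,
  # every carbon in the network is 13C with probability 0.2, whatever the
  # fluxes: fractional enrichment of every fragment is exactly 20%
  net <- build_canonical_network()
  param <- free_flux_basis(net)
  fs <- canonical_reference_state(param)
  ms <- simulate_panel_measurements(net, fs, glucose_tracer(frac_u = 0.2),
                                    default_fragment_panel())
  enr <- vapply(unique(ms$fragment_id), function(f) {
    fractional_enrichment(ms$value[ms$fragment_id == f])
  }, 0)
  expect_equal(unname(enr), rep(0.2, 27), tolerance = 1e-9)
  # and at a different flux state too
  fs2 <- complete_fluxes(param, c(100, 30, 60, 10, 7.56))
  ms2 <- simulate_panel_measurements(net, fs2, glucose_tracer(frac_u = 0.2),
                                     default_fragment_panel())
  enr2 <- vapply(unique(ms2$fragment_id), function(f) {
    fractional_enrichment(ms2$value[ms2$fragment_id == f])
  }, 0)
  expect_equal(unname(enr2), rep(0.2, 27), tolerance = 1e-9)
})

test_that("an unlabelled tracer with natural abundance gives 1.1% everywhere", {
  net <- build_canonical_network()
  fs <- canonical_reference_state()
  tr <- glucose_tracer(frac_1 = 0, frac_u = 0, natural_abundance = 0.011)
  ms <- simulate_panel_measurements(net, fs, tr, default_fragment_panel())
  enr <- vapply(unique(ms$fragment_id), function(f) {
    fractional_enrichment(ms$value[ms$fragment_id == f])
  }, 0)
  expect_equal(unname(enr), rep(0.011, 27), tolerance = 1e-9)
})

test_that("the solver stays stable at extreme exchange (xch01 = 0.99)", {
  net <- build_fig2_network()
  fs <- complete_fluxes(free_flux_basis(net), c(0.5, 0.99))
  mids <- simulate_mids(net, fs, tracer_pos1(),
                        list("A[1-2]", "B[1]", "C[1]"))
  expect_mid_sums_to_one(mids, tol = 1e-9)
  expect_equal(mids[["B[1]"]][2], toy_b_fraction(0.5, 0.99), tolerance = 1e-9)
})

test_that("sweep over the toy grid reproduces linear B labelling at zero exchange", {
  net <- build_fig2_network()
  grid <- expand.grid(R1.net = seq(0, 1, 0.1), R1.xch = 0)
  sw <- sweep_toy_network(net, grid, tracer_pos1(), c("B", "C"))
  b1 <- sw[sw$metabolite == "B" & sw$pattern == "1", ]
  expect_equal(b1$abundance, b1$R1.net, tolerance = 1e-9)
  # the xch = 0 row of the two-flux network reproduces the one-flux network
  net1 <- build_fig1_network()
  sw1 <- sweep_toy_network(net1, data.frame(R1.net = seq(0, 1, 0.1)),
                           tracer_pos1(), c("B", "C"))
  expect_equal(sw1[sw1$metabolite == "B" & sw1$pattern == "1", "abundance"],
               b1$abundance, tolerance = 1e-12)
})

test_that("flux-weighted label inflow balances outflow at every pool", {
  # closed-carbon steady state: 13C brought in by substrate consumption
  # equals 13C leaving into sinks
  net <- mini_cycle_network()
  param <- free_flux_basis(net)
  tr <- mini_cycle_tracer()
  set.seed(7)
  for (k in 1:5) {
    fs <- complete_fluxes(param, c(runif(1), runif(1, 0, 0.9)))
    mids <- simulate_mids(net, fs, tr, list("E[1,2]"))
    in13 <- 1 * (0.7 * 1 + 0.3 * 2)  # u = 1; S carries 1.3 labelled carbons
    out13 <- fs$net[["ex"]] * fractional_enrichment(mids[["E[1,2]"]]) * 2
    expect_equal(unname(out13), unname(in13), tolerance = 1e-9)
  }
})

test_that("zero-throughput pools are pruned with a warning, fatally if targeted", {
  net <- build_canonical_network()
  param <- free_flux_basis(net)
  fs0 <- complete_fluxes(param, c(100, 50, 80, 0, 7.56))  # ICL off: Glx dead
  tr <- glucose_tracer(frac_u = 0.2)
  expect_warning(simulate_mids(net, fs0, tr, list("Ala[1-3]")),
                 "Glx")
  expect_error(suppressWarnings(simulate_mids(net, fs0, tr, list("Glx[1-2]"))),
               "zero total input")
})
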