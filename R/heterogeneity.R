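# The core experiment: mixtures of cell types with different flux states,
# fitted as if they were one homogeneous network, compared with the true
# weighted-average fluxes; plus the reporter-vs-total equivalence test.

#' Mixture of cell-type flux states
#'
#' @param members List of \code{flux_state} objects sharing one network.
#' @param weights Positive weights summing to 1: each cell type's fractional
#'   contribution to the measured (protein) pool.
#' @param label Free-text description of the comparison.
#' @return A \code{mixture_scenario}.
#' @export
mixture_scenario <- function(members, weights = NULL, label = "") {
  if (is.null(weights)) weights <- rep(1 / length(members), length(members))
  stopifnot(length(members) == length(weights), all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  for (m in members) stopifnot(inherits(m, "flux_state"))
  nm <- names(members[[1]]$net)
  for (m in members[-1]) {
    if (!identical(names(m$net), nm)) stop("members must share one network")
  }
  structure(list(members = members, weights = weights, label = label),
            class = "mixture_scenario")
}

#' Weighted-average flux state of a mixture
#'
#' Net fluxes average linearly, so the result is itself stoichiometrically
#' balanced.  Exchange fluxes are averaged on the raw exchange scale and
#' mapped back to xch01.
#'
#' @param sc A \code{\link{mixture_scenario}}.
#' @return A \code{flux_state}.
#' @export
weighted_average_flux <- function(sc) {
  net <- Reduce(`+`, Map(function(m, w) w * m$net, sc$members,
                         as.list(sc$weights)))
  xch_names <- names(sc$members[[1]]$xch01)
  xch <- NULL
  if (length(xch_names)) {
    e_avg <- Reduce(`+`, Map(function(m, w) {
      w * m$xch01[xch_names] / (1 - m$xch01[xch_names])
    }, sc$members, as.list(sc$weights)))
    xch <- e_avg / (1 + e_avg)
    names(xch) <- xch_names
  }
  flux_state(net, if (is.null(xch)) numeric() else xch)
}

#' Simulate the averaged labelling dataset of a mixture
#'
#' Each member's dataset is simulated at its own flux state and the
#' per-isotopomer abundances are averaged with the mixture weights; this is
#' what a measurement on the pooled material would see.
#'
#' @param net An \code{atn} network.
#' @param sc A \code{\link{mixture_scenario}}.
#' @param tracer A \code{\link{substrate_labelling}}.
#' @param panel List of \code{\link{fragment_spec}} (MID measurement model)
#'   or NULL to use positional isotopomers of \code{metabolites}.
#' @param metabolites Metabolites for the isotopomer measurement model.
#' @param sd Measurement sd rule (see
#'   \code{\link{simulate_panel_measurements}}).
#' @return A \code{\link{measurement_set}}.
#' @export
simulate_mixture_dataset <- function(net, sc, tracer, panel = NULL,
                                     metabolites = NULL, sd = sd_nominal) {
  sets <- lapply(sc$members, function(m) {
    if (!is.null(panel)) {
      simulate_panel_measurements(net, m, tracer, panel, sd = sd)
    } else {
      simulate_iso_measurements(net, m, tracer, metabolites, sd = sd)
    }
  })
  average_measurement_sets(sets, sc$weights)
}

#' Physiology summary of a flux state
#'
#' Gas exchange and derived quantities: CO2 production (net flux of the CO2
#' exit reaction), O2 uptake from the electron balance (half a mole of O2
#' per NADH or FADH2 oxidized; NADPH is assumed consumed by biosynthesis),
#' respiratory quotient, carbon conversion efficiency (fraction of imported
#' carbon retained in biomass = 1 - CO2/carbon influx), and biomass output.
#'
#' @param net An \code{atn} network with cofactor stoichiometry.
#' @param flux A \code{flux_state}.
#' @param co2_out Name of the CO2 exit reaction (NA if absent).
#' @param biomass Name of the biomass-scale reaction (NA if absent).
#' @param respired Cofactors counted as respired (default NADH, FADH2).
#' @return A \code{physiology_summary} list: co2, o2, rq, cce, biomass,
#'   carbon_in.
#' @export
physiology_summary <- function(net, flux, co2_out = "co2x",
                               biomass = "biomass",
                               respired = c("NADH", "FADH2")) {
  v <- flux$net
  co2 <- if (!is.na(co2_out) && co2_out %in% names(v)) v[[co2_out]] else NA_real_
  redox <- 0
  for (rx in net$reactions) {
    for (cf in respired) {
      if (!is.null(rx$cofactors) && cf %in% names(rx$cofactors)) {
        redox <- redox + v[[rx$name]] * rx$cofactors[[cf]]
      }
    }
  }
  o2 <- redox / 2
  carbon_in <- 0
  subs <- net$metabolites$name[net$metabolites$role == "substrate"]
  for (rx in net$reactions) {
    nc_in <- sum(vapply(rx$reactants, function(inst) {
      if (inst$met %in% subs) length(inst$atoms) else 0L
    }, 0L))
    if (nc_in > 0) carbon_in <- carbon_in + v[[rx$name]] * nc_in
  }
  bm <- if (!is.na(biomass) && biomass %in% names(v)) v[[biomass]] else NA_real_
  structure(list(co2 = co2, o2 = o2,
                 rq = respiratory_quotient(co2, o2),
                 cce = carbon_conversion_efficiency(co2, carbon_in),
                 biomass = bm, carbon_in = carbon_in),
            class = "physiology_summary")
}

#' @export
print.physiology_summary <- function(x, ...) {
  cat(sprintf("CO2 production: %.4g\nO2 uptake: %.4g\nRespiratory quotient: %s\nCarbon conversion efficiency: %.4g\nBiomass output: %.4g\n",
              x$co2, x$o2,
              if (is.na(x$rq)) "undefined" else sprintf("%.4g", x$rq),
              x$cce, x$biomass))
  invisible(x)
}

#' Respiratory quotient: CO2 produced / O2 consumed
#' @param co2,o2 Gas-exchange fluxes in consistent units.
#' @return CO2/O2; 0 when CO2 is 0; NA (undefined) when O2 is 0 but CO2 > 0.
#' @export
respiratory_quotient <- function(co2, o2) {
  if (is.na(co2) || is.na(o2)) return(NA_real_)
  if (co2 == 0) return(0)
  if (o2 <= 0) return(NA_real_)
  co2 / o2
}

#' Carbon conversion efficiency: fraction of imported carbon kept in biomass
#' @param co2 CO2 production flux (carbon atoms lost).
#' @param carbon_in Carbon atoms imported per unit time.
#' @export
carbon_conversion_efficiency <- function(co2, carbon_in) {
  if (is.na(co2) || is.na(carbon_in) || carbon_in <= 0) return(NA_real_)
  1 - co2 / carbon_in
}

#' Run the mixture experiment and compare fitted with weighted fluxes
#'
#' Simulates the averaged dataset of a mixture, fits the single-network
#' model to it, derives continuation confidence intervals, and reports each
#' free flux (plus physiology when available) against the true weighted
#' average: the central question being whether averaged labelling data yield
#' averaged fluxes.
#'
#' @param net,sc,tracer,panel,metabolites As in
#'   \code{\link{simulate_mixture_dataset}}.
#' @param param Free-flux parameterization used for fitting.
#' @param settings,ci \code{\link{fit_settings}} and
#'   \code{\link{ci_settings}}.
#' @param mc Optional \code{\link{mc_settings}} for replicate statistics.
#' @param extra_measurements Optional \code{\link{measurement_set}} appended
#'   to the averaged dataset, typically \code{\link{flux_measurements}} for
#'   measured external rates that pin the absolute flux scale.
#' @return A \code{comparison_report}: data.frame(quantity, expected,
#'   estimate, ci_lo, ci_hi, percent) with the fit attached as attribute.
#' @export
run_mixture_experiment <- function(net, sc, tracer, param, panel = NULL,
                                   metabolites = NULL,
                                   settings = fit_settings(),
                                   ci = ci_settings(), mc = NULL,
                                   extra_measurements = NULL) {
  data <- simulate_mixture_dataset(net, sc, tracer, panel, metabolites,
                                   sd = function(v) rep(ci$nominal_sd, length(v)))
  if (!is.null(extra_measurements)) {
    data <- bind_measurements(data, extra_measurements)
  }
  expected_state <- weighted_average_flux(sc)
  expected <- free_values(param, expected_state)
  fit <- if (is.null(mc)) {
    fit_fluxes(net, param, data, tracer, settings)
  } else {
    monte_carlo_fit(net, param, data, tracer, mc, settings)
  }
  civ <- continuation_ci(fit, ci)
  rows <- data.frame(quantity = names(fit$par),
                     expected = unname(expected[names(fit$par)]),
                     estimate = unname(fit$par),
                     ci_lo = civ$lo, ci_hi = civ$hi,
                     stringsAsFactors = FALSE)
  phys_fit <- physiology_summary(net, fit$fitted_state)
  if (!is.na(phys_fit$co2)) {
    phys_exp <- physiology_summary(net, expected_state)
    rows <- rbind(rows, data.frame(
      quantity = c("CO2_production", "O2_uptake", "respiratory_quotient",
                   "carbon_conversion_efficiency"),
      expected = c(phys_exp$co2, phys_exp$o2, phys_exp$rq, phys_exp$cce),
      estimate = c(phys_fit$co2, phys_fit$o2, phys_fit$rq, phys_fit$cce),
      ci_lo = NA_real_, ci_hi = NA_real_, stringsAsFactors = FALSE))
  }
  rows$percent <- ifelse(rows$expected != 0,
                         100 * rows$estimate / rows$expected, NA_real_)
  structure(rows, class = c("comparison_report", "data.frame"),
            fit = fit, ci_table = civ, label = sc$label)
}

#' Test equivalence of two labelling datasets (reporter vs total protein)
#'
#' Ordinary least-squares regression of dataset B's isotopomer abundances on
#' dataset A's over the shared fragment panel, plus a paired t-test of the
#' per-isotopomer differences.  Equivalence (the reporter protein reading
#' the same amino-acid pools as total protein) shows as slope 1, intercept
#' 0, and a non-significant paired t.
#'
#' @param set_a,set_b \code{\link{measurement_set}} objects with a shared
#'   panel (>= 3 common abundances).
#' @return list(slope, intercept, r_squared, t, df, p, n).
#' @export
reporter_equivalence_test <- function(set_a, set_b) {
  key <- function(s) paste(s$fragment_id, s$index)
  common <- intersect(key(set_a), key(set_b))
  if (length(common) < 3) stop("shared fragment panel too small (need >= 3 abundances)")
  va <- set_a$value[match(common, key(set_a))]
  vb <- set_b$value[match(common, key(set_b))]
  # identical inputs are legitimate (a perfect fit); silence lm's warning
  fitlm <- suppressWarnings(stats::lm(vb ~ va))
  d <- vb - va
  n <- length(d)
  if (all(abs(d) < .Machine$double.eps * 10)) {
    tstat <- 0; p <- 1
  } else {
    tt <- stats::t.test(vb, va, paired = TRUE)
    tstat <- unname(tt$statistic); p <- tt$p.value
  }
  list(slope = unname(stats::coef(fitlm)[2]),
       intercept = unname(stats::coef(fitlm)[1]),
       r_squared = suppressWarnings(summary(fitlm)$r.squared),
       t = tstat, df = n - 1L, p = p, n = n)
}
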