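# Synthetic-data generators: fixture networks, the default fragment panel,
# GC-MS noise with ion-count-dependent variance, and null reporter datasets.

#' Two-carbon toy network with a single variable flux
#'
#' Substrate S (labelled in position 1) feeds intermediate A; two
#' alternative irreversible reactions transfer A's carbons to products B and
#' C in opposite orientations; B and C exit.  The input flux is constrained
#' to 1, leaving the single free net flux R1.net in [0, 1].
#'
#' @return A validated \code{atn} network.
#' @export
build_fig1_network <- function() {
  parse_network(c(
    "NETWORK toy_single_flux",
    "METABOLITES",
    "S 2 substrate",
    "A 2 internal",
    "B 1 internal",
    "C 1 internal",
    "Bout 1 sink",
    "Cout 1 sink",
    "REACTIONS",
    "R0: S (ab) -> A (ab)",
    "R1: A (ab) -> B (a) + C (b)",
    "R2: A (ab) -> B (b) + C (a)",
    "R3: B (a) -> Bout (a)",
    "R4: C (a) -> Cout (a)",
    "CONSTRAINTS",
    "R0.net = 1",
    "FREE",
    "R1.net [0, 1]"))
}

#' Toy network with two variable fluxes (reversible R1)
#'
#' The single-flux toy with R1 made reversible (a condensation of B and C
#' back to A), adding the exchange flux R1.xch on the compactified [0, 0.99]
#' scale as a second degree of freedom.
#'
#' @return A validated \code{atn} network.
#' @export
build_fig2_network <- function() {
  parse_network(c(
    "NETWORK toy_two_fluxes",
    "METABOLITES",
    "S 2 substrate",
    "A 2 internal",
    "B 1 internal",
    "C 1 internal",
    "Bout 1 sink",
    "Cout 1 sink",
    "REACTIONS",
    "R0: S (ab) -> A (ab)",
    "R1: A (ab) -> B (a) + C (b) rev",
    "R2: A (ab) -> B (b) + C (a)",
    "R3: B (a) -> Bout (a)",
    "R4: C (a) -> Cout (a)",
    "CONSTRAINTS",
    "R0.net = 1",
    "FREE",
    "R1.net [0, 1]",
    "R1.xch [0, 0.99]"))
}

# Biomass precursor composition (flux units per unit of the biomass scale
# flux).  Amino acids follow an E. coli-like protein composition restricted
# to the 12 panel amino acids; the precursor block covers carbohydrate,
# nucleotide and lipid outputs.  All coefficients are scaled so that one
# unit of biomass flux drains 300/7.56 carbon atoms, i.e. the reference
# state (glucose uptake 100, biomass 7.56) respires half of the imported
# carbon.
canonical_composition <- function() {
  aa <- c(Ala = 0.488, Gly = 0.582, Ser = 0.205, Asp = 0.458, Thr = 0.241,
          Glu = 0.500, Pro = 0.210, Phe = 0.176, Tyr = 0.131, Val = 0.402,
          Leu = 0.428, Ile = 0.276)
  prec <- c(G6P = 1.0, F6P = 0.2, R5P = 0.5, E4P = 0.05, PGA = 0.3,
            PEP = 0.1, PYR = 0.3, AcCoA = 1.6, AKG = 0.2, OAA = 0.3)
  aa_carbons <- c(Ala = 3, Gly = 2, Ser = 3, Asp = 4, Thr = 4, Glu = 5,
                  Pro = 5, Phe = 9, Tyr = 9, Val = 5, Leu = 6, Ile = 6)
  prec_carbons <- c(G6P = 6, F6P = 6, R5P = 5, E4P = 4, PGA = 3, PEP = 3,
                    PYR = 3, AcCoA = 2, AKG = 5, OAA = 4)
  # the one-carbon (C1/THF) drain is slaved to glycine synthesis
  cpu <- sum(aa * aa_carbons) + sum(prec * prec_carbons) + aa[["Gly"]] * 1
  scale <- (300 / 7.56) / cpu
  list(aa = aa * scale, prec = prec * scale)
}

#' Canonical core carbon metabolism network
#'
#' An uncompartmented network of primary carbon metabolism: EMP glycolysis,
#' the oxidative and non-oxidative pentose phosphate pathway, the TCA cycle
#' with succinate/fumarate scrambling, the glyoxylate shunt, PEP carboxylase
#' and malic enzyme, synthesis of the 12 panel amino acids from their
#' canonical precursors, and biomass drains with fixed composition.  Net
#' fluxes are completely determined by five free fluxes: glucose uptake
#' (upt), G6P dehydrogenase (g6pdh), PEP carboxylase (ppc), isocitrate
#' lyase (icl) and the biomass scale flux (biomass).
#'
#' @return A validated \code{atn} network.
#' @export
build_canonical_network <- function() {
  comp <- canonical_composition()
  aa_prec <- list(
    Ala = c("PYR (abc) -> Ala (abc)", 3),
    Gly = c("Ser (abc) -> Gly (ab) + C1 (c)", 2),
    Ser = c("PGA (abc) -> Ser (abc)", 3),
    Asp = c("OAA (abcd) -> Asp (abcd)", 4),
    Thr = c("Asp (abcd) -> Thr (abcd)", 4),
    Glu = c("AKG (abcde) -> Glu (abcde)", 5),
    Pro = c("Glu (abcde) -> Pro (abcde)", 5),
    Phe = c("PEP (abc) + PEP (def) + E4P (ghij) -> Phe (abcefghij) + CO2 (d)", 9),
    Tyr = c("PEP (abc) + PEP (def) + E4P (ghij) -> Tyr (abcefghij) + CO2 (d)", 9),
    Val = c("PYR (abc) + PYR (def) -> Val (abecf) + CO2 (d)", 5),
    Leu = c("AcCoA (ab) + PYR (cde) + PYR (fgh) -> Leu (abgdhe) + CO2 (c) + CO2 (f)", 6),
    Ile = c("OAA (abcd) + PYR (efg) -> Ile (abfcdg) + CO2 (e)", 6))
  mets <- c(
    "Gluc 6 substrate", "BIO 0 substrate",
    "G6P 6 internal", "F6P 6 internal", "GAP 3 internal", "PGA 3 internal",
    "PEP 3 internal", "PYR 3 internal", "AcCoA 2 internal",
    "Cit 6 internal", "AKG 5 internal", "Suc 4 internal", "Fum 4 internal",
    "Mal 4 internal", "OAA 4 internal", "Glx 2 internal",
    "Ru5P 5 internal", "R5P 5 internal", "X5P 5 internal", "S7P 7 internal",
    "E4P 4 internal", "CO2 1 internal", "C1 1 internal",
    vapply(names(aa_prec), function(a) {
      paste(a, aa_prec[[a]][2], "internal")
    }, ""),
    "CO2out 1 sink", "BIOout 0 sink",
    vapply(names(aa_prec), function(a) {
      paste0("BM_", a, " ", aa_prec[[a]][2], " sink")
    }, ""),
    vapply(names(comp$prec), function(p) {
      nc <- c(G6P = 6, F6P = 6, R5P = 5, E4P = 4, PGA = 3, PEP = 3,
              PYR = 3, AcCoA = 2, AKG = 5, OAA = 4)[[p]]
      paste0("BMP_", p, " ", nc, " sink")
    }, ""),
    "BM_C1 1 sink")
  atom_str <- function(n) paste(letters[seq_len(n)], collapse = "")
  rxns <- c(
    "upt: Gluc (abcdef) -> G6P (abcdef)",
    "pgi: G6P (abcdef) -> F6P (abcdef)",
    "ald: F6P (abcdef) -> GAP (cba) + GAP (def)",
    "gapdh: GAP (abc) -> PGA (abc)",
    "eno: PGA (abc) -> PEP (abc)",
    "pyk: PEP (abc) -> PYR (abc)",
    "pdh: PYR (abc) -> AcCoA (bc) + CO2 (a)",
    "g6pdh: G6P (abcdef) -> Ru5P (bcdef) + CO2 (a)",
    "rpi: Ru5P (abcde) -> R5P (abcde)",
    "rpe: Ru5P (abcde) -> X5P (abcde)",
    "tkt1: X5P (abcde) + E4P (fghi) -> F6P (abfghi) + GAP (cde)",
    "tkt2: X5P (abcde) + R5P (fghij) -> S7P (abfghij) + GAP (cde)",
    "tal: S7P (abcdefg) + GAP (hij) -> F6P (abchij) + E4P (defg)",
    "cs: OAA (abcd) + AcCoA (ef) -> Cit (efbcda)",
    "idh: Cit (abcdef) -> AKG (edcba) + CO2 (f)",
    "akgdh: AKG (abcde) -> Suc (bcde) + CO2 (a)",
    "sdh: Suc (abcd) -> Fum (abcd)",
    "fum: Fum (abcd) -> Mal (abcd)",
    "mdh: Mal (abcd) -> OAA (abcd) rev",
    "mae: Mal (abcd) -> PYR (abc) + CO2 (d)",
    "icl: Cit (abcdef) -> Suc (abcf) + Glx (de)",
    "ms: Glx (ab) + AcCoA (cd) -> Mal (badc)",
    "ppc: PEP (abc) + CO2 (d) -> OAA (abcd)",
    "co2x: CO2 (a) -> CO2out (a)",
    "biomass: BIO -> BIOout",
    vapply(names(aa_prec), function(a) {
      paste0(tolower(a), "_syn: ", aa_prec[[a]][1])
    }, ""),
    vapply(names(aa_prec), function(a) {
      n <- as.integer(aa_prec[[a]][2])
      paste0("bm_", a, ": ", a, " (", atom_str(n), ") -> BM_", a,
             " (", atom_str(n), ")")
    }, ""),
    vapply(names(comp$prec), function(p) {
      nc <- c(G6P = 6, F6P = 6, R5P = 5, E4P = 4, PGA = 3, PEP = 3,
              PYR = 3, AcCoA = 2, AKG = 5, OAA = 4)[[p]]
      paste0("bmp_", p, ": ", p, " (", atom_str(nc), ") -> BMP_", p,
             " (", atom_str(nc), ")")
    }, ""),
    "bm_c1: C1 (a) -> BM_C1 (a)")
  cof <- c(
    "gapdh: NADH +1", "pdh: NADH +1", "idh: NADH +1", "akgdh: NADH +1",
    "mdh: NADH +1", "mae: NADH +1", "sdh: FADH2 +1", "g6pdh: NADPH +2")
  cons <- c(
    vapply(names(comp$aa), function(a) {
      sprintf("bm_%s.net = %.8f * biomass.net", a, comp$aa[[a]])
    }, ""),
    vapply(names(comp$prec), function(p) {
      sprintf("bmp_%s.net = %.8f * biomass.net", p, comp$prec[[p]])
    }, ""))
  free <- c(
    "upt.net [0, 200]",
    "g6pdh.net [0, 150]",
    "ppc.net [0, 150]",
    "icl.net [0, 80]",
    "biomass.net [0, 15]")
  parse_network(c(
    "NETWORK canonical_core",
    "METABOLITES", mets,
    "REACTIONS", rxns,
    "COFACTORS", cof,
    "SYMMETRIC", "Suc", "Fum",
    "CONSTRAINTS", cons,
    "FREE", free))
}

#' Reference flux state of the canonical network
#'
#' Free fluxes glucose uptake 100, G6PDH 50, PEPCase 80, ICL 25,
#' biomass 7.56 (arbitrary consistent flux units).
#'
#' @param param Optional pre-built parameterization.
#' @return A \code{flux_state}.
#' @export
canonical_reference_state <- function(param = NULL) {
  if (is.null(param)) param <- free_flux_basis(build_canonical_network())
  complete_fluxes(param, c(upt.net = 100, g6pdh.net = 50, ppc.net = 80,
                           icl.net = 25, biomass.net = 7.56))
}

# amino acid formulas and tBDMS group counts for the default panel
.aa_chem <- list(
  #          C  H  N  O  S  tBDMS
  Ala = c(3, 7, 1, 2, 0, 2), Gly = c(2, 5, 1, 2, 0, 2),
  Ser = c(3, 7, 1, 3, 0, 3), Asp = c(4, 7, 1, 4, 0, 3),
  Thr = c(4, 9, 1, 3, 0, 3), Glu = c(5, 9, 1, 4, 0, 3),
  Pro = c(5, 9, 1, 2, 0, 2), Phe = c(9, 11, 1, 2, 0, 2),
  Tyr = c(9, 11, 1, 3, 0, 3), Val = c(5, 11, 1, 2, 0, 2),
  Leu = c(6, 13, 1, 2, 0, 2), Ile = c(6, 13, 1, 2, 0, 2))

#' Default GC-MS fragment panel
#'
#' 27 fragments from the 12 protein-derived amino acids used in routine
#' steady-state MFA, with tBDMS derivative chemistry: [M-57] (loss of the
#' tert-butyl group; all backbone carbons), [M-159] (additional loss of the
#' derivatized alpha-carboxyl; backbone carbon 1 lost) and f302 (the
#' C1-C2 backbone core ion) for Asp, Phe and Val.  Elemental compositions
#' exclude the backbone carbons and are what
#' \code{\link{build_correction_matrix}} corrects for.
#'
#' @return Named list of \code{\link{fragment_spec}} objects (length 27).
#' @export
default_fragment_panel <- function() {
  panel <- list()
  add <- function(frag) panel[[frag$fragment_id]] <<- frag
  for (aa in names(.aa_chem)) {
    ch <- .aa_chem[[aa]]
    c_aa <- ch[1]; h <- ch[2]; n <- ch[3]; o <- ch[4]; s <- ch[5]; d <- ch[6]
    add(fragment_spec(paste0(aa, "_M57"), aa, seq_len(c_aa),
                      c(C = 6 * d - 4, H = h + 14 * d - 9, N = n, O = o,
                        S = s, Si = d)))
    add(fragment_spec(paste0(aa, "_M159"), aa, seq(2, c_aa),
                      c(C = 6 * (d - 1), H = h + 14 * d - 15, N = n,
                        O = o - 2, S = s, Si = d - 1)))
  }
  for (aa in c("Asp", "Phe", "Val")) {
    add(fragment_spec(paste0(aa, "_f302"), aa, 1:2,
                      c(C = 12, H = 28, N = 1, O = 2, Si = 2)))
  }
  panel
}

#' Ion-count-dependent GC-MS noise model
#'
#' Emulates the statistical behaviour of baseline-corrected GC-MS abundance
#' measurements: per-channel Gaussian noise with
#' sd = a / sqrt(ion_count) + b, additive and mean-unbiased, so that low
#' ion counts produce wildly scattered (including negative) fractional
#' abundances while counts of 1e5 and above are reliable (enrichment sd
#' around 0.01 at 1e5 counts).
#'
#' @param a Count-dependent amplitude (default 2.0).
#' @param b Count-independent floor (default 1e-4).
#' @param seed RNG seed.
#' @export
noise_model <- function(a = 2.0, b = 1e-4, seed = 1L) {
  stopifnot(a >= 0, b >= 0)
  structure(list(a = a, b = b, seed = as.integer(seed)), class = "noise_model")
}

#' Apply GC-MS noise to a measurement set
#'
#' @param truth A \code{\link{measurement_set}} of true abundances.
#' @param noise A \code{\link{noise_model}}.
#' @param ion_counts Ion count per fragment: either a single number, a named
#'   vector (by fragment_id), or NULL to keep the counts in \code{truth}.
#' @return A \code{\link{measurement_set}} with noisy values, per-row sd set
#'   to the noise sd, and ion counts recorded.
#' @export
generate_gcms_noise <- function(truth, noise = noise_model(), ion_counts = NULL) {
  ms <- truth
  if (!is.null(ion_counts)) {
    if (!is.null(names(ion_counts))) {
      ms$ion_count <- unname(ion_counts[ms$fragment_id])
    } else if (length(ion_counts) == 1L) {
      ms$ion_count <- ion_counts
    } else {
      stop("ion_counts must be a scalar or named by fragment_id")
    }
  }
  sds <- noise$a / sqrt(ms$ion_count) + noise$b
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(noise$seed)
  ms$value <- ms$value + stats::rnorm(nrow(ms), 0, sds)
  ms$sd <- pmax(sds, 1e-12)
  measurement_set(ms)
}

#' Paired null datasets for the reporter-equivalence test
#'
#' Two independent noisy realizations of the same true labelling: the null
#' model under which a reporter protein (e.g. GFP) reads the same amino
#' acid pools as total protein.
#'
#' @param truth A \code{\link{measurement_set}}.
#' @param sd Absolute measurement sd (default 0.001).
#' @param seed RNG seed.
#' @return list(reporter, total): two \code{\link{measurement_set}}s.
#' @export
generate_reporter_null_dataset <- function(truth, sd = 0.001, seed = 1L) {
  stopifnot(sd >= 0)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  one <- function() {
    ms <- truth
    ms$value <- ms$value + stats::rnorm(nrow(ms), 0, sd)
    ms$sd <- rep(max(sd, 1e-12), nrow(ms))
    measurement_set(ms)
  }
  list(reporter = one(), total = one())
}

#' Construct a two-member mixture averaging to a reference state
#'
#' Given a reference free-flux vector and the first member's free fluxes,
#' solves member2 = (reference - w1 * member1) / w2 so that the mixture's
#' weighted-average flux equals the reference ("identical mean flux
#' distributions"), and validates that both members are feasible.
#'
#' @param param A \code{free_flux_param}.
#' @param reference,member1 Free-flux vectors (net, then exchange if freed).
#' @param weights Two positive weights summing to 1 (default 0.5/0.5).
#' @param label Scenario label.
#' @return A \code{\link{mixture_scenario}}.
#' @export
make_balanced_scenario <- function(param, reference, member1,
                                   weights = c(0.5, 0.5), label = "") {
  stopifnot(length(weights) == 2, abs(sum(weights) - 1) < 1e-9)
  member2 <- (reference - weights[1] * member1) / weights[2]
  fs1 <- complete_fluxes(param, member1)
  fs2 <- complete_fluxes(param, member2)
  mixture_scenario(list(fs1, fs2), weights, label)
}
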