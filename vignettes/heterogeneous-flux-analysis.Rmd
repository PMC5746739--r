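---
title: "Models and methods: steady-state 13C-MFA for heterogeneous cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: steady-state 13C-MFA for heterogeneous cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetflux)
```

## The scientific question

Steady-state ¹³C-MFA deduces intracellular fluxes from the isotopomer
patterns a labelled substrate leaves in metabolites and proteinogenic amino
acids. When the sample contains several cell types with different flux
distributions, every measured abundance is a weighted average over the
population. Whether such averaged data still identify the averaged fluxes
depends on the *shape* of the map from fluxes to labelling: if the map is
linear over the relevant flux range, averaging commutes with fitting; as
soon as a second independent flux makes it non-linear, the average of the
datasets is no longer the dataset of the average, and a fit to the averaged
data converges — often with deceptively tight confidence intervals — to a
flux distribution that no cell in the population possesses. `hetflux`
builds each link of this argument as reusable, tested code.

## Networks and the flux space

A network is a set of metabolites (substrate, internal, or sink roles) and
reactions with per-carbon atom maps; the atom map of every reaction must be
a bijection from reactant carbons to product carbons, which the parser
enforces. CO₂ is a one-carbon metabolite (so decarboxylations and PEP
carboxylase are label-correct), while NADH, FADH₂, NADPH and ATP are
carbon-free cofactor annotations used only by the physiology summary.

Net fluxes live in the null space of the internal stoichiometric matrix.
`free_flux_basis()` turns balances, fixed-value constraints
(`R0.net = 1`), proportionality constraints (each biomass drain is a fixed
multiple of one biomass scale flux), and a designated free-flux set into an
affine map `v = v0 + B f`, rejecting under- or over-determined choices.
The map is computed by double-precision QR with a residual check at 1e−9;
the networks shipped here have small integer and fractional coefficients,
for which this is exact to roughly 1e−13, so no exact rational arithmetic
is needed. Reversible reactions carry an exchange flux on the compactified
scale `xch01 ∈ [0, 1)` with raw exchange `e = xch01/(1 − xch01)`; forward
and backward rates are `max(net, 0) + e` and `max(−net, 0) + e`. The
compactified scale is what the toy-network sweeps traverse (0–0.99).

Rotationally symmetric metabolites (succinate, fumarate) are declared in a
`SYMMETRIC` section; every consumption of such a pool is expanded into both
carbon orientations at half weight. This is implemented as weighted
atom-map variants of the consuming reaction rather than literal duplicate
reactions at half flux — the label balances are identical, and the
stoichiometry and free-flux bookkeeping stay single-reaction.

## Label simulation

The simulator decomposes the network into elementary metabolite units
(EMUs): the carbon subsets that can influence a requested fragment, found
by tracing atom maps backwards from the targets. At isotopic steady state
the MID of every EMU of size *s* obeys a linear balance whose inputs are
substrate EMUs and convolutions of smaller EMUs, so the whole system is a
size-ordered cascade of dense linear solves. Positional isotopomer
distributions are recovered from the cascade by the cumomer transform: the
probability that all carbons of a subset are labelled is the top mass
isotopomer of that subset's EMU, and Möbius inversion over subsets returns
the isotopomer abundances.

Two numerical choices matter. Pools with total throughput below 1e−12 are
pruned with a warning (their MIDs are set to unlabelled; every rate that
could propagate them onward is itself zero) unless a requested fragment
sits on one, which is an error naming the pool. And the solver is used
unchanged at extreme exchange (xch01 = 0.99, e = 99), where the balance
matrices remain well-conditioned because the diagonal grows with the same
rates as the off-diagonal terms.

The independent check on all of this is `simulate_isotopomers_oracle()`: a
brute-force Gauss–Seidel fixed-point iteration on the complete isotopomer
balance equations of every internal pool, with no EMU reduction and no
cumomer transform, limited to networks whose internal pools carry at most
16 carbons. Each sweep renormalizes every pool's distribution; the exact
solution sums to one, and the projection suppresses the slow amplification
of rounding drift that the quadratic condensation terms would otherwise
cause. The test suite requires cascade and oracle to agree to 1e−8 across
random flux states on three structurally different networks (linear split,
reversible condensation, and a scrambled condensation cycle).

Tracers are lists of substrate isotopomer patterns with fractions
(e.g. 80 % `100000` + 20 % `111111` for the glucose mixture used on the
canonical network). Natural ¹³C abundance (1.1 %) is applied at the
substrate definition — positions left unlabelled by a pattern are ¹³C with
probability 0.011 — rather than convolved in afterwards, so simulation and
measurement correction can be tested independently. A useful exact
consequence: with a tracer whose molecules are either fully labelled
(fraction 0.2) or fully unlabelled, every carbon in a closed network is
labelled with probability exactly 0.2 whatever the fluxes, so every
fragment's fractional enrichment is exactly 20 %. This is both a test
oracle and the reference value the acceptance script recomputes.

## GC-MS measurement model

Measured fragments are tBDMS-derivatized amino-acid ions. The correction
matrix of a fragment is the natural-abundance mass distribution of all
non-backbone atoms (derivative carbons, H, N, O, S, Si), built by direct
polynomial expansion and truncated at 1e−9 tail mass; correcting a spectrum
is a least-squares deconvolution against this matrix followed by
renormalization. Negative corrected abundances are *retained* by default:
they are the statistical fingerprint of baseline-corrected low-intensity
signals, and clamping them would bias downstream enrichment statistics
(a `clamp` option exists for display purposes). Fractional enrichment is
`Σ i·Mᵢ / n`, likewise unclamped.

The ion-count QC rule drops fragments below 10⁵ total counts. The noise
generator that motivates it draws per-channel Gaussian noise with
`sd = a/√(ion count) + b`, defaults `a = 2.0`, `b = 1e−4`, chosen so the sd
of a fragment's enrichment is about 0.01 at 10⁵ counts — the calibration at
which the reliability threshold emerges, with wild scatter and frequent
negative abundances below 10⁴ counts. This emulates the *statistical
effect* of baseline correction on weak signals; it is not an instrument
model, and the default panel of 27 fragments over 12 amino acids (M−57,
M−159, and three f302 ions) is a documented reconstruction of a typical
panel, not a published fragment list.

## Fitting, Monte Carlo, confidence intervals

The objective is the variance-weighted SSR over a measurement set that may
mix positional isotopomer abundances (the toy-network measurement model,
including the fully unlabelled isotopomer, whose sum-to-one redundancy is
retained), fragment MIDs (the canonical measurement model), and direct
rate measurements. Rate rows exist because steady-state MIDs are invariant
to a uniform scaling of all fluxes: without at least one measured rate
(here glucose uptake), the absolute flux scale is unidentifiable, which the
fitter would otherwise report as a perfect fit at an arbitrary scale.

Optimization is multistart bounded Levenberg–Marquardt (`minpack.lm`),
with starts at the box midpoint plus Latin-hypercube samples, stopping
early when a start reaches SSR below 1e−10 (a practically perfect fit).
Distinct optima within ΔSSR ≤ 1e−6 of the best are stored and flagged as
multimodality rather than silently discarded.

Monte Carlo reliability follows a fixed protocol: 100 replicate datasets
with independent Gaussian noise at `sd = max(0.01·value, 0.001)`,
replicates refit warm-started from the point estimate, per-flux means and
SDs reported, all under a single seed.

Confidence intervals use parameter continuation: one flux is stepped away
from its optimum while the others are re-optimized, until the SSR crosses
`SSR_min + qchisq(0.95, 1) = SSR_min + 3.84`; the step grows by 1.6 while
inside, halves on overshoot, and the crossing is refined by bisection. The
measurement error used during continuation is a nominal absolute 0.001 for
all labelling abundances. On a model that is linear in its single free
flux the profile is an exact parabola, and the test suite checks the
continuation interval against that closed form to 1 %; a parameter bound
reached while still under the threshold is reported as an open interval.

## The heterogeneity experiment

A mixture scenario is a list of flux states sharing one network with
weights interpreted as each cell type's fractional contribution to the
measured (protein) pool — 0.5/0.5 by default. Net fluxes average
linearly, so the weighted-average state is itself balanced; exchange
fluxes are averaged on the raw exchange scale (actual bidirectional rates
average linearly; the compactified scale does not). A scenario helper
solves `member2 = (reference − w₁·member1)/w₂` so that two-member mixtures
average exactly to a chosen reference state, validating feasibility of
both members.

The experiment simulates each member's dataset, averages per-isotopomer,
fits the single-network model, derives continuation CIs, and reports every
free flux plus physiology against the weighted truth, with an exact
percent-of-expected column. Physiology: CO₂ production is the net flux of
the CO₂ exit reaction; O₂ uptake is half the net NADH + FADH₂ production
(NADPH is assumed consumed by biosynthesis — no transhydrogenase — and the
respired cofactor set is an argument); RQ = CO₂/O₂; carbon conversion
efficiency is 1 − CO₂/(carbon atoms imported). CO₂, O₂ and biomass are
linear in the flux state and therefore commute with mixture averaging; RQ
and CCE are ratios of linear quantities and do not, which is itself part
of the phenomenon being studied.

The reporter-equivalence test asks whether two measurement sets are two
noisy readings of the same labelling: ordinary least-squares regression of
one set's abundances on the other's across the shared panel, plus a paired
*t*-test with df = pairs − 1 (identical inputs return t = 0, p = 1 rather
than 0/0). Under the synthetic null — two independent noisy realizations
(sd 0.001) of one truth — the slope is 1 and the intercept 0 to within a
percent. A paired *t* detects systematic offsets; cell types with
genuinely different fluxes produce sign-balanced MID differences that
appear as scatter about the regression line (reduced R²) rather than as a
slope or mean shift, a limitation worth knowing when interpreting such
comparisons.

## The canonical network reconstruction

The shipped core-metabolism model follows standard atom mappings: EMP
glycolysis, oxidative PPP (G6P dehydrogenase lumped with the
decarboxylating step), canonical transketolase/transaldolase carbon maps,
citrate synthase through α-ketoglutarate with the textbook carbon fates,
succinate/fumarate scrambling, glyoxylate shunt (isocitrate lyase/malate
synthase), PEP carboxylase, malic enzyme, and a reversible malate
dehydrogenase (anaplerosis at 80 flux units forces carbon back out of the
OAA/malate node). Amino-acid syntheses use the standard precursor maps
(Ala←pyruvate; Ser/Gly←3PG with a one-carbon unit; Asp/Thr←OAA;
Glu/Pro←AKG; Phe/Tyr←2 PEP + E4P − CO₂; Val←2 pyruvate − CO₂;
Leu←AcCoA + 2 pyruvate − 2 CO₂; Ile←OAA + pyruvate − CO₂). Net fluxes are
completely defined by glucose uptake, G6PDH, PEPCase, ICL and one biomass
scale flux.

Biomass composition is a reconstruction: an E. coli-like protein
composition over the 12 panel amino acids plus precursor drains for
carbohydrate, nucleotide and lipid output, with all coefficients scaled so
one unit of biomass flux drains 300/7.56 carbon atoms. At the reference
state (glucose 100, G6PDH 50, PEPCase 80, ICL 25, biomass 7.56) the model
therefore respires exactly half the imported carbon (CCE 0.50, CO₂ 300);
its O₂ uptake and RQ depend on the cofactor assignments (NAD-linked
isocitrate dehydrogenase here) and are in the right range rather than
matched to any particular reference. No attempt is made to reproduce
specific published estimated-flux values for mixtures on this network,
since those depend on model definitions not available to this package.

## Problem sizes and runtimes

The test suite and scripts are sized for a single CPU: toy-network checks
use closed forms and 20–40 random flux states per property; the
EMU-vs-oracle comparison runs on networks of at most 16 internal carbons;
CI coverage uses 200 replicate toy datasets; the canonical fits use the
27-fragment panel with one rate measurement, 4–20 multistarts, and two
mixture scenarios with full continuation CIs. The complete suite runs in
a few minutes; `analysis/03_canonical_mixture.R`, the heaviest script, in
about three.

## Known limitations

* Isotopically stationary only — no time-course (INST) simulation; single
  element (¹³C) only.
* No subcellular compartmentation (single pools per metabolite) and no
  duplicated-network deconvolution of mixtures; the package quantifies the
  confounding, it does not resolve it.
* The GC-MS noise model reproduces the variance structure of
  baseline-corrected abundances, not chromatograms, detector physics, or
  derivatization chemistry beyond elemental composition.
* The canonical network, fragment panel and biomass composition are
  documented reconstructions; conclusions that depend on their exact
  coefficients (e.g. O₂ uptake) should be read qualitatively.
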