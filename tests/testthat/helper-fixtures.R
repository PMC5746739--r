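# Shared fixtures: tracers, toy networks, and a small cyclic network with a
# symmetric metabolite used for EMU-vs-oracle equivalence checks.

tracer_pos1 <- function() substrate_labelling(list(S = c("10" = 1)))

# passthrough chain S -> A -> sink
passthrough_network <- function() {
  parse_network(c(
    "METABOLITES",
    "S 2 substrate",
    "A 2 internal",
    "Aout 2 sink",
    "REACTIONS",
    "R0: S (ab) -> A (ab)",
    "R1: A (ab) -> Aout (ab)",
    "FREE",
    "R0.net [0, 2]"), name = "passthrough")
}

# condensation/cleavage cycle with a symmetric 4-carbon pool and a bypass:
# exercises convolution sources, scrambling, recycling and reversibility.
mini_cycle_network <- function() {
  parse_network(c(
    "NETWORK mini_cycle",
    "METABOLITES",
    "S 2 substrate",
    "A 2 internal",
    "B 2 internal",
    "D 4 internal",
    "E 2 internal",
    "Eout 2 sink",
    "REACTIONS",
    "u: S (ab) -> A (ab)",
    "cond: A (ab) + B (cd) -> D (abcd) rev",
    "split: D (abcd) -> B (bc) + E (ad)",
    "byp: A (ab) -> E (ba)",
    "ex: E (ab) -> Eout (ab)",
    "SYMMETRIC",
    "D",
    "CONSTRAINTS",
    "u.net = 1",
    "FREE",
    "byp.net [0, 1]",
    "cond.xch [0, 0.9]"))
}

mini_cycle_tracer <- function() substrate_labelling(list(S = c("10" = 0.7,
                                                               "11" = 0.3)))

# closed form for the two-flux toy: labelled fraction of B at net flux n and
# raw exchange e is (n + 2e - ne) / (1 + 3e - 2ne)
toy_b_fraction <- function(n, xch01) {
  e <- xch01 / (1 - xch01)
  (n + 2 * e - n * e) / (1 + 3 * e - 2 * n * e)
}

expect_mid_sums_to_one <- function(mids, tol = 1e-9) {
  for (m in mids) expect_lt(abs(sum(m) - 1), tol)
}
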