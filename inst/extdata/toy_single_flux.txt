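# Toy network with a single variable flux: substrate S (labelled in
# position 1) feeds intermediate A, whose carbons are transferred to
# products B and C in opposite orientations by two irreversible reactions.
NETWORK toy_single_flux
METABOLITES
S 2 substrate
A 2 internal
B 1 internal
C 1 internal
Bout 1 sink
Cout 1 sink
REACTIONS
R0: S (ab) -> A (ab)
R1: A (ab) -> B (a) + C (b)
R2: A (ab) -> B (b) + C (a)
R3: B (a) -> Bout (a)
R4: C (a) -> Cout (a)
CONSTRAINTS
R0.net = 1
FREE
R1.net [0, 1]
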