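---
title: "Methods: quantum search over Markush claim languages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum search over Markush claim languages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpatent)
```

# The model

`qpatent` decides whether two Markush-structure patent claims share a
compound by running Grover amplitude amplification around a
constraint-satisfaction oracle, entirely on an exact classical simulator.
This vignette records the model, its assumptions, the tunable parameters,
and the design decisions that were genuinely open.

## Claim grammars

A claim is a finite context-free-like grammar: a core string with `{NAME}`
references, production rules per R group, and terminal fragment choices.
The reference graph must be acyclic, so the language is finite. Two
quantities are exposed separately because they genuinely differ:
`enumerate_claims()` returns the deduplicated language, while
`count_claims()` counts *derivations* by dynamic programming (sum over
productions, product over positions). When two derivations yield the same
string the count exceeds the language size; the nested R2 grammar in the
test suite has five derivations collapsing, with one terminal choice, to
two strings. We kept the DP semantics because it is the quantity that can
be computed without enumeration at claim scale; the divergence is
documented and the property test comparing the two runs on grammars built
to be duplicate-free.

## Encoding

A code table maps each SMILES symbol to a fixed-width code of
`ceil(log2(n_symbols + 1))` bits, reserving the all-ones code for a padding
("empty") symbol; a compound of at most `max_len` symbols becomes the
concatenation of its codes right-padded with empty codes. Read left to
right as a big-endian integer, that bitstring is the compound's basis
state. The convention is pinned by the worked examples (C→`00`, O→`10`,
empty→`11`, `CCCO`→|2⟩, `OCCC`→|128⟩); the code `01` is not fixed by those
examples and the builder therefore accepts explicit assignments, defaulting
otherwise to input order. `max_len` for a comparison defaults to the
longest enumerated claim across both patents.

One molecule admits several SMILES strings, so claim sets are closed under
`alternative_notations()` before encoding. Only the unbranched-chain rule
(a chain equals its token-wise reversal) ships, because it covers linear
claims exactly and is an involution we can test; anything with rings or
branches is rejected unless the caller plugs in an enumerator. This is a
real limitation: for branched chemistry the closure is the user's
responsibility (e.g. via an external cheminformatics toolkit).

## Oracles and the intersection

`mark_state()` marks one basis state: X gates on the data qubits whose bit
is 0, a multi-controlled X from all data qubits onto the patent's indicator
ancilla, and the X gates again. A patent oracle is the concatenation of one
block per claimed state — emitted in lexicographic order purely for
determinism, since the blocks commute. The intersection oracle runs oracle
M, oracle K, one controlled-Z between the two indicator ancillas, and then
both oracles reversed. The CZ imparts the −1 phase exactly on states
marked by both (a Toffoli onto a third qubit would do the same at the cost
of one more qubit), and the reversal uncomputes the ancillas on *every*
basis state, which the tests check exhaustively at small widths. The same
copy-then-uncompute pattern is exposed generically as
`uncompute_garbage()` for reversible computations `V_f|x,0,0⟩ = |x,f(x),g(x)⟩`.

## The Grover schedule

With `N = 2^n_data` and `M` solutions the package uses the standard
schedule `k = floor((pi/4) * sqrt(N/M))`, falling back to `k = 0` when the
uniform state already meets the post-iteration success probability. `M` is
computed classically from the (desk-scale) enumerations; quantum counting
for unknown `M` is out of scope. After `k` iterations a marked state's
amplitude is `sin((2k+1)·asin(sqrt(M/N)))/sqrt(M)`, which the test suite
verifies to 1e-9 against the simulator. When the claim intersection is
empty there is nothing to amplify; rather than amplifying noise, the
pipeline skips the search, reports the uniform distribution, and lets the
classical verification reject every candidate — every decoded
high-probability state is checked for membership in *both* claim sets
before it is reported, so false positives cannot survive sampling flukes.

## Simulator conventions

* Dense statevector over at most 14 qubits, with a clear error above; the
  worked problems need at most 10.
* Qubit 0 is the most significant bit of the basis index, so register
  bitstrings read left to right match the encoding. Data qubits come first,
  the two oracle ancillas last; for table-style reporting `state_index`
  relabels states with the ancilla bits on top, so ancilla-excited states
  appear at indices ≥ 2^n_data.
* Global phase is quotiented out in every equivalence check (it is
  unobservable). The diffusion circuit (H/X conjugated multi-controlled Z)
  equals the reflection `2|s⟩⟨s| − I` only up to a −1 phase, which cancels
  in probabilities.
* Multi-controlled X decomposes ancilla-free: the textbook T-gate Toffoli
  at two controls, and above that the recursion `C^k(U) = C(V) · C^{k−1}X ·
  C(V†) · C^{k−1}X · C^{k−1}(V)` with `V² = U`, with single-controlled
  unitaries synthesized by ZYZ (A·X·B·X·C plus a phase gate). Gate counts
  grow like 3^k; they are pinned in the tests as regression values (9
  single-qubit + 6 CNOT for the Toffoli), not as external truths, because
  synthesis counts are convention-dependent.
* Measurement sampling is a seeded multinomial draw over the exact
  distribution; all randomness in the package flows from caller-supplied
  seeds.

## Boolean compression

A marked set is also a Boolean function, and marking circuits can be
compressed by minimizing it: `dnf_from_marked()` builds the sum of
minterms, `simplify_expr()` runs Quine–McCluskey prime-implicant
computation with a deterministic essential-then-greedy cover (ties broken
lexicographically) followed by shared-literal factoring, and
`circuit_from_expr()` synthesizes the indicator with one scratch qubit per
OR clause (OR via De Morgan), uncomputing all scratch qubits. Equivalence
with the uncompressed oracle is established by exhaustive truth-table
simulation (`oracles_equivalent()`, capped at 10 data qubits). The
"3-SAT"-style form is a factoring target, not a clause-width-3
normalization: the worked minimization only factors, and we follow that.
When factoring does not reduce residual products to single literals the
simplifier returns the minimized sum of products, which the synthesizer
compiles with one scratch per product instead.

## Noise engine

Noisy runs evolve a density matrix (register capped at 7 qubits; the
2-data-qubit comparison circuit uses 4). After each gate: depolarizing
error at the 1-qubit or CNOT rate on the touched qubits, then thermal
relaxation for the gate's duration on each touched qubit — amplitude
damping `1 − exp(−t/T1)` composed with just enough pure dephasing that
off-diagonals scale by `exp(−t/T2)` (requiring `T2 ≤ 2·T1`). Readout error
is a per-qubit row-stochastic bit-flip matrix applied to the final
data-register distribution. Idle-qubit relaxation is deliberately not
modeled: the error-type experiments compare one family at a time across
scale factors, and idle noise would only rescale the thermal column.

Parameters and defaults (`default_noise_model()`): times in nanoseconds,
T1 = 60 µs, T2 = 80 µs, single-qubit gates 50 ns, CNOT 300 ns, depolarizing
0.002 per single-qubit gate and 0.02 per CNOT, symmetric 3% readout flips.
These are *synthetic*, chosen once as plausible for a small superconducting
device of the 5-qubit era — large enough that halving/doubling one family
separates the mean correctness across factors by several percentage points,
i.e. well beyond the sampling error of the 10 × 1024-shot protocol. They
are not a calibration snapshot of any machine, so the experiment's output
is meaningful as a *protocol and ordering* (correctness non-increasing in
each family's scale; per-gate depolarizing dominating when its rates
dominate), never as device percentages. Scaling the thermal family scales
the decay rates `1/T1`, `1/T2`; scaled probabilities are clipped to [0, 1]
with a warning.

The routing metric is similarly an analogue, not a transpiler: the cost of
a mapping is the sum over two-qubit gates of (shortest coupling-graph path
between the mapped endpoints − 1), i.e. SWAP-equivalent overhead. On the
5-qubit T-shaped layout (edges 0–1, 1–2, 1–3, 3–4) it prefers the mapping
that places the busy qubits on the high-connectivity center, matching the
qualitative device observation that mapping choice matters.

## The synthetic fixture generator

`generate_fixture()` produces patent pairs with *planted* overlaps so the
whole pipeline is testable end to end. Compounds are sampled as canonical
representatives (the lexicographic minimum of a chain and its reversal);
planted compounds go to both patents, the rest are split disjointly. Because
representatives are canonical, notation closure cannot manufacture
accidental extra overlaps, so the expected answer is exactly the closure of
the planted set. Defaults — 3 symbols (2 bits each), compounds of up to 3
symbols (6 data qubits), 4 claims per patent, 1 planted overlap — mirror
the scale of the worked examples while keeping a 100-seed
end-to-end recovery suite fast. Two presets reproduce the worked problems:
the 2-data-qubit target sets {11, 00} vs {00}, and the 8-data-qubit pair
whose overlap encodes to basis states 2 and 128.

What the generator does *not* emulate: chemical validity (strings are
arbitrary words over the symbol alphabet), branched/ring structures,
duplicate-inducing grammars, or claim languages too large to enumerate.
Passing the planted-recovery suite therefore shows the search machinery is
correct on finite linear-chain languages; it says nothing about notation
closure for general chemistry, which is pluggable.

## Problem sizes in the shipped suites

The test and acceptance suites run at desk scale, chosen to keep the full
run around half a minute: exhaustive oracle checks at 2–4 data qubits,
matrix-oracle comparisons on random circuits of up to 5 qubits,
multi-controlled-X equivalence up to 6 controls, the 10-qubit worked
search, noise experiments on the 4-qubit comparison circuit at
10 × 1024 shots, and 100 random planted fixtures at 6 data qubits.

## Known limitations

* Register caps: 14 qubits (statevector), 7 (density matrix); above that
  the constructors refuse rather than degrade.
* `alternative_notations()` covers unbranched chains only (pluggable hook
  otherwise).
* `count_claims()` counts derivations, not distinct strings.
* Gate counts depend on this package's synthesis scheme and are not
  comparable across toolkits.
* The noise defaults are synthetic; conclusions from
  `error_scaling_experiment()` are qualitative orderings.
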