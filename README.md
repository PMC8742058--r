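# qpatent

Exact comparison of two pharmaceutical Markush-structure patent claims by
Grover amplitude amplification, on a built-in classical statevector
simulator.

## The problem

A Markush structure is the standard way a pharmaceutical patent claims a
*family* of compounds: an invariant core plus variable substituents
(R groups), each defined by production rules that may reference further
R groups. The claimed language grows combinatorially — easily past 10^10
compounds — so database tools fall back on approximate substructure
screening, which misses overlaps when one claim's core hides inside
another claim's R groups. The question that actually matters for
infringement is exact: *do two claims contain a common compound?*

`qpatent` frames this as an unstructured search. Every claimed compound's
SMILES string is transcribed symbol-by-symbol through a fixed-width code
table into a bitstring, i.e. a computational basis state |x⟩ of an
n-qubit data register (short strings are right-padded with a reserved
"empty" code). Membership in each patent becomes a Boolean oracle, and the
two oracles are joined into an *intersection oracle*:

```
U_{M∩K} |x⟩|00⟩ = (−1)^{f_M(x)·f_K(x)} |x⟩|00⟩
```

built as: run oracle M and oracle K (each XORs its membership bit into its
own ancilla), apply a controlled-Z between the two ancillas (the phase
kickback lands exactly on compounds claimed by both patents; using CZ
instead of a Toffoli saves one qubit), then run both oracles in reverse so
the ancillas return to |00⟩. Standard Grover search around this oracle —
k = ⌊(π/4)√(N/M)⌋ iterations of oracle + diffusion from the uniform
superposition — amplifies the overlapping compounds, which are measured,
decoded back to SMILES, and verified classically against both claim sets.

Around that core the package provides:

* a claim-grammar module (enumeration, derivation counting by dynamic
  programming, acyclicity checks, YAML claim files);
* a gate/circuit model with exact statevector simulation, circuit
  inversion, ancilla-free multi-controlled-X decomposition into
  {single-qubit, CNOT}, gate counting and OpenQASM 2.0 export;
* Boolean oracle compression: Quine–McCluskey minimization with
  shared-literal factoring (e.g. three marked states
  `Ā B̄ C̄ D̄ + Ā B̄ C̄ D + Ā B C̄ D̄` compress to `Ā·C̄·(B̄+D̄)`) and
  synthesis of the compressed indicator circuit with uncomputed scratch
  qubits;
* a density-matrix noise engine (depolarizing, thermal relaxation with
  T1/T2 over gate durations, readout bit-flips) with one-family-at-a-time
  ×0.5/×1/×2 scaling experiments, plus a coupling-graph routing-cost
  metric for comparing qubit mappings;
* a seeded synthetic fixture generator producing patent pairs with planted
  overlaps, and a command-line interface.

## Worked example

The proposed patent claims `CCR1` with R1 ∈ {CO, OC}; the existing patent
claims `OR2` with R2 ∈ {CCC, CCO, COO}. Both claim the butanol chain —
written `CCCO` in one and `OCCC` in the other.

```r
library(qpatent)
pa <- read_patent(system.file("extdata", "patent_proposed.yaml", package = "qpatent"))
pb <- read_patent(system.file("extdata", "patent_existing.yaml", package = "qpatent"))
tb <- read_code_table(system.file("extdata", "code_table.tsv", package = "qpatent"))

cmp <- compare_patents(pa, pb, table = tb, shots = 1024, seed = 1)
cmp
#> Verified overlapping compounds:
#>   |2>  CCCO
#>   |128>  OCCC

subset(comparison_report(cmp), verified_overlap)
#>  basis_index bitstring decoded_smiles amplitude probability counts verified_overlap
#>            2  00000010           CCCO 0.7055565   0.4978099    507             TRUE
#>          128  10000000           OCCC 0.7055565   0.4978099    512             TRUE
```

With the code table C→`00`, O→`10`, empty→`11`, the compound `CCCO` padded
to four symbols becomes the bitstring `00000010`, i.e. basis state |2⟩ of
the 8-qubit data register, and `OCCC` becomes `10000000` = |128⟩. The two
claim languages, closed under alternative linear notations, intersect in
exactly these two states (M = 2 among N = 256), so the schedule runs k = 8
Grover iterations: each overlap ends with amplitude 0.706 (probability
0.498), every unmarked state with amplitude 0.004, and the two oracle
ancillas carry zero probability of leaving |00⟩. The sampled 1024-shot
counts split accordingly, and both decoded candidates verify as members of
both claim sets.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/qpatent.R compare \
  --patent-a inst/extdata/patent_proposed.yaml \
  --patent-b inst/extdata/patent_existing.yaml \
  --code-table inst/extdata/code_table.tsv \
  --shots 1024 --seed 1 --report overlap.csv
```

Other subcommands: `encode`, `simulate` (QASM in), `noise-sweep`,
`fixture`, `export-qasm`.

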