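# ddsnp

An exact simulator for **spiking neural P systems with neuron division and
dissolution** (DDSN P systems), written for researchers in membrane
computing and natural computing who want to execute, trace and verify these
systems rather than reason about them only on paper.

A spiking neural P system is a directed graph of neurons exchanging spikes
of a single type `a` under rules guarded by regular languages over `a`:
firing rules `E/a^c -> a^p; d`, forgetting rules `E/a^s -> λ`, and — in the
DDSN variant — division rules `[E]_i -> [ ]_j || [ ]_k` and dissolution
rules `[E]_i -> δ`.  Division rewrites the graph (children inherit the
parent's synapses and gain the pairs a static *synapse dictionary*
prescribes for their labels); dissolution removes a neuron and its wiring.
Dividing for `2n - 1` steps yields a `2^n`-neuron workspace that enumerates
every candidate answer; dissolving the neurons that encode wrong answers
leaves the full solution set readable off the surviving labels.

The package provides:

* the execution engine (`ddsn_system()`, `ddsn_run()`, `ddsn_step()`), with
  strict-deterministic and seeded-random conflict resolution, delays and
  closed neurons, lost-spike accounting, JSON-lines traces and DOT export;
* the uniform **SAT** construction (`build_sat_system()`, `solve_sat()`):
  any instance with `n` variables and `m` clauses is solved in `2n + m + 3`
  steps, the survivors being exactly the satisfying assignments;
* the uniform **Subset Sum** construction (`build_subsetsum_system()`,
  `solve_subsetsum()`, horizon `2n + x_max + S + 5`), plus a closed-form
  replay of its checking stage (`checking_stage_trace()`);
* brute-force oracles (`brute_force_sat()`, `brute_force_subsetsum()`) and
  seeded instance generators used to cross-check the simulator;
* step-complexity formulas and tables comparing against earlier SN P system
  variants (`sat_steps()`, `subsetsum_steps()`, `sat_step_table()`,
  `subsetsum_step_series()`);
* DIMACS CNF input and a thin command-line front end (`exec/ddsnp`).

## Worked example

The 3-variable, 3-clause instance `(x1 ∨ x2) ∧ (¬x2 ∨ x3) ∧ (¬x1 ∨ x2 ∨ x3)`:

```r
library(ddsnp)
cnf <- sat_example_instance()
sol <- solve_sat(cnf)
sol$run
#> <ddsn_run: halted at step 12; 16 live neurons>
#>   surviving outputs: o_011, o_101, o_111
sol$assignments
#> [1] "011" "101" "111"
```

The three surviving output neurons encode the three satisfying assignments
(`011` means `x1 = false, x2 = true, x3 = true`), obtained in
`2·3 + 3 + 3 = 12` steps.  The same sizes cost `21` and `26` steps under the
earlier division-and-budding and division-only constructions:

```r
sat_steps(3, 3)
#>  budding division     ddsn
#>       21       26       12
```

Subset Sum on `X = {1, 2, 3, 4}`, `S = 5`:

```r
sol <- solve_subsetsum(subsetsum_example_instance())
sol$subsets
#> [1] "0110" "1001"
```

i.e. `{2, 3}` and `{1, 4}` are the two solutions.  The construction's
declared horizon is `2·4 + 4 + 5 + 5 = 22` steps (the simulator quiesces one
step later; see `subsetsum_halting_offset()` and the methods vignette), and
the comparison formulas for the nondeterministic predecessors give:

```r
round(subsetsum_steps(subsetsum_example_instance()))
#> binary_snp  unary_snp      snpsp   timefree       ddsn
#>        165        330        250        270         22
```

From a shell, the same runs are:

```sh
ddsnp sat --dimacs instance.cnf --oracle
ddsnp subsetsum --set 1,2,3,4 --target 5
ddsnp complexity sat --n-max 50 --m-max 50 --out sat_steps.tsv
```

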