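---
title: "Verification, validation and visualization of reaction-contingency Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verification, validation and visualization of reaction-contingency Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolvvv)
```

## The modeling setting

Signal-transduction systems can be described as bipartite
reaction-contingency networks: *elemental states* record the status of one
protein domain or residue (what partner is bound there, or which covalent
modification it carries), and *reactions* produce and consume those states,
while states in turn act as contingencies that activate or inhibit
reactions. Compiled to Boolean form, every reaction and every state becomes
a node that is ON or OFF; the vector of all node values is a network
*state*, updated in discrete synchronous ticks where each node's next value
is a Boolean function of the current values. Because the state space is
finite and the update deterministic, every simulation eventually enters a
cycle of states — an *attractor* — that stands in for a (pseudo-)steady
state of the cell.

boolvvv works on such models in the BoolNet text format (`targets, factors`
header, one `<node>, <expression>` line per node, operators `!`, `&`, `|`,
parentheses, constants `0`/`1`). Node semantics are recovered from the
rxncon naming convention: `A_[d]--B_[e]` is a bond state, `A_[d]--0` its
unbound neutral form, `A_[r]-{p}` a modification state and `A_[r]-{0}` its
neutral form, and names with a reaction-verb infix such as `_ppi+_` or
`_p+_` are reactions. The grammar is a parameter (`rxncon_grammar()`)
because models in the wild use additional verbs; unrecognized names are a
legitimate `unknown` class, never an error. The *neutral state* — all
reactions off, every component unbound and unmodified — is the default
initial condition throughout.

## Simulation and attractor comparison

`simulate_path()` iterates the synchronous update from an initial state
while recording visited states in a hash, stopping at the first revisit;
for deterministic dynamics the segment from the first occurrence of the
revisited state onward is exactly the attractor cycle. Clamps (`clamps()`)
model stimuli, inhibitors and knockouts: forced nodes are overwritten in
the initial state and after every tick, so their values are invariant along
the trajectory. `max_steps` defaults to 100,000 — a revisit is guaranteed
once more than `2^n` ticks have run, but memory has to be bounded somewhere
and the limit is configurable; exceeding it is a clear error rather than a
silent truncation.

Attractors are stored in a canonical rotation (the lexicographically
smallest packed state first). That one choice resolves several
underdetermined points at once: attractor identity becomes plain equality,
"the first state of the attractor" used when a ligand is added back is well
defined, and repeated runs are bit-reproducible.

Attractor similarity is the phase-shift-aware Hamming distance: both cycles
are repeated to the least common multiple of their lengths and the distance
is the minimum over all cyclic shifts of the mean per-node, per-tick
disagreement. This construction is symmetric, lies in `[0, 1]`, and is zero
exactly for rotation-equivalent cycles. For unequal-length cycles other
readings of "accounting for phase shifts" are conceivable; the LCM
construction is the one this package commits to, and `attractors_equal()`
additionally requires equal cycle lengths so that a fixed point never
equals a longer cycle.

## Ligand-cycling verification

`verify_model()` asks whether a model responds reproducibly to repeated
ligand stimulation. The ligand is designated by its unbound presence
node(s); removing it turns those nodes off and dissolves any complex
containing a ligand component, switching the partner's own neutral node
back on so the partner stays in the system. Adding it simply turns the
presence nodes on.

The workflow alternates no-ligand and with-ligand phases. The crucial
detail is that each transform is applied from *every* state of the current
attractor, not just one: if different intra-cycle states lead to non-equal
attractors, the destination depends on timing and the meta-attractor (the
cycle through attractor space driven by ligand events) is undefined — this
is *branching*, reported with all branch trajectories and the pairwise
attractor-distance matrix. When the with-ligand attractor is a fixed point
the fan-out is vacuous and can never create spurious branching. Rounds end
when a (no-ligand, with-ligand) attractor pair repeats, which must happen
because the dynamics are deterministic and the attractor space finite.

Consistency is deliberately stricter than "no branching". A model can halt
in a perfectly deterministic meta-attractor that nevertheless excludes its
own initial no-ligand attractor: the classic case is a substrate that stays
phosphorylated after ligand removal because no dephosphorylation reaction
exists. The system is then *trapped* — it never returns to its resting
state, even though each individual transition is unambiguous. Such runs
report `trap = TRUE` and `consistent = FALSE` alongside the meta-attractor
they did reach, so the irreversible-by-design case (apoptosis-like
behavior) remains inspectable rather than being collapsed into an error.
`consistent = TRUE` therefore means: no branching, and a reversible
two-sided response in which all no-ligand attractors agree and all
with-ligand attractors agree.

Multi-ligand scheduling is intentionally out of scope: a `ligand_spec()`
with several presence nodes is toggled as one unit, and no claim is made
about independent toggling orders.

## Truth tables and sensitivity

`truth_table()` simulates all `2^n` subsets of the declared stimuli and
inhibitors (active stimuli clamped ON, active inhibitors clamped OFF,
inactive perturbations untouched — "selected" perturbations are the only
ones forced) and averages each output over the attractor states, giving a
score in `[0, 1]` that is 1 exactly when the output is ON in every
attractor state. The default cap of 12 perturbations exists because the
table grows as `2^n`; the intended use on large models is module extraction
first.

Compression is display-oriented but *lossless*: a (perturbation, value)
pair is merged into a single `"any"` row only when all rows carrying that
value have identical score vectors and no previously merged row overlaps
the subcube being formed, so the rows always partition the assignment
hypercube and `expand_table()` reproduces the full `2^n` score map exactly.
Merging per (perturbation, value) pair — rather than across both values —
is the choice here; it is the weakest operation that still collapses the
"this inhibitor makes everything else irrelevant" pattern.

`sensitivity_analysis()` operationalizes a "semi-quantitative effect of
inhibition on the ligand-to-output signal" as a difference of differences:
the ligand response delta (with-ligand minus no-ligand attractor-averaged
activity, computed exactly as in verification round 1) under the
perturbation, minus the unperturbed baseline delta, giving effects in
`[-1, 1]` with 0 meaning no influence. Reactions are inhibited one at a
time; components are knocked out by clamping all of their reaction nodes
and non-neutral state nodes OFF while leaving the neutral nodes free, which
mirrors how a knockout removes activity without inventing new species.

## Scoring against MIDAS data

The experimental database follows the MIDAS convention of treatment
(`TR:`), acquisition-time (`DA:`) and data-value (`DV:`) columns, organized
as one sheet per experiment plus a `TreatmentDefs` sheet mapping treatment
names to model nodes and effect types (stimulation, inhibition, knockout).
Values must already be normalized to `[0, 1]`; out-of-range cells are
reported as normalization errors naming the cell, because silently
rescaling heterogeneous data would hide exactly the problems the score is
meant to surface. A database is a directory of CSV sheets or an `.xlsx`
workbook; an optional `OutputMap` sheet maps readout names to model nodes
(identity by default).

Since Boolean attractors are not time-resolved, the data are collapsed to
two points per (perturbation combination, output): the mean of all `t = 0`
measurements (pre-stimulation) and the mean of all `t > 0` measurements,
optionally restricted to user-supplied time bins. Predictions mirror the
experiment's two phases: the pre-stimulation run clamps knocked-out *and*
stimulated nodes OFF (the stimulus is explicitly absent before
stimulation), and the post-stimulation run starts from the pre-stimulation
attractor's canonical first state with inhibited and knocked-out nodes OFF
and stimulated nodes ON. Knockouts remain clamped in the post phase — a
gene that is absent does not return when a stimulus arrives. A combination
whose treatments simultaneously stimulate and inhibit the same node is
reported as an error, not resolved silently. For a verified-consistent
model the choice of seeding state within the pre-stimulation attractor
cannot change the outcome; the canonical first state makes the run
deterministic regardless.

Each cell is scored as the two-timepoint mean squared error
`((exp_pre - sim_pre)^2 + (exp_post - sim_post)^2) / 2` and the total score
averages all cells with data; a cell missing one timepoint is scored on the
available one (dividing by the number of available timepoints) and flagged,
and cells with no data are excluded and shown grey in the comparison grid.
The score runs from 0 (perfect agreement) to 1 (perfect disagreement).

## The synthetic fixtures, and what passing them shows

`make_cascade()` builds the canonical test system: ligand binding
(`L_ppi+_R_[ext]` forming `L_[lig]--R_[ext]` from the two neutral states),
a bond-gated kinase reaction phosphorylating the substrate, and optionally
a phosphatase reaction reversing it. The phosphatase is given a negative
contingency on the bond so kinase and phosphatase are never simultaneously
active; this keeps every attractor a fixed point, which makes the
reversible/trap dichotomy razor sharp: with the phosphatase the model
verifies as a clean two-attractor meta-attractor, without it the substrate
stays phosphorylated after ligand removal and verification reports a trap
whose two no-ligand attractors differ only in the substrate's
phosphorylation nodes. Extra kinase tiers scale the model while preserving
the dichotomy. The construction is fully deterministic, so the `seed`
argument is accepted only for interface uniformity.

`make_random_model()` draws `k` regulators and a uniform random Boolean
function per node, reproducibly from a seed; it exists to support
property-style testing in which the attractors found by simulation from
every one of the `2^n` states are compared against an independent
exhaustive enumeration of the transition graph (cycle extraction by
iterated squaring of the successor map — a different algorithm than the
simulator's first-revisit hashing).

`make_synthetic_midas()` writes a database whose `t = 0` and `t > 0` values
equal the model's own pre/post predictions plus optional clipped Gaussian
noise. With zero noise the scoring pipeline must return exactly 0, and
complementing every value must return exactly 1 (the fixture's predictions
are Boolean-extremal); these bounds exercise the collapsing, prediction and
MSE arithmetic end to end.

What these fixtures do *not* emulate: real experimental data have
between-lab normalization artifacts, non-extremal graded responses,
missing-at-random patterns and timepoint placements that straddle the
pre/post boundary; real compiled models contain Boolean gates, input nodes
and far denser contingency structure. Passing the packaged checks
demonstrates the algorithms' correctness on their defined semantics, not
the biological adequacy of any particular model.

## Numerical and design choices, in brief

* Cycle detection is exact (first revisit under deterministic updates);
  there are no tolerances anywhere in the Boolean core. The only
  floating-point arithmetic is attractor averaging and MSE, both plain
  means.
* Canonical attractor rotation (lexicographically smallest packed state
  first) is the single tie-break used for attractor identity, hashing, the
  "first state", and reproducibility.
* Module extraction keeps tagged nodes plus untagged boundary nodes
  referenced (transitively) by kept rules; removed nodes are substituted by
  their neutral-state value and constants folded, so extracted models are
  closed and valid. Quality filtering acts at the node level: the Boolean
  compilation has already merged contingencies into reaction rules, so
  removing a below-threshold reaction node is the faithful image of
  removing the rule.
* Trajectory alignment left-pads the shorter transient and phase-aligns
  the cycles by minimizing the LCM Hamming distance; global alignment of
  transients was considered and rejected as it can tear matched cycle
  columns apart.
* Degenerate inputs are errors with names in them: empty models, rules
  referencing undeclared nodes, clamp conflicts, treatments targeting
  missing nodes, truth tables past the size cap, databases without a
  `TreatmentDefs` sheet.

The packaged checks run at deliberate desk scale — random models of 4-12
nodes (50+ of them for the oracle comparison, exhausting all `2^n` initial
states each), perturbation sets up to 5, and the 8-node cascade for the
end-to-end pipelines — sizes chosen so the full exhaustive oracles remain
feasible while still covering cyclic attractors, branching and traps.

## Worked example

```{r example}
cas <- make_cascade(with_phosphatase = TRUE)
lig <- ligand_spec(cas$model, cas$ligand)
verify_model(cas$model, lig)

trap <- make_cascade(with_phosphatase = FALSE)
verify_model(trap$model, ligand_spec(trap$model, trap$ligand))

init <- remove_ligand(neutral_state(cas$model), lig, cas$model)
tt <- truth_table(cas$model, stimuli = cas$ligand,
                  outputs = "S_[site]-{p}", init = init)
tt
```

## Known limitations

Only synchronous deterministic updates are supported; asynchronous or
stochastic schemes, and rule-based/agent-based simulation, are out of
scope. Whole-model truth tables are intentionally capped. The XGMML writer
emits attributes but no layout coordinates. Reading `.xlsx` databases
requires the optional readxl package; writing databases always uses CSV
sheets.
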