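# boolvvv

Verification, validation and visualization of reaction-contingency Boolean
network models of cell signaling.

Reaction-contingency models describe signaling as *elemental states*
(what is bound or modified at one protein domain/residue) produced and
consumed by *reactions*, with states acting as contingencies that regulate
reactions. Compiled to a Boolean network — one ON/OFF node per reaction and
state, updated in synchronous ticks — such a model is cheap to simulate but
hard to trust: does it respond reproducibly to repeated stimulation, do its
modules behave as the literature says, and how well do its predictions match
measured data? boolvvv is for modelers who build these networks and need
those three questions answered mechanically.

## What it does

* **Model handling** — read/write BoolNet-format files
  (`targets, factors`), recover node semantics from rxncon-style names
  (`L_[lig]--R_[ext]`, `S_[site]-{p}`, `K_p+_S_[site]`), attach module/quality
  annotations, and extract self-contained tagged modules
  (`read_boolnet()`, `parse_node_name()`, `extract_module()`).
* **Simulation** — deterministic synchronous updates with clamped
  (forced-ON/OFF) nodes, exact attractor detection, attractor-averaged output
  activities, and a rotation-aware Hamming distance between cyclic attractors
  (`simulate_path()`, `quantify_attractor()`, `attractor_distance()`).
* **Verification** — cycle a ligand on and off, applying each transform from
  *every* attractor state, and map the reachable attractor space into a
  meta-attractor graph; detects *branching* (the destination depends on the
  intra-cycle state at the ligand event) and *traps* (the system never
  returns to its resting attractor, e.g. a substrate with no
  dephosphorylation reaction) (`verify_model()`, `export_state_graph()`).
* **Validation** — exhaustive `2^n` stimulus/inhibitor truth tables with
  lossless row compression (`truth_table()`, `compress_table()`);
  single-reaction inhibition and component-knockout sensitivity of the
  ligand response (`sensitivity_analysis()`); and MSE scoring against a
  MIDAS-format experimental database (`read_midas()`, `score_model()`).
  Each cell scores `((exp_pre − sim_pre)² + (exp_post − sim_post)²) / 2` and
  the total is the mean over cells with data: 0 is perfect agreement, 1
  perfect disagreement.
* **Visualization** — trajectory matrix plots, aligned two-trajectory
  overlays, bipartite regulatory-graph export (XGMML/GraphML), and per-tick
  animation frames (`plot_trajectory()`, `align_trajectories()`,
  `export_regulatory_graph()`, `export_animation_frames()`).
* **Fixtures** — a programmatic ligand→receptor→kinase→substrate cascade
  (reversible or trapped), seeded random networks, and a synthetic MIDAS
  generator, so the whole workflow is testable with no external data
  (`make_cascade()`, `make_random_model()`, `make_synthetic_midas()`).

## Worked example

```r
library(boolvvv)

cas <- make_cascade(with_phosphatase = TRUE)
lig <- ligand_spec(cas$model, cas$ligand)
verify_model(cas$model, lig)
#> Meta-attractor verification
#>   attractors found: 2 (1 no-ligand, 1 with-ligand)
#>   verdict: CONSISTENT - reversible meta-attractor: N1 -> W1

trap <- make_cascade(with_phosphatase = FALSE)
verify_model(trap$model, ligand_spec(trap$model, trap$ligand))
#> Meta-attractor verification
#>   attractors found: 3 (2 no-ligand, 1 with-ligand)
#>   verdict: INCONSISTENT - trap: the system does not return to its initial attractor after ligand removal
```

The consistent cascade reaches one attractor with ligand (substrate
phosphorylated) and returns to one resting attractor without it. Dropping
the phosphatase leaves the substrate phosphorylated after ligand removal:
two distinct "no-ligand" attractors that differ only in the substrate's
phosphorylation state — the flagged trap.

Scoring against a database generated from the model's own predictions:

```r
treatments <- list(
  treatment_def("LIG", "stimulation", cas$ligand),
  treatment_def("KIN-i", "inhibition", "K_p+_S_[site]")
)
db <- make_synthetic_midas(cas$model, treatments,
                           outputs = c("S_[site]-{p}", "L_[lig]--R_[ext]"),
                           dir = tempfile(), noise_sd = 0, seed = 1)
score_model(cas$model, db)
#> Model-vs-database score: 4 combination(s) x 2 output(s), MSE_tot = 0
```

MSE_tot = 0 means every predicted pre/post value matches the data exactly;
with every data value complemented the same pipeline returns exactly 1.

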