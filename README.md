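# interwater

Water-mediated hydrogen-bond bridges at protein–protein interfaces of
molecular-glue ternary complexes.

## The problem

Molecular glues (rapamycin, WDB002, …) stabilize ternary complexes between
an effector protein such as FKBP12 and a target protein (FRAP, CEP250).
Because the two proteins often make few direct contacts, individual water
molecules bridge them through short hydrogen-bond chains, and the stability
of these *water-mediated hydrogen bonds* changes when the glue binds.
`interwater` is for computational chemists and structural bioinformaticians
who have apo/holo MD trajectories (or crystal structures) of such systems
and want reproducible bridge statistics, flexibility profiles and
free-energy bookkeeping.

At its core:

* **Hydrogen bonds** are geometric: donor–acceptor distance ≤ 3.0 Å and
  D–H–A angle ≥ 120° (vertex at H); for hydrogen-free crystal models a
  distance-only criterion at 3.5 Å between N/O/S atoms is used.
* A **water bridge of order k ≤ 2** is a simple path
  P₁–w₁(–w₂)–P₂ whose every link is a hydrogen bond in that frame.
* Per residue pair: **occupancy** = fraction of frames with ≥ 1 path, and
  **frequency of occurrence** = mean number of distinct water paths per
  frame (can exceed 1 when several waters bridge the pair at once). Pairs
  are kept only if occupancy ≥ 0.20 (the persistence filter).
* **Flexibility**: equal-weight Kabsch superposition (proper rotation),
  per-frame RMSD, per-residue backbone RMSF, per-frame minimum inter-chain
  distance.
* **Thermodynamics**: ΔG = RT ln(K_d/c°) at c° = 1 M with first-order error
  propagation, and cooperativity
  ΔG⁰_coop = ΔG_ternary − ΔG_target–glue with SDs combined in quadrature.

A synthetic-trajectory generator (`forge_system()`) plants bridges with
known per-frame occupancy schedules and writes a ground-truth manifest, so
the whole pipeline is testable without downloading any simulation data.

## Worked example

```r
library(interwater)

## a small synthetic holo system with two planted bridges
spec <- interface_spec(n_residues_per_chain = 3, n_bulk_waters = 6,
                       noise_sigma = 0.02)
bridges_holo <- list(planted_bridge(1, 1, order = 1, occupancy = 0.85),
                     planted_bridge(2, 2, order = 2, occupancy = 0.60))
sys <- forge_system(spec, bridges_holo, n_frames = 500, seed = 11)

hb <- detect_hbonds_frames(sys$trajectory, sys$topology, hbond_criteria())
g1 <- select_atoms(sys$topology, "chain A")
g2 <- select_atoms(sys$topology, "chain B")
wb <- enumerate_water_bridges(hb, sys$topology, g1, g2)
stats <- pair_statistics(wb, n_frames = 500, condition = "holo", replica = "1")
apply_persistence_filter(stats, 0.20)
#>        pair occupancy frequency mean_order n_frames condition replica
#> 1 Ser1-Ser1     0.878     0.878          1      500      holo       1
#> 2 Ser2-Ser2     0.610     0.610          2      500      holo       1
```

Both planted pairs are recovered: `Ser1-Ser1` was planted at occupancy 0.85
and realised 0.878 in this finite run, `Ser2-Ser2` (a two-water bridge,
hence `mean_order` 2) at 0.60 → 0.610. The detection-based numbers equal
the generator's ground truth exactly (`truth_pair_statistics(sys$manifest)`
prints the same table), because planted geometry sits inside the criteria
with margin.

```r
kd_to_free_energy(41.2e-9, 5.7e-9)
#> binding: dG = -10.07 +/- 0.08 kcal/mol (computed-from-Kd)
cooperativity(energy_record("ternary", -63.34, 1.66),
              energy_record("CEP250-WDB002", -20.82, 0.70))
#> cooperative free energy: -42.52 +/- 1.80 kcal/mol
```

The Kd of the CEP250 ternary complex (41.2 ± 5.7 nM at 25 °C) converts to
−10.07 ± 0.08 kcal/mol, and the MM/GBSA component energies give a
cooperative free energy of −42.52 ± 1.80 kcal/mol — strongly negative,
i.e. the glue makes the protein–protein association much more favourable.

A full config-driven run (apo + holo replicas, comparison table, RMSF and
minimum-distance profiles, thermodynamics, run report) is
`run_pipeline(<config list or YAML path>)`; see `?run_pipeline`.

## Layout

* `R/` — forge (synthetic systems), structio (multi-model PDB I/O and
  selections), hbond, bridges, bridgestats, flex, thermo, crystal mode,
  pipeline.
* `tests/testthat/` — unit + property tests with independent brute-force
  oracles; `test-acceptance.R` holds the end-to-end checks.
* `vignettes/water-mediated-bridges.Rmd` — the methods vignette: model,
  conventions, generator design, numerical choices, limitations.
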