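---
title: "Water-mediated hydrogen-bond bridges at molecular-glue interfaces: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-mediated hydrogen-bond bridges at molecular-glue interfaces: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interwater)
```

## Scope and model

Molecular glues such as rapamycin and WDB002 stabilize a ternary complex
between the effector protein FKBP12 and a target protein (FRAP or CEP250).
Because the two proteins make few direct contacts, much of the interface is
solvated, and individual water molecules can connect the proteins by short
hydrogen-bond chains. `interwater` quantifies these *water-mediated hydrogen
bonds* in molecular-dynamics trajectories and compares their stability
between simulations with the glue bound (*holo*) and without it (*apo*),
alongside standard flexibility measures (RMSD, RMSF, minimum inter-chain
distance) and the binding/cooperativity free-energy bookkeeping.

A hydrogen bond is purely geometric here: donor heavy atom D carrying a
hydrogen H, acceptor heavy atom A, with

* donor–acceptor distance $d(D, A) \le 3.0$ Å, and
* angle $\angle(D, H, A) \ge 120^\circ$, vertex at the hydrogen
  ($180^\circ$ = linear).

A *water bridge of order k* is a simple path
$P_1 - w_1 - \dots - w_k - P_2$ between atoms of the two proteins in which
every link is a hydrogen bond in that frame; only $k \le 2$ is considered,
and for $k = 2$ the default requires the two waters to be hydrogen-bonded to
each other. Per residue pair, two statistics are accumulated over frames:

* **occupancy** — fraction of frames with at least one bridge path;
* **frequency of occurrence** — mean number of distinct water paths per
  frame. A value above 1 means several waters bridge the same pair
  simultaneously; frequency ≥ occupancy always.

Pairs are reported only when they persist for at least 20 % of the
simulation length (occupancy ≥ 0.20, boundary inclusive).

## Decisions taken where the convention is genuinely open

Several conventions are not fixed by common usage, so the package fixes them
explicitly and surfaces each as a configurable option:

* **Angle convention and boundaries.** The D–H–A angle is measured at the
  hydrogen, and both cut-offs are inclusive (`<=` on distance, `>=` on the
  angle). This matches the prevailing convention of trajectory-analysis
  toolkits; inclusivity is arbitrary but deterministic and documented
  (`hbond_criteria()`).
* **Path direction.** A water-mediated hydrogen bond names a *pair* of
  protein atoms, not a directed chain, so donor/acceptor roles along the
  path are ignored by default. `directional = TRUE` restricts paths to run
  donor→acceptor from the first group to the second.
* **Order-2 inter-water link.** The chain interpretation (the two waters
  hydrogen-bonded to each other) is the default; `ww_link = "oo_distance"`
  accepts mere oxygen–oxygen proximity instead, for sensitivity analysis.
* **Persistence.** "Lasted for at least 20 % of the simulation" is read as
  total occupancy ≥ 0.20, the standard practice for hydrogen-bond lifetimes
  in trajectory analysis; a longest-contiguous-run variant is available
  (`apply_persistence_filter(mode = "contiguous")`).
* **Path multiplicity.** Frequency counts distinct *water sets* per residue
  pair and frame; an order-1 and an order-2 path sharing their first water
  are distinct paths, and the same water set reached through different atom
  pairs of the same residues counts once.
* **Replica handling.** Replicas are never pooled into one trajectory;
  statistics are computed per replica and summarised across replicas as
  mean ± SD, and both per-replica and aggregated tables are emitted.
* **Superposition.** Backbone means N, CA, C, O; alignment is equal-weight
  Kabsch (proper rotation enforced, determinant +1) onto the first frame of
  each replica; RMSF is then taken about the time-average position, averaged
  over backbone atoms per residue. Mass weighting is deliberately not used —
  equal weighting is the convention when nothing else is stated.
* **Crystal structures.** Hydrogen-free models use a distance-only criterion
  between N/O/S atoms at 3.5 Å, the standard crystallographic practice,
  because no angle can be computed without hydrogens.

## Thermodynamic bookkeeping

Dissociation constants convert to binding free energies at the standard
state $c^\circ = 1$ M:

$$\Delta G = R\,T\,\ln \frac{K_d}{c^\circ}, \qquad
\sigma_{\Delta G} = R\,T\,\frac{\sigma_{K_d}}{K_d},$$

with $R = 1.987 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and 25 °C read as
$T = 298.15$ K. That choice of constants reproduces the published
conversions ($K_d = 12.0 \pm 0.8$ nM $\to -10.80 \pm 0.04$;
$41.2 \pm 5.7$ nM $\to -10.07 \pm 0.08$ kcal/mol) exactly at the printed
two-decimal precision, which a 5-digit gas constant does not.

The cooperative free energy of a ternary complex is

$$\Delta G^0_{\mathrm{coop}} = \Delta G_{\mathrm{ternary}}
  - \Delta G_{\mathrm{target\text{-}glue}},$$

negative values meaning the glue makes the protein–protein association more
favourable. Uncertainties combine in quadrature,
$\sigma = \sqrt{\sigma_1^2 + \sigma_2^2}$; this propagation rule is the one
that reproduces both published table SDs (±5.35 and ±1.80 kcal/mol) from
their components, which is why it was adopted over alternatives such as
per-replica differencing. Values are kept at full precision internally and
rounded to two decimals only for presentation. The MM/GBSA evaluation
itself is out of scope: its outputs enter as printed numbers through
`thermo_table()`.

```{r thermo}
kd_to_free_energy(12.0e-9, 0.8e-9)
cooperativity(energy_record("ternary", -61.15, 5.30),
              energy_record("target-glue binary", -34.82, 0.70))
```

## The synthetic-data generator and what it does (not) emulate

Real 500-ns solvated-protein replicas cannot be regenerated at desk scale,
so every statistical claim in the package is validated on synthetic
trajectories with *planted ground truth* (`interface_spec()`,
`planted_bridge()`, `forge_system()`). The generator emulates exactly the
features the detectors consume:

* two serine-like chains facing each other across a solvated gap, with
  hydroxyl anchor sites pointing into the interface;
* water bridges of order 1 and 2 switched on/off per frame by an occupancy
  schedule — independent Bernoulli draws by default (the kinetics of real
  bridge formation are unknown, so the simplest exchangeable model is the
  default), or a two-state Markov chain with rates `p_on`/`p_off` whose
  stationary occupancy must equal the target, for dwell-time sensitivity;
* isotropic Gaussian thermal noise on every coordinate (default
  $\sigma = 0.02$ Å) and an optional rigid-body wobble of chain B;
* a manifest recording every per-frame on/off draw, sufficient to recompute
  every planted statistic without the trajectory
  (`truth_pair_statistics()`).

Key geometric choices: an "on" link is placed at 2.8 Å donor–acceptor with
collinear O–H···O geometry, leaving ≥ 0.1 Å and ≥ 10° of margin inside the
criteria so boundary flicker cannot occur; an "off" bridge displaces its
dedicated water to a parking region far beyond the cutoff rather than
deleting it, keeping the atom count constant as multi-model formats require;
a clearance check guarantees that no planted water comes within 3.2 Å of
any polar atom it is not meant to bond, so the rendered truth is exact. With
the 0.2 Å distance margin, thermal noise up to about
$\sigma \approx 0.05$ Å leaves detection-based statistics identical to the
manifest; the default 0.02 Å is used throughout the tests. No periodic box
is emitted (bridges are local; minimum-image handling is exercised
separately in the readers and detectors).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: continuous water exchange and residence-time
kinetics, competing bulk solvent at the interface, protein conformational
coupling, force-field energetics, and periodic boundary wrap-around. The
generator validates the *bookkeeping* (detection, path enumeration,
occupancy statistics, filters, comparisons), not the physics upstream of it.

## Numerical choices and degenerate inputs

* Detection is vectorised over all donor–hydrogen × acceptor pairs; the
  test suite holds it equal to a brute-force double loop on every tested
  frame, so any future acceleration must preserve the exact result set.
* Kabsch superposition uses SVD with a reflection guard; fewer than three
  non-collinear atoms is an error. A single-frame RMSF is all-zero with a
  warning. Empty donor or acceptor tables yield empty results, not errors.
* An unknown chain or residue in a selection yields an empty set plus a
  warning (a malformed query is an error) — so a typo in a chain name
  surfaces loudly without aborting batch runs.
* Frames are 0-based in the multi-model files and 1-based inside R, matching
  each environment's convention; author residue numbers are preserved
  untouched (FKBP12-style 1–107 and FRAP-style 2018–2112 coexist).
* Reported statistics are invariant under frame reordering and, for the
  bridge set, under relabelling of water ids.

## Problem sizes used in the validation suite

The automated suite exercises: oracle equivalence on 50 random frames per
detector; planted-truth recovery on 20 random apo/holo configurations of
2000 frames each (occupancy within the binomial 99 % confidence interval of
the manifest value, exact persistence-filter agreement at the 0.20
boundary, and sign-correct apo/holo frequency differences whenever the
planted occupancy contrast is at least 0.3); RMSF convergence to
$\sigma\sqrt{3}$ within 5 % at 2000 frames; and Kabsch-vs-quaternion
agreement within $10^{-6}$ Å. These sizes were chosen so each property is
tested at the scale where its statistical guarantee is meaningful.

## Known limitations

* Only orders ≤ 2 are enumerated; longer chains are out of scope by design.
* No significance testing is attached to apo/holo frequency differences;
  the comparison reports replicate mean ± SD only.
* The crystal-structure mode inherits all limitations of distance-only
  criteria (no angles, no symmetry mates, no occupancy weighting); on a
  user-supplied PDB entry such as 1FAP it recovers the named bridging pairs
  (e.g. Lys48–Tyr2105), but exact-count agreement with literature
  inventories depends on their unstated criteria and is treated as a soft
  check.
* Binary trajectory formats (DCD/XTC) are supported only insofar as an
  external reader maps them onto `trajectory()`; the native tested path is
  multi-model PDB.
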