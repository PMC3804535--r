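---
title: "Stepwise assembly of protein loops: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise assembly of protein loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the ansatz

Predicting the conformation of a protein loop on a fixed scaffold at atomic
accuracy is hard because the all-atom energy landscape is rugged: favorable
states are narrow basins stabilized by specific side-chain packing and
hydrogen bonds, and coarse search phases that strip side chains cannot see
them. Stepwise assembly (SWA) takes the opposite approach: it **never
leaves the all-atom representation**. The loop is grown one residue at a
time, enumerating backbone torsions on a grid at each step, optimizing side
chains in full atomic detail, and carrying forward only low-energy
intermediates. The working hypothesis (the *stepwise ansatz*) is that
native loops are reachable through sequences of residue-by-residue
additions whose intermediates are themselves low-energy.

A build-up state is a *stage* $(i, j)$: the N-terminal fragment is built
forward from the residue before the loop (residue $k-1$) through residue
$i$, and the C-terminal fragment backward from residue $l+1$ through $j$.
Stages form a directed acyclic graph: growth moves $(i-1,j) \to (i,j)$ and
$(i,j+1) \to (i,j)$, chain-closure moves bridge 1-3 remaining gap residues,
and recombination pairs independently built pure-N and pure-C fragments.
The full graph costs $O(N^2)$ stage computations for an $N$-residue loop;
the simplified graph (pure-N and pure-C chains only) costs $O(N)$ and is
run first. If the final energy gap between the two best models is below 1
energy unit ($\approx 1\,k_BT$), the calculation has not clearly converged
and is repeated on the full graph.

## The moves

**Growth** (`grow_step`). The new residue is added with ideal bond lengths
and angles and a capping group — a methylamide cap after the N-fragment
terminus, an acetyl cap before the C-fragment terminus — so that the next
peptide unit's hydrogen-bonding groups are present before that residue is
built. Backbone $\phi,\psi$ of the new residue (and, at protocol scale,
the fragment-adjacent residue) are enumerated from $-180°$ to $180°$ in
20° steps (18 samples per torsion, left-inclusive so $\pm 180°$ is not
duplicated). $\omega$ is fixed at $180°$, with $0°$ (cis) also sampled
before proline. Samples whose Ramachandran score exceeds 0.8 units are
discarded. Each surviving assignment gets side-chain optimization by
*rotamer trials* — seeded-random one-at-a-time greedy replacement from the
rotamer library with $\pm 1\sigma$ expansions at $\chi_1/\chi_2$ — then
models are leader-clustered at 0.10 Å (backbone N, Cα, C, O of the rebuilt
residues, no superposition since the scaffold frame is shared), the lowest
400 are kept, each is minimized (BFGS over the new residue's backbone
torsions plus neighboring $\chi$), and clustered again.

**Stage collation** (`run_dag`). All models arriving at a stage are pooled,
the 4000 lowest-energy models kept, reclustered at 0.25 Å over the full
rebuilt fragments, and the lowest 400 carried forward. At the final
full-loop stage, models are reclustered at 1.0 Å over loop Cα and the five
lowest-energy models are the predictions.

**Closure** (`close_from_stage`). For stages with 1-3 gap residues the gap
is bridged: one designated end gap residue is grid-sampled, the remaining
bridge torsions are closed by cyclic coordinate descent (CCD), each torsion
set in turn to the analytic angle minimizing the summed squared deviation
of three virtual/real atom pairs at the cutpoint (virtual N/Cα on the
N-side, virtual C on the C-side). Closures with RMS deviation ≥ 1.5 Å are
discarded; survivors get full-loop side-chain optimization, clustering, and
full-loop torsional minimization with the `linear_chainbreak` term (the sum
of the three atom-pair deviations, in Å) applied at weight 150.0, which
holds or improves the near-perfect closure geometry. Because coarse
minimization can stall short of the sub-0.01 Å regime, the full-loop
optimizer alternates a CCD re-tightening pass with backbone-only
minimization; the *last* operation is always a minimization under the
weighted energy, so the "closed" geometry is also an energy optimum. Both
gap-end variants are attempted (they coincide for a single-residue gap),
and pure-N/pure-C ensembles are additionally recombined (pairings ranked by
summed fragment energy, capped by `max_pairs`).

## The surrogate energy

The packaged energy function is deliberately transparent rather than a
reproduction of any published force field; its terms mirror the *roles* of
the terms the protocol depends on:

| term | form | default weight (sampling / minimization) |
|---|---|---|
| `fa_atr` | Lennard-Jones attraction, $r \ge r_{min}$, cubic switch to 0 at 6 Å | 0.8 / 0.8 |
| `fa_rep` | LJ repulsion for $r < r_{min}$, linear continuation below $0.6\,r_{min}$ (finite at $r=0$) | **0.10 / 0.44** |
| `hbond_bb`, `hbond_sc` | smooth radial well on donor-acceptor distance, flat to 2.9 Å, hard zero at 3.2 Å, times $\cos^2$ of the D-H···A deviation from linearity | 1.17 / 1.17 and **3.1 / 1.1** |
| `rama` | bilinear interpolation of shipped 20°-binned log-odds tables (generic / glycine / proline / pre-proline) | 0.2 |
| `rotamer` | $\min_{\text{rotamer}} \sum_k (1 - \cos(\chi_k - \hat\chi_k))$ over the library | 0.4 |
| `linear_chainbreak` | sum of the three virtual/real atom deviations (Å) | 0 (150 during closure) |
| `coordinate_constraint` | per-residue fade spline on Cα deviation: 0 below 2 Å, 10 units above 4 Å, cubic with zero end slopes between | 0 (1 in native-constrained runs) |

One energy unit is treated as one $k_BT$ everywhere (retention windows,
the convergence gap). The *sampling* dialect (soft repulsion, strong
side-chain hydrogen bonds) forgives the discreteness of grid and rotamer
sampling; the *minimization* dialect scores and ranks models. Hydrogen-bond
strength is never attenuated by burial, in either dialect. There is no
explicit solvation term: this is the surrogate's largest known physical
omission, and it biases the model toward over-forming surface hydrogen
bonds. Polar hydrogens only are modeled (amide H plus side-chain N-H/O-H);
nonpolar hydrogens are implicit in the carbon radii.

The Ramachandran tables are built procedurally from mixtures of wrapped
Gaussian basins (construction script under `data-raw/`), scaled so that the
0.8-unit filter retains roughly the ±1.8σ core of each basin — wide enough
that every canonical secondary structure is buildable, narrow enough that
the grid survivors stay in the tens per residue. The rotamer library is a
coarse backbone-independent set (gauche+/trans/gauche− at sp³ chis, ±90° at
aromatic $\chi_2$, σ = 10°); its $\pm1\sigma$ $\chi_1/\chi_2$ expansion
multiplies candidates at most 9-fold. Both are versioned package data, not
literals in code.

## Geometry

All loop atoms are placed by sequential internal-coordinate (NeRF-style)
construction from one fixed table of ideal bond lengths and angles
(Engh-Huber-like values, shipped in `inst/extdata/residue_topology.tsv`).
Bond lengths and angles are never sampled or minimized; the only degrees of
freedom are torsions. The molecule is a tree of bonded-parent pointers, so
a torsion edit rotates exactly the atoms on the free-fragment side of the
bond — or toward the cutpoint once one exists — and scaffold backbone atoms
can never move (attempting it is an error). Proline's $\phi$ is fixed near
−65° by its ring, which is placed as a rigid ideal template. The amide H
of residue $l+1$ is coupled to the loop through $\phi_{l+1}$; this takeoff
torsion is frozen unless `sample_loop_takeoff` is enabled.

## The synthetic fixtures

`make_scaffold` builds deterministic, clash-checked all-atom chains from
canonical secondary-structure torsions plus seeded jitter: a `helix_turn`
topology (helix — glycine/aspartate turn — strand) and a `hairpin`
(antiparallel strands joined by a two-glycine turn, with strand torsions
calibrated once, against ideal-geometry builds, so the cross-strand
backbone H-bond ladder sits near 2.95 Å; the calibration script is
documented in `data-raw/` notes). A short whole-chain torsional relaxation
relieves residual template strain.

`make_recovery_problem` turns a scaffold region into a benchmark-style
problem: the loop is polished (side-chain trials plus full-loop
minimization around a mid-loop cutpoint with the chainbreak penalty) until
it is a strong local optimum of the package's own energy, recorded as the
native answer, then the loop atoms and *all* side chains are stripped.
Because the planted native is an optimum of the same energy the pipeline
searches, recovery isolates the sampling algorithm: a failure where the
search finds a *lower*-energy non-native loop indicates the energy surface
(here: the surrogate's limitations), a failure to reach the native at all
indicates sampling. What these fixtures do **not** emulate: real loops are
optima of physics, not of our surrogate; crystallographic scaffolds have
non-ideal geometry, alternate conformations, waters and ligands; and real
benchmark loops are longer and more irregular. Passing the packaged
recovery tests therefore demonstrates the *algorithm*, not force-field
accuracy on real proteins.

## Problem sizes and numerical choices

The full protocol scale (400-model ensembles, 4000-model stage pools,
adjacent-residue resampling, ~10^3 CPU-hours per loop) is the package
default (`swa_config("default")`). The packaged examples, tests, and the
acceptance script run the `"coarse"` preset, the desk scale chosen for
single-CPU work: per-parent retention 8, stage retention 50, 600-model
pools, adjacent-residue resampling off, one rotamer-trials sweep, BFGS
capped at 30 iterations, 200 CCD cycles with a plateau break, and at most
8 parent models per closure edge. Scaffolds of 16-24 residues with loops
of 3-6 residues keep a full run in the minutes range. The protocol
structure — grid, filters, clustering radii and retention *rules*,
closure screens, weights — is identical at both scales.

Numerical choices worth knowing:

* **Tie-breaks.** Clustering is greedy in energy order with stable order of
  insertion, so equal-energy models resolve deterministically by parent and
  grid index.
* **Seeds.** All stochasticity (rotamer-trial visit order, annealed
  prepacking) flows from one master seed through stable per-stage hashes,
  so serial and re-ordered executions agree.
* **Minimization.** BFGS with central-difference gradients in unwrapped
  radians (wrapped on write-back), up to three restarts to reset the
  Hessian, and a best-of guarantee: the returned model never scores above
  the input.
* **Degenerate inputs.** Empty move sets and empty ensembles are no-ops;
  collinear anchor frames, unknown residue codes, scaffold-torsion edits
  and sequence/structure mismatches are errors.
* **Closure bookkeeping.** The 1.5 Å screen applies to the RMS deviation
  over the three virtual/real atom pairs (the chainbreak *sum* divided by
  √3-per-atom metric); the per-model 400 cap is applied both before and
  after the per-model minimization.

## Open design points, as decided here

* The closure-screen metric ("chain closure RMSD") is implemented as the
  RMS over the three virtual/real pairs.
* Capping groups are modeled with the atoms that matter for hydrogen
  bonding plus one methyl carbon for sterics (methylamide: N, H, CH3;
  acetyl: C=O, CH3).
* Rotamer-trials sweeps per build step default to 2 (1 at desk scale);
  the optimum on the small coupled cases is reached either way.
* The escalation rule is always honored unless the user pins `mode`;
  desk-scale examples pin `mode = "linear"` and report convergence.
* The in-process stage executor replaces any job-farm infrastructure;
  stage outputs can be archived to disk (`archive_write`) for inspection,
  but runs are not resumable mid-graph.

## Known limitations

The surrogate energy has no solvation, no electrostatics beyond hydrogen
bonds, a backbone-independent rotamer library, and approximate aromatic
ring closure geometry; absolute energies are not comparable to any
published force field. Desk-scale retention is far below protocol scale,
so sampling breadth — especially the diversity of fragment ends available
to chain closure — is the binding constraint on longer loops; zero
surviving closures on a given edge at coarse settings is expected behavior,
not an error. Disulfides, RNA-containing systems, and non-ideal bond
geometry are out of scope.
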