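---
title: "Methods: fragmentation model, balance identities, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation model, balance identities, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lssmf)
```

## The model

Systematic molecular fragmentation approximates the total electronic
energy of a large molecule as a signed sum over small, overlapping,
hydrogen-capped fragments. The pipeline has five stages, each exposed as
package functions:

1. **Bond perception.** Interatomic distances are compared against sums of
   Cordero covalent radii. A pair at distance $R$ with radii $r_i, r_j$
   gets bond order 1 if $R < r_i + r_j + \Delta_{sb}$, tightened to 2 if
   $R < r_i + r_j - \Delta_{db}$ and to 3 if $R < r_i + r_j - \Delta_{tb}$.
2. **Grouping.** Groups — the elementary fragmentation units — are the
   connected components of the heavy-atom graph restricted to bonds of
   order $\ge 2$, plus each component's hydrogens. In saturated alkanes
   every carbon is its own group; an aromatic ring merges into one group.
   Only order-1 (severable) bonds connect groups.
3. **Bonded expansion at level $m$.** All connected sets of $m+1$ groups
   are the *main fragments* (coefficient $+1$). Renormalization terms with
   signed integer coefficients cancel the multiple counting among
   overlapping mains.
4. **Nonbonded fragments at level $n$.** Group pairs never co-resident in
   a bonded fragment contribute through-space interactions: at level 1 as
   dimers of capped groups, at level 2 as three-body complexes (a group
   against a two-group fragment) with dimer renormalization. A cutoff —
   DBE (Å on the closest-atom distance) or DCRR (dimensionless
   $\min_{ij} R_{ij}/(r_i+r_j)$) — prunes distant complexes; beyond-cutoff
   interactions are neglected entirely, which is what makes fragment
   counts, and hence cost, linear in system size.
5. **Capping and assembly.** Every severed bond $i\!-\!j$ is replaced by a
   hydrogen on the bond vector at
   $X_i + \rho\,(X_j - X_i)$, $\rho = (r_i + r_H)/(r_i + r_j)$.
   The energy ledger is
   $E_b = \sum_i f_i E(F_i)$ and, by default,
   $E_{nb} = \sum_\mu g_\mu [E(\text{complex}_\mu) - \sum E(\text{component})]$.

## Coefficient derivation as an intersection closure

The renormalization coefficients are computed by closing the set of main
fragments under pairwise intersection (splitting disconnected
intersections into connected components) and assigning, in decreasing
size order,

$$c(S) \;=\; 1 \;-\; \sum_{T \supsetneq S,\; T \in \text{plan}} c(T),$$

with zero-coefficient sets dropped. This operationalizes "repeating
groups enter with appropriate negative coefficients" as a provable
property rather than a heuristic: by construction every closure set — and,
by the Möbius structure of the intersection lattice, every group and every
group pair inside some main fragment — has signed coverage exactly 1. Three
identities follow and are asserted on every plan the engine builds:

* **group balance** — each group nets once;
* **pair balance** — each main-covered pair nets once, others zero;
* **cap balance** — the signed cap-hydrogen count is zero (for
  2,4-dimethylpentane at level 3: $+14 - 20 + 6 = 0$).

Together they imply the *exactness theorem* the test suite exercises: for
any additive energy model with per-atom terms and a group-pair potential,
and no cutoff, the assembled $E_b + E_{nb}$ equals the direct energy of
the whole molecule up to floating-point error. Level-2 nonbonded plans
additionally reproduce any three-body term summed over their eligible
(group, edge) complexes.

Main-fragment enumeration grows connected sets from each seed group inside
a graph-distance ball of radius $\lceil m/2 \rceil$ — the radius of a tree
on $m+1$ vertices, so every connected set is found from one of its central
groups. On alkanes the two-hop pool (the union of bonded domains) holds at
most 16 groups. The result is equal to exhaustive connected-subset
enumeration, which the tests verify against an independent brute-force
oracle on graphs up to 12 groups.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `deltaSB` | 0.40 | Å | single-bond slack over radius sums |
| `deltaDB` | 0.05 | Å | double-bond tightening |
| `deltaTB` | 0.20 | Å | triple-bond tightening |
| `m` | 3 | — | bonded level; mains have $m+1$ groups |
| `nbLevel` | 1 | — | 1 = dimers, 2 = three-body complexes |
| `deltaNB` | ∞ | Å | DBE cutoff on closest-atom distance |
| `dcrrThreshold` | ∞ | — | DCRR cutoff on $\min R_{ij}/(r_i+r_j)$ |

The perception tolerances are calibrated against textbook bond lengths
with the Cordero radii (carbon sum 1.52 Å): C–C 1.54 Å reads single,
aromatic ≈1.39 Å and ethene 1.33 Å double, acetylene 1.20 Å triple — so
benzene-like rings merge into one group while alkane carbons stay
separate. They are configuration values, not constants: production values
for a new element set should be re-checked the same way. For carbon-only
contacts a DBE cutoff of $\Delta$ Å corresponds to a DCRR threshold of
$\Delta/1.52$ (6.0 Å ≈ 4.0), which the suite verifies on hydrogen-free
chains.

## Design choices at genuinely open points

* **Interaction vs. raw complex energies in $E_{nb}$.** The ledger
  defaults to interaction energies (complex minus capped components), so
  far-separated complexes contribute nothing and neglecting beyond-cutoff
  terms is self-consistent. `assembleEnergy(..., nbEnergy = "raw")`
  preserves the alternative reading; monomer energies are deduplicated
  either way.
* **Three-body cutoff.** A 3BC is kept when the single group is within the
  cutoff of the two-group fragment as a whole (closest-atom criterion),
  not when all three pairwise distances pass. This matches the
  closest-atom definition of the pair cutoff; the dimer corrections then
  use the pair criterion, so the signed pair coverage always equals the
  allowed-pair indicator.
* **Correction coefficients.** Dimer corrections carry whatever integer
  the coverage arithmetic dictates (target − count). Typical values are
  negative, but pairs touched by no three-body complex fall back to $+1$
  dimers; the invariant, not the sign, is what guarantees energy
  consistency.
* **Hydrogen assignment.** A hydrogen with several bonded heavy atoms
  joins the nearest one (lowest atom index on exact ties); isolated heavy
  atoms form their own group with a warning. Group ids follow the first
  occurrence of each group's lowest-index heavy atom, making plans
  reproducible across runs and platforms.
* **Rings.** Cyclic group graphs are accepted — disconnected intersections
  are split into connected components before entering the closure — but
  acyclic molecules are the validated domain; ring systems should be
  treated as experimental.
* **Config format.** Run configurations serialize as flat YAML
  (`config.yaml` beside the outputs) mirrored by CLI flags, flags winning
  on conflict; YAML was chosen over other flat formats because a parser is
  universally available in R environments.

## Numerical choices

* Coordinates are Å end-to-end; energies hartree, with kcal/mol
  (627.509) only in display summaries.
* Signed assembly sums are performed with R's extended-precision
  accumulator over a contribution vector rather than a running double:
  bonded expansions cancel numbers of order $|E(\text{fragment})|$ against
  each other, and naive accumulation costs several digits on long chains.
  With this choice the exactness defect stays below $10^{-10}$ hartree
  (observed $\sim 10^{-12}$) across all tested levels.
* Degenerate geometry guards: molecules reject atom pairs closer than
  0.1 Å; the generators reject anything under 0.9 Å; cap placement rejects
  coincident anchor/removed positions.
* Emitted jobs use a fixed ordering (size-descending, then lexicographic
  group keys) and a fixed `%14.6f` coordinate format, so reruns are
  byte-identical.

## What the synthetic fixtures do and do not emulate

The generators produce idealized alkanes: C–C 1.54 Å, C–H 1.09 Å,
tetrahedral angles, all-anti chains, with branches packed by a
deterministic steric score and terminal methyls twist-relaxed on a
5° grid. The maximally branched C17 fixture (a central carbon with four
tert-butyl arms) idealizes that molecule's severe real-world strain as a
uniformly stretched 1.66 Å C–C bond so tetrahedral angles can be kept
without nonbonded contacts entering bonding range. An optional seeded
Gaussian jitter (σ ≤ 0.01 Å) exists to confirm that perception and plans
are stable under small perturbations.

These fixtures exercise the combinatorics, capping and assembly exactly,
but they are not conformational ensembles, contain no heteroatoms or
multiple bonds beyond the dedicated ethene/ethyne checks, and carry no
electronic structure: passing the closed-loop tests demonstrates the
correctness of the fragmentation algebra, not the accuracy of any
fragment-based approximation to a real wavefunction method, which depends
on the external engine and on cutoff/level choices.

Test problem sizes are deliberately modest — chains up to C40 for scaling
counts, C20 for the full exactness sweep over $m \in 1..6$ and both
nonbonded levels — because every identity checked is size-independent;
the scaling blocks exist to show the linear-versus-quadratic fragment
count behavior, not to benchmark.

## Known limitations

* Embedded point charges for polar molecules (a production feature of the
  original pipeline's step 13) are out of scope; plans for polar systems
  therefore omit electrostatic embedding.
* No electronic-structure backend is bundled: `toyParams()` and the
  dry-run emitter are the built-ins; real engines connect through the job
  manifest and the `readEnergies()` table.
* PDB support is minimal (elements + coordinates; altLoc 'A'/blank only);
  protonation and structure preparation must happen upstream.
* Bond perception is purely geometric; unusual bond lengths (transition
  states, metal coordination) will need adjusted tolerances or manual
  grouping.
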