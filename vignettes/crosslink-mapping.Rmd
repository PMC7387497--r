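---
title: "Mapping XL-MS distance restraints on structure ensembles"
author: "xlmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping XL-MS distance restraints on structure ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmapr)
```

## The procedure

A cross-link between residue $i$ of protein $A$ and residue $j$ of protein
$B$ is an upper bound on their Cα–Cα distance, set by the cross-linker
spacer plus the two side chains. `xlmapr` evaluates each cross-link on the
whole ensemble of deposited structures that contain the relevant protein(s):

1. **Candidate selection.** A structure index (one row per structure ×
   protein, with method and resolution) is filtered to entries with
   resolution ≤ 3.5 Å; NMR entries without a deposited resolution are always
   kept. Intermolecular links require both partners in the same entry;
   intramolecular links only their own protein. Links with no candidate at
   all end up in the *novel* class — they point at regions or contacts that
   no high-resolution structure covers.
2. **Anchor resolution.** Coordinates are reduced to a Cα table (author
   chain ids, author residue numbers). For each cross-linked residue a
   tripeptide anchor centred on the residue (a dipeptide at sequence
   termini, which must then sit at the corresponding chain terminus) is
   matched against the chain's resolved sequence at the assumed author
   number; on failure the anchor is shifted through offsets
   $0, +1, -1, \dots, +5, -5$. The first unique hit wins and its offset is
   recorded; no hit, or an ambiguous hit, excludes that cross-link/structure
   pair. Matching is against *consecutive resolved residues*, so an
   unresolved neighbour correctly breaks the anchor rather than silently
   measuring across a gap.
3. **Measurement.** $d = \sqrt{(x_1-x_2)^2 + (y_1-y_2)^2 + (z_1-z_2)^2}$
   for every chain combination mapped to the link's proteins. Chain pairs
   that look like asymmetric-unit copies (mixed case, e.g. `A`–`b`; or
   two-character ids with differing first characters, e.g. `AA`–`BB`) are
   flagged and excluded from classification, as are between-copy
   measurements of intramolecular links on multi-copy proteins (those are
   interesting — they can reveal oligomer contacts — but they are not
   evidence about the monomer fold, so they are segregated).
4. **Classification.** A structure satisfies a link when its *minimum*
   eligible distance is at or below the threshold: one compatible copy pair
   is enough to explain the chemistry. Aggregating per-structure verdicts
   gives the four-way class: satisfied / violated / mixed-type / novel.
   Mixed-type links are the directly useful ones: they demonstrate that the
   linked region moves between deposited conformations.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| resolution cutoff | 3.5 | Å | ensemble restricted to models where Cα positions are trustworthy; NMR without resolution always included |
| intra threshold | 30 | Å | intramolecular links need no interface flexibility allowance |
| inter threshold | 37.5 | Å | 150% of the ~25 Å maximum Cα–Cα span of cross-linked lysines, allowing for conformational flexibility of interfaces |
| tie policy | inclusive (≤) | — | a distance exactly at the threshold satisfies; exposed as a switch because the boundary convention is not universal |
| alignment window | ±5 | residues | covers start-Met cleavage and small construct offsets without admitting remote spurious matches |
| SASD grid spacing | 1.0 | Å | path length discretization error is a fraction of a residue spacing |
| SASD clash radius | 2.0 | Å | heavy-atom exclusion comparable to a united-atom van der Waals radius |
| restraint ladder | 45 → 25 step 5 | Å | gradual tightening preserves the integrity of flexible domains during remodeling |
| restraint σ | 0.1 | (modeling program units, conventionally Å) | recorded verbatim; the consuming engine interprets it |
| environment cutoff | 10 | Å | bounds the static context around the single mobile protein |

The threshold sweep (`sweep_thresholds()`) exists precisely because the
inter threshold is a judgement call: a plateau of the violated-link count
around the chosen cutoff shows the classification is not knife-edge
sensitive to it.

## Solvent-accessible distances

`build_occupancy_grid()` marks every grid cell whose centre lies within the
clash radius of a heavy atom as occupied, with a guaranteed free margin
around the bounding box. `accessible_distance()` snaps each Cα to its
nearest free cell (within twice the clash radius — a buried endpoint is
*unreachable*, not an error), runs Dijkstra over the 26-connected free-cell
graph with Euclidean edge weights, and adds the two straight segments from
the true endpoints to their snapped cell centres. Because the result is a
genuine start-to-end polyline, it can never be shorter than the Euclidean
distance — the invariant the Euclidean-vs-accessible comparison relies on.
Side chains are not reconstructed; both measures are Cα-anchored, which
underestimates the physical path by roughly a side-chain length on each end
(a systematic, not random, bias, so the *difference* between accessible and
Euclidean distance remains informative). This is a functional equivalent of
grid path solvers used in the field, not a reimplementation of any
particular one; spacing, clash radius and connectivity are configuration,
and on empty space the accessible distance converges to the Euclidean one
as the spacing shrinks (checked in the tests at spacings 2, 1 and 0.5 Å).

## The synthetic generator

`assemble_complex()` builds ideal α-helical Cα traces (rise 1.5 Å, 100°
turn, radius 2.3 Å — giving the canonical ~3.8 Å consecutive spacing) with
seeded random sequences; `duplicate_asymmetric()` adds a displaced copy
under either chain-relabeling convention; `perturb_numbering()` applies
constant shifts, start-Met removal or segment deletions with the true
offset recorded; `sample_crosslinks()` draws residue pairs whose true
distances lie in a requested band. Generated sequences have all tripeptides
unique, so anchor placement on the toy chains is unambiguous *by
construction* — real proteins only approximate this (low local sequence
repetition), which is exactly why the ambiguity-exclusion rule exists in
the aligner.

What passing the ground-truth suite shows: the bookkeeping — numbering
reconciliation, asymmetric-unit exclusion, classification logic, file
round-trips — is exact on inputs whose truth is known. What it does not
show: robustness to real-world mess the generator does not emulate
(insertion codes beyond skipping, chimeric chains, residue-level
heterogeneity, non-standard residues at link sites, genuinely repetitive
sequences). The benchmark (`synthetic_benchmark()`) runs 24 complexes,
cycling plain / asymmetric-lowercase / asymmetric-two-character / shift /
start-Met / segment-deletion variants, two structures each (the second
moves one protein so long links change class between structures, populating
the mixed-type class), roughly 200 links in total — sizes chosen so the
whole study re-runs in seconds while exercising every code path.

## Numerical and design choices

* **Window scan order** is nearest-offset-first with the positive offset
  before the negative at equal magnitude; deterministic and favouring the
  smallest correction consistent with "around the assumed position".
* **Ambiguity** (an offset admitting more than one placement, in practice a
  duplicated author number) fails the anchor; an unmeasurable distance is
  better than a possibly wrong one.
* **Altlocs** keep the highest occupancy, ties alphabetically; residues
  with insertion codes are skipped with a warning (the integer-keyed
  bookkeeping has no slot for them and they are rare in large assemblies);
  multi-model files contribute model 1 only; non-standard residues map to
  `X` and are excluded from anchors.
* **Canonical pair order** (lexicographic on accession, then position)
  makes redundancy collapse and all reports order-independent.
* **Chemistry validation warns, never rejects**: the upstream
  identifications are taken as ground truth; the check (Lys/Ser/Thr/Tyr or
  N-terminus on one reactive site, Lys or N-terminus on the other, both
  orderings tried) is a sanity layer for table-assembly mistakes.
* **Cross-copy intra distances** are measured once per unordered chain
  pair and kept in the record with a flag, never classified.
* **The restraint ladder is always emitted in full** with an early-stop
  annotation; whether a stage suffices depends on remodeling outcomes this
  package deliberately does not compute. A link already under threshold
  gets an empty ladder.
* **Both satisfaction percentages** ("always satisfied" and "satisfied in
  ≥ 1 structure") are reported, since both framings are in common use and
  they answer different questions (consistency vs explicability).
* **Environment proximity is Cα-to-Cα**, consistent with the package's
  structure model; with all-atom input the cutoff would bite slightly
  earlier.

## Limitations

* No legacy PDB-format parsing and no assembly expansion from symmetry
  operators: files are taken as deposited, and the asymmetric-unit rules
  are heuristics over chain-label conventions — a deposition that violates
  the conventions will not be caught (numeric or blank chain ids
  deliberately never trigger the rules).
* N-terminal cross-links are anchored at residue 1; when residue 1 is
  absent from a structure the dipeptide anchor fails rather than migrating
  to the first resolved residue.
* SASD is Cα-anchored on a discrete grid: path lengths carry a
  discretization overhead of up to about one cell diagonal per turn, and
  obstacle monotonicity can in principle be perturbed by endpoint
  re-snapping when an obstacle lands on a snap cell.
* The pipeline reproduces distance evidence only; remodeling itself
  (restraint consumption, template search, model optimization) is out of
  scope by design.
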