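---
title: "Planning and simulating BASIC DNA assembly runs"
author: "basicbuild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and simulating BASIC DNA assembly runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basicbuild)
```

# The method

BASIC assembly builds circular constructs from stored plasmid parts and a
set of orthogonal linkers in four steps. `basicbuild` compiles a construct
design table into the exact liquid-handling plan for each step, and models
the underlying molecular biology well enough to predict every product
sequence. This vignette is the package's own account of how and why.

## The design grammar

A construct design is a circular alternation `linker, part, linker, part,
...` starting with a linker; the element after the last part wraps to the
first linker. Walking the circle gives one **clip** per part: the triple
(linker before, part, linker after). Clips — not constructs — are the unit
of Step 1, because a clip shared between constructs is made once and
pipetted into several assemblies. Deduplication is by the exact triple,
and clip order is the order of first occurrence while scanning constructs
in file order, so regenerated scripts are reproducible without sorting
surprises.

Half-linkers live on the linker source plate as `<name>-P` (prefix half,
ligates at a part's upstream/Prefix end) and `<name>-S` (suffix half,
downstream/Suffix end). A clip therefore draws from wells `<L_before>-P`
and `<L_after>-S`. Both halves must exist for any linker a design uses;
validation reports a missing half as an error.

## Capacities and layout

One run supports at most **48 clip reactions** and **96 constructs**. The
48 comes from the plate geometry: raw clips occupy the left half-plate
(columns 1–6, filled column-major A1, B1, … H1, A2, …), and purification
deposits each eluate in the mirror well (same row, column + 6) of the
right half. All plate iteration in the package is column-major; the
mirror map is a bijection between half-plates and is checked structurally.

## Volume arithmetic

All volumes are microlitres, fixed per reagent class (parts are assumed
pre-diluted to 200 ng/µl, so there is no concentration-based
normalisation):

* **Clip reaction, 30 total**: 20 master mix + 1 part + 2 × 1 half-linker
  + water to volume. The master mix is prepared manually; per 20 µl
  (one reaction): 3 of 10× T4 ligase buffer, 1 of BsaI-HF v2, 0.5 of T4
  DNA ligase, 15.5 water. Totals scale by reactions × (1 + excess); the
  default excess of 0.1 covers manual-mix dead volume and appears only in
  the meta-information, never in dispensing instructions. A configuration
  whose DNA volumes leave negative water is rejected.
* **Purification**: 54 beads per well; washes of 150 of 70% ethanol
  (2 by default — the count is configurable since protocols differ);
  resuspension in 40 water (configurable, must be ≥ the 38 transferred);
  38 of eluate moved to the mirror well. Bind/settle/dry delays default to
  300/60/300 s and are emitted as delay instructions.
* **Assembly, 15 total**: 1.5 per purified clip + annealing buffer (20 mM
  Tris-HCl pH 8.0, 10 mM MgCl~2~, 50 mM KCl) to volume. Every assembly
  well totals exactly 15 regardless of clip count; with the default
  volumes at most 9 clips fit, keeping at least one clip-volume of buffer
  — zero-buffer assemblies are refused.
* **Transformation**: 5 of assembly into 20 of competent cells at 4 °C
  (cells are assumed pre-aliquoted in a commercial 96-well plate), heat
  shock as a user prompt (per the cell manufacturer's instructions), 125
  of SOC, 1 h recovery at 37 °C, then spotting: one single-well agar tray
  per requested spot volume (5 and/or 10), on an 8 × 12 grid at 9 mm pitch
  whose coordinates mirror the transformation plate. With controls
  enabled, wells A12–H12 are reserved (backbone-plasmid in A12–D12,
  no-plasmid in E12–H12 — the split is a package choice), capping a run
  at 88 constructs.

Emitted scripts satisfy a ledger property: for every destination well,
the summed dispensed volume equals the planned volume exactly, and every
planned transfer appears exactly once. Multi-dispense is deliberately not
used — one aspirate per dispense keeps instruction counts simple,
deterministic and auditable, at the price of speed. For the same reason
the package makes no claim of instruction-level equivalence with any
other implementation of these protocols: pipetting decomposition (mix
counts, air gaps, multi-dispense) is a free choice that volume ledgers,
not step counts, pin down.

Tip policy: fresh tip for every DNA-bearing transfer; reuse within a
single clean-reagent distribution (water, master mix, ethanol, buffer).
The policy is recorded per instruction and configurable.

## The sequence model

Fragments are written on the plus strand with two integers giving the
lengths of the 5′ single-stranded extensions at each end (the right
extension belongs to the bottom strand but is stored as plus-strand
text). Two fragments join when the right overhang text of one equals the
left overhang text of the other — for 4-nt scars this is ligation, for
21-base tails annealing. This representation makes every join a string
concatenation dropping one duplicated overhang, which is why independent
concatenation oracles can check the machinery in the tests.

Digestion models a Type IIS enzyme (default BsaI: `GGTCTC`, 1-nt spacer,
4-nt overhang) on both strands of circular or linear molecules. A valid
stored part has exactly one unprotected plus-strand site (in the Prefix)
and one minus-strand site (in the Suffix); fewer is a missing-site error,
more is an internal-site error naming the positions. A methyl mark
anywhere inside a recognition hit protects it completely — hemi- versus
full methylation is not distinguished, since a single C-5 methyl group
suffices to block cleavage, and marks never increase the cut count
(a tested monotonicity property).

Assembly order is recovered from tail complementarity alone, never from
input order: each clip's right tail must match exactly one other clip's
left tail, the matching must close a single circle using every clip, and
ambiguous matches (a linker used twice) or leftover clips are errors.
Tail matching requires exact 21/21 identity; there is no mismatch
tolerance because the standard's orthogonal linker sets are designed for
exact annealing. The predicted circle is rotated so the first part core
of the design starts at position 0, giving stable output; features
(parts and linkers, 0-based half-open) tile the circle and share only
their 4-nt scar junctions.

Idempotence verification re-scans the product: it must contain exactly
one regenerated, unprotected Prefix-like and Suffix-like site, and
digesting the product must return the payload between them. Methylation
is not propagated to products — the marks exist only on the synthetic
linker oligos, so the regenerated sites are cuttable, which is precisely
what makes the standard idempotent. Any unprotected site outside the
regenerated pair is flagged in the construct's notes.

Canonical Prefix/Suffix and commercial linker sequences are **data, not
constants**: they load from a JSON/YAML linker configuration and
GenBank/FASTA part files. The package hardcodes no published sequence;
test fixtures use synthetic sequences with the same structural grammar.

## The fixture generator

`factorialSpec()` describes the built-in demonstration library: a
three-gene operon (sfGFP, mCherry, BFP) on a p15A backbone, expanded over
4 promoters, per-gene RBS options (3 for sfGFP, 2 each for mCherry and
BFP) carried on position-specific UTR-RBS linkers, and 2 gene orders,
minus all combinations of the weak J23105 promoter with the sfGFP RBS1
linker: 4 × 12 × 2 − 8 = 88 constructs, 38 unique clips.

Two generator choices deserve explanation:

* **Gene orders.** Because a UTR-RBS linker is identified by operon
  position plus RBS label, the same linker can serve different genes in
  different orders, and the deduplicated clip count depends on which two
  orders are chosen. Enumerating all order pairs shows the count ranges
  from 34 to 39; the default pair — (sfGFP, mCherry, BFP) and its
  rotation (mCherry, BFP, sfGFP) — is one of the two that yield exactly
  38 clips, matching the library this design space is known to compile
  to. The orders are configurable, and the construct count (88) is
  order-invariant even though the clip count is not.
* **RBS split.** The 3/2/2 split over (sfGFP, mCherry, BFP) is the unique
  assignment consistent with "2 or 3 RBSs per gene" and a 96-combination
  product; it is recorded as an assumption in generated metadata.
  Promoter names other than J23105 are arbitrary Anderson-series labels.

Destination wells fill column-major over columns 1–11, leaving column 12
for the transformation controls.

`makeToyLibrary()` generates the synthetic sequences behind the
simulator tests: seeded, byte-for-byte reproducible random parts and
linkers obeying the stored-part grammar, with rejection sampling so no
stray recognition motif appears outside the planted Prefix/Suffix sites
(junction-spanning motifs cannot arise because every junction's text is
contained in a checked fragment). What these fixtures exercise is the
*structural* correctness of planning and simulation — alternation,
deduplication, volumes, overhang logic, idempotence. What they do not
emulate: real sequence composition (GC content, repeats), synthesis or
ligation errors, annealing thermodynamics, or transformation efficiency
— so passing tests say nothing about wet-lab yield, only that the plans
and predictions are internally exact.

## Problem sizes and determinism

All tests and the acceptance script run at desk scale: the 88-construct
library (the package's natural full-scale case), toy libraries of 3-6
designs with 60-nt part cores, and randomized property checks of 10-25
iterations — enough to cover every boundary (48th clip well, 96th
construct, zero-water, zero-buffer) while keeping a full run in seconds.
Every random choice is seeded; planning and emission are purely
deterministic functions of their inputs, and the run manifest records
MD5 digests of the inputs so identical outputs are traceable to
identical inputs.

## Known limitations

* The simulator is exact-match and structural: no thermodynamics, no
  ligation fidelity or efficiency model, no primer or oligo design.
* One clip plate per run (the left half-plate); larger builds need
  multiple runs.
* The GenBank writer/reader covers the subset the package emits (LOCUS
  topology, misc_features with labels, ORIGIN); it is not a general
  GenBank parser.
* The robot-script rendering is a textual backend for review, not a
  validated executable protocol; deck slots are symbolic labels bound by
  configuration.
* Spreadsheet input and SBOL exchange are out of scope.
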