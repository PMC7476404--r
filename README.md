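# basicbuild

Planning and in-silico simulation of automated BASIC DNA assembly.

## The problem

BASIC (Biopart Assembly Standard for Idempotent Cloning) joins standard DNA
parts through orthogonal linkers in four bench steps: (1) **clip reactions**,
where BsaI digestion releases each part from its storage vector and T4
ligase attaches a prefix (P-) and a suffix (S-) half-linker; (2) **SPRI
purification** of the clips on paramagnetic beads; (3) **assembly**, where
purified clips anneal through their 21-base single-stranded linker tails
into circular constructs; and (4) **heat-shock transformation** with
spotting onto selective agar. Because the methylated LMP/LMS linkers
regenerate the standard Prefix and Suffix around the payload, every product
is itself a valid BASIC part — the standard is idempotent.

Running this workflow on a low-cost liquid-handling robot at 96-well scale
means turning a table of construct designs into exact, auditable pipetting
plans. `basicbuild` is that compiler, plus the sequence model that predicts
what each assembly will look like. It is aimed at synthetic-biology labs
planning combinatorial construct libraries (e.g. promoter x RBS x gene-order
scans of an operon).

Given three CSV inputs — construct designs (one row per construct:
destination well, then alternating linker/part names, read circularly), a
part plate map and a half-linker plate map — the package:

* validates the designs against the plates (unknown reagents, broken
  linker/part alternation, missing linker halves, duplicate wells);
* derives the **deduplicated clip set** (each part with its flanking
  linker halves; shared clips are made once and reused across constructs),
  enforcing the platform capacities of 48 clip reactions and 96 constructs;
* computes exact volumes: 30 µl clip reactions (20 µl master mix; per
  reaction 3 µl 10× ligase buffer, 1 µl BsaI, 0.5 µl T4 ligase), 54 µl
  bead additions, 150 µl ethanol washes, 38 µl eluate transfers, 15 µl
  assemblies at 1.5 µl per clip, 125 µl SOC per transformation, and 5/10 µl
  agar spots with controls in wells A12–H12;
* emits one deterministic instruction script per step, rendered as picklist
  CSV/JSON, markdown protocol, and robot-API-style text, bundled under a
  run manifest with input digests;
* predicts each construct's circular sequence with a methylation-aware
  Type IIS digestion / ligation / 21-base annealing model, writes annotated
  GenBank, and verifies idempotence by re-digesting the product.

## Worked example

The built-in fixture generator expands the default factorial operon
library: 4 promoters × (3 GFP RBSs × 2 mCherry RBSs × 2 BFP RBSs) × 2 gene
orders = 96 combinations, minus the 8 pairing the weak J23105 promoter with
the GFP RBS1 linker — 88 constructs, five parts and five linkers each.

```r
library(basicbuild)

fx  <- makeFactorialDesign()           # designs + part/linker plate maps
run <- planBasicRun(fx$designs, fx$partPlate, fx$linkerPlate)
run
#> BasicRun: 88 constructs, 38 clip reactions, 4 scripts
run$clipPlan
#> ClipPlan: 38 unique clips for 88 constructs
#>   wells assigned: A1 ... F5
run$recipe
#> MasterMixRecipe for 38 reactions (excess 10%):
#>                   per_reaction_ul total_ul
#> ligase_buffer_10x             3.0    125.4
#> bsaI                          1.0     41.8
#> t4_ligase                     0.5     20.9
#> water                        15.5    647.9
run$scripts$step1
#> Script step 1: 192 instructions (190 transfers), deck: clip_plate, part_plate, linker_plate, reagents
head(clips(run$clipPlan), 3)
#>      prefix              part    suffix
#> 1       LMS p15A_cmR_backbone       LMP
#> 2       LMP            J23100 UTR1-RBS1
#> 3 UTR1-RBS1             sfGFP UTR2-RBS1

writeRunOutputs(run, "my_run")         # picklists, protocols, manifest
```

The 88 constructs deduplicate to 38 clip reactions: the backbone clip is
shared by everything, each promoter clip by all constructs starting the
operon with the same first RBS, and so on — this reuse is what makes the
96-well format fit 88 parallel assemblies. The master-mix totals include a
10% manual-pipetting excess; per-reaction composition is fixed.

Sequence prediction on synthetic sequences with the real structural grammar
(4-nt scars, 21-base tails, GGTCTC sites):

```r
toy <- makeToyLibrary(seed = 1)
res <- predictConstructs(toy$designs, toy$partSeqs, toy$linkerSeqs)
res$constructs$toy1
#> PredictedConstruct 'toy1': 337 bp circular, 6 features
verifyIdempotence(res$constructs$toy1)$pass
#> [1] TRUE
```

A command-line wrapper for the same pipeline ships at
`inst/cli/basicbuild` (subcommands `fixtures`, `validate`, `plan`, `emit`,
`simulate`; exit 1 on validation errors, 2 on capacity errors).

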