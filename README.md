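# g4topo

Topology annotation and geometric analysis of intramolecular
G-quadruplex (G4) 3D structures, for structural biologists and nucleic
acid chemists working with deposited PDB/mmCIF coordinates or designed
G4 sequences.

## What it does

G4s are four-stranded nucleic-acid structures built from stacked
G-tetrads: planar cycles of four guanines linked by Hoogsteen hydrogen
bonds (N1–H⋯O6 and N2–H⋯N7). Viewed from the top of the stem (5′-tetrad)
with the strands numbered clockwise and the first strand running down
(d), a one-block G4 adopts one of eight topologies determined by the
strand-direction pattern:

| pattern | topology | pattern | topology |
|---------|----------|---------|----------|
| dddd | parallel | ddud | hybrid1 |
| dudu | antiparallel-chair | dddu | hybrid2 |
| duud | antiparallel-basket | dudd | hybrid3 |
| dduu | antiparallel-basket2 | duuu | hybrid4 |

`g4topo` detects the tetrads from Hoogsteen donor–acceptor geometry,
assembles the stem (strand columns, clockwise numbering, blocks), and
derives the full per-structure report: topology, glycosidic syn/anti
(gc) patterns per tetrad, groove-width signature (wide ≥ 16 Å, narrow
≤ 11.5 Å, intermediate between), the loop taxonomy — propeller (p,
adjacent strands / different tetrads), lateral (l, adjacent / same
tetrad), diagonal (d, opposite / same tetrad), internal (i) — with
clockwise/anticlockwise progression signs, discontinuities (bulges,
snapbacks, two-block layouts), 0-nt loops and the V-shaped strands that
follow them, stem-extremity sides, rise/twist/handedness and tetrad
planarity.

Two quantitative components complement the annotator:

* a **geometric loop-span model**: a loop of *n* nucleotides spans
  `(n + 1) × 6.25 Å` (the mean successive C5′–C5′ step); a diagonal loop
  must clear `21.0 + 2 × 3.42 ≈ 28 Å`, which is why diagonal loops need
  at least 4 nt (a 3-nt loop models to 25 Å);
* a **rule engine** mapping loop-length triples (L1, L2, L3) to the
  topologies observed to accommodate them (e.g. two 1-nt loops force
  parallel; (2,3,2) forces antiparallel-chair; (2,4–5,2) forces
  antiparallel-basket), with rule provenance and caveats for modified
  guanines or bound ligands.

A built-in generator (`build_g4()`) produces idealized coordinate models
for all eight topologies (plus two-block layouts, bulges, snapbacks,
left-handed stems and Gaussian noise) with known ground truth, so the
entire annotation stack is testable without downloading structures.

## Worked example

```r
library(g4topo)
m   <- build_g4("antiparallel-basket", n_tetrads = 3,
                loop_lengths = c(2, 4, 2))
annotate_g4(m)
#> G4 annotation: synthetic-antiparallel-basket
#>   topology: antiparallel-basket (duud)
#>   tetrads: 3
#>   gc pattern: saas assa assa
#>   grooves: wini
#>   loops: -ld+l (2,4,2 nt)
#>   extremities: same
```

The report reads: strand pattern `duud` (antiparallel-basket); the
first tetrad's gc letters clockwise are syn-anti-anti-syn with the
inverted pattern below; grooves wide/intermediate/narrow/intermediate;
the chain makes an anticlockwise lateral loop, a diagonal loop and a
clockwise lateral loop of 2, 4 and 2 nt; both chain ends exit on the
same side of the stem.

The rule engine agrees that these loop lengths admit only this fold,
and the geometric model shows why the diagonal loop needs its 4 nt:

```r
allowed_topologies(rule_query(2, 4, 2))
#> Loop lengths (2,4,2) [DNA]
#> Allowed: antiparallel-basket (100%)
#>   rule R3d - L1 = L3 = 2, L2 = 4-5: basket (diagonal central loop)

diagonal_feasibility(3)
#> $feasible  FALSE
#> $modeled_length  25
#> $threshold  27.84
```

Real structures are annotated the same way:
`annotate_g4(read_structure("1kf1.pdb"))`, or from the shell via
`inst/exec/g4topo annotate 1kf1.pdb`, `... predict --loops 2,3,2`,
`... simulate --topology hybrid4 -o out.pdb`, `... summarize table.tsv`.

## Documentation

The methods vignette (`vignettes/g4-annotation.Rmd`) describes the
model, the conventions (orientation, clockwise numbering, progression
signs), every tunable threshold with its default and rationale, what
the synthetic generator does and does not emulate, and known
limitations.
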