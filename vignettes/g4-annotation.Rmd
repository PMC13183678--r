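---
title: "Annotating G-quadruplex topologies: models, conventions and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating G-quadruplex topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4topo)
```

## The model

An intramolecular G-quadruplex (G4) is a knot in a single nucleic-acid
chain: four guanine tracts fold into a stem of 2–4 stacked G-tetrads,
each tetrad a planar cycle of four guanines held by Hoogsteen hydrogen
bonds (N1–H⋯O6 and N2–H⋯N7, donor to acceptor around the cycle). The
stem's four vertical guanine columns are the *strands*; the connectors
between them are the *loops*. Everything `g4topo` reports follows from
a small set of orientation conventions:

* **Top and bottom.** The stem is viewed from top to bottom. The top
  (tetrad 1) is chosen so that the strand carrying the chain's 5′-most
  stem guanine runs *down*. For canonical structures this makes tetrad
  1 the 5′-tetrad; for hybrid4 structures that start with a 5′-bottom
  snapback it correctly leaves the 5′ end in a middle tetrad.
* **Clockwise numbering.** Strands are numbered clockwise as seen by a
  viewer above the top tetrad, starting from the strand with the
  5′-most stem guanine (strand 1, always direction `d`). Working the
  optics out: with the stem axis `u` oriented top→bottom and a
  right-handed in-plane frame `(e1, e2, u)`, clockwise on the viewer's
  image corresponds to *increasing* azimuth `atan2(v·e2, v·e1)`. This
  single convention reproduces the canonical pictures on synthetic
  structures (parallel strand order follows the chain; the chair's
  first loop connects strands 1 and 4).
* **Handedness.** The signed inter-tetrad twist is measured about the
  same axis; +30°/step is right-handed (RH). Left-handed stems simply
  measure negative and raise the `platypus_suspect` flag.
* **Loop progression.** Loop signs are read from the *bottom*: a
  transition from strand *k* to *k−1* (clockwise from below) is `+`, to
  *k+1* is `−`. Diagonal and internal loops carry no sign.

### Loop taxonomy

Loops are classified by where their two anchoring stem guanines sit,
independent of loop length or strand directions: **propeller** (p) =
adjacent strands, different tetrads; **lateral** (l) = adjacent
strands, same tetrad; **diagonal** (d) = opposite strands, same tetrad;
**internal** (i) = same strand bottom→top, or any connector crossing
blocks in a two-block structure. Adjacency is on the clockwise square
(strands k and k±1 mod 4); opposite is k and k+2. The rare
opposite-strand different-tetrad connector is reported as diagonal.
This partition is exhaustive, so every connector gets exactly one kind.

A **0-nt loop** (a single phosphate group) is always propeller and
only exists when a discontinuity precedes one of the two guanines it
connects; the annotator verifies this licensing and warns otherwise.
The V shape traditionally attributed to such loops actually belongs to
the *strand that follows* the 0-nt loop: its three phosphorus atoms
trace a V through the stem. `v_shaped_strands()` flags a strand when it
follows a 0-nt loop and the angle at the middle of three successive P
atoms drops below 140° — on idealized structures V-shaped strands
measure ≈ 130° while straight helical strand paths stay above 150°, so
the default separates the two regimes with margin on both sides.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `hbond_cutoff` | 3.5 Å | Hoogsteen contact scale. An edge between two guanines is *strong* when the mean of its two donor–acceptor distances (N1→O6, N2→N7) is ≤ cutoff; candidates are collected up to cutoff + 0.75 Å. A 4-cycle is accepted with ≥ 3 strong edges, or all four within cutoff + 0.5 Å. The mean-distance form tolerates deposited-structure distortion (and 0.3 Å coordinate noise) without admitting spurious cycles. |
| `planarity_tol` | 0.5 Å | tetrads above this best-fit-plane RMS are flagged `non-planar`, never rejected (deposited 2-tetrad baskets with short diagonal loops are exactly the interesting cases). |
| stacking bounds | 2–6.5 Å | base-centroid distance for vertical adjacency between consecutive tetrads; outside this the assembly aborts with an ambiguity error rather than guessing. |
| syn window | (−90°, 90°] | chi = O4′–C1′–N9–C4 (purines) / O4′–C1′–N1–C2 (pyrimidines); standard nucleic-acid convention. Undefined chi (missing atoms) reports `undefined`, never silently `anti`. |
| groove letters | w ≥ 16 Å, n ≤ 11.5 Å | thresholds centered between the observed anchors (~17 Å wide, ~15 Å medium, ~12 Å parallel-side, ~11 Å narrow); "medium" and "intermediate" share the letter `i`. Widths are the *mean* over tetrads of adjacent-strand C5′–C5′ distances; per-tetrad minima are also reported but signatures use the mean. |
| geometry constants | 6.25 / 3.42 / 21.0 Å | mean successive C5′ step, mean guanine rise, diagonal C5′ separation. All overridable through `g4_constants()`; the diagonal threshold `21.0 + 2 × 3.42 = 27.84 Å` (≈ 28) rederives automatically from overrides. |
| V angle | 140° | see above. |

The diagonal-loop threshold implements the clearance as **one rise at
each loop end** (2 × 3.42 Å) above the diagonal C5′ span, which
reproduces the reported ≈ 28 Å total; the supplementary derivation
behind that figure is not available, so this reconstruction — matching
the printed value — is the package's reading.

## The rule engine

`allowed_topologies()` encodes the observed loop-length regularities as
prioritized rules (R1: ≥ two 1-nt loops → parallel; R2: L1 = L3 = 1;
R3: L1 = L3 = 2 family; R4: L1 = L3 = 3 family), each carrying its
provenance and the dataset percentage as an *ordinal label*
(major/minor), not a probability — the source counts are dataset
frequencies, not a calibrated model, and the engine is a constraint
checker, not a predictor. Modified guanines (e.g. 8-bromo-G, which
forces syn) and bound ligands are strains that void the forcing rules;
they emit caveats instead of exclusions. Unmatched queries return all
eight topologies with a "no rule" caveat, so the result is never
empty. Long central loops (≥ 10 nt = 3 Watson–Crick pairs + 4-nt turn,
`duplex_capable()`) are treated as duplex-forming, which is what lets a
15-nt L2 behave like a 3-nt one in the chair rule.

## The synthetic generator

`build_g4()` is a first-class module, not a fixture: it emulates the
stated world the annotator is tested against.

What it emulates: planar tetrads whose guanine placement is solved
numerically so the Hoogsteen donor–acceptor distances come out at
~2.9 Å and the C1′ corners at the physical ~7.5 Å radius; stacking at
rise 3.42 Å and twist ±30°; the canonical chain path of each topology
(reproducing the dominant loop combinations: `-p-p-p`, `+l+l+l`,
`-ld+l`, `+ld-l`, `-p-l-l`, `-pd+l`, `-l-l-p` and the snapback hybrid4
forms); glycosidic letters written into the O4′ placement via chi (syn
+60°, anti −120°), with the canonical per-tetrad pattern — tetrad 1
syn-on-down/anti-on-up strands, inverted from tetrad 2 on, all-anti
for all-parallel stems; backbone C5′ atoms on a 9.6 Å cylinder with an
18° azimuthal lean set by strand direction, which makes the groove
signatures (wide between d→u neighbours, narrow between u→d) emerge
from geometry rather than from a lookup table; loop nucleotides on
circular arcs with ~6.25 Å C5′ spacing; phosphates interpolated along
the backbone path (which is what renders V-shaped strands); bulges,
the 2-nt 5′-bottom snapback of hybrid4 with its 0-nt loop, a 2+2
dddd/uuuu two-block layout, flanking nucleotides, left-handed stems
and seeded Gaussian noise.

What it does **not** emulate: real sugar-ring chemistry (loop residues
carry only P/C5′/C1′; stem sugars only the atoms the annotator reads),
ions, hydrogens, sequence-dependent loop conformations, NMR ensemble
heterogeneity, or energetics. A green round-trip therefore establishes
that the conventions are self-consistent and the classifiers exact on
ideal geometry and robust to 0.3 Å noise — not that detection
thresholds are optimal for every deposited structure.

Two generator choices worth recording: a 2-tetrad hybrid4 is built
without the snapback (with only two tetrads there is no middle tetrad
for the 5′ end; deposited 2-tetrad hybrid4 structures do not exist),
and diagonal loops shorter than 4 nt are refused at build time (the
feasibility model above) unless `force = TRUE`.

## The synthetic characteristics table

The dataset-accounting module normally consumes the per-structure
characteristics spreadsheet distributed with the source dataset. That
file cannot be redistributed here, so
`synthetic_characteristics_table()` reconstructs a row-level stand-in
from printed aggregate counts only: 353 structures (318 one-block + 35
two-block), the per-topology structure/non-redundant-sequence counts,
four polymorphic sequences shared across topologies, and the 8:3
parallel:chair split of the (2,2,2)-loop subset. Row-level details
(synthetic sequences, loop lengths) are placeholders; the table
validates the aggregation machinery, not the dataset. Note one
source-internal inconsistency: the per-topology non-redundant counts as
printed sum to 198, while the stated pair total is 197 (= 192 unique
one-block sequences + 5 extra pairs); the reconstruction follows the
197/192 accounting.

## Degenerate inputs and error behaviour

Fewer than four guanines or no closed Hoogsteen cycle → an empty tetrad
list, and the annotator reports `undetermined` (with an empty, present
loop field). A single tetrad → a degenerate stem; pattern, grooves and
extremities are errors at the operation level and `undetermined` at the
report level. Ambiguous stacking aborts assembly with the offending
distances. When snapbacks break the strand directions the topology
falls back to matching the gc pattern and groove signature against the
canonical per-topology expectations, reported with
`confidence = "pattern" | "signature" | "both"` instead of the default
`"pattern"`.

## Known limitations

* Mixed tetrads (G·C·G·C), triads and pentads are out of scope; a
  3-guanine tetrad completed by an extrinsic molecule is reported as
  not detected.
* Left-handed/platypus structures are only flagged
  (`platypus_suspect`), not sub-classified.
* Internal (D-)loops carry no progression sign; the viewpoint for one
  is not defined in the conventions this package follows.
* The two-block generator covers the 2+2 dddd/uuuu parallel/parallel
  layout only; the annotator handles other block layouts but they are
  untested against ground truth.
* Groove letters from *mean* widths may disagree with tools that use
  minimum widths on strongly distorted deposited structures; both
  quantities are reported.

All numeric claims in this vignette (the 12.5/18.75/25/27.84 Å spans,
the Table-style signatures, the robustness grid) are computed by the
test suite (`tests/testthat/`) and the acceptance script
(`scripts/acceptance.R`), not asserted by hand.
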