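---
title: "Structure-based comparison and screening of single-strand annealing proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based comparison and screening of single-strand annealing proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annealr)
```

## The problem this package addresses

Single-strand annealing proteins (SSAPs) — Rad52 in eukaryotes, Redβ, RecT,
Erf and Sak3 in phage and bacteria — promote the pairing of complementary
single-stranded DNA during double-strand break repair. Their sequences have
diverged to the point where pairwise identity is often below 10%, yet they
share a characteristic fold: a three-stranded β-sheet traversed by an α-helix,
accompanied by a β-hairpin of variable complexity. Because structure is
conserved several-fold longer than sequence, relationships within this
superfamily are best assessed on predicted 3D structures rather than
sequences.

`annealr` implements that structural workflow end to end: read predicted
models (with per-residue pLDDT confidence in the B-factor column), filter by
mean confidence, compute TM-score structural similarity for all pairs, build
an average-linkage dendrogram, pick medoid representatives, screen every
structure against the representatives at tiered TM thresholds, quantify
helix/strand residue counts inside the two diagnostic motifs, and test
whether a monomer is geometrically compatible with an 11-subunit ring by
superposition and steric-clash counting. A deterministic synthetic-structure
generator supplies inputs with the statistical properties the analysis
assumes, so the entire pipeline — and its test suite — runs without any
external downloads.

## The statistic at the core: TM-score

For a residue mapping between structures $a$ and $b$ with post-superposition
Cα distances $d_i$,

$$\mathrm{TM} = \frac{1}{L_\mathrm{norm}} \sum_{i=1}^{L_\mathrm{aligned}}
\frac{1}{1 + (d_i/d_0)^2}, \qquad
d_0 = \max\!\bigl(0.5,\; 1.24\,(L_\mathrm{norm}-15)^{1/3} - 1.8\bigr),$$

normalized either by the length of $a$ or of $b$. Scores above 0.5
conventionally indicate the same fold; above 0.7, close structural agreement.
The alignment itself is found by a TM-align-style heuristic: seed mappings
from gapless threading at multiple offsets and from matching
secondary-structure strings, then iterate superposition (Kabsch), a
$1/(1+(d/d_0)^2)$ score matrix, and dynamic programming (gap-open penalty
0.6, no extension penalty, diagonal-preferring traceback) until the mapping
repeats. Everything is deterministic for fixed inputs.

Two normalization choices appear downstream and are recorded in all outputs:

* **pairwise trees** use the mean of the two normalizations (symmetric by
  construction);
* **screening** normalizes by the representative's length, so the
  representative acts as a fixed yardstick across queries of different
  lengths.

## Module-by-module notes

### Structure I/O and the confidence filter

PDB ATOM records are parsed by fixed columns; only the first MODEL is read,
alternate locations keep the first occurrence, residues are ordered by
(residue number, insertion code), and residues lacking a Cα are dropped and
counted. Confidence is the Cα B-factor, clipped to [0, 100]; experimental
templates conventionally carry 100. The filter removes models whose *mean*
confidence is strictly below the threshold (default 70), so a model at
exactly 70 is kept. The mean is taken over all parsed residues — the natural choice for
predicted models, which have no unresolved residues (for experimental
structures with gaps, only modeled residues enter the mean).

### Secondary structure from Cα geometry

Full hydrogen-bond-based assignment (DSSP) needs backbone amide geometry that
predicted Cα traces do not always provide reliably, so assignment uses
P-SEA-style Cα-only rules: window start $i$ passes the helix test when
$d(i,i+3) \in [4.7, 5.7]$ Å and $d(i,i+4) \in [5.7, 7.0]$ Å, and the strand
test when $d(i,i+2) \in [6.4, 7.4]$ Å and the pseudo-dihedral
$\tau(i..i+3) \in [150°, 215°]$ (mod 360). Two consecutive passing starts are
required, i.e. the conditions must hold over ≥ 6 (helix) resp. ≥ 5 (strand)
consecutive residues, and the residues spanned by all passing runs are
labeled. This union-of-windows rule was chosen over a
run-of-all-starts rule deliberately: a single mid-element geometric
perturbation must not erase a 15-residue helix (robustness under the
coordinate divergence real families exhibit), while two-start confirmation
keeps isolated chance hits in random coil from inflating the decoy
background (< ~5% spurious H+E on self-avoiding random walks versus ~28%
with single-start labeling).

Motif spans (the three sheet strands plus traversing helix; the hairpin
strands, turn and optional inserted helix) are **configuration data on
representatives** — on real data they are annotated once per representative
and shipped as an editable TSV; for synthetic data the generator emits its
true spans. Spans are transferred to members through the alignment mapping,
and H/E labels are counted inside the transferred spans (E is reported as
"S"). Counts therefore cover mapped residues only; an empty transfer yields
zero counts and a flag.

### Trees and representatives

Pairwise distance is $1 - \mathrm{TM}$ (the natural bounded dissimilarity;
recorded in output metadata). Clustering is UPGMA (average linkage),
implemented directly so the tie-break is fully specified: among equal-distance
pairs, the pair whose lexicographically smallest member ids sort first is
merged. Heights are non-decreasing, and the Newick serialization places a
node of height $h$ at ultrametric depth $h/2$. The tree is cut at the $k-1$
highest merges; each cluster is represented by its **medoid** (the member
maximizing mean similarity to its co-members, ties to the smallest id). In practice a first, over-clustered set of representatives is often refined
by visual inspection; that manual step has no algorithmic definition, so it
is exposed as an explicit user override (`override =` ids / the
`representatives` config key) rather than guessed.

The sequence-side dendrogram uses local alignment with BLOSUM62 (gap open 11,
extend 1) and scores each pair by identity × coverage. Identity is identical
positions over alignment columns. Coverage is defined as alignment columns
over the *longer* sequence's length (capped at 1): this is symmetric in the
pair, reproduces the defining examples (identical sequences score 1; a
sequence against its own first half scores 0.5), and avoids the asymmetry a
query-relative definition would introduce into a similarity matrix.

### Screening and tallies

Each query is aligned to every representative; the tier follows the best
TM-score with boundaries *below* < 0.5 ≤ *moderate* ≤ 0.7 < *high* (the
moderate band is closed on both sides, so the three tiers partition [0, 1]
with 0.5 and 0.7 counted as moderate). Tally counts use strict "greater than" thresholds at 0.5/0.6/0.7
against at least 1–4 representatives and are monotone non-increasing along
both axes by construction.

### Ring feasibility

An assembly is built by aligning the monomer onto each chain of a template
and applying the resulting rigid transform to all atoms; adjacency follows
consecutive chain order, with the wrap-around pair for rings. A clash is a
heavy atom of the reference monomer (copy 1 by default) within 2 Å (strict)
of any heavy atom of an *adjacent* copy — distinct atoms are counted, not
atom pairs, so the headline number reads as "k out of N monomer atoms". Non-adjacent contacts are reported separately and excluded from the
headline count. All heavy atoms and reference copy 1 are used, and both choices are
recorded in the report (Cα-only counting and a different reference copy are
the obvious alternatives; the per-interface table makes either easy to
recompute). The spatial-hash implementation is held equal to an all-pairs
oracle in the tests.

## What the synthetic generator emulates — and what it does not

`make_ssap_monomer()` assembles ideal secondary-structure elements
(α-helix: radius 2.3 Å, rise 1.5 Å/residue, 100°/residue; strand: 3.8 Å steps
with alternating pleat) into the SSAP topology: three antiparallel sheet
strands 4.8 Å apart, a traversing helix packed against one sheet face, and a
strand–turn–strand hairpin with an optional inserted helix, joined by
irregular coil. Five presets echo the median helix/strand residue counts
observed across the real families (e.g. per-strand length 12 for the
eukaryotic-Rad52-like preset — 36 designed strand residues against the
observed median of 37; a 42-residue hairpin helix for the RecT-like preset; no
hairpin helix for the Sak3-like preset). The presets also differ in packing
layout (helix face and tilt, hairpin tilt), because the real families differ
in arrangement and not only in element lengths; without this, between-family
TM-scores overlap within-family ones and no clustering method could separate
the families — the separation assumption the whole dendrogram-plus-medoid
design rests on.

Within-family divergence is **chain-correlated** Gaussian displacement
(white noise smoothed along the chain over a 9-residue window, rescaled to
the requested σ, default 0.5 Å). Independent per-atom noise at σ = 0.5 Å
would corrupt local Cα distances in a way no real family divergence does —
real structural variation is dominated by low-frequency, elastic-network-like
deformation — and would make any Cα-geometry secondary-structure assignment
fail on data that real pipelines handle. Confidence values are drawn from
N(90, 5) clipped to [0, 100], emulating high-confidence predictions; member
sequences carry 5% residue mutations. Fragments (truncation to a fraction of
the chain, default 0.6) emulate the incomplete sequences that dominate the
low-TM tail in the real data. Decoys are compact self-avoiding Cα walks
(step 3.8 Å, non-consecutive separation ≥ 3.5 Å, radius cap 3·n^{1/3} Å) that
provide the empirical null for screening. Rings place principal-axis-oriented
copies with n-fold symmetry; the auto radius is the smallest (0.5 Å grid)
with zero clashes at 2.0 + 0.5 Å margin.

What the generator does **not** emulate: real loop conformations
(Ramachandran statistics), side chains beyond a Cβ stub, sheet twist,
disordered termini, and the heavy-tailed length and quality distributions of
real predicted proteomes. A green test on synthetic data therefore
establishes the *logic* of the pipeline — formula correctness, determinism,
separability under the stated geometric contrasts, clash bookkeeping — not
agreement with corpus-scale numbers computed on real predicted proteomes,
which would require bulk downloads.

## Numerical choices and degenerate inputs

* Kabsch superposition excludes reflections by determinant correction;
  fewer than 3 points or mismatched lengths are errors.
* `d0` is floored at 0.5 Å, and the cube root is taken with sign for
  normalizing lengths below 15.
* Empty mappings score TM = 0 (not an error); structures under 5 residues
  cannot be aligned.
* The aligner refines the best-ranked seeds only and stops when the mapping
  repeats, the score converges (|ΔTM| < 1e-7), or 30 iterations — a speed
  heuristic that leaves self-alignments exact (TM = 1, RMSD = 0).
* UPGMA tie-breaks and medoid tie-breaks are lexicographic on ids, making
  every tree and representative choice reproducible.
* The confidence filter at threshold 0 is the identity; at 101 it empties
  the set (confidence is capped at 100).
* All randomness flows from explicit integer seeds; per-member seeds are
  derived from a master seed and stay below 2^31.

## Known limitations

* The aligner is sequential (colinear) only — no non-sequential alignment,
  no multi-chain alignment in one pass, and no claim of USalign parity;
  it targets the TM-score *statistic*, not a specific implementation.
* Cα-only secondary structure under-counts at element boundaries by a
  residue or two compared to hydrogen-bond methods; motif medians inherit a
  small downward bias (the recovered sheet-strand median is typically 33-34
  of 36 designed residues, occasionally a residue lower depending on the
  divergence realization).
* Sequence scoring uses one local alignment per pair; no composition-based
  statistics or E-values.
* Proteome-scale screening (hundreds of millions of structures) is out of
  scope; only the per-structure computation (`screen()`) is provided, to be
  driven by whatever batch machinery the corpus requires.
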