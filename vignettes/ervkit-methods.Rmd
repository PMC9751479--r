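---
title: "Methods: simulating, discovering, dating and typing HML2-like proviruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, discovering, dating and typing HML2-like proviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

ervkit studies the genomic footprint of the HML2 group of endogenous
retroviruses (ERVs) in a multi-species primate setting: full proviruses
(LTR–gag–pro–pol–env–LTR) and solo LTRs scattered through host genomes,
classified by cross-species orthology, dated by LTR divergence, and
characterized structurally (signature indels, residual coding capacity,
env subtypes, and an env×MER11A recombination event).

Because the real analysis rests on multi-gigabase public assemblies, the
package is built around a *synthetic cohort generator* whose outputs carry a
complete truth table. Every analysis stage is therefore testable offline:
the generator plants loci with known age, category, structure and
recombination status, and the pipeline must recover them.

## The synthetic reference provirus

`build_reference()` constructs an HML2-like reference: a 968-nt LTR flanking
an 8,000-nt internal region annotated with the canonical gene layout
(internal-relative, 1-based inclusive): gag 156–2,297, pro 2,063–3,082,
pol 3,037–5,785, env 5,624–7,951. The genes overlap (gag/pro, pro/pol,
pol/env), each pair in a different reading frame, and the constructor keeps
*all* frames stop-free up to each gene's terminal stop codon by a bounded
local-repair search. Nested domains are fixed at defendable positions: MA,
CA and NC in gag (with two CX~2~CX~4~HX~4~C zinc knuckles in NC), RT, RH and
IN in pol, SU and TM in env, and a 200-codon Rec portion inside env carrying
one fixed NLS peptide and one fixed NES peptide. The NLS/NES peptide
sequences are recorded in the model — the literature names these motifs
without printing sequences, so fixing synthetic peptides is what makes motif
scanning well-defined and checkable.

Choices worth noting:

* **LTR length 968 nt, internal length 8,000 nt.** Typical LTR5 dimensions;
  the internal length is the smallest round figure accommodating env
  (≤ 7,951).
* **Gene coordinates are internal-sequence-relative.** Read as
  provirus-relative they would place gag inside the 5′ LTR, which is
  impossible.
* **The reference is CpG-free by default** and the divergence planter never
  creates a CG dinucleotide. CpG masking during dating is then *exactly*
  neutral on simulated data, so planted ages are recoverable to the rounding
  quantum. This deliberately idealizes real data, where CpG hypermutation is
  a genuine noise source; a CpG-bearing reference (`cpg_free = FALSE`)
  combined with `cpg_boost > 1` in the planter exercises the masking code
  and shows the expected inflation of unmasked estimates.
* **Coordinates.** All internal interval arithmetic is 0-based half-open
  (the BED convention); published 1-based inclusive coordinates are
  converted on load by `iv_from_1based()`, and the converters compose to the
  identity.

`build_mer11a_parent()` provides the HML8 MER11A-like recombination parent;
positions 201–873 of it (673 nt) are the donor segment planted into
variant-3 env genes.

## Divergence planting and the molecular clock

Ages are planted and estimated under T = D% / 0.34, with 0.34 %/nt/Myr the
primate substitution rate; LTR-vs-LTR estimates are halved because the two
LTR copies are identical at integration and mutate independently afterwards.

`plant_divergence()` gives each LTR copy exactly `round(968 × 0.0034 × T)`
substitutions at sites disjoint between the two copies — no coincident or
multiple hits — so the pairwise LTR divergence is 2 × 0.0034 × T up to one
site quantum (≈ 0.15 Myr at L = 968). This makes the p-distance estimator
exactly calibrated by construction; a saturation correction (Jukes–Cantor
and relatives) is deliberately out of scope, and ages with
2 × 0.0034 × T ≥ 1 are refused. The internal region is mutated at the same
per-lineage fraction.

Dating (`estimate_age()`) uses the CpG-masked p-distance with pairwise
deletion: positions gapped or `N` in either sequence are excluded, and with
masking both positions of any CG dinucleotide observed in either sequence
(on the aligned strings) are excluded as well. Masking both sequences'
CpGs — rather than only the reference's — is the stricter reading of
"CG dinucleotides excluded"; the reference-only alternative is available via
the `mask_cpg` flag on the lower-level functions. Consensus-based estimators
(`ltr_vs_consensus`, `gag_vs_consensus`, `pol_vs_consensus`) take a
consensus from `build_consensus()` (per reference column: plurality base
among non-gap members, ties toward the reference, majority-gap columns
emitted as gaps) and do not halve T. Summaries use the standard even/odd
median and type-7 (linear interpolation) quartiles.

## Cohort simulation

`simulate_cohort()` plants loci of three categories — human-shared (carried
by all species), macaque-shared (both macaques only), species-specific
(one macaque) — at configurable counts and ages. The defaults *are* the
study conditions: 12 / 46 / 19 loci at 32.4 / 15.7 / 5.6 Myr, one solo LTR
among the macaque-shared loci. Each locus is embedded in neutral DNA with a
6-nt target-site duplication and 200-nt ancestral flanks shared across
carrier species; about 30 % of loci are planted on the minus strand.
Spacers between planted loci are 3,000 nt, comfortably larger than the
discovery chaining gap so adjacent elements cannot merge.

Flanking DNA diverges at its own rate, 0.1 %/nt/Myr per lineage — the
genome-wide neutral primate rate — rather than the 0.34 ERV-calibration
rate. At the ERV rate, human-shared flanks would be ~22 % divergent and no
flank-identity threshold could both group 32-Myr orthologs and separate
unrelated loci; at the neutral rate they sit near 93.5 % identity, matching
the empirical situation in which flank-based orthology calling works.

Species profiles: macaque-profile copies carry the recurrent 12-nt gag
deletion (reference 156–167) and the 96-nt gag insertion anchored at
reference 745 — read as 96 novel nucleotides inserted at anchor 745, one of
two defensible readings of "insertion between 745–838". Env variants are
macaque-only: variant 2 adds a 191-nt insertion inside TM (anchored at env
position 7,300 internal-relative); variant 3 replaces the interior of env —
all but a 150-nt 5′ stub and a 120-nt 3′ stub — with the 673-nt MER11A
donor. The type-I 292-nt env deletion is human-only and fixed at
env-relative position 401 (inside the Rec portion; the literature does not
print the position, so the generator fixes and documents one). Truth
coding-intactness per gene is computed by the generator from the realized
sequence using its exact coordinate bookkeeping, independent of the
alignment pipeline.

Default env-variant proportions per category (variant 1/2/3): human-shared
copies carry no macaque variant; macaque-shared 0.45/0.35/0.20;
species-specific 0.15/0.15/0.70 — mirroring the observed predominance of
the recombinant variant among recent, species-specific insertions.

All randomness flows from one explicit seed through named substreams
(`seed_stream()`), so results are stable under stage reordering and
byte-identical across reruns.

## Discovery and orthology

`scan_genome()` is a seed-and-extend scan: exact 16-mers from the reference
(both strands) are located with Biostrings, clustered per strand with a
2,000-nt chaining gap, and filtered. Exact-match seeding suffices because
planted divergence ≤ ~25 % still leaves abundant clean 16-mers. Two
parameters deserve comment:

* `min_seeds = 5` (distinct seed positions per hit). Against a megabase of
  neutral DNA, a 16-mer catalog of ~20,000 seeds produces a handful of
  chance matches; requiring five distinct seeds in one cluster reduces the
  false-hit rate to effectively zero while full-length elements and solo
  LTRs carry hundreds.
* **Boundary refinement by diagonal voting.** Divergence erodes the
  outermost exact seeds, so raw cluster bounds can sit up to ~100 nt inside
  the true element at 32 Myr. Each edge is refined from the dominant seed
  diagonal at that edge (strand-aware), which restores boundaries to within
  a few nucleotides and makes the flanks extracted for orthology truly
  homologous. The identical 5′/3′ LTR k-mers are what make the naive
  "leftmost reference seed" rule unusable — every LTR seed reports both LTR
  coordinates — and also what lets a solo LTR vote a correct right boundary.

A hit with LTR seeds but no internal seeds is a solo LTR. Hits overlapping
after chaining are unioned (leftmost start wins).

`classify_orthology()` compares 200-nt upstream and downstream flanks across
species: both must align at ≥ 0.9 identity. Identity is *end-gap-free*
(terminal overhangs excluded): residual boundary offsets of a few bases are
an artifact of seed-accurate bounds, not sequence divergence. Groups are the
symmetric/transitive closure of pairwise matches; a group containing the
outgroup is human-shared, a multi-species group without it macaque-shared,
and singletons species-specific. Loci whose flanks would run off the contig
are flagged `unclassifiable` rather than dropped.

## Alignment and projection

All structural analysis runs through one affine-gap global alignment
(Gotoh, implemented in C++ for speed) of each locus against the reference,
followed by projection into reference coordinates — a pseudo-multiple
alignment over shared reference columns. This replaces a true MSA (the
original workflow used MAFFT): adequate because every comparison here is
locus-vs-reference or column-wise, and documented as a deliberate
divergence.

General-purpose alignment defaults are match +2, mismatch −3, gap open −5,
gap extend −2 (a length-L gap costs 5 + 2L), with deterministic traceback
tie-breaking (match > deletion > insertion). `N` mismatches everything,
including `N`. Two stages override the gap costs with a *stiffer* scheme
(open −12, extend −1):

* `project_locus()`: with permissive gaps the optimal alignment can split a
  long planted insertion around a few chance matches (a 191-nt insertion
  surfacing as 184 + 7); a high opening cost keeps each biological event in
  one run, so called indel lengths stay faithful.
* `parent_cost()` inside the recombination test: permissive gaps let a
  parent "stitch" chance matches inside non-parental segments, blurring the
  per-position mismatch signal the segmentation DP relies on.

Indel calling reports maximal gap runs as single deletions and each
insertion run as one insertion, annotated with the overlapped gene(s);
anchors are reproducible to ±2 nt (alignment ambiguity in mutated
neighborhoods), which is the tolerance used throughout.

## Coding capacity and motifs

`orf_integrity()` splices the projected gene sequence (aligned bases plus
internal insertions), translates it from the reference gene frame (snapping
to the first present in-frame position when the 5′ end is missing), and
reports premature stops, a frameshift flag, coverage, domains and motifs. A
frameshift is defined as net indel phase ≠ 0 within the gene — the
operational reading of an otherwise undefined term — and intactness
requires no premature stop, no frameshift and ≥ 0.95 coverage. Domain
presence requires ≥ 0.9 of the domain span covered.

`detect_rec()` calls the Rec portion present when its interval is ≥ 0.95
covered and frame-intact (net indel phase 0). Point substitutions — even
nonsense ones — do not remove the Rec portion structurally; this matches
how "complete Rec portions" can be counted in env genes that nowhere encode
a full ORF. NLS/NES are then scanned on the Rec translation with one
mismatched residue tolerated per four (2 of 8 for the NLS, 3 of 12 for the
NES): a neutral substitution should not abolish a signal a motif scanner
would still call. Zinc knuckles are matched with the literal
CX~2~CX~4~HX~4~C pattern, overlapping matches allowed.

## env typing and recombination

`classify_env()` applies rules in precedence order: a parent-B (MER11A)
segment ≥ 300 nt inside env → variant 3; else an insertion of 150–250 nt
inside TM → variant 2; else variant 1. The windows tolerate alignment
slippage around the printed 191-nt value; precedence goes to the
recombination signal because the MER11A replacement destroys the context of
everything else. Independently, a deletion of 280–300 nt within ±20 nt of
the type-I anchor calls type I, else type II. Conflicting evidence is
resolved by rule order and flagged `conflict` in the evidence string.

`segment_two_parents()` aligns each parent to the query, assigns per-query
position cost 0/1 (gap = mismatch, keeping the DP alphabet-free), and finds
the minimum-cost parent labeling with switch penalty σ (default 3, i.e.
roughly four informative sites must justify a switch; the original
recombination software's parameters are not published). A
forward-backward pass identifies, for every switch, the run of equally
optimal split points; the breakpoint is reported at the run's midpoint with
the run as an interval. `oracle_segment()` enumerates all ≤ 2-breakpoint
labelings exhaustively (refusing queries > 1,000 nt) and is used to verify
the DP.

## Phylogeny

`distance_matrix()` computes pairwise CpG-maskable p-distances over shared
reference columns (pairwise deletion); `nj_tree()` performs standard
Saitou–Nei neighbor joining via ape, clamping negative branch-length
estimates to zero with a warning; `bootstrap_support()` resamples projected
reference columns (the shared coordinate space, not raw sequences) with
replacement, default 500 replicates, and scores each internal edge by the
percentage of replicate trees containing its split. Trees are emitted
unrooted; whether the original figures were midpoint-rooted for display is
not stated.

## Pipeline

`run_all()` chains simulate → discover → orthology → annotate → date →
orf → env-type → recomb → phylo and writes TSV reports (category table,
ages and per-category summary, ORF report, env calls, segmentations), a
Newick tree, the truth table, a serialized config, a run log with per-stage
counts, and a MANIFEST recording stage completion — a failed stage leaves
partial output recognizable. Reruns with the same config and seed are
byte-identical. The demo default is 3 + 12 + 5 loci with 100 bootstrap
replicates, which keeps a full run near a minute; the test suite and the
acceptance script use 12/46/19 cohorts where category structure itself is
under test, and 10 replicate cohorts for dating medians. Solo LTRs are
excluded from projection-based structural reports (as in the source
analysis, which restricts those to full-length elements); they remain in
the category table and can be dated by the consensus methods through
`estimate_age()`.

There is no shell entry point: the exported functions, `run_all()` and
`scripts/acceptance.R` are the interface, driven from R.

## What passing tests do and do not show

The generator emulates: orthologous insertions with exactly shared ancestral
flanks, exact per-copy divergence without multiple hits, recurrent signature
indels of exact published lengths, a single contiguous recombination donor,
and neutral flanking DNA. It does not emulate: substitution-rate
heterogeneity or saturation, CpG hypermutation (by default), segmental
duplication or nested/fragmented elements, polymorphic (non-fixed)
insertions, or realistic repeat landscapes. Recovery of planted truth
therefore validates the *logic* of each stage and its calibration under the
stated model, not performance on real assemblies — in particular, real
boundary calling, orthology in repeat-rich flanks, and dating under rate
variation are all harder than their synthetic counterparts.

## Known limitations

* p-distances are uncorrected; ages near saturation are refused rather than
  corrected.
* The reference-anchored projection cannot represent homology between two
  loci at positions absent from the reference.
* Breakpoint and indel anchors carry the ±2-nt alignment ambiguity
  discussed above; the segmentation midpoint rule can sit a few nucleotides
  from a planted breakpoint when chance matches extend across it.
* The orthology stage is quadratic in the number of loci across species;
  the fast ungapped path keeps the default cohort comfortable, but
  genome-scale catalogs would need an indexed flank comparison.
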