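---
title: "Antigen-binding regions from structural consensus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antigen-binding regions from structural consensus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrkit)
```

## The model

An antibody's antigen-binding site is usually located via its CDRs, which a
numbering scheme (Kabat, Chothia or IMGT) assigns from sequence
variability or loop structure. `abrkit` instead defines binding regions
*empirically* from structures: across a multiple structural alignment of
antibody–antigen complexes, each aligned column is scored by the fraction
of antibodies whose residue at that column contacts the antigen. Columns
where that fraction reaches a threshold θ form six contiguous stretches —
three per chain — which we call antigen-binding regions (ABRs). The
derived column spans are frozen: a new antibody is annotated by projecting
the training-set columns onto it, not by re-detecting contacts. This
matters for interpretation — a training antibody whose own contact lies
just outside the frozen boundary will have that contact excluded, which is
the expected behaviour, not a defect.

Two contact conventions anchor everything:

* **Contact (6 Å rule).** An antibody residue and an antigen residue are
  in contact when any atom–atom distance between them is ≤ 6 Å. All atoms
  present in the file participate; crystal structures typically lack
  hydrogens and we place none. 6 Å is permissive by design (an unbiased
  positive set); the evaluation functions accept any cutoff in (0, 10] so
  sensitivity analyses at 4–6 Å are one-liners.
* **Consensus threshold.** θ = 0.10, *inclusive*: a column where exactly
  10 % of antibodies contact the antigen belongs to an ABR. The
  denominator is all antibodies in the set, not just those with a residue
  at the column — consensus is over antibodies, and a gap is evidence of
  absence, not missing data. Both choices are exposed as arguments
  (`theta`, and the occupancy column of `build_column_profiles()` for
  users who prefer the other convention).

## Deriving boundaries

`derive_abr_boundaries()` takes the per-column contact fractions and finds
maximal runs of super-threshold columns. Two knobs handle sparse data:

* `gap_merge` (default 2): runs separated by at most this many
  sub-threshold columns are merged. With dense training sets the six
  stretches emerge cleanly and this has no effect; with small sets it
  prevents fragmentation. Set it to 0 for strict maximal runs.
* `regions_per_chain` (3): if more than three runs survive merging, the
  two runs separated by the smallest gap are merged iteratively. Fewer
  than three runs is an error instructing a lower θ or more data — we do
  not invent boundaries.

## The multiple structural alignment

The consensus logic needs *some* consistent column assignment; it is not
itself sensitive to which multiple structure aligner produced it. We
implement a deterministic reference-anchored progressive alignment: the
antibody with the most resolved residues anchors the column set (ties
broken by smallest id); each other antibody is superposed onto it per
chain — a Kabsch fit on sequence-pre-aligned Cα pairs — and residues adopt
the column of their nearest reference Cα within 4 Å (greedy by distance,
injective, crossings dropped to keep columns ordered). Unmatched residues
open insertion columns after their preceding matched column, shared across
antibodies by order. `alignment_from_rows()` ingests an externally
computed alignment for users who prefer a published MSTA program; the
downstream consensus code is identical either way.

`superpose()` is a plain SVD Kabsch solver (proper rotation enforced via
the determinant correction; collinear inputs rejected). It is
cross-checked in the test suite against an independent reference
implementation.

## Numbering schemes

Kabat/Chothia/IMGT CDR extraction needs numbered sequences.
`number_sequence()` transfers labels from pre-numbered variable-domain
templates by ends-free alignment: matched residues inherit the template
label, insertions get the preceding label plus letters (35 < 35A < 35B <
36 collation), unaligned termini stay unnumbered. The templates shipped in
`scheme_templates()` are *synthetic* — fixed sequences whose per-position
Kabat/Chothia/IMGT label columns encode the canonical correspondence
between the schemes for an insertion-free domain. The CDR boundary tables
(`inst/extdata/cdr_boundaries.csv`) are the standard published ranges and
are data, not code, so an alternative revision can be pinned.

Two deliberate simplifications:

* **Insertion anchors.** Kabat and Chothia place L1/H1 insertions at
  different canonical positions. We let the alignment place the insertion
  gap and letter it on the preceding label, rather than relocating letters
  to a per-scheme anchor: relocation can violate the strict label-ordering
  invariant whenever the insertion is not adjacent to the anchor, and for
  boundary extraction (the only downstream consumer) both conventions
  assign the inserted residues to the same CDR.
* **Conversion.** `convert_numbering()` maps labels through the template
  correspondence (letters preserved), which makes conversion bijective and
  round-trip exact on labels the templates cover.

The consequence to keep in mind: label *values* for real antibodies may
drift by a residue relative to a curated numbering service, so CDR
boundaries carry the same one-residue uncertainty. All comparative
statistics in the package are computed on residue sets, which is robust to
this.

## Annotation transfer

The sequence route (`infer_abrs_sequence()`) aligns only the framework
regions: the best reference hit (full-scan Smith–Waterman, highest score ≈
lowest E-value; ties by identity then id) contributes its four framework
segments per chain, each locally aligned to the query independently; query
ABR k is the segment strictly between the aligned end of framework k and
the aligned start of framework k+1. Aligning frameworks rather than whole
chains avoids mis-alignment inside hypervariable stretches, and
independent per-segment alignment means a failed middle framework raises
an error instead of silently shifting its neighbours. Scoring uses
BLOSUM62 with gap open 11 / extend 1 — the standard protein-search
defaults. The credibility floor (≥ 40 % identity over ≥ 50 aligned
residues, configurable) rejects non-antibody queries. Heavy and light
chains are annotated independently from their own best hits; a message is
emitted when the hits differ.

The structure route (`infer_abrs_structure()`) superposes the query onto
the hit per chain — the Kabsch fit is anchored on framework pairs only, so
a divergent H3 cannot skew the fit — transfers regions through a
nearest-Cα ≤ 4 Å correspondence, and refuses transfers whose framework
RMSD exceeds 5 Å. On families with ≤ 10 % divergence the two routes agree
on ≥ 99 % of assigned residues (a property asserted in the test suite).

Best-hit search is a full scan because reference sets here are a few
hundred entries at most; an external search tool can replace it for large
sets without touching the transfer logic.

## Curation

`curate_pool()` mirrors standard non-redundant set construction: screening
(three roles, protein antigen ≥ 5 residues, interacting at 6 Å; every
rejection logged with exactly one reason), single-linkage sequence
clustering at identity ≥ 0.97 with mutual coverage ≥ 0.95 (both-ways
coverage, since one-sided coverage would let fragments cluster with
full-length chains), and within-cluster redundancy removal on contact
fingerprints: similarity = |shared contacts| / size of the shorter list,
groups linked at ≥ 0.77, each represented by its member with the most
contacts. Per-class score thresholds for `classify_chain()` are config —
E-value thresholds are search-tool-specific, so we expose calibrated
alignment-score floors instead and record the adapter that produced them.

## Evaluation conventions

* Precision and recall are macro-averaged (mean of per-antibody values);
  antibodies with an empty prediction have undefined precision and are
  excluded from the precision mean; micro (pooled) values are reported
  alongside.
* Consensus/Δ comparisons report pooled residue totals, matching the
  raw-count table layout; coverage additivity (consensus + Δ of a method
  = that method's full coverage) holds exactly and is asserted on
  randomized annotations.
* ΔΔG values are *inputs* (computed by any external energy program); the
  package only bins them: > 0.25 destabilizing, < −0.25 stabilizing,
  neutral in between with inclusive boundaries.

## What the synthetic generator does and does not emulate

`generate_complex()`/`generate_family()` build schematic complexes: chains
are extended Cα/Cβ traces laid out along the alignment-column axis (7.5 Å
column spacing, a 1.2 Å zigzag so frames are never degenerate), and each
planted contact places an antigen residue 5.0–5.5 Å from its antibody
residue and ≥ 8 Å from every other one. This makes contact extraction,
alignment transfer and consensus recovery exactly testable; it does not
emulate immunoglobulin fold geometry, side-chain packing, or binding
energetics, so passing tests certify the *logic* of the pipeline, not its
behaviour on crystal-structure noise (conformational variability, missing
residues, crystal contacts).

Default study conditions: 20-member families, inside-ABR contact density
0.5, outside density 0.02, mutation rate 0.05, θ = 0.10. Densities are
realized as exact per-column counts (`round(density × n)` members contact
the antigen at each column, membership random). With independent
per-member sampling, an outside column of a 20-member family would cross
the 10 % threshold with probability ≈ 6 %, so "exact recovery" would fail
sporadically for reasons unrelated to the boundary logic; the balanced
realization makes the intended guarantee — exact span recovery whenever
inside-density > θ > outside-density with margin — hold by construction.
Planted ABR spans track the scheme CDRs but extend beyond them in L2 and
H2, emulating the empirically wider binding regions there; this is what
drives the recall gap between the consensus regions and the CDR schemes in
the synthetic benchmark.

The acceptance script (`scripts/acceptance.R`) uses a 20-member training
family and a 15-member disjoint query family — sizes at which every
quantity is stable across seeds while the whole study runs in about a
minute on one CPU.

## Known limitations

* Real-structure reproduction (worked examples on specific PDB entries,
  published benchmark sets) requires those structures on disk; the
  corresponding test blocks fail with instructions when they are absent.
* Numbering is template-transfer, not a full port of a curated numbering
  service; expect occasional one-residue boundary drift on real
  antibodies (see above).
* Single-domain (VHH) antibodies, non-protein antigens and mmCIF input
  are out of scope.
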