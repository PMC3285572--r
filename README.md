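# abrkit

Identification of antibody **antigen-binding regions (ABRs)** by structural
consensus, and quantitative comparison against the classic CDR definitions
(Kabat, Chothia, IMGT).

## The problem

The residues of an antibody that actually touch its antigen — the paratope —
are conventionally assumed to lie in the six complementarity-determining
regions (CDRs) assigned by a numbering scheme. But a substantial fraction of
observed antigen-contacting residues falls *outside* every CDR definition.
An alternative is to define binding regions empirically: align many
antibody–antigen complexes structurally, mark which aligned positions
contact the antigen, and call a position part of a binding region when at
least a threshold fraction θ of antibodies contact the antigen there. The
maximal stretches of such positions form six **ABRs** (three per chain)
that can then be transferred to any new antibody — from its sequence alone,
or from its structure.

`abrkit` implements this pipeline end to end for structural immunologists
and antibody engineers:

* **structure I/O** — parse antibody–antigen complexes from PDB files,
  extract residue–residue contacts under the standard 6 Å any-atom rule,
  Kabsch rigid-body superposition;
* **consensus** — reference-anchored multiple structural alignment,
  per-column contact profiles, ABR boundary derivation at θ = 0.10
  (inclusive, "at least 10 % of antibodies in contact");
* **schemes** — Kabat/Chothia/IMGT numbering by template transfer and CDR
  extraction from shipped boundary tables;
* **annotate** — transfer of ABRs to a query antibody via framework-only
  Smith–Waterman alignment of the best reference hit (sequence route), or
  via superposition and nearest-Cα correspondence (structure route);
* **curation** — chain classification, complex screening, sequence
  clustering (identity ≥ 0.97, coverage ≥ 0.95) and contact-fingerprint
  redundancy removal (similarity cut-off 0.77, representative = most
  contacts);
* **evaluate** — precision `tp/(tp+fp)` and recall `tp/(tp+fn)` against
  observed binding residues, consensus/Δ residue-set comparisons,
  method-unique binding residues, and ternary ΔΔG classification of
  alanine-scan results (destabilizing > 0.25, stabilizing < −0.25,
  neutral in between, boundaries inclusive);
* **fixtures** — a deterministic generator of synthetic antibody-like
  complexes with planted contacts and known ABR spans, so the entire
  pipeline is testable without structure downloads.

## Worked example

Derive ABR boundaries from a synthetic family, annotate an unseen antibody
from sequence, and score the annotation against the observed 6 Å contacts:

```r
library(abrkit)

fam  <- generate_family(fixture_spec(seed = 11, n_members = 8))
cxs  <- lapply(fam$members, `[[`, "complex")
aln  <- align_antibody_set(cxs)
defn <- derive_abr_boundaries(build_column_profiles(aln))
refs <- build_reference_set(cxs, aln, defn)

q <- generate_complex(fixture_spec(seed = 99))
h <- paste(q$complex$heavy$residues$aa, collapse = "")
l <- paste(q$complex$light$residues$aa, collapse = "")

(abr <- infer_abrs_sequence(h, l, refs, id = "query"))
#> <abr_regions query scheme=paratome>
#>   H1: 26-35 (10 aa)
#>   H2: 49-64 (16 aa)
#>   H3: 95-102 (8 aa)
#>   L1: 24-34 (11 aa)
#>   L2: 46-56 (11 aa)
#>   L3: 89-97 (9 aa)

gold <- extract_contacts(q$complex)           # observed binding residues
kab  <- annotate_cdrs(h, l, "kabat", id = "query")

round(unlist(score_annotation(abr, gold)[c("precision", "recall")]), 3)
#> precision    recall
#>     0.462     0.968
round(unlist(score_annotation(kab, gold)[c("precision", "recall")]), 3)
#> precision    recall
#>     0.464     0.839

compare_methods(abr, kab, gold)$stats
#>         set n_residues n_binding  coverage
#> 1 consensus         55        26 0.8387097
#> 2   delta_a         10         4 0.1290323
#> 3   delta_b          1         0 0.0000000
```

The consensus regions recover 97 % of the binding residues here while the
Kabat CDRs recover 84 %; the residues unique to the consensus regions
(`delta_a`) carry a further 13 % of the binding site, while the residues
unique to the CDRs (`delta_b`) carry none — the pattern the consensus
approach is designed to expose.

A thin CLI wraps the same functions:

```sh
exec/abrkit annotate --heavy H.fasta --light L.fasta --refs refs.json --out annot.json
exec/abrkit fixtures --spec spec.json --out fixtures/
```

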