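## Building the non-redundant annotated reference pool: chain
## classification, complex screening, sequence clustering and
## contact-fingerprint redundancy removal.

#' Curation configuration
#'
#' @param class_thresholds Named numeric vector of minimum local-alignment
#'   scores per chain class (`antibody-heavy`, `antibody-light`, `mhc1`,
#'   `mhc2`, `tcra`, `tcrb`). Defaults were calibrated once on the shipped
#'   exemplars.
#' @param cutoff Interaction distance cutoff in angstroms (default 6).
#' @param min_antigen_len Minimum antigen length (default 5).
#' @param identity Sequence-cluster identity threshold (default 0.97).
#' @param coverage Mutual coverage threshold (default 0.95).
#' @param similarity Contact-similarity redundancy cutoff (default 0.77).
#' @return A `curation_config` list.
#' @export
curation_config <- function(class_thresholds = NULL, cutoff = 6.0,
                            min_antigen_len = 5L, identity = 0.97,
                            coverage = 0.95, similarity = 0.77) {
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1,
            similarity > 0, similarity <= 1, cutoff > 0, cutoff <= 10)
  if (is.null(class_thresholds))
    class_thresholds <- c(`antibody-heavy` = 150, `antibody-light` = 150,
                          mhc1 = 150, mhc2 = 150, tcra = 150, tcrb = 150)
  structure(list(class_thresholds = class_thresholds, cutoff = cutoff,
                 min_antigen_len = min_antigen_len, identity = identity,
                 coverage = coverage, similarity = similarity),
            class = "curation_config")
}

#' Classify a chain sequence
#'
#' Scores the sequence against one exemplar per class by local alignment
#' and returns the highest-scoring class whose score passes its threshold.
#' Antibody classes are rejected whenever any TCR/MHC class also passes
#' (exclusion precedence: a chain resembling a T-cell receptor or MHC
#' molecule must not enter the antibody pool).
#'
#' @param seq Amino-acid sequence.
#' @param references Named list of exemplar sequences; names must cover
#'   `antibody-heavy`, `antibody-light`, `mhc1`, `mhc2`, `tcra`, `tcrb`.
#' @param cfg A [curation_config()].
#' @return Class label, or `"other"`.
#' @export
classify_chain <- function(seq, references, cfg = curation_config()) {
  need <- names(cfg$class_thresholds)
  if (!all(need %in% names(references)))
    stopf("references must cover classes: %s", paste(need, collapse = ", "))
  score <- vapply(need, function(cl)
    smith_waterman(seq, references[[cl]])$score, numeric(1))
  passes <- need[score >= cfg$class_thresholds[need]]
  if (length(passes) == 0) return("other")
  best <- passes[order(-score[passes], passes)][1]
  non_ab <- setdiff(passes, c("antibody-heavy", "antibody-light"))
  if (startsWith(best, "antibody") && length(non_ab) > 0) return("other")
  best
}

#' Screen a pool of complexes
#'
#' Retains complexes with exactly the three roles, a protein antigen of at
#' least `cfg$min_antigen_len` residues and a non-empty contact set at
#' `cfg$cutoff`. Per-complex decisions are attached as the `"report"`
#' attribute.
#'
#' @param pool List of `abr_complex`.
#' @param cfg A [curation_config()].
#' @return The retained sublist, with a `report` attribute (data frame
#'   `id`, `decision`, `reason`).
#' @export
filter_complexes <- function(pool, cfg = curation_config()) {
  rows <- lapply(pool, function(cx) {
    if (!inherits(cx, "abr_complex"))
      return(data.frame(id = NA, decision = "reject", reason = "not a complex"))
    if (nrow(cx$antigen$residues) < cfg$min_antigen_len)
      return(data.frame(id = cx$pdb_id, decision = "reject",
                        reason = "antigen too short"))
    if (!is_interacting(cx, cfg$cutoff))
      return(data.frame(id = cx$pdb_id, decision = "reject",
                        reason = "not interacting"))
    data.frame(id = cx$pdb_id, decision = "retain", reason = "")
  })
  report <- do.call(rbind, rows)
  keep <- pool[report$decision == "retain"]
  attr(keep, "report") <- report
  keep
}

## Global-alignment identity and mutual coverage of two sequences.
pair_identity_coverage <- function(a, b) {
  pr <- align_pairs(a, b, type = "global")
  both <- !is.na(pr$pos_a) & !is.na(pr$pos_b)
  n_pair <- sum(both)
  ident <- if (n_pair == 0) 0 else
    sum(pr$a_char[both] == pr$b_char[both]) / n_pair
  list(identity = ident,
       coverage = min(n_pair / nchar(a), n_pair / nchar(b)))
}

#' Cluster sequences by identity and coverage
#'
#' Greedy single-linkage clustering over pairwise global-alignment identity
#' and mutual coverage; two sequences link when identity and both-ways
#' coverage meet the thresholds. Processing order is deterministic (longest
#' sequence first, ties by name).
#'
#' @param seqs Named character vector of sequences.
#' @param identity Identity threshold (default 0.97).
#' @param coverage Mutual coverage threshold (default 0.95).
#' @return List of character vectors of sequence names.
#' @export
cluster_sequences <- function(seqs, identity = 0.97, coverage = 0.95) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  nms <- names(seqs)[ord]
  n <- length(nms)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- pair_identity_coverage(seqs[[nms[i]]], seqs[[nms[j]]])
      if (p$identity >= identity && p$coverage >= coverage) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(nms, roots), identity))
}

#' Contact fingerprint of a complex
#'
#' The set of contact identifiers used for redundancy scoring: antibody
#' amino acid at its alignment position (falling back to author numbering
#' when no alignment row is given) paired with the antigen amino acid at
#' its position.
#'
#' @param contacts An `abr_contacts`.
#' @param row Optional alignment row (list `heavy`, `light` of column
#'   vectors) giving "alignment position within the antibody".
#' @return Character vector of unique contact keys.
#' @export
contact_fingerprint <- function(contacts, row = NULL) {
  cc <- contacts$contacts
  ab_pos <- if (!is.null(row)) {
    mapply(function(ch, i) row[[ch]][i], cc$ab_chain, cc$ab_idx)
  } else paste0(cc$ab_resno, cc$ab_ins)
  unique(paste0(substr(cc$ab_chain, 1, 1), ":", cc$ab_aa, "@", ab_pos, "|",
                cc$ag_aa, "@", cc$ag_resno, cc$ag_ins))
}

#' Contact-list similarity of two complexes
#'
#' Number of identical contacts divided by the size of the shorter of the
#' two contact lists. Defined as 0 (with a warning) if either list is
#' empty.
#'
#' @param a,b Contact fingerprints (character vectors from
#'   [contact_fingerprint()]).
#' @return Fraction in \[0, 1\].
#' @export
contact_similarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    warning("empty contact fingerprint; similarity defined as 0")
    return(0)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Remove redundant complexes within a sequence cluster
#'
#' Members whose contact similarity reaches the cutoff are linked (single
#' linkage) into redundancy groups; each group is represented by its member
#' with the most contacts (ties: id order). Members below the cutoff to all
#' others are retained as-is.
#'
#' @param fingerprints Named list of contact fingerprints (one per member).
#' @param cutoff Similarity cutoff (default 0.77).
#' @return Character vector of representative ids.
#' @export
remove_redundancy <- function(fingerprints, cutoff = 0.77) {
  ids <- names(fingerprints)
  n <- length(ids)
  if (n <= 1) return(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (contact_similarity(fingerprints[[i]], fingerprints[[j]]) >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  roots <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), roots), function(grp) {
    sizes <- vapply(grp, function(i) length(fingerprints[[i]]), numeric(1))
    cand <- grp[sizes == max(sizes)]
    ids[cand[order(ids[cand])][1]]
  }, character(1))
  sort(unname(reps))
}

#' Run the full curation pipeline
#'
#' Screens a pool of complexes, clusters their concatenated antibody
#' sequences, scores within-cluster contact-fingerprint similarity and
#' keeps one representative per redundancy group.
#'
#' @param pool List of `abr_complex`.
#' @param cfg A [curation_config()].
#' @return List of retained `abr_complex`, with a `report` attribute.
#' @export
curate_pool <- function(pool, cfg = curation_config()) {
  screened <- filter_complexes(pool, cfg)
  report <- attr(screened, "report")
  if (length(screened) == 0) return(screened)
  ids <- vapply(screened, function(x) x$pdb_id, character(1))
  seqs <- stats::setNames(vapply(screened, function(x)
    paste0(chain_seq(x$heavy), chain_seq(x$light)), character(1)), ids)
  clusters <- cluster_sequences(seqs, cfg$identity, cfg$coverage)
  contacts <- stats::setNames(
    lapply(screened, function(x) extract_contacts(x, cfg$cutoff)), ids)
  keep <- unlist(lapply(clusters, function(cl) {
    fps <- stats::setNames(lapply(cl, function(id)
      contact_fingerprint(contacts[[id]])), cl)
    remove_redundancy(fps, cfg$similarity)
  }))
  dropped <- setdiff(ids, keep)
  report$decision[report$id %in% dropped] <- "reject"
  report$reason[report$id %in% dropped] <- "redundant"
  out <- screened[ids %in% keep]
  attr(out, "report") <- report
  out
}
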