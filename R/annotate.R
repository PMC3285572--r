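## Transferring ABR annotations to query antibodies from the best hit in an
## annotated reference set, by framework-only local alignment (sequence
## route) or rigid superposition (structure route).

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap penalties (first gapped
#' position costs `gap_open + gap_extend`, each further position
#' `gap_extend`). A negative optimum is reported as the empty alignment
#' with score 0.
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`) or an
#'   explicit substitution matrix.
#' @param gap_open,gap_extend Gap penalties (defaults 11 / 1, the standard
#'   protein-search values).
#' @return A `local_alignment`: list with `score`, `a_span`, `b_span`
#'   (inclusive start/end, `c(0, -1)` for the empty alignment), `a_aln`,
#'   `b_aln` (gapped strings), `pid` (percent identity over aligned
#'   columns) and `n_aligned`.
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = if (is.character(matrix)) get_submat(matrix) else matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- aln@score
  if (score <= 0)
    return(structure(list(score = 0, a_span = c(0L, -1L), b_span = c(0L, -1L),
                          a_aln = "", b_aln = "", pid = NA_real_,
                          n_aligned = 0L),
                     class = "local_alignment"))
  a_aln <- as.character(Biostrings::alignedPattern(aln))
  b_aln <- as.character(Biostrings::alignedSubject(aln))
  pa <- strsplit(a_aln, "")[[1]]; pb <- strsplit(b_aln, "")[[1]]
  n_aligned <- sum(pa != "-" & pb != "-")
  pid <- 100 * sum(pa == pb & pa != "-") / max(n_aligned, 1L)
  rng_a <- Biostrings::pattern(aln)@range
  rng_b <- Biostrings::subject(aln)@range
  structure(list(score = score,
                 a_span = c(rng_a@start, rng_a@start + rng_a@width - 1L),
                 b_span = c(rng_b@start, rng_b@start + rng_b@width - 1L),
                 a_aln = a_aln, b_aln = b_aln, pid = pid,
                 n_aligned = n_aligned),
            class = "local_alignment")
}

#' Build an annotated reference set
#'
#' Packages a list of complexes with their consensus-derived annotations
#' (and alignment rows) into the reference set used for annotation
#' transfer.
#'
#' @param complexes List of `abr_complex`.
#' @param aligned The `abr_alignment` covering them.
#' @param defn The `abr_definition` derived from that alignment.
#' @return An `abr_refset`: named list of entries, each with `id`,
#'   `heavy`/`light` (list of `seq`, `regions`), `structure`, `row`.
#' @export
build_reference_set <- function(complexes, aligned, defn) {
  entries <- lapply(seq_along(complexes), function(k) {
    cx <- complexes[[k]]
    row <- list(heavy = aligned$heavy$rows[[k]],
                light = aligned$light$rows[[k]])
    ann <- map_abrs_to_antibody(defn, row, id = cx$pdb_id)
    list(id = cx$pdb_id,
         heavy = list(seq = chain_seq(cx$heavy),
                      regions = ann$regions$heavy),
         light = list(seq = chain_seq(cx$light),
                      regions = ann$regions$light),
         structure = cx, row = row)
  })
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  structure(entries, class = "abr_refset")
}

#' Serialize / read an annotated reference set as JSON
#'
#' Sequences and region annotations are written; structures are not (the
#' sequence-based transfer route is fully usable from the JSON form).
#'
#' @param refs An `abr_refset`.
#' @param path File path.
#' @export
write_reference_set <- function(refs, path) {
  stopifnot(inherits(refs, "abr_refset"))
  payload <- lapply(unclass(refs), function(e)
    list(id = e$id,
         heavy = list(seq = e$heavy$seq,
                      regions = lapply(e$heavy$regions, as.integer)),
         light = list(seq = e$light$seq,
                      regions = lapply(e$light$regions, as.integer))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(e)
    list(id = e$id,
         heavy = list(seq = e$heavy$seq,
                      regions = lapply(e$heavy$regions,
                                       function(v) unlist(v, use.names = FALSE))),
         light = list(seq = e$light$seq,
                      regions = lapply(e$light$regions,
                                       function(v) unlist(v, use.names = FALSE))),
         structure = NULL, row = NULL))
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  structure(entries, class = "abr_refset")
}

#' Find the best reference hit for a query chain
#'
#' Full-scan Smith-Waterman against every reference entry; the entry with
#' the highest score wins (ties: higher identity, then lexicographically
#' smaller id). A hit below the credibility floor raises an error.
#'
#' @param query Amino-acid sequence of one chain.
#' @param refs An `abr_refset`.
#' @param chain `"heavy"` or `"light"`.
#' @param min_identity,min_aligned Credibility floor: the best hit must
#'   reach this percent identity (default 40) over at least this many
#'   aligned residues (default 50).
#' @return List with `entry` (the winning reference entry) and `alignment`
#'   (its `local_alignment`).
#' @export
find_best_hit <- function(query, refs, chain = c("heavy", "light"),
                          min_identity = 40, min_aligned = 50L) {
  chain <- match.arg(chain)
  stopifnot(inherits(refs, "abr_refset"), length(refs) > 0)
  alns <- lapply(refs, function(e) smith_waterman(query, e[[chain]]$seq))
  score <- vapply(alns, `[[`, numeric(1), "score")
  pid <- vapply(alns, function(a) a$pid %||% NA_real_, numeric(1))
  ord <- order(-score, -ifelse(is.na(pid), -Inf, pid), names(refs))
  best <- ord[1]
  a <- alns[[best]]
  if (a$score <= 0 || is.na(a$pid) || a$pid < min_identity ||
      a$n_aligned < min_aligned)
    stopf("no credible hit for %s chain (best: %s, id %.1f%% over %d aa)",
          chain, names(refs)[best], a$pid %||% 0, a$n_aligned)
  list(entry = refs[[best]], alignment = a)
}

## Framework segments of a reference chain: the four index ranges around
## its three regions (empty segments allowed).
framework_segments <- function(seq_len_, regions) {
  bounds <- lapply(regions, range)
  starts <- c(1L, vapply(bounds, function(b) b[2] + 1L, numeric(1)))
  ends <- c(vapply(bounds, function(b) b[1] - 1L, numeric(1)), seq_len_)
  lapply(seq_len(4), function(i)
    if (starts[i] > ends[i]) integer(0) else starts[i]:ends[i])
}

#' Infer ABRs for a query antibody from sequence
#'
#' The four framework segments of the best reference hit are each locally
#' aligned to the query chain; the query's k-th ABR is the segment strictly
#' between the aligned end of framework k and the aligned start of
#' framework k+1. Chains are annotated independently from their own best
#' hits; a message is emitted when the two hits differ.
#'
#' @param heavy,light Query chain sequences.
#' @param refs An `abr_refset`.
#' @param id Query id for the annotation.
#' @param min_identity,min_aligned Best-hit credibility floor, see
#'   [find_best_hit()].
#' @return An `abr_regions` annotation (scheme `"paratome"`) with meta
#'   fields `hit` (per chain) and `fr_identity`.
#' @export
infer_abrs_sequence <- function(heavy, light, refs, id = "query",
                                min_identity = 40, min_aligned = 50L) {
  seqs <- list(heavy = heavy, light = light)
  regions <- list(); meta <- list(hit = list(), fr_identity = list())
  for (ch in c("heavy", "light")) {
    hit <- find_best_hit(seqs[[ch]], refs, ch,
                         min_identity = min_identity,
                         min_aligned = min_aligned)
    e <- hit$entry[[ch]]
    frs <- framework_segments(nchar(e$seq), e$regions)
    fr_spans <- vector("list", 4); fr_pid <- numeric(4)
    for (i in seq_len(4)) {
      if (length(frs[[i]]) == 0) { fr_spans[[i]] <- NULL; next }
      seg <- substr(e$seq, min(frs[[i]]), max(frs[[i]]))
      a <- smith_waterman(seqs[[ch]], seg)
      if (a$score <= 0)
        stopf("framework FR%d of %s chain failed to align to hit %s",
              i, ch, hit$entry$id)
      fr_spans[[i]] <- a$a_span
      fr_pid[i] <- a$pid
    }
    present <- which(!vapply(fr_spans, is.null, logical(1)))
    ## framework alignments must appear in order without overlap
    for (j in seq_along(present)[-1])
      if (fr_spans[[present[j]]][1] <= fr_spans[[present[j - 1]]][2])
        stopf("framework FR%d of %s chain aligns out of order",
              present[j], ch)
    nm <- region_names(ch)
    regs <- stats::setNames(vector("list", 3), nm)
    for (k in seq_len(3)) {
      lo <- if (k %in% present) fr_spans[[k]][2] + 1L else 1L
      hi <- if ((k + 1L) %in% present) fr_spans[[k + 1L]][1] - 1L
            else nchar(seqs[[ch]])
      regs[[nm[k]]] <- if (lo > hi) integer(0) else lo:hi
    }
    regions[[ch]] <- regs
    meta$hit[[ch]] <- hit$entry$id
    meta$fr_identity[[ch]] <- fr_pid
  }
  if (!identical(meta$hit$heavy, meta$hit$light))
    message(sprintf("chains annotated from different hits (heavy %s, light %s)",
                    meta$hit$heavy, meta$hit$light))
  new_regions(id = id, scheme = "paratome", regions = regions, meta = meta)
}

#' Infer ABRs for a query antibody from structure
#'
#' The query is superposed, per chain, onto the best hit's structure
#' (Kabsch fit anchored on a sequence pre-alignment); residues correspond
#' by nearest C-alpha within `match_dist`; the hit's ABR residues are
#' transferred through the correspondence. Framework RMSD above
#' `max_fr_rmsd` aborts with an "unreliable transfer" error.
#'
#' @param query An `abr_complex` (antigen chain may be a stub).
#' @param refs An `abr_refset` whose entries carry structures.
#' @param id Annotation id (defaults to the query's pdb id).
#' @param match_dist Correspondence cutoff in angstroms (default 4).
#' @param max_fr_rmsd Maximum framework RMSD in angstroms (default 5).
#' @inheritParams find_best_hit
#' @return An `abr_regions` annotation (scheme `"paratome"`).
#' @export
infer_abrs_structure <- function(query, refs, id = NULL, match_dist = 4.0,
                                 max_fr_rmsd = 5.0, min_identity = 40,
                                 min_aligned = 50L) {
  stopifnot(inherits(query, "abr_complex"))
  id <- id %||% query$pdb_id
  regions <- list(); meta <- list(hit = list(), fr_rmsd = list())
  for (ch in c("heavy", "light")) {
    qch <- query[[ch]]
    hit <- find_best_hit(chain_seq(qch), refs, ch,
                         min_identity = min_identity,
                         min_aligned = min_aligned)
    hx <- hit$entry$structure
    if (is.null(hx)) stopf("best hit %s has no structure", hit$entry$id)
    hch <- hx[[ch]]
    pr <- align_pairs(chain_seq(qch), chain_seq(hch))
    pair <- !is.na(pr$pos_a) & !is.na(pr$pos_b)
    if (sum(pair) < 3) stopf("cannot anchor query %s chain on hit", ch)
    q_ca <- ca_coords(qch); h_ca <- ca_coords(hch)
    ## anchor the fit on framework pairs only
    hit_abr <- unlist(hit$entry[[ch]]$regions, use.names = FALSE)
    fr_pair <- pair & !(pr$pos_b %in% hit_abr)
    if (sum(fr_pair) < 3) fr_pair <- pair
    fit <- superpose(h_ca[pr$pos_b[fr_pair], , drop = FALSE],
                     q_ca[pr$pos_a[fr_pair], , drop = FALSE])
    if (fit$rmsd > max_fr_rmsd)
      stopf("unreliable transfer: framework RMSD %.2f A > %.2f A on %s chain",
            fit$rmsd, max_fr_rmsd, ch)
    q_fit <- apply_transform(q_ca, fit)
    ## nearest hit residue per query residue
    d2 <- outer(rowSums(q_fit^2), rowSums(h_ca^2), "+") - 2 * q_fit %*% t(h_ca)
    d2[d2 < 0] <- 0
    nearest <- max.col(-d2, ties.method = "first")
    ok <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)]) <= match_dist
    corr <- ifelse(ok, nearest, NA_integer_)
    regions[[ch]] <- lapply(hit$entry[[ch]]$regions, function(v)
      which(corr %in% v))
    meta$hit[[ch]] <- hit$entry$id
    meta$fr_rmsd[[ch]] <- fit$rmsd
  }
  new_regions(id = id, scheme = "paratome", regions = regions, meta = meta)
}
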