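## Deriving ABR boundaries from contact consensus across structurally
## aligned antibodies, and projecting boundary columns onto individual
## antibodies.

#' Structurally align a set of antibodies
#'
#' Reference-anchored progressive superposition: the antibody with the most
#' resolved residues (ties: lexicographically smallest id) is the reference;
#' every other antibody is rigidly superposed onto it per chain (Kabsch fit
#' anchored on a sequence pre-alignment) and residues are assigned to the
#' reference's columns by nearest C-alpha within `match_dist` angstroms.
#' Unmatched residues open dedicated insertion columns after the preceding
#' matched column; insertion columns at the same anchor are shared across
#' antibodies in order.
#'
#' An externally computed alignment (e.g. from a multiple structure aligner)
#' can be supplied instead via [alignment_from_rows()].
#'
#' @param complexes List of `abr_complex` objects (>= 2) with both antibody
#'   chains.
#' @param contact_sets Optional list of `abr_contacts` (same order) used to
#'   set per-column contact flags; computed at 6 A when omitted.
#' @param match_dist Column-assignment distance cutoff in angstroms.
#' @param min_chain_len Minimum chain length required to anchor (default 60).
#' @return An `abr_alignment`: list with `ids` and per chain (`heavy`,
#'   `light`) a list of `n_col`, `rows` (per-antibody integer vectors
#'   mapping residue index to column) and `contacts` (antibody x column
#'   logical matrix).
#' @export
align_antibody_set <- function(complexes, contact_sets = NULL,
                               match_dist = 4.0, min_chain_len = 60L) {
  stopifnot(length(complexes) >= 2)
  ids <- vapply(complexes, function(x) x$pdb_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate antibody ids in alignment set")
  for (cx in complexes)
    for (ch in c("heavy", "light"))
      if (nrow(cx[[ch]]$residues) < min_chain_len)
        stopf("%s chain of %s too short to anchor (%d < %d residues)",
              ch, cx$pdb_id, nrow(cx[[ch]]$residues), min_chain_len)
  if (is.null(contact_sets))
    contact_sets <- lapply(complexes, extract_contacts)

  n_res <- vapply(complexes, function(x)
    nrow(x$heavy$residues) + nrow(x$light$residues), numeric(1))
  ref <- order(-n_res, ids)[1]

  out <- list(ids = ids)
  for (ch in c("heavy", "light")) {
    ref_chain <- complexes[[ref]][[ch]]
    ref_ca <- ca_coords(ref_chain)
    m <- nrow(ref_chain$residues)
    ## insertion bookkeeping: per reference anchor (0..m), rows of inserted
    ## residues per antibody
    ins_count <- integer(m + 1L)          # columns inserted after anchor r
    raw_rows <- vector("list", length(complexes))
    for (k in seq_along(complexes)) {
      if (k == ref) {
        raw_rows[[k]] <- list(anchor = seq_len(m), slot = rep(0L, m))
        next
      }
      qch <- complexes[[k]][[ch]]
      q_ca <- ca_coords(qch)
      pr <- align_pairs(chain_seq(qch), chain_seq(ref_chain))
      pair <- !is.na(pr$pos_a) & !is.na(pr$pos_b)
      if (sum(pair) < 3)
        stopf("cannot anchor %s chain of %s onto reference", ch, ids[k])
      fit <- superpose(ref_ca[pr$pos_b[pair], , drop = FALSE],
                       q_ca[pr$pos_a[pair], , drop = FALSE])
      q_fit <- apply_transform(q_ca, fit)
      ## nearest reference residue per query residue, greedy injective
      d2 <- outer(rowSums(q_fit^2), rowSums(ref_ca^2), "+") -
        2 * q_fit %*% t(ref_ca)
      d2[d2 < 0] <- 0
      nq <- nrow(q_fit)
      anchor <- rep(NA_integer_, nq)
      cand <- which(sqrt(d2) <= match_dist, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d2[cand]), , drop = FALSE]
        used_q <- logical(nq); used_r <- logical(m)
        for (i in seq_len(nrow(cand))) {
          qi <- cand[i, 1]; ri <- cand[i, 2]
          if (!used_q[qi] && !used_r[ri]) {
            anchor[qi] <- ri; used_q[qi] <- TRUE; used_r[ri] <- TRUE
          }
        }
      }
      ## enforce monotone matches (drop crossings) so columns stay ordered
      anchor <- enforce_monotone(anchor)
      ## unmatched residues -> insertion slots after previous matched anchor
      slot <- rep(0L, nq); run_anchor <- 0L; run_len <- 0L
      for (i in seq_len(nq)) {
        if (!is.na(anchor[i])) { run_anchor <- anchor[i]; run_len <- 0L }
        else {
          run_len <- run_len + 1L
          anchor[i] <- run_anchor; slot[i] <- run_len
          ins_count[run_anchor + 1L] <- max(ins_count[run_anchor + 1L], run_len)
        }
      }
      raw_rows[[k]] <- list(anchor = anchor, slot = slot)
    }
    ## final column numbering: leading insertion columns, then each
    ## reference residue's column followed by its insertion columns
    lead <- ins_count[1L]
    col_ref <- integer(m); acc <- lead
    for (r in seq_len(m)) {
      acc <- acc + 1L
      col_ref[r] <- acc
      acc <- acc + ins_count[r + 1L]
    }
    rows <- lapply(raw_rows, function(rr)
      ifelse(rr$anchor == 0L, rr$slot, col_ref[rr$anchor] + rr$slot))
    n_col <- acc
    contacts <- matrix(FALSE, length(complexes), n_col)
    for (k in seq_along(complexes)) {
      cc <- contact_sets[[k]]$contacts
      idx <- unique(cc$ab_idx[cc$ab_chain == ch])
      contacts[k, rows[[k]][idx]] <- TRUE
    }
    out[[ch]] <- list(n_col = n_col, rows = rows, contacts = contacts)
  }
  structure(out, class = "abr_alignment")
}

## Drop matches that cross a previous match (keeps columns monotone).
enforce_monotone <- function(anchor) {
  last <- 0L
  for (i in seq_along(anchor)) {
    if (!is.na(anchor[i])) {
      if (anchor[i] <= last) anchor[i] <- NA_integer_
      else last <- anchor[i]
    }
  }
  anchor
}

#' Build an alignment object from known rows
#'
#' Hook for ingesting an externally computed multiple alignment: supply the
#' per-antibody column vectors directly (e.g. parsed from gapped FASTA).
#'
#' @param ids Antibody ids.
#' @param heavy_rows,light_rows Lists of integer vectors mapping each
#'   residue to its alignment column.
#' @param contact_sets Optional list of `abr_contacts` to set contact flags.
#' @return An `abr_alignment`.
#' @export
alignment_from_rows <- function(ids, heavy_rows, light_rows,
                                contact_sets = NULL) {
  mk <- function(rows, ch) {
    n_col <- max(unlist(rows))
    contacts <- matrix(FALSE, length(rows), n_col)
    if (!is.null(contact_sets))
      for (k in seq_along(rows)) {
        cc <- contact_sets[[k]]$contacts
        idx <- unique(cc$ab_idx[cc$ab_chain == ch])
        contacts[k, rows[[k]][idx]] <- TRUE
      }
    list(n_col = n_col, rows = rows, contacts = contacts)
  }
  structure(list(ids = ids, heavy = mk(heavy_rows, "heavy"),
                 light = mk(light_rows, "light")),
            class = "abr_alignment")
}

#' Per-column contact and occupancy profiles
#'
#' For every alignment column, the fraction of antibodies whose residue at
#' that column contacts the antigen (denominator: all antibodies in the
#' set) and the fraction of antibodies with any residue there.
#'
#' @param aligned An `abr_alignment`.
#' @return Data frame with columns `chain`, `column`, `contact_fraction`,
#'   `occupancy`.
#' @export
build_column_profiles <- function(aligned) {
  stopifnot(inherits(aligned, "abr_alignment"))
  n_ab <- length(aligned$ids)
  do.call(rbind, lapply(c("heavy", "light"), function(ch) {
    al <- aligned[[ch]]
    occ <- integer(al$n_col)
    for (row in al$rows) occ[row] <- occ[row] + 1L
    data.frame(chain = ch, column = seq_len(al$n_col),
               contact_fraction = colSums(al$contacts) / n_ab,
               occupancy = occ / n_ab,
               stringsAsFactors = FALSE)
  }))
}

#' Derive ABR boundaries from column profiles
#'
#' Columns where the contact fraction is at least `theta` (inclusive, per
#' the "at least 10%" consensus rule) form runs; runs separated by at most
#' `gap_merge` sub-threshold columns are merged; if more than
#' `regions_per_chain` runs remain, the two closest runs are merged
#' iteratively until exactly `regions_per_chain` spans remain per chain.
#'
#' @param profiles Data frame from [build_column_profiles()].
#' @param theta Consensus threshold (default 0.10).
#' @param gap_merge Maximum sub-threshold gap bridged when merging runs.
#' @param regions_per_chain Number of regions enforced per chain (3).
#' @param provenance Optional list stored on the definition.
#' @return An `abr_definition`: list with `theta`, `spans` (per chain, named
#'   inclusive column ranges), `n_col` and `provenance`.
#' @export
derive_abr_boundaries <- function(profiles, theta = 0.10, gap_merge = 2L,
                                  regions_per_chain = 3L,
                                  provenance = list()) {
  spans <- list(); n_col <- list()
  for (ch in c("heavy", "light")) {
    pf <- profiles[profiles$chain == ch, , drop = FALSE]
    if (nrow(pf) == 0) stopf("no profiles for %s chain", ch)
    pf <- pf[order(pf$column), , drop = FALSE]
    hot <- pf$contact_fraction >= theta
    runs <- runs_of(hot)
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
        if (gap <= gap_merge) merged$end[nrow(merged)] <- runs$end[i]
        else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    if (nrow(runs) < regions_per_chain)
      stopf(paste0("only %d contact-consensus runs on the %s chain; ",
                   "lower theta or provide more antibodies"),
            nrow(runs), ch)
    while (nrow(runs) > regions_per_chain) {
      gaps <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
      j <- which.min(gaps)
      runs$end[j] <- runs$end[j + 1L]
      runs <- runs[-(j + 1L), , drop = FALSE]
    }
    nm <- region_names(ch)
    spans[[ch]] <- stats::setNames(
      lapply(seq_len(nrow(runs)), function(i) c(runs$start[i], runs$end[i])),
      nm)
    n_col[[ch]] <- max(pf$column)
  }
  structure(list(theta = theta, spans = spans, n_col = n_col,
                 provenance = provenance),
            class = "abr_definition")
}

runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Project ABR boundary columns onto one antibody
#'
#' Maps each span of alignment columns to the antibody's own residue
#' numbering by collecting the residues whose columns fall inside the span;
#' a fully gapped span yields an empty region.
#'
#' @param defn An `abr_definition`.
#' @param row List with `heavy` and `light` integer vectors mapping residue
#'   index to alignment column (one antibody's rows).
#' @param id Antibody id recorded on the annotation.
#' @return An `abr_regions` annotation with scheme `"paratome"`.
#' @export
map_abrs_to_antibody <- function(defn, row, id = NA_character_) {
  stopifnot(inherits(defn, "abr_definition"))
  regions <- list()
  for (ch in c("heavy", "light")) {
    rv <- row[[ch]]
    if (max(rv) > defn$n_col[[ch]])
      stopf("row of %s chain has %d columns but definition has %d",
            ch, max(rv), defn$n_col[[ch]])
    regions[[ch]] <- lapply(defn$spans[[ch]], function(sp)
      which(rv >= sp[1] & rv <= sp[2]))
  }
  new_regions(id = id, scheme = "paratome", regions = regions)
}

#' Serialize / read an ABR definition as JSON
#' @param defn An `abr_definition`.
#' @param path File path.
#' @export
write_abr_definition <- function(defn, path) {
  jsonlite::write_json(unclass(defn), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_abr_definition
#' @export
read_abr_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spans <- lapply(x$spans, function(ch) lapply(ch, as.integer))
  structure(x, class = "abr_definition")
}
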