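## Antibody numbering schemes (Kabat / Chothia / IMGT): template-transfer
## numbering, CDR boundary tables, label-level scheme conversion.

## Synthetic pre-numbered variable-domain templates. The sequences are
## synthetic (fixed pseudo-random composition, not germline-derived); what
## matters is the per-position label columns, which encode the canonical
## correspondence between the three numbering conventions for an
## insertion-free domain. Light template: 107 positions; heavy: 113.
TEMPLATE_LIGHT_SEQ <- "TCAIDWTPEDCFVWPNHDCMCVRGNAILPGDDWMCDRWNTWQQRVNRQIGCATEDMIHKVHLNSCFCRWTWCFGGDDEIWMYSTKHLSGQAMFCHSLIIAYTFFPQP"
TEMPLATE_HEAVY_SEQ <- "LCSTTWRQQQVPRIKHARRLFRRICITTCNFFACNMLVTVDVLTHTMTVATARGSNCMKAYCPQSIEHHNWPPVSAQLHVMCLPRQAFSTLWRIDVPETCVWHLQIHYHLYDI"

imgt_light_labels <- function() {
  c(1:9, 13:26,            # FR1 (positions 1-23)
    27:32, 34:38,          # CDR1 slots (positions 24-34)
    39:53, 54, 55,         # FR2 (positions 35-51)
    56, 57, 65,            # CDR2 slots (positions 52-54)
    66, 67, 68:99,         # FR3 (positions 55-88)
    105:109, 114:117,      # CDR3 slots (positions 89-97)
    118:127)               # FR4 (positions 98-107)
}

imgt_heavy_labels <- function() {
  c(1:25,                  # FR1
    27:32, 35:38,          # CDR1 slots (positions 26-35)
    39:52, 54,             # FR2 (positions 36-50)
    56:63,                 # CDR2 slots (positions 51-58)
    66:72, 73:101,         # FR3 (positions 59-94)
    105:108, 114:117,      # CDR3 slots (positions 95-102)
    118:128)               # FR4 (positions 103-113)
}

#' Pre-numbered variable-domain reference templates
#'
#' Returns the package's built-in numbering templates: one light and one
#' heavy variable-domain sequence with, for every position, its Kabat,
#' Chothia and IMGT labels. The template sequences are synthetic; the label
#' columns carry the scheme correspondence used for template-transfer
#' numbering and for label conversion. Users may supply their own templates
#' of the same shape to pin an alternative table revision.
#'
#' @return List with elements `light` and `heavy`; each is a list of `seq`
#'   (character scalar) and `labels` (data frame `pos`, `aa`, `kabat`,
#'   `chothia`, `imgt`).
#' @export
scheme_templates <- function() {
  mk <- function(seq, imgt) {
    aa <- strsplit(seq, "")[[1]]
    n <- length(aa)
    data.frame(pos = seq_len(n), aa = aa,
               kabat = as.character(seq_len(n)),
               chothia = as.character(seq_len(n)),
               imgt = as.character(imgt),
               stringsAsFactors = FALSE)
  }
  list(light = list(seq = TEMPLATE_LIGHT_SEQ,
                    labels = mk(TEMPLATE_LIGHT_SEQ, imgt_light_labels())),
       heavy = list(seq = TEMPLATE_HEAVY_SEQ,
                    labels = mk(TEMPLATE_HEAVY_SEQ, imgt_heavy_labels())))
}

#' CDR boundary tables per numbering scheme
#'
#' The standard Kabat/Chothia/IMGT CDR boundaries expressed as inclusive
#' scheme-label ranges, shipped as data (a CSV under `inst/extdata/`) so an
#' alternative table revision can be pinned.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `scheme`, `chain`, `region`, `start`, `end`.
#' @return Data frame with those five character columns.
#' @export
cdr_boundary_tables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cdr_boundaries.csv", package = "abrkit")
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

## Ends-free (overlap) global alignment of two plain sequences; returns the
## per-position pairing as index vectors.
align_pairs <- function(a, b, type = "overlap") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = type, substitutionMatrix = get_submat("BLOSUM62"),
    gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- Biostrings::pattern(aln)@range@start
  ib <- Biostrings::subject(aln)@range@start
  map_a <- integer(0); map_b <- integer(0)
  ca <- ia - 1L; cb <- ib - 1L
  pos_a <- integer(length(pa)); pos_b <- integer(length(pb))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ca <- ca + 1L
    if (pb[k] != "-") cb <- cb + 1L
    pos_a[k] <- if (pa[k] != "-") ca else NA_integer_
    pos_b[k] <- if (pb[k] != "-") cb else NA_integer_
  }
  list(pos_a = pos_a, pos_b = pos_b, a_char = pa, b_char = pb, score = aln@score)
}

#' Number an antibody sequence under a scheme
#'
#' Transfers scheme position labels from the best-matching pre-numbered
#' reference template by ends-free alignment. Query residues aligned to a
#' template position inherit its label; query insertions (template gaps) get
#' the preceding label with insertion letters A, B, ...; unaligned terminal
#' residues are left unnumbered (`NA` label).
#'
#' @param seq Amino-acid sequence (character scalar), length >= 70.
#' @param chain `"heavy"` or `"light"`.
#' @param scheme `"kabat"`, `"chothia"` or `"imgt"`.
#' @param references Templates as returned by [scheme_templates()].
#' @param min_fr_identity Minimum framework identity to the template
#'   (default 0.5) below which the sequence is rejected as unnumberable.
#' @return An `abr_numbering` object: data frame (`pos`, `aa`, `label`) with
#'   attributes `chain` and `scheme`.
#' @export
number_sequence <- function(seq, chain = c("heavy", "light"),
                            scheme = c("kabat", "chothia", "imgt"),
                            references = scheme_templates(),
                            min_fr_identity = 0.5) {
  chain <- match.arg(chain); scheme <- match.arg(scheme)
  if (nchar(seq) < 70) stopf("sequence too short to number (%d aa)", nchar(seq))
  tpl <- references[[chain]]
  pr <- align_pairs(seq, tpl$seq)

  ## framework identity: aligned pairs at template positions outside the
  ## scheme's CDRs
  tab <- cdr_boundary_tables()
  tab <- tab[tab$scheme == scheme & tab$chain == chain, , drop = FALSE]
  in_cdr <- rep(FALSE, nchar(tpl$seq))
  lbl <- tpl$labels[[scheme]]
  for (r in seq_len(nrow(tab)))
    in_cdr <- in_cdr | label_between(lbl, tab$start[r], tab$end[r])
  both <- !is.na(pr$pos_a) & !is.na(pr$pos_b)
  fr_pairs <- both & !in_cdr[ifelse(is.na(pr$pos_b), 1L, pr$pos_b)]
  n_fr <- sum(fr_pairs)
  ident <- if (n_fr == 0) 0 else
    sum(pr$a_char[fr_pairs] == pr$b_char[fr_pairs]) / n_fr
  if (ident < min_fr_identity)
    stopf("unnumberable: framework identity %.2f below %.2f to %s template",
          ident, min_fr_identity, chain)

  qaa <- strsplit(seq, "")[[1]]
  labels <- rep(NA_character_, length(qaa))
  last_label <- NA_character_; ins_count <- 0L
  for (k in seq_along(pr$pos_a)) {
    qa <- pr$pos_a[k]; tb <- pr$pos_b[k]
    if (is.na(qa)) {                      # deletion in query
      if (!is.na(tb)) { last_label <- lbl[tb]; ins_count <- 0L }
      next
    }
    if (!is.na(tb)) {
      labels[qa] <- lbl[tb]
      last_label <- lbl[tb]; ins_count <- 0L
    } else if (!is.na(last_label)) {      # insertion in query
      ins_count <- ins_count + 1L
      labels[qa] <- paste0(last_label, LETTERS[ins_count])
    }
  }
  out <- data.frame(pos = seq_along(qaa), aa = qaa, label = labels,
                    stringsAsFactors = FALSE)
  structure(out, chain = chain, scheme = scheme,
            fr_identity = ident, class = c("abr_numbering", "data.frame"))
}

#' Extract CDRs from a numbered sequence
#'
#' A CDR consists of the residues whose scheme labels lie inclusively
#' between the region's start and end labels (insertion-lettered labels
#' included). A boundary label absent from the sequence truncates the region
#' at the nearest present label (with a warning only when the whole region
#' is shifted).
#'
#' @param numbered An `abr_numbering` object.
#' @param table A boundary table as from [cdr_boundary_tables()]; rows for
#'   other schemes/chains are ignored.
#' @return An `abr_regions` annotation (scheme-tagged) for the one chain;
#'   regions are integer vectors of residue positions.
#' @export
extract_cdrs <- function(numbered, table = cdr_boundary_tables()) {
  stopifnot(inherits(numbered, "abr_numbering"))
  chain <- attr(numbered, "chain"); scheme <- attr(numbered, "scheme")
  tab <- table[table$scheme == scheme & table$chain == chain, , drop = FALSE]
  regions <- stats::setNames(
    vector("list", length(region_names(chain))), region_names(chain))
  has <- !is.na(numbered$label)
  for (nm in names(regions)) {
    row <- tab[tab$region == nm, , drop = FALSE]
    if (nrow(row) == 0) { regions[[nm]] <- integer(0); next }
    sel <- has & label_between(numbered$label, row$start, row$end)
    regions[[nm]] <- numbered$pos[which(sel)]
  }
  new_regions(id = NA_character_, scheme = scheme,
              regions = stats::setNames(list(regions), chain))
}

#' Convert a numbered sequence between schemes
#'
#' Applies the fixed label-to-label correspondence encoded in the reference
#' templates. Insertion-lettered labels map their base label and keep the
#' letter. Unmappable labels raise an error naming the label.
#'
#' @param numbered An `abr_numbering` object.
#' @param target Target scheme.
#' @inheritParams number_sequence
#' @return An `abr_numbering` under the target scheme.
#' @export
convert_numbering <- function(numbered, target = c("kabat", "chothia", "imgt"),
                              references = scheme_templates()) {
  stopifnot(inherits(numbered, "abr_numbering"))
  target <- match.arg(target)
  source <- attr(numbered, "scheme")
  if (identical(source, target)) return(numbered)
  tpl <- references[[attr(numbered, "chain")]]$labels
  map <- stats::setNames(tpl[[target]], tpl[[source]])
  out_label <- numbered$label
  for (i in seq_along(out_label)) {
    l <- out_label[i]
    if (is.na(l)) next
    p <- parse_label(l)
    base <- as.character(p$num)
    if (!base %in% names(map)) {
      ## letterless label absent from the template is unmappable
      if (p$ins == "" || !as.character(p$num) %in% names(map))
        stopf("unmappable label: %s (%s -> %s)", l, source, target)
    }
    out_label[i] <- paste0(map[[base]], p$ins)
  }
  out <- data.frame(pos = numbered$pos, aa = numbered$aa, label = out_label,
                    stringsAsFactors = FALSE)
  structure(out, chain = attr(numbered, "chain"), scheme = target,
            fr_identity = attr(numbered, "fr_identity"),
            class = c("abr_numbering", "data.frame"))
}

#' Annotate both chains of an antibody with scheme CDRs
#'
#' Convenience wrapper: numbers the heavy and light sequences under a scheme
#' and extracts the six CDRs into a single annotation.
#'
#' @param heavy,light Amino-acid sequences.
#' @param scheme Numbering scheme.
#' @param id Antibody identifier recorded on the annotation.
#' @inheritParams number_sequence
#' @return An `abr_regions` annotation with six regions.
#' @export
annotate_cdrs <- function(heavy, light, scheme = c("kabat", "chothia", "imgt"),
                          id = NA_character_,
                          references = scheme_templates()) {
  scheme <- match.arg(scheme)
  nh <- number_sequence(heavy, "heavy", scheme, references)
  nl <- number_sequence(light, "light", scheme, references)
  rh <- extract_cdrs(nh); rl <- extract_cdrs(nl)
  new_regions(id = id, scheme = scheme,
              regions = list(heavy = rh$regions$heavy,
                             light = rl$regions$light))
}
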