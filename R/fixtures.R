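## Synthetic antibody-like complexes and families with planted contacts and
## known ABR spans. Geometry is schematic: each chain is laid out as an
## extended C-alpha trace (one backbone and one dummy side-chain atom per
## residue) with inter-column spacing chosen so that a planted contact is
## unambiguous at the 6 A rule: antigen partner atoms sit 5.0-5.5 A from
## their antibody residue and >= 8 A from every other antibody residue.

COL_SPACING <- 7.5   # A between alignment columns along the chain axis
CONTACT_OFFSET <- 5.0  # A from antibody CA to its planted antigen partner

#' Default planted ABR spans (template coordinates)
#'
#' Spans used by the fixture generator, expressed as inclusive residue
#' ranges on the built-in templates. They track the scheme CDRs but extend
#' beyond them in L2 and H2, emulating consensus regions that are wider
#' than the classic CDR definitions there.
#' @return List with `heavy` and `light`, each a named list of `c(start, end)`.
#' @export
default_abr_spans <- function() {
  list(heavy = list(H1 = c(26L, 35L), H2 = c(49L, 64L), H3 = c(95L, 102L)),
       light = list(L1 = c(24L, 34L), L2 = c(46L, 56L), L3 = c(89L, 97L)))
}

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_members Family size (default 20).
#' @param inside_density Fraction of family members contacting the antigen
#'   at each ABR column (default 0.5). Realized as an exact per-column
#'   member count `round(density * n)`, membership random.
#' @param outside_density Same outside the ABRs (default 0.02).
#' @param mutation_rate Per-residue substitution rate for family members
#'   (default 0.05).
#' @param indel Optional list `list(member =, region =, length =)` planting
#'   an insertion of `length` residues in `region` of one member.
#' @param spans Planted ABR spans; see [default_abr_spans()].
#' @param contacts Optional explicit contacts for [generate_complex()]:
#'   list with integer vectors `heavy` and `light` of residue positions.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_members = 20L, inside_density = 0.5,
                         outside_density = 0.02, mutation_rate = 0.05,
                         indel = NULL, spans = default_abr_spans(),
                         contacts = NULL) {
  stopifnot(inside_density >= 0, inside_density <= 1,
            outside_density >= 0, outside_density <= 1)
  tpl <- scheme_templates()
  for (ch in names(spans))
    for (r in names(spans[[ch]]))
      if (spans[[ch]][[r]][2] > nchar(tpl[[ch]]$seq))
        stopf("span %s exceeds %s template length", r, ch)
  structure(list(seed = as.integer(seed), n_members = as.integer(n_members),
                 inside_density = inside_density,
                 outside_density = outside_density,
                 mutation_rate = mutation_rate, indel = indel,
                 spans = spans, contacts = contacts),
            class = "fixture_spec")
}

mutate_seq <- function(seq, rate) {
  aa <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) aa[i] <- sample(setdiff(AA1, aa[i]), 1)
  paste(aa, collapse = "")
}

span_positions <- function(spans_chain) {
  unlist(lapply(spans_chain, function(s) s[1]:s[2]), use.names = FALSE)
}

## Build one chain object from a sequence and per-residue x positions.
## The CA trace zigzags in z so that chains are never collinear (rigid
## superposition needs a well-defined frame); the zigzag phase follows the
## alignment column so structurally equivalent residues superpose exactly.
make_chain <- function(seq, chain_id, xs, y, cols) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  zig <- 1.2 * (cols %% 2L)
  residues <- data.frame(resno = seq_len(n), ins = "", aa = aa,
                         key = as.character(seq_len(n)),
                         stringsAsFactors = FALSE)
  atoms <- data.frame(
    res_idx = rep(seq_len(n), each = 2),
    elety = rep(c("CA", "CB"), n),
    x = rep(xs, each = 2),
    y = y,
    z = as.vector(rbind(zig, zig + 1.5)),
    o = 1,
    stringsAsFactors = FALSE)
  list(chain_id = chain_id, residues = residues, atoms = atoms)
}

## Antigen chain from partner positions: each planted contact gets one
## antigen residue next to it; padding residues are placed 30 A away.
make_antigen <- function(partners, min_len = 5L) {
  n_far <- max(min_len - nrow(partners), 2L)
  xs <- c(partners$x, COL_SPACING * seq_len(n_far) - 40)
  ys <- c(partners$y, rep(30, n_far))
  n <- length(xs)
  aa <- rep("G", n)
  residues <- data.frame(resno = seq_len(n), ins = "", aa = aa,
                         key = as.character(seq_len(n)),
                         stringsAsFactors = FALSE)
  atoms <- data.frame(res_idx = seq_len(n), elety = "CA",
                      x = xs, y = ys, z = 0, o = 1, stringsAsFactors = FALSE)
  list(chain_id = "A", residues = residues, atoms = atoms)
}

## Assemble an abr_complex plus its PDB text and ground truth for one
## member, given sequences, column assignments and contact positions.
assemble_member <- function(id, seqs, cols, contact_pos, spans_res) {
  xs <- lapply(cols, function(cv) COL_SPACING * cv)
  heavy <- make_chain(seqs$heavy, "H", xs$heavy, y = 0, cols = cols$heavy)
  light <- make_chain(seqs$light, "L", xs$light, y = 60, cols = cols$light)

  partner_rows <- list(); truth <- list(); k <- 0L
  for (ch in c("heavy", "light")) {
    ypart <- if (ch == "heavy") CONTACT_OFFSET else 60 - CONTACT_OFFSET
    for (i in contact_pos[[ch]]) {
      k <- k + 1L
      partner_rows[[k]] <- data.frame(x = xs[[ch]][i], y = ypart)
      truth[[k]] <- data.frame(ab_chain = ch, ab_idx = i, ag_idx = k,
                               stringsAsFactors = FALSE)
    }
  }
  partners <- if (k) do.call(rbind, partner_rows) else
    data.frame(x = numeric(0), y = numeric(0))
  antigen <- make_antigen(partners)
  cx <- structure(list(pdb_id = id, heavy = heavy, light = light,
                       antigen = antigen), class = "abr_complex")
  truth_df <- if (k) do.call(rbind, truth) else
    data.frame(ab_chain = character(0), ab_idx = integer(0),
               ag_idx = integer(0))
  regions <- new_regions(id = id, scheme = "paratome", regions = spans_res)
  list(id = id, complex = cx, pdb = complex_to_pdb(cx),
       contacts_truth = truth_df, regions_truth = regions, col_map = cols)
}

#' Generate one synthetic antibody-antigen complex
#'
#' Emits a parseable PDB file together with its ground truth: the planted
#' contact pairs and the planted ABR annotation. Antigen partner atoms are
#' placed within 5.5 A of each planted-contact antibody residue and at
#' least 8 A from all other antibody residues, so contact extraction at the
#' 6 A rule recovers exactly the planted set.
#'
#' @param spec A [fixture_spec()]. If `spec$contacts` is NULL, contact
#'   residues are sampled per residue at the inside/outside densities.
#' @param id Identifier for the complex.
#' @return List with `id`, `complex` (an `abr_complex`), `pdb` (PDB text),
#'   `contacts_truth` (data frame `ab_chain`, `ab_idx`, `ag_idx`),
#'   `regions_truth` (an `abr_regions`), `col_map`.
#' @export
generate_complex <- function(spec, id = "fix1") {
  stopifnot(inherits(spec, "fixture_spec"))
  tpl <- scheme_templates()
  with_seed(spec$seed, {
    seqs <- list(heavy = mutate_seq(tpl$heavy$seq, spec$mutation_rate),
                 light = mutate_seq(tpl$light$seq, spec$mutation_rate))
    cols <- list(heavy = seq_len(nchar(seqs$heavy)),
                 light = seq_len(nchar(seqs$light)))
    contact_pos <- spec$contacts
    if (is.null(contact_pos)) {
      contact_pos <- lapply(c(heavy = "heavy", light = "light"), function(ch) {
        inside <- span_positions(spec$spans[[ch]])
        p <- ifelse(cols[[ch]] %in% inside,
                    spec$inside_density, spec$outside_density)
        which(stats::runif(length(p)) < p)
      })
    }
    spans_res <- lapply(spec$spans, function(sp)
      lapply(sp, function(s) s[1]:s[2]))
    assemble_member(id, seqs, cols, contact_pos, spans_res)
  })
}

#' Generate a synthetic antibody family sharing planted ABR columns
#'
#' Members share the planted ABR column spans; they differ by point
#' mutations at `spec$mutation_rate` and, optionally, one member carries an
#' insertion inside a planted ABR. Contacting members are drawn per column:
#' `round(density * n)` members contact the antigen at every ABR column,
#' `round(outside_density * n)` at every other column.
#'
#' @param spec A [fixture_spec()].
#' @param n Number of members (default `spec$n_members`).
#' @return List with `members` (each as in [generate_complex()]),
#'   `alignment_truth` (per chain: `n_col`, list of per-member column
#'   vectors), `span_cols_truth` (planted spans in global column
#'   coordinates) and `spec`.
#' @export
generate_family <- function(spec, n = spec$n_members) {
  stopifnot(inherits(spec, "fixture_spec"), n >= 2)
  tpl <- scheme_templates()
  base_len <- c(heavy = nchar(tpl$heavy$seq), light = nchar(tpl$light$seq))

  ## global column layout: base positions plus insertion columns
  ins <- spec$indel
  if (!is.null(ins)) {
    ch_ins <- if (grepl("^H", ins$region)) "heavy" else "light"
    sp <- spec$spans[[ch_ins]][[ins$region]]
    ins_after <- floor((sp[1] + sp[2]) / 2)  # insertion point inside region
  }
  n_col <- list(); base_col <- list()
  for (ch in c("heavy", "light")) {
    extra <- if (!is.null(ins) && ch == ch_ins) ins$length else 0L
    bc <- seq_len(base_len[[ch]])
    if (extra > 0L) bc <- ifelse(bc > ins_after, bc + extra, bc)
    base_col[[ch]] <- bc
    n_col[[ch]] <- base_len[[ch]] + extra
  }

  with_seed(spec$seed, {
    members <- vector("list", n)
    rows <- list(heavy = vector("list", n), light = vector("list", n))
    for (m in seq_len(n)) {
      seqs <- list(); cols <- list(); spans_res <- list()
      for (ch in c("heavy", "light")) {
        s <- mutate_seq(tpl[[ch]]$seq, spec$mutation_rate)
        cv <- base_col[[ch]]
        sp_res <- lapply(spec$spans[[ch]], function(x) x[1]:x[2])
        if (!is.null(ins) && ch == ch_ins && m == ins$member) {
          aa <- strsplit(s, "")[[1]]
          insert <- sample(AA1, ins$length, replace = TRUE)
          aa <- append(aa, insert, after = ins_after)
          s <- paste(aa, collapse = "")
          cv <- sort(c(cv, ins_after + seq_len(ins$length)))
          sp_res <- lapply(names(sp_res), function(r) {
            v <- spec$spans[[ch]][[r]]
            lo <- v[1]; hi <- v[2]
            if (r == ins$region) hi <- hi + ins$length
            else if (lo > ins_after) { lo <- lo + ins$length; hi <- hi + ins$length }
            lo:hi
          })
          names(sp_res) <- names(spec$spans[[ch]])
        }
        seqs[[ch]] <- s; cols[[ch]] <- cv; spans_res[[ch]] <- sp_res
      }
      members[[m]] <- list(seqs = seqs, cols = cols, spans_res = spans_res)
      rows$heavy[[m]] <- cols$heavy; rows$light[[m]] <- cols$light
    }

    ## per-column contacting members (exact counts, random membership)
    span_cols <- list()
    contact_pos <- lapply(seq_len(n), function(m)
      list(heavy = integer(0), light = integer(0)))
    for (ch in c("heavy", "light")) {
      inside_res <- span_positions(spec$spans[[ch]])
      inside_cols <- base_col[[ch]][inside_res]
      if (!is.null(ins) && ch == ch_ins)
        inside_cols <- sort(c(inside_cols, ins_after + seq_len(ins$length)))
      span_cols[[ch]] <- lapply(names(spec$spans[[ch]]), function(r) {
        v <- spec$spans[[ch]][[r]]
        lo <- base_col[[ch]][v[1]]; hi <- base_col[[ch]][v[2]]
        if (!is.null(ins) && ch == ch_ins && r == ins$region)
          hi <- base_col[[ch]][v[2]]  # already shifted past insertion
        c(lo, hi)
      })
      names(span_cols[[ch]]) <- names(spec$spans[[ch]])
      for (col in seq_len(n_col[[ch]])) {
        carriers <- which(vapply(seq_len(n), function(m)
          col %in% members[[m]]$cols[[ch]], logical(1)))
        dens <- if (col %in% inside_cols) spec$inside_density
                else spec$outside_density
        k <- min(round(dens * n), length(carriers))
        if (k == 0) next
        chosen <- if (length(carriers) == 1) carriers
                  else sample(carriers, k)
        for (m in chosen) {
          i <- match(col, members[[m]]$cols[[ch]])
          contact_pos[[m]][[ch]] <- c(contact_pos[[m]][[ch]], i)
        }
      }
    }

    out <- vector("list", n)
    for (m in seq_len(n)) {
      mm <- members[[m]]
      out[[m]] <- assemble_member(sprintf("fam%02d", m), mm$seqs, mm$cols,
                                  lapply(contact_pos[[m]], sort), mm$spans_res)
    }
    list(members = out,
         alignment_truth = list(
           heavy = list(n_col = n_col$heavy, rows = rows$heavy),
           light = list(n_col = n_col$light, rows = rows$light)),
         span_cols_truth = span_cols,
         spec = spec)
  })
}

#' Write an `abr_complex` as PDB-format text
#'
#' @param complex An `abr_complex`.
#' @return Character scalar of PDB text (ATOM/TER/END records).
#' @export
complex_to_pdb <- function(complex) {
  stopifnot(inherits(complex, "abr_complex"))
  lines <- character(0); serial <- 0L
  for (role in c("heavy", "light", "antigen")) {
    ch <- complex[[role]]
    for (i in seq_len(nrow(ch$atoms))) {
      a <- ch$atoms[i, ]
      r <- ch$residues[a$res_idx, ]
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, a$elety, " ", AA1TO3[[r$aa]] %||% "UNK", ch$chain_id,
        r$resno, if (nzchar(r$ins)) r$ins else " ",
        a$x, a$y, a$z, a$o, 0))
    }
    lines <- c(lines, sprintf("TER   %5d", serial + 1L))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}
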