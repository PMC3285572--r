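## Parsing antibody-antigen complexes, residue-residue contacts and
## rigid-body superposition.

#' Parse an antibody-antigen complex from PDB text
#'
#' Reads PDB-format text and assembles a three-chain complex: one heavy
#' antibody chain, one light antibody chain and one protein antigen chain.
#' Waters and non-peptide ligands are dropped; alternate locations are
#' collapsed to the highest-occupancy conformer (ties keep the first
#' encountered); modified residues are mapped to their parent amino acid
#' where known, otherwise to `X`.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text,
#'   or a path to a PDB file.
#' @param role_map Named character vector mapping chain ids to roles, e.g.
#'   `c(H = "heavy", L = "light", A = "antigen")`.
#' @param pdb_id Identifier recorded on the returned object.
#' @param min_antigen_len Minimum number of antigen residues (default 5).
#'
#' @return An object of class `abr_complex` with elements `pdb_id`, `heavy`,
#'   `light`, `antigen`; each chain holds a `residues` data frame
#'   (`resno`, `ins`, `aa`, `key`) and an `atoms` data frame
#'   (`res_idx`, `elety`, `x`, `y`, `z`, `o`).
#' @export
parse_complex <- function(pdb_text, role_map, pdb_id = "complex",
                          min_antigen_len = 5L) {
  roles <- c("heavy", "light", "antigen")
  if (!all(role_map %in% roles))
    stopf("role_map values must be heavy/light/antigen")
  path <- pdb_text
  if (length(pdb_text) > 1L || grepl("\n", pdb_text) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK)", pdb_text[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb_text) > 1L) pdb_text
               else strsplit(pdb_text, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom

  chains <- lapply(names(role_map), function(cid) {
    sub <- at[at$chain == cid & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    build_chain(sub, cid)
  })
  names(chains) <- unname(role_map)

  for (r in roles)
    if (is.null(chains[[r]]) || nrow(chains[[r]]$residues) == 0)
      stopf("missing role: %s", r)
  if (identical(chains$heavy$chain_id, chains$light$chain_id))
    stopf("heavy and light roles map to the same chain id")
  if (nrow(chains$antigen$residues) < min_antigen_len)
    stopf("antigen too short: %d residues (need >= %d)",
          nrow(chains$antigen$residues), min_antigen_len)

  structure(list(pdb_id = pdb_id, heavy = chains$heavy,
                 light = chains$light, antigen = chains$antigen),
            class = "abr_complex")
}

## Assemble one chain from a bio3d atom table: altloc collapse, residue
## typing, peptide filter (a residue must be a known amino acid or carry CA).
build_chain <- function(at, chain_id) {
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$o[is.na(at$o)] <- 1
  rid <- paste0(at$resno, at$ins)
  ord <- order(match(rid, unique(rid)))  # keep author order
  at <- at[ord, , drop = FALSE]
  rid <- rid[ord]

  res_list <- list(); atom_rows <- list(); idx <- 0L
  for (key in unique(rid)) {
    ra <- at[rid == key, , drop = FALSE]
    resid <- ra$resid[1]
    aa <- unname(AA3TO1[resid])
    if (is.na(aa)) {
      if (!any(trimws(ra$elety) == "CA")) next  # water/ligand
      aa <- "X"
    }
    ## altloc: per atom name keep highest occupancy, tie -> first seen
    keep <- unlist(lapply(split(seq_len(nrow(ra)), trimws(ra$elety)),
                          function(i) i[which.max(ra$o[i])]))
    ra <- ra[sort(keep), , drop = FALSE]
    idx <- idx + 1L
    res_list[[idx]] <- data.frame(resno = ra$resno[1], ins = ra$ins[1],
                                  aa = aa, key = key,
                                  stringsAsFactors = FALSE)
    atom_rows[[idx]] <- data.frame(res_idx = idx, elety = trimws(ra$elety),
                                   x = ra$x, y = ra$y, z = ra$z, o = ra$o,
                                   stringsAsFactors = FALSE)
  }
  if (idx == 0L)
    return(list(chain_id = chain_id,
                residues = data.frame(resno = integer(0), ins = character(0),
                                      aa = character(0), key = character(0)),
                atoms = data.frame()))
  residues <- do.call(rbind, res_list)
  if (any(!is.finite(as.matrix(do.call(rbind, atom_rows)[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in chain %s", chain_id)
  list(chain_id = chain_id, residues = residues,
       atoms = do.call(rbind, atom_rows))
}

chain_seq <- function(chain) paste(chain$residues$aa, collapse = "")

#' @export
print.abr_complex <- function(x, ...) {
  cat(sprintf("<abr_complex %s> heavy %s (%d aa), light %s (%d aa), antigen %s (%d aa)\n",
              x$pdb_id, x$heavy$chain_id, nrow(x$heavy$residues),
              x$light$chain_id, nrow(x$light$residues),
              x$antigen$chain_id, nrow(x$antigen$residues)))
  invisible(x)
}

#' Extract residue-residue antibody-antigen contacts
#'
#' An antibody residue and an antigen residue are in contact if any of their
#' atom pairs lie within `cutoff` angstroms (all atoms present in the file,
#' no filtering). The default 6 A is the permissive interaction rule used to
#' define observed binding residues.
#'
#' @param complex An `abr_complex`.
#' @param cutoff Distance cutoff in angstroms, in (0, 10].
#' @return An object of class `abr_contacts`: list with `pdb_id`, `cutoff`
#'   and a data frame `contacts` with columns `ab_chain` ("heavy"/"light"),
#'   `ab_idx`, `ab_resno`, `ab_ins`, `ab_aa`, `ag_idx`, `ag_resno`, `ag_ins`,
#'   `ag_aa`, `min_dist`.
#' @export
extract_contacts <- function(complex, cutoff = 6.0) {
  stopifnot(inherits(complex, "abr_complex"))
  if (!(cutoff > 0 && cutoff <= 10)) stopf("cutoff must be in (0, 10]")
  ag <- complex$antigen
  out <- lapply(c("heavy", "light"), function(role) {
    ab <- complex[[role]]
    if (nrow(ab$residues) == 0 || nrow(ag$residues) == 0) return(NULL)
    dm <- cross_min_res_dist(ab, ag)
    hit <- which(dm <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(
      ab_chain = role,
      ab_idx = hit[, 1],
      ab_resno = ab$residues$resno[hit[, 1]],
      ab_ins = ab$residues$ins[hit[, 1]],
      ab_aa = ab$residues$aa[hit[, 1]],
      ag_idx = hit[, 2],
      ag_resno = ag$residues$resno[hit[, 2]],
      ag_ins = ag$residues$ins[hit[, 2]],
      ag_aa = ag$residues$aa[hit[, 2]],
      min_dist = dm[hit],
      stringsAsFactors = FALSE
    )
  })
  contacts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(contacts))
    contacts <- data.frame(ab_chain = character(0), ab_idx = integer(0),
                           ab_resno = integer(0), ab_ins = character(0),
                           ab_aa = character(0), ag_idx = integer(0),
                           ag_resno = integer(0), ag_ins = character(0),
                           ag_aa = character(0), min_dist = numeric(0))
  contacts <- contacts[order(match(contacts$ab_chain, c("heavy", "light")),
                             contacts$ab_idx, contacts$ag_idx), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(pdb_id = complex$pdb_id, cutoff = cutoff,
                 contacts = contacts),
            class = "abr_contacts")
}

## Min atom-atom distance between every residue pair of two chains.
cross_min_res_dist <- function(ca, cb) {
  A <- as.matrix(ca$atoms[, c("x", "y", "z")])
  B <- as.matrix(cb$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  na <- nrow(ca$residues); nb <- nrow(cb$residues)
  m <- matrix(Inf, na, nb)
  ia <- ca$atoms$res_idx; ib <- cb$atoms$res_idx
  for (i in seq_len(nrow(d))) {
    ri <- ia[i]
    mins <- tapply(d[i, ], ib, min)
    cols <- as.integer(names(mins))
    m[ri, cols] <- pmin(m[ri, cols], mins)
  }
  m
}

#' Does the antibody interact with the antigen?
#'
#' TRUE iff at least one antibody atom lies within `cutoff` of any antigen
#' atom, i.e. the contact set is non-empty.
#' @inheritParams extract_contacts
#' @export
is_interacting <- function(complex, cutoff = 6.0) {
  nrow(extract_contacts(complex, cutoff)$contacts) > 0
}

#' Write a contact set as TSV
#'
#' Columns: pdb_id, ab_chain, ab_resnum, ab_aa, ag_resnum, ag_aa, min_dist.
#' @param contacts An `abr_contacts` object.
#' @param path Output file path.
#' @export
write_contacts_tsv <- function(contacts, path) {
  stopifnot(inherits(contacts, "abr_contacts"))
  cc <- contacts$contacts
  df <- data.frame(pdb_id = contacts$pdb_id,
                   ab_chain = cc$ab_chain,
                   ab_resnum = paste0(cc$ab_resno, cc$ab_ins),
                   ab_aa = cc$ab_aa,
                   ag_resnum = paste0(cc$ag_resno, cc$ag_ins),
                   ag_aa = cc$ag_aa,
                   min_dist = round(cc$min_dist, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `coords_b %*% R + t` onto `coords_a`.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices (n >= 3) of paired
#'   coordinates in angstroms.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd`.
#' @export
superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3 ||
      ncol(coords_b) != 3)
    stopf("coordinate sets must be equal-length n x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3) stopf("superposition needs at least 3 points")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  if (svd(A)$d[2] < 1e-8 || svd(B)$d[2] < 1e-8)
    stopf("degenerate (collinear) coordinates")
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- ca - as.vector(cb %*% R)
  fitted <- sweep(coords_b %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - coords_a)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

## Apply a superposition transform to an n x 3 matrix.
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

## C-alpha coordinate matrix of a chain (one row per residue; residues
## lacking CA fall back to their first atom).
ca_coords <- function(chain) {
  n <- nrow(chain$residues)
  m <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    a <- chain$atoms[chain$atoms$res_idx == i, , drop = FALSE]
    j <- which(a$elety == "CA")[1]
    if (is.na(j)) j <- 1L
    m[i, ] <- c(a$x[j], a$y[j], a$z[j])
  }
  m
}
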