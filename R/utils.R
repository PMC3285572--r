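## Shared helpers: amino-acid tables, scheme-label collation, seeded RNG.

#' @keywords internal
"_PACKAGE"

AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  ## common modified residues -> parent amino acid
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C",
  HYP = "P", MLY = "K", M3L = "K", PCA = "Q", KCX = "K"
)

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

## Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## ---- scheme position labels ("35", "35A", ...) ----------------------------

## Split labels into numeric part and insertion letter ("" sorts before "A").
parse_label <- function(label) {
  num <- as.integer(sub("([0-9]+)[A-Z]*$", "\\1", label))
  ins <- sub("^[0-9]+", "", label)
  list(num = num, ins = ins)
}

## Collation order of scheme labels: 35 < 35A < 35B < 36.
label_order_key <- function(label) {
  p <- parse_label(label)
  ltr <- ifelse(p$ins == "", 0L, match(p$ins, LETTERS))
  p$num * 100L + ltr
}

label_leq <- function(a, b) label_order_key(a) <= label_order_key(b)

## TRUE for labels lying inclusively between start and end per collation.
label_between <- function(labels, start, end) {
  key <- vapply(labels, label_order_key, integer(1))
  key >= label_order_key(start) & key <= label_order_key(end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Substitution matrix lookup (Biostrings data), cached per session.
.abr_env <- new.env(parent = emptyenv())

get_submat <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (is.null(.abr_env[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .abr_env[[key]] <- get(name, envir = e)
  }
  .abr_env[[key]]
}

## Region names in chain order.
region_names <- function(chain) {
  if (chain == "heavy") c("H1", "H2", "H3") else c("L1", "L2", "L3")
}

## Residue keys "H:12"/"L:45" used throughout evaluation.
residue_keys <- function(chain, idx) {
  tag <- if (chain == "heavy") "H" else "L"
  if (length(idx) == 0) character(0) else paste0(tag, ":", idx)
}
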