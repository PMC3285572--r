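## Scoring region annotations against observed binding residues, comparing
## methods (consensus / method-specific residue sets), extracting
## method-unique binding residues, and binning alanine-scan ddG values.

#' Score an annotation against observed binding residues
#'
#' Precision = tp / (tp + fp) and recall = tp / (tp + fn), where the gold
#' standard is the set of antibody residues observed in contact with the
#' antigen. An empty prediction yields `NA` precision; recall is 0 unless
#' the gold set is also empty (then `NA`).
#'
#' @param pred An `abr_regions` annotation, or a character vector of
#'   residue keys (`"H:12"`, `"L:45"`).
#' @param gold An `abr_contacts` object, or a character vector of residue
#'   keys.
#' @return List with `counts` (`tp`, `fp`, `fn`), `precision`, `recall`.
#' @export
score_annotation <- function(pred, gold) {
  p <- as_keys(pred); g <- as_keys(gold)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  precision <- if (length(p) == 0) NA_real_ else tp / (tp + fp)
  recall <- if (length(g) == 0) NA_real_ else tp / (tp + fn)
  list(counts = c(tp = tp, fp = fp, fn = fn),
       precision = precision, recall = recall)
}

as_keys <- function(x) {
  if (inherits(x, "abr_regions")) return(annotation_keys(x))
  if (inherits(x, "abr_contacts")) return(binding_keys(x))
  as.character(x)
}

#' Compare two region annotations
#'
#' Splits the union of the two residue sets into consensus residues
#' (identified by both) and two method-specific sets (identified by one
#' only), and reports for each: size, number of binding residues and
#' binding-site coverage (# binding residues in the set / # binding
#' residues total).
#'
#' @param a,b Annotations (or key vectors); `a` is conventionally the
#'   consensus-region method.
#' @param gold Observed binding residues (`abr_contacts` or key vector).
#' @return An `abr_comparison`: list of `consensus`, `delta_a`, `delta_b`
#'   key vectors and a data frame `stats` (`set`, `n_residues`,
#'   `n_binding`, `coverage`).
#' @export
compare_methods <- function(a, b, gold) {
  ka <- as_keys(a); kb <- as_keys(b); kg <- as_keys(gold)
  if (inherits(a, "abr_regions") && inherits(b, "abr_regions") &&
      !is.na(a$id) && !is.na(b$id) && !identical(a$id, b$id))
    stopf("annotations refer to different antibodies: %s vs %s", a$id, b$id)
  consensus <- intersect(ka, kb)
  delta_a <- setdiff(ka, kb)
  delta_b <- setdiff(kb, ka)
  cov <- function(set)
    if (length(kg) == 0) NA_real_ else length(intersect(set, kg)) / length(kg)
  stats <- data.frame(
    set = c("consensus", "delta_a", "delta_b"),
    n_residues = c(length(consensus), length(delta_a), length(delta_b)),
    n_binding = c(length(intersect(consensus, kg)),
                  length(intersect(delta_a, kg)),
                  length(intersect(delta_b, kg))),
    coverage = c(cov(consensus), cov(delta_a), cov(delta_b)),
    stringsAsFactors = FALSE)
  structure(list(consensus = consensus, delta_a = delta_a, delta_b = delta_b,
                 stats = stats),
            class = "abr_comparison")
}

#' Per-region residue counts, precision and recall
#'
#' For each of the six regions of an annotation: the number of residues,
#' the fraction of them contacting the antigen (region precision) and the
#' fraction of all binding residues captured by the region (region
#' recall; the six region recalls sum to the whole-antibody recall when
#' the regions are disjoint).
#'
#' @param ann An `abr_regions` annotation.
#' @param gold Observed binding residues (`abr_contacts` or key vector).
#' @return Data frame: `region`, `n_residues`, `precision`, `recall`.
#' @export
per_region_stats <- function(ann, gold) {
  stopifnot(inherits(ann, "abr_regions"))
  kg <- as_keys(gold)
  rows <- list()
  for (ch in c("light", "heavy")) {
    if (is.null(ann$regions[[ch]])) next
    for (r in names(ann$regions[[ch]])) {
      keys <- residue_keys(ch, ann$regions[[ch]][[r]])
      nb <- length(intersect(keys, kg))
      rows[[r]] <- data.frame(
        region = r, n_residues = length(keys),
        precision = if (length(keys) == 0) NA_real_ else nb / length(keys),
        recall = if (length(kg) == 0) NA_real_ else nb / length(kg),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binding residues unique to the consensus-region method or to the CDRs
#'
#' `paratome_unique` = binding residues inside the consensus-region
#' annotation but outside every CDR scheme; `cdrs_unique` = binding
#' residues inside at least one CDR scheme but outside the
#' consensus-region annotation.
#'
#' @param paratome The consensus-region annotation.
#' @param cdr_annotations Named list of annotations with names covering
#'   `kabat`, `chothia`, `imgt`.
#' @param gold Observed binding residues.
#' @return List of key vectors `paratome_unique`, `cdrs_unique`.
#' @export
find_unique_binding_residues <- function(paratome, cdr_annotations, gold) {
  for (s in c("kabat", "chothia", "imgt"))
    if (!s %in% names(cdr_annotations))
      stopf("missing CDR scheme: %s", s)
  kg <- as_keys(gold)
  kp <- as_keys(paratome)
  kc <- unique(unlist(lapply(cdr_annotations[c("kabat", "chothia", "imgt")],
                             as_keys)))
  list(paratome_unique = setdiff(intersect(kg, kp), kc),
       cdrs_unique = setdiff(intersect(kg, kc), kp))
}

#' Classify alanine-scan ddG values
#'
#' Ternary classification of externally computed interaction-energy changes
#' (kcal/mol scale): `> 0.25` destabilizing, `< -0.25` stabilizing,
#' otherwise neutral (boundaries inclusive in the neutral class).
#'
#' @param ddg Numeric vector of finite ddG values.
#' @return Character vector of `"stabilizing"`, `"neutral"`,
#'   `"destabilizing"`.
#' @export
classify_ddg <- function(ddg) {
  if (any(!is.finite(ddg))) stopf("non-finite ddG value")
  ifelse(ddg > 0.25, "destabilizing",
         ifelse(ddg < -0.25, "stabilizing", "neutral"))
}

#' Macro-averaged evaluation over a set of antibodies
#'
#' Computes per-antibody precision/recall for one annotation scheme and
#' averages them (macro average); antibodies with an undefined precision
#' (empty prediction) are excluded from the precision mean. Pooled
#' (micro-average) values are reported alongside.
#'
#' @param annotations List of `abr_regions` (one per antibody).
#' @param golds List of gold sets (`abr_contacts` or key vectors), same
#'   order.
#' @return List with `macro_precision`, `macro_recall`, `micro_precision`,
#'   `micro_recall`, `n`.
#' @export
evaluate_scheme <- function(annotations, golds) {
  stopifnot(length(annotations) == length(golds))
  pr <- re <- numeric(0); TP <- FP <- FN <- 0L
  for (i in seq_along(annotations)) {
    s <- score_annotation(annotations[[i]], golds[[i]])
    pr <- c(pr, s$precision); re <- c(re, s$recall)
    TP <- TP + s$counts["tp"]; FP <- FP + s$counts["fp"]
    FN <- FN + s$counts["fn"]
  }
  list(macro_precision = mean(pr, na.rm = TRUE),
       macro_recall = mean(re, na.rm = TRUE),
       micro_precision = as.numeric(TP / (TP + FP)),
       micro_recall = as.numeric(TP / (TP + FN)),
       n = length(annotations))
}
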