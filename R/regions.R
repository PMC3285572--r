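## RegionAnnotation container: six residue spans (ABRs or CDRs) per
## antibody, indexed by position within each chain.

#' Construct a region annotation
#'
#' Holds up to six per-chain residue spans (L1-L3, H1-H3) for one antibody
#' under one definition scheme. Regions are stored as sorted integer vectors
#' of residue positions (1-based index within the chain); empty regions are
#' allowed. Regions within a chain must not overlap and must appear in
#' order.
#'
#' @param id Antibody identifier.
#' @param scheme One of `"paratome"`, `"kabat"`, `"chothia"`, `"imgt"`.
#' @param regions List with elements `heavy` and/or `light`, each a named
#'   list of integer vectors (`H1`..`H3` / `L1`..`L3`).
#' @param meta Optional list of provenance fields (hit id, identities, ...).
#' @return An object of class `abr_regions`.
#' @export
new_regions <- function(id, scheme, regions, meta = list()) {
  for (ch in names(regions)) {
    rs <- regions[[ch]]
    rs <- lapply(rs, function(v) sort(unique(as.integer(v))))
    nm <- region_names(ch)
    rs <- rs[intersect(nm, names(rs))]
    prev_end <- -Inf
    for (r in names(rs)) {
      v <- rs[[r]]
      if (length(v)) {
        if (v[1] <= prev_end)
          stopf("regions overlap or out of order in %s chain at %s", ch, r)
        prev_end <- v[length(v)]
      }
    }
    regions[[ch]] <- rs
  }
  structure(list(id = id, scheme = scheme, regions = regions, meta = meta),
            class = "abr_regions")
}

#' @export
print.abr_regions <- function(x, ...) {
  cat(sprintf("<abr_regions %s scheme=%s>\n", x$id, x$scheme))
  for (ch in names(x$regions))
    for (r in names(x$regions[[ch]])) {
      v <- x$regions[[ch]][[r]]
      cat(sprintf("  %s: %s\n", r,
                  if (length(v)) paste0(min(v), "-", max(v),
                                        " (", length(v), " aa)") else "empty"))
    }
  invisible(x)
}

## All residue keys ("H:i"/"L:i") covered by an annotation.
annotation_keys <- function(ann) {
  stopifnot(inherits(ann, "abr_regions"))
  unlist(lapply(names(ann$regions), function(ch)
    unlist(lapply(ann$regions[[ch]], function(v) residue_keys(ch, v)))),
    use.names = FALSE) %||% character(0)
}

## Gold-standard binding residue keys from a contact set.
binding_keys <- function(contacts) {
  stopifnot(inherits(contacts, "abr_contacts"))
  cc <- contacts$contacts
  unique(residue_keys_vec(cc$ab_chain, cc$ab_idx))
}

residue_keys_vec <- function(chain, idx) {
  tag <- ifelse(chain == "heavy", "H", "L")
  if (length(idx) == 0) character(0) else paste0(tag, ":", idx)
}

#' Serialize region annotations to JSON
#'
#' @param ann An `abr_regions` object (or list of them).
#' @param path Output path.
#' @export
write_regions_json <- function(ann, path) {
  if (inherits(ann, "abr_regions")) ann <- list(ann)
  payload <- lapply(ann, function(a)
    list(id = a$id, scheme = a$scheme,
         regions = lapply(a$regions, function(ch) lapply(ch, as.integer))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
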