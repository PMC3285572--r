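# Independent oracles and shared fixture builders. The oracles deliberately
# avoid the code paths they check: contacts by a literal all-atom-pairs
# scan, local alignment by a from-scratch Gotoh dynamic program.

# Brute-force all-atom-pairs residue contact oracle.
brute_force_contacts <- function(complex, cutoff = 6.0) {
  out <- list(); k <- 0L
  ag <- complex$antigen
  for (role in c("heavy", "light")) {
    ab <- complex[[role]]
    for (i in seq_len(nrow(ab$residues))) {
      ai <- ab$atoms[ab$atoms$res_idx == i, , drop = FALSE]
      for (j in seq_len(nrow(ag$residues))) {
        aj <- ag$atoms[ag$atoms$res_idx == j, , drop = FALSE]
        dmin <- Inf
        for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj)))
          dmin <- min(dmin, sqrt((ai$x[p] - aj$x[q])^2 +
                                 (ai$y[p] - aj$y[q])^2 +
                                 (ai$z[p] - aj$z[q])^2))
        if (dmin <= cutoff) {
          k <- k + 1L
          out[[k]] <- data.frame(ab_chain = role, ab_idx = i, ag_idx = j,
                                 min_dist = dmin, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0)
    return(data.frame(ab_chain = character(0), ab_idx = integer(0),
                      ag_idx = integer(0), min_dist = numeric(0)))
  do.call(rbind, out)
}

# Gotoh affine-gap local alignment score (first gapped position costs
# open + extend, each further position extend).
sw_score_oracle <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- submat[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                              Iy[i - 1, j - 1]))
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    best <- max(best, M[i, j])
  }
  best
}

AA_LETTERS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_aa_seq <- function(n) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Apply a random rigid transform to every atom of a complex.
transform_complex <- function(cx, angle = 0.8, axis = c(0, 0, 1),
                              shift = c(10, -5, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  for (role in c("heavy", "light", "antigen")) {
    xyz <- as.matrix(cx[[role]]$atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(R), 2, shift, "+")
    cx[[role]]$atoms$x <- xyz[, 1]
    cx[[role]]$atoms$y <- xyz[, 2]
    cx[[role]]$atoms$z <- xyz[, 3]
  }
  cx
}

# A small shared family + reference set, built once per test run.
shared_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- fixture_spec(seed = 11, n_members = 8, mutation_rate = 0.05)
      fam <- generate_family(sp)
      cxs <- lapply(fam$members, `[[`, "complex")
      al <- align_antibody_set(cxs)
      defn <- derive_abr_boundaries(build_column_profiles(al))
      refs <- build_reference_set(cxs, al, defn)
      cache <<- list(fam = fam, cxs = cxs, al = al, defn = defn, refs = refs)
    }
    cache
  }
})

ROLE_MAP <- c(H = "heavy", L = "light", A = "antigen")
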