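test_that("parse_complex reads a minimal complex and validates roles", {
  g <- generate_complex(fixture_spec(seed = 1,
                                     contacts = list(heavy = 30L,
                                                     light = integer(0))))
  cx <- parse_complex(g$pdb, ROLE_MAP, pdb_id = "t1")
  expect_s3_class(cx, "abr_complex")
  expect_equal(nrow(cx$heavy$residues), 113)
  expect_equal(nrow(cx$light$residues), 107)
  expect_gte(nrow(cx$antigen$residues), 5)
  # reparse equals direct construction (sequences and coordinates)
  expect_equal(cx$heavy$residues$aa, g$complex$heavy$residues$aa)
  expect_equal(cx$light$atoms$x, g$complex$light$atoms$x, tolerance = 1e-3)

  # missing role errors by name
  no_light <- grep(" L ", strsplit(g$pdb, "\n")[[1]],
                   fixed = TRUE, invert = TRUE, value = TRUE)
  expect_error(parse_complex(paste(no_light, collapse = "\n"), ROLE_MAP),
               "missing role: light")
})

test_that("antigen shorter than five residues is rejected", {
  g <- generate_complex(fixture_spec(seed = 2,
                                     contacts = list(heavy = c(10L, 20L),
                                                     light = integer(0))))
  lines <- strsplit(g$pdb, "\n")[[1]]
  # keep only the first 4 antigen residues
  drop <- grepl("^ATOM", lines) & substr(lines, 22, 22) == "A" &
    as.integer(substr(lines, 23, 26)) > 4
  expect_error(parse_complex(paste(lines[!drop], collapse = "\n"), ROLE_MAP),
               "antigen too short")
})

test_that("altloc collapse keeps the highest-occupancy conformer", {
  pdb <- paste(c(
    "ATOM      1  CA AALA H   1      0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA H   1      9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA  GLY L   1      0.000  60.000   0.000  1.00  0.00           C",
    paste0(sprintf("ATOM  %5d  CA  GLY A%4d      0.000  30.000%8.3f  1.00  0.00           C",
                   3 + 1:5, 1:5, 3.8 * 1:5)),
    "END", ""), collapse = "\n")
  cx <- parse_complex(pdb, ROLE_MAP)
  h_atoms <- cx$heavy$atoms
  expect_equal(nrow(h_atoms), 1)
  expect_equal(h_atoms$x, 0)    # altloc A (occupancy 0.6) retained
  expect_equal(h_atoms$o, 0.6)
})

test_that("modified residues map to parent letters and waters are dropped", {
  pdb <- paste(c(
    "ATOM      1  CA  MSE H   1      0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY L   1      0.000  60.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A   1      0.000  30.000   0.000  1.00  0.00           O",
    paste0(sprintf("ATOM  %5d  CA  GLY A%4d      0.000  30.000%8.3f  1.00  0.00           C",
                   3 + 1:5, 2:6, 3.8 * 1:5)),
    "END", ""), collapse = "\n")
  cx <- parse_complex(pdb, ROLE_MAP)
  expect_equal(cx$heavy$residues$aa, "M")
  expect_equal(nrow(cx$antigen$residues), 5)  # water excluded
})

test_that("contact extraction respects the distance threshold exactly", {
  mk <- function(zag) paste(c(
    "ATOM      1  CA  ALA H   1      0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY L   1      0.000  60.000   0.000  1.00  0.00           C",
    sprintf("ATOM      3  CA  GLY A   1      0.000   0.000%8.3f  1.00  0.00           C", zag),
    sprintf("ATOM  %5d  CA  GLY A%4d    100.000  30.000%8.3f  1.00  0.00           C",
            3 + 1:4, 1 + 1:4, 3.8 * 1:4),
    "END", ""), collapse = "\n")
  near <- extract_contacts(parse_complex(mk(5.9), ROLE_MAP), 6.0)
  expect_equal(nrow(near$contacts), 1)
  expect_equal(near$contacts$min_dist, 5.9)
  far <- extract_contacts(parse_complex(mk(6.01), ROLE_MAP), 6.0)
  expect_equal(nrow(far$contacts), 0)
})

test_that("contact extraction matches the brute-force all-pairs oracle", {
  set.seed(42)
  for (s in 1:6) {
    g <- generate_complex(fixture_spec(seed = 100 + s, inside_density = 0.4,
                                       outside_density = 0.05))
    for (cutoff in c(4, 6)) {
      got <- extract_contacts(g$complex, cutoff)$contacts
      want <- brute_force_contacts(g$complex, cutoff)
      expect_equal(got[, c("ab_chain", "ab_idx", "ag_idx")],
                   want[, c("ab_chain", "ab_idx", "ag_idx")],
                   ignore_attr = TRUE)
      expect_equal(got$min_dist, want$min_dist, tolerance = 1e-9)
    }
  }
})

test_that("contact sets are monotone in the cutoff", {
  g <- generate_complex(fixture_spec(seed = 55, inside_density = 0.5,
                                     outside_density = 0.05))
  key <- function(cc) paste(cc$ab_chain, cc$ab_idx, cc$ag_idx)
  cuts <- c(4, 4.5, 5, 5.5, 6)
  sets <- lapply(cuts, function(d) key(extract_contacts(g$complex, d)$contacts))
  for (i in seq_along(cuts)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("is_interacting agrees with non-emptiness of the oracle scan", {
  for (s in 1:10) {
    dens <- if (s %% 2) 0.1 else 0
    g <- generate_complex(fixture_spec(seed = 200 + s, inside_density = dens,
                                       outside_density = 0))
    expect_equal(is_interacting(g$complex),
                 nrow(brute_force_contacts(g$complex)) > 0)
  }
  far <- generate_complex(fixture_spec(seed = 300,
                                       contacts = list(heavy = integer(0),
                                                       light = integer(0))))
  expect_false(is_interacting(far$complex))
})

test_that("superposition recovers exact transforms", {
  set.seed(7)
  A <- matrix(rnorm(45), 15, 3)

  f0 <- superpose(A, A)
  expect_equal(f0$rmsd, 0, tolerance = 1e-10)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)

  f1 <- superpose(A, sweep(A, 2, c(5, 0, 0), "+"))
  expect_equal(f1$rmsd, 0, tolerance = 1e-10)
  expect_equal(f1$translation, c(-5, 0, 0), tolerance = 1e-10)

  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, byrow = TRUE)
  f2 <- superpose(A, A %*% R)   # rows transformed by t(R)
  expect_lt(f2$rmsd, 1e-6)
  expect_equal(f2$rotation, t(R), tolerance = 1e-6)

  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition RMSD is invariant under common rigid transforms", {
  set.seed(8)
  A <- matrix(rnorm(30), 10, 3)
  B <- A + 0.3 * matrix(rnorm(30), 10, 3)
  base <- superpose(A, B)$rmsd
  for (k in 1:5) {
    th <- runif(1, 0, pi)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    sh <- rnorm(3, sd = 10)
    rmsd <- superpose(sweep(A %*% R, 2, sh, "+"),
                      sweep(B %*% R, 2, sh, "+"))$rmsd
    expect_equal(rmsd, base, tolerance = 1e-8)
  }
})

test_that("superposition agrees with an established reference fit", {
  set.seed(9)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + 0.5 * matrix(rnorm(36), 12, 3)
  f <- superpose(A, B)
  ref <- suppressWarnings(bio3d::fit.xyz(as.vector(t(A)), as.vector(t(B))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(f$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("contact TSV export round-trips the pair list", {
  g <- generate_complex(fixture_spec(seed = 61,
                                     contacts = list(heavy = c(30L, 31L),
                                                     light = 28L)))
  ct <- extract_contacts(g$complex)
  path <- tempfile(fileext = ".tsv")
  write_contacts_tsv(ct, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 3)
  expect_equal(df$ab_resnum, c(30, 31, 28))
  expect_true(all(df$min_dist <= 6))
})
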