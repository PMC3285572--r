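fraction_profiles <- function(frac, occupancy = 1) {
  do.call(rbind, lapply(c("heavy", "light"), function(ch)
    data.frame(chain = ch, column = seq_along(frac),
               contact_fraction = frac, occupancy = occupancy)))
}

test_that("column profiles tally contacts and occupancy correctly", {
  fam <- shared_family()
  pf <- build_column_profiles(fam$al)
  n <- length(fam$al$ids)
  # direct tally oracle from the contact matrices
  for (ch in c("heavy", "light")) {
    al <- fam$al[[ch]]
    want_frac <- apply(al$contacts, 2, sum) / n
    got <- pf[pf$chain == ch, ]
    expect_equal(got$contact_fraction[order(got$column)], want_frac)
    occ <- integer(al$n_col)
    for (row in al$rows) occ[row] <- occ[row] + 1L
    expect_equal(got$occupancy[order(got$column)], occ / n)
    expect_true(all(got$contact_fraction <= got$occupancy))
  }
})

test_that("single antibody with contacts at given columns gives 0/1 fractions", {
  rows <- list(1:80)
  ct <- structure(list(pdb_id = "x", cutoff = 6,
                       contacts = data.frame(ab_chain = "heavy",
                                             ab_idx = 5:7)),
                  class = "abr_contacts")
  ct$contacts$ag_idx <- 1:3
  al <- alignment_from_rows("x", heavy_rows = rows, light_rows = rows,
                            contact_sets = list(ct))
  pf <- build_column_profiles(al)
  h <- pf[pf$chain == "heavy", ]
  expect_equal(h$contact_fraction, as.numeric(seq_len(80) %in% 5:7))
})

test_that("boundary derivation finds separated runs and honors >= theta", {
  pf <- fraction_profiles(c(0, 0, .5, .6, 0, 0, .3, .4, 0, 0, .9, 0))
  defn <- derive_abr_boundaries(pf, theta = 0.10, gap_merge = 0)
  expect_equal(unname(defn$spans$heavy),
               list(c(3L, 4L), c(7L, 8L), c(11L, 11L)))

  # a column at exactly the threshold is included (inclusive semantics)
  pf2 <- fraction_profiles(c(0, .5, .10, 0, 0, .5, 0, 0, .5, 0))
  defn2 <- derive_abr_boundaries(pf2, theta = 0.10, gap_merge = 0)
  expect_equal(defn2$spans$light[[1]], c(2L, 3L))

  # fewer than three runs errors with guidance
  pf3 <- fraction_profiles(c(0, .5, 0, 0, .5, 0))
  expect_error(derive_abr_boundaries(pf3, theta = 0.10), "lower theta")
})

test_that("sub-threshold gaps merge and extra runs collapse to three", {
  # two runs separated by 2 cold columns merge at gap_merge 2, not 1
  frac <- c(.5, .5, 0, 0, .5, 0, 0, 0, .5, .3, 0, 0, 0, 0, .4, 0)
  d2 <- derive_abr_boundaries(fraction_profiles(frac), gap_merge = 2)
  expect_equal(unname(d2$spans$heavy),
               list(c(1L, 5L), c(9L, 10L), c(15L, 15L)))
  # four runs at gap_merge 0: the two closest get merged
  frac4 <- c(.5, 0, 0, .5, 0, .9, 0, 0, 0, .5, 0)
  d4 <- derive_abr_boundaries(fraction_profiles(frac4), gap_merge = 0)
  expect_equal(unname(d4$spans$heavy),
               list(c(1L, 1L), c(4L, 6L), c(10L, 10L)))
})

test_that("consensus recovers planted spans exactly on generated families", {
  fam <- generate_family(fixture_spec(seed = 21, n_members = 20,
                                      inside_density = 0.5,
                                      outside_density = 0.02))
  al <- align_antibody_set(lapply(fam$members, `[[`, "complex"))
  defn <- derive_abr_boundaries(build_column_profiles(al), theta = 0.10)
  expect_equal(defn$spans, fam$span_cols_truth)
})

test_that("spans are monotone in theta", {
  fam <- shared_family()
  pf <- build_column_profiles(fam$al)
  cols_in <- function(defn, ch) unlist(lapply(defn$spans[[ch]],
                                              function(s) s[1]:s[2]))
  d_lo <- derive_abr_boundaries(pf, theta = 0.10, gap_merge = 0)
  d_hi <- derive_abr_boundaries(pf, theta = 0.30, gap_merge = 0)
  for (ch in c("heavy", "light")) {
    hot_lo <- pf$column[pf$chain == ch & pf$contact_fraction >= 0.10]
    expect_true(all(cols_in(d_hi, ch) %in% hot_lo))
  }
})

test_that("column spans project onto antibodies through gapped rows", {
  pf <- fraction_profiles(c(0, 0, .5, .5, 0, 0, .5, .5, 0, .5, .5, 0))
  defn <- derive_abr_boundaries(pf, gap_merge = 0)

  # ungapped row: residue indices equal column indices
  row <- list(heavy = 1:12, light = 1:12)
  ann <- map_abrs_to_antibody(defn, row, id = "u")
  expect_equal(ann$regions$heavy$H1, 3:4)
  expect_equal(ann$regions$light$L2, 7:8)

  # two leading gap columns shift residue coordinates by -2
  row2 <- list(heavy = 3:12, light = 3:12)
  ann2 <- map_abrs_to_antibody(defn, row2, id = "g")
  expect_equal(ann2$regions$heavy$H1, 1:2)

  # fully gapped region is empty
  row3 <- list(heavy = c(1:9, 12L), light = c(1:9, 12L))
  ann3 <- map_abrs_to_antibody(defn, row3, id = "d")
  expect_length(ann3$regions$heavy$H3, 0)

  # column-count mismatch errors
  expect_error(map_abrs_to_antibody(defn, list(heavy = 1:20, light = 1:12)),
               "columns")
})

test_that("projection round-trips on ungapped rows", {
  fam <- shared_family()
  defn <- fam$defn
  for (k in c(1, 4)) {
    row <- list(heavy = fam$al$heavy$rows[[k]],
                light = fam$al$light$rows[[k]])
    ann <- map_abrs_to_antibody(defn, row, id = fam$al$ids[k])
    for (ch in c("heavy", "light"))
      for (r in names(ann$regions[[ch]])) {
        cols <- row[[ch]][ann$regions[[ch]][[r]]]
        sp <- defn$spans[[ch]][[r]]
        expect_true(all(cols >= sp[1] & cols <= sp[2]))
        # every occupied column of the span is recovered
        occupied <- which(row[[ch]] >= sp[1] & row[[ch]] <= sp[2])
        expect_equal(ann$regions[[ch]][[r]], occupied)
      }
  }
})

test_that("structural alignment is the identity for identical structures", {
  g <- generate_complex(fixture_spec(seed = 23, mutation_rate = 0))
  g2 <- generate_complex(fixture_spec(seed = 24, mutation_rate = 0))
  cx1 <- g$complex; cx2 <- g2$complex
  cx2$pdb_id <- "copy"
  al <- align_antibody_set(list(cx1, cx2))
  expect_equal(al$heavy$rows[[1]], al$heavy$rows[[2]])
  expect_equal(al$heavy$rows[[1]], seq_len(113))

  # rigid-rotated copy aligns identically
  cx3 <- transform_complex(cx2)
  cx3$pdb_id <- "rot"
  al2 <- align_antibody_set(list(cx1, cx3))
  expect_equal(al2$heavy$rows, al$heavy$rows)
  expect_equal(al2$light$rows, al$light$rows)
})

test_that("alignment isolates a planted insertion in dedicated columns", {
  fam <- generate_family(fixture_spec(
    seed = 25, n_members = 5, mutation_rate = 0.02,
    indel = list(member = 3L, region = "H3", length = 2L)))
  al <- align_antibody_set(lapply(fam$members, `[[`, "complex"))
  expect_equal(al$heavy$rows, fam$alignment_truth$heavy$rows)
  carrier <- al$heavy$rows[[3]]
  others <- unlist(al$heavy$rows[-3])
  ins_cols <- setdiff(carrier, unique(others))
  expect_length(ins_cols, 2)
  # chains too short to anchor are refused
  short <- fam$members[[1]]$complex
  short$heavy$residues <- short$heavy$residues[1:50, ]
  short$heavy$atoms <- short$heavy$atoms[short$heavy$atoms$res_idx <= 50, ]
  expect_error(align_antibody_set(list(short, fam$members[[2]]$complex)),
               "too short to anchor")
})

test_that("definitions serialize to JSON and back", {
  fam <- shared_family()
  path <- tempfile(fileext = ".json")
  write_abr_definition(fam$defn, path)
  back <- read_abr_definition(path)
  expect_equal(back$spans, fam$defn$spans)
  expect_equal(back$theta, fam$defn$theta)
})
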