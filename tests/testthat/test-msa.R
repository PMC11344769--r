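write_msa_file <- function(rows, ext = ".a3m") {
  path <- tempfile(fileext = ext)
  writeLines(as.vector(rbind(paste0(">", names(rows)), unname(rows))), path)
  path
}

test_that("aligned FASTA parsing builds an identity-like column map", {
  path <- write_msa_file(c(target = "ACDEFG", hom = "ACDQFG"),
                         ext = ".fasta")
  msa <- read_msa(path)
  expect_equal(msa$format, "fasta")
  expect_equal(msa$target_sequence, "ACDEFG")
  expect_equal(msa$column_map, 1:6)

  # target gap: that column is skipped by the map
  path2 <- write_msa_file(c(target = "AC-EFG", hom = "ACDEFG"),
                          ext = ".fasta")
  msa2 <- read_msa(path2, format = "fasta")
  expect_equal(msa2$target_sequence, "ACEFG")
  expect_equal(msa2$column_map, c(1, 2, 4, 5, 6))

  # ragged FASTA is an error
  bad <- write_msa_file(c(target = "ACDEFG", hom = "ACD"), ext = ".fasta")
  expect_error(read_msa(bad, format = "fasta"), "ragged")
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(read_msa(empty), "empty")
})

test_that("A3M lowercase insertions do not create alignment columns", {
  path <- write_msa_file(c(target = "ACDEFG", hom = "ACDEfFG"))
  msa <- read_msa(path)
  expect_equal(msa$format, "a3m")
  expect_equal(msa$column_map, 1:6)
  expect_equal(nchar(msa$rows$aligned[2]), 7)  # insertion kept verbatim
})

test_that("sliding windows tile the region with unit step", {
  wins <- sliding_windows("11-66", w = 11)
  expect_length(wins, 46)                       # 56 - 11 + 1
  expect_equal(wins[[1]], 11:21)
  expect_equal(wins[[46]], 56:66)
  expect_length(sliding_windows(1:11, w = 11), 1)
  expect_error(sliding_windows(1:10, w = 11), "smaller w")
})

test_that("contact positions honor the distance cutoff and sequence exclusion", {
  co <- cbind(10 * (1:30), 0, 0)
  co[5, ] <- c(200, 3.5, 0)    # 3.5 A from window residue 20
  co[28, ] <- c(250, 3.0, 0)   # 3 A from residue 25 but |28-25| <= 4
  co[30, ] <- c(150, 3.0, 0)   # 3 A from residue 15, |30-q| >= 5
  s <- ca_structure(co)
  hits <- contact_positions(s, 15:25, cutoff = 4.0, seq_exclusion = 4)
  expect_true(5 %in% hits)
  expect_false(28 %in% hits)   # within 4 residues of the window: excluded
  expect_true(30 %in% hits)
  expect_false(any(15:25 %in% hits))  # window residues never returned
  # residue 29 (|29-25| = 4, boundary) also excluded even if close
  co[29, ] <- c(250, 3.0, 0)
  expect_false(29 %in% contact_positions(ca_structure(co), 15:25))
  expect_error(contact_positions(s, 40:50), "missing")
})

test_that("masking converts homolog columns to alanine, never the target", {
  path <- write_msa_file(c(target = "ACDEFG", hom1 = "ACDEfFG",
                           hom2 = "A-DEFG"))
  msa <- read_msa(path)
  m <- mask_msa(msa, c(2, 3))
  expect_equal(m$rows$aligned[1], "ACDEFG")          # target untouched
  expect_equal(m$rows$aligned[2], "AAAEfFG")         # insertion untouched
  expect_equal(m$rows$aligned[3], "A-AEFG")          # gap preserved
  expect_equal(mask_msa(msa, integer(0))$rows$aligned, msa$rows$aligned)
  expect_error(mask_msa(msa, 99), "outside target")
})

test_that("masking preserves row count, length and gap pattern", {
  msa <- make_toy_msa(strrep("ACDEFGHIKL", 3), n_rows = 6,
                      mutation_rate = 0.2, gap_rate = 0.1, seed = 5)
  m <- mask_msa(msa, c(4, 9, 22))
  expect_equal(nrow(m$rows), nrow(msa$rows))
  expect_equal(nchar(m$rows$aligned), nchar(msa$rows$aligned))
  gaps <- function(s) gregexpr("-", s, fixed = TRUE)
  for (r in seq_len(nrow(m$rows)))
    expect_equal(gaps(m$rows$aligned[r]), gaps(msa$rows$aligned[r]))
  # only the masked columns changed, and only to A
  for (r in 2:nrow(m$rows)) {
    a <- strsplit(msa$rows$aligned[r], "")[[1]]
    b <- strsplit(m$rows$aligned[r], "")[[1]]
    changed <- which(a != b)
    expect_true(all(changed %in% c(4, 9, 22)))
    expect_true(all(b[changed] == "A"))
  }
})

test_that("dedupe keeps the earliest of identical masks and is idempotent", {
  msa <- make_toy_msa("ACDEFGHIKL", n_rows = 4, seed = 2)
  m1 <- mask_msa(msa, c(2, 3)); m1$window <- 1:3
  m2 <- mask_msa(msa, c(2, 3)); m2$window <- 2:4   # same mask, later window
  m3 <- mask_msa(msa, 5); m3$window <- 3:5
  dd <- dedupe_masked(list(m1, m2, m3))
  expect_length(dd, 2)
  expect_equal(dd[[1]]$window, 1:3)
  expect_equal(dedupe_masked(dd), dd)
  expect_length(dedupe_masked(list(m1, m3)), 2)
})

test_that("A3M writing round-trips rows exactly", {
  msa <- make_toy_msa("ACDEFGHIKLMNPQRSTVWY", n_rows = 5,
                      mutation_rate = 0.15, seed = 9)
  m <- mask_msa(msa, c(3, 7, 11))
  out <- tempfile(fileext = ".a3m")
  write_a3m(m, out)
  back <- read_msa(out)
  expect_equal(back$rows$id, m$rows$id)
  expect_equal(back$rows$aligned, m$rows$aligned)
})

test_that("the mask generator emits at most one MSA per window, masks within contacts", {
  p <- make_toy_pair(length = 70, fs_region = "20-50", seed = 17)
  msa <- make_toy_msa(p$ref_A$sequence, n_rows = 6, seed = 18)
  masked <- generate_masked_msas(msa, p$ref_A, "20-50", w = 11)
  n_windows <- length(sliding_windows("20-50", w = 11))
  expect_lte(length(masked), n_windows)
  expect_gt(length(masked), 0)
  for (m in masked) {
    expect_equal(m$rows$aligned[1], msa$rows$aligned[1])
    contacts <- contact_positions(p$ref_A, m$window)
    expect_true(all(m$masked_positions %in% contacts))
  }
})
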