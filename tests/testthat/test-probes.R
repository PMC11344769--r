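line_structure <- function(bf, spacing = 10) {
  ca_structure(cbind(spacing * seq_along(bf), 0, 0), bf = bf)
}

test_that("B-factor normalization matches hand-computed z-scores", {
  pr <- normalize_bfactors(line_structure(c(10, 20, 30)))
  expect_equal(pr$profile$bf_norm, c(-1, 0, 1))      # sample sd = 10
  expect_equal(pr$mu_bf, 20)
  expect_equal(pr$sigma_bf, 10)
  expect_false(any(pr$profile$flexible))

  # mean 10, sample sd 20: max z = 1.5, nothing flexible
  pr2 <- normalize_bfactors(line_structure(c(0, 0, 0, 40)))
  expect_equal(max(pr2$profile$bf_norm), 1.5)
  expect_false(any(pr2$profile$flexible))

  expect_error(normalize_bfactors(line_structure(c(5, 5, 5))), "constant")
  expect_error(normalize_bfactors(line_structure(7)), "at least 2")

  # invariant: mean 0, unit sd under the sample convention
  set.seed(8)
  pr3 <- normalize_bfactors(line_structure(runif(40, 5, 80)))
  expect_equal(mean(pr3$profile$bf_norm), 0, tolerance = 1e-9)
  expect_equal(sd(pr3$profile$bf_norm), 1, tolerance = 1e-9)
  expect_equal(pr3$profile$flexible, pr3$profile$bf_norm >= 2)
})

test_that("region flexibility reports both region- and residue-level readings", {
  pr <- normalize_bfactors(line_structure(c(10, 10, 10, 10, 10, 10, 10, 60)))
  full <- region_flexibility(pr, 1:8)
  expect_true(full$any_flexible)
  expect_equal(full$fraction_flexible, 1 / 8)
  quiet <- region_flexibility(pr, 1:7)
  expect_false(quiet$any_flexible)
  expect_equal(quiet$fraction_flexible, 0)
  expect_error(region_flexibility(pr, 100:110), "no residues")
})

test_that("contact maps honor cutoff, sequence separation and dimer tagging", {
  co <- cbind(100 * (1:10), 0, 0)
  co[8, ] <- c(100, 7.9, 0)    # 7.9 A from residue 1, |8-1| >= 5
  co[3, ] <- c(100, 4.0, 0)    # 4 A from residue 1 but |3-1| < 5
  cm <- contact_map(ca_structure(co), cutoff = 8, atom_mode = "CA",
                    min_seq_sep = 5)
  expect_true(any(cm$contacts$i == 1 & cm$contacts$j == 8))
  expect_false(any(cm$contacts$i == 1 & cm$contacts$j == 3))
  expect_true(all(cm$contacts$i < cm$contacts$j))
  expect_true(all(cm$contacts$kind == "intramolecular"))

  # rigid-motion invariance of the contact set
  s <- ca_structure(co)
  cm2 <- contact_map(rigid_move(s, random_rotation(3), c(5, 5, 5)),
                     cutoff = 8, atom_mode = "CA", min_seq_sep = 5)
  expect_equal(cm$contacts[, c("i", "j")], cm2$contacts[, c("i", "j")])

  # dimer: cross-chain contact at 6 A is intermolecular, unrestricted in |i-j|
  a <- ca_structure(cbind(100 * (1:4), 0, 0), id = "chA")
  bco <- cbind(100 * (1:4), 6, 0)
  b <- ca_structure(bco, id = "chB"); b$chain_id <- "B"
  dm <- contact_map(list(a, b), cutoff = 8, atom_mode = "CA")
  inter <- dm$contacts[dm$contacts$kind == "intermolecular", ]
  expect_true(any(inter$i == 1 & inter$j == 1))
})

test_that("contact-map comparison is an exact partition and swap-symmetric", {
  mk <- function(pairs) {
    cm <- contact_map(ca_structure(cbind(100 * (1:2), 0, 0)), cutoff = 8,
                      atom_mode = "CA")
    cm$contacts <- data.frame(i = pairs[, 1], j = pairs[, 2],
                              chain_i = "A", chain_j = "A",
                              kind = "intramolecular", dist = 5)
    cm
  }
  A <- mk(rbind(c(1, 10), c(2, 11), c(3, 12)))
  B <- mk(rbind(c(2, 11), c(3, 12), c(4, 13)))
  cmp <- compare_contact_maps(A, B)
  expect_equal(unname(cmp$counts), c(1, 1, 2))
  expect_equal(nrow(cmp$unique_A) + nrow(cmp$unique_B) + 2 * nrow(cmp$common),
               nrow(A$contacts) + nrow(B$contacts))
  rev <- compare_contact_maps(B, A)
  expect_equal(cmp$unique_A, rev$unique_B, ignore_attr = TRUE)
  expect_equal(unname(cmp$counts["common"]), unname(rev$counts["common"]))

  same <- compare_contact_maps(A, A)
  expect_equal(nrow(same$unique_A), 0)
  expect_equal(nrow(same$common), 3)
  C <- mk(rbind(c(5, 20)))
  expect_equal(nrow(compare_contact_maps(A, C)$common), 0)
})

test_that("coevolution pair files are validated, canonicalized and deduplicated", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("i\tj\tscore", "5\t20\t0.9", "20\t5\t1.3", "7\t30\t0.4"), path)
  pairs <- load_coevolution_pairs(path)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$score[pairs$i == 5 & pairs$j == 20], 1.3)  # max kept
  expect_true(all(pairs$i < pairs$j))

  bad <- tempfile(); writeLines(c("1\t2\t0.5", "oops"), bad)
  expect_error(load_coevolution_pairs(bad), "line 2")
  expect_error(load_coevolution_pairs(path, seq_length = 25), "outside")
})

test_that("residue distances are Euclidean and obey the triangle inequality", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 0))
  s <- ca_structure(co)
  expect_equal(residue_distance(s, 1, 2), 1)
  expect_equal(residue_distance(s, 1, 1), 0)
  expect_equal(residue_distance(s, 1, 3), 5)
  expect_lte(residue_distance(s, 2, 3),
             residue_distance(s, 2, 1) + residue_distance(s, 1, 3))
  expect_error(residue_distance(s, 1, 99), "99")
})

test_that("windowed mean plDDT averages CA values over the author region", {
  s <- ca_structure(cbind(1:4, 0, 0), bf = c(10, 60, 80, 20))
  expect_equal(mean_plddt_window(s, "2-3"), 70)
  expect_equal(mean_plddt_window(s, 3), 80)
  expect_equal(mean_plddt_window(s, "1-4"), mean(c(10, 60, 80, 20)))
  expect_error(mean_plddt_window(s, "50-60"), "no residues")
})
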