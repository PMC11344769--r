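test_that("classification reproduces the threshold and tie rules exactly", {
  eps <- 1e-9
  # boundary grid around tau = 0.6: equality never exceeds the threshold
  expect_equal(classify_model(0.7, 0.3), "FOLD1")
  expect_equal(classify_model(0.3, 0.7), "FOLD2")
  expect_equal(classify_model(0.65, 0.72), "FOLD2")   # both above: larger wins
  expect_equal(classify_model(0.72, 0.65), "FOLD1")
  expect_equal(classify_model(0.60, 0.60), "OTHER")
  expect_equal(classify_model(0.6 + eps, 0.6), "FOLD1")
  expect_equal(classify_model(0.6, 0.6 + eps), "FOLD2")
  expect_equal(classify_model(0.6 - eps, 0.6 - eps), "OTHER")
  expect_equal(classify_model(0, 0), "OTHER")
  expect_equal(classify_model(1, 1), "FOLD1")         # exact tie above: Fold1

  # total function over a grid: exactly one label each
  for (t1 in seq(0, 1, by = 0.1)) for (t2 in seq(0, 1, by = 0.1)) {
    lab <- classify_model(t1, t2)
    expect_true(lab %in% c("FOLD1", "FOLD2", "OTHER"))
  }
})

test_that("fold order follows the 3-of-5 majority with a mean-TM tie-break", {
  p <- make_toy_pair(seed = 4)
  # 5 baseline models all near ref A -> Fold1 = A, no tie-break
  near_A <- lapply(1:5, function(k) perturb(p$ref_A, 0.5, seed = k))
  fo <- assign_fold_order(p, near_A)
  expect_equal(fo$fold1, "A")
  expect_equal(fo$wins_A, 5)
  expect_false(fo$tie_break)

  # 3 near A, 2 near B -> still A
  mixed <- c(lapply(1:3, function(k) perturb(p$ref_A, 0.5, seed = k)),
             lapply(4:5, function(k) perturb(p$ref_B, 0.5, seed = k)))
  expect_equal(assign_fold_order(p, mixed)$fold1, "A")

  # 2-2 split with n = 4: tie broken by mean region TM, flagged
  tied <- c(lapply(1:2, function(k) perturb(p$ref_A, 0.4, seed = k)),
            lapply(3:4, function(k) perturb(p$ref_B, 0.4, seed = k)))
  fo4 <- assign_fold_order(p, tied)
  expect_true(fo4$tie_break)
  expect_equal(fo4$fold1,
               if (fo4$mean_tm_A >= fo4$mean_tm_B) "A" else "B")

  expect_error(assign_fold_order(p, list()), "fold_order")
})

test_that("pair success requires each conformation at least once", {
  expect_equal(pair_success(c("FOLD1", "OTHER", "FOLD1")),
               list(fold1 = TRUE, fold2 = FALSE, overall = FALSE))
  expect_equal(pair_success(c("FOLD1", "FOLD2")),
               list(fold1 = TRUE, fold2 = TRUE, overall = TRUE))
  expect_equal(pair_success("OTHER"),
               list(fold1 = FALSE, fold2 = FALSE, overall = FALSE))
})

test_that("success rate is the fraction of overall successes", {
  expect_equal(round(success_rate(rep(c(TRUE, FALSE), c(32, 60))), 4), 0.3478)
  expect_equal(success_rate(rep(FALSE, 10)), 0)
  expect_equal(success_rate(rep(TRUE, 7)), 1)
})

test_that("difficulty labelling honors both geometric routes and the amyloid flag", {
  expect_equal(label_difficulty(12.0, 0.7, FALSE), "COMPLEX")  # wRMSD > 10
  expect_equal(label_difficulty(4.0, 0.45, FALSE), "COMPLEX")  # fsTM < 0.5
  expect_equal(label_difficulty(4.0, 0.7, FALSE), "EASY")
  expect_equal(label_difficulty(4.0, 0.7, TRUE), "COMPLEX")    # amyloid/swap
  # boundaries: strict inequalities on both cuts
  expect_equal(label_difficulty(10.0, 0.5, FALSE), "EASY")
  expect_equal(label_difficulty(10.0 + 1e-9, 0.7, FALSE), "COMPLEX")
  expect_equal(label_difficulty(4.0, 0.5 - 1e-9, FALSE), "COMPLEX")
  # configurable conjunction
  expect_equal(label_difficulty(12, 0.7, FALSE, conjunction = "and"), "EASY")
  expect_equal(label_difficulty(12, 0.4, FALSE, conjunction = "and"),
               "COMPLEX")
})

test_that("false-positive rate counts confident OTHER models only", {
  labs <- c("OTHER", "OTHER", "FOLD1", "FOLD2")
  expect_equal(false_positive_rate(labs, c(80, 75, 90, 71)), 0.5)
  expect_true(is.na(false_positive_rate(labs, c(10, 20, 30, 40))))
  expect_equal(false_positive_rate(rep("FOLD1", 3), c(80, 90, 70)), 0)
  # boundary: exactly 70 counts as confident
  expect_equal(false_positive_rate(c("OTHER", "FOLD1"), c(70, 69.9)), 1)
})

test_that("training-roster matching is case-insensitive on PDB id only", {
  roster <- tempfile()
  writeLines(c("2oug_C 5jyt_A", "3gmh_L"), roster)
  expect_equal(match_training_roster(c("2oug_C", "2OUG_C", "2oug_c",
                                       "9zzz_A", "3gmh_L"), roster),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_error(match_training_roster("2oug_C", tempfile()), "not found")
})

test_that("swapping the fold order swaps FOLD1/FOLD2 counts and preserves the rest", {
  p <- make_toy_pair(seed = 6)
  ens <- make_ensemble(p, n_models = 30, weights = c(0.5, 0.2, 0.3),
                       seed = 5)
  a_fwd <- assess_pair(p, ens$models, fold_order = "A")
  a_rev <- assess_pair(p, ens$models, fold_order = "B")
  expect_equal(unname(a_fwd$summary$counts["FOLD1"]),
               unname(a_rev$summary$counts["FOLD2"]))
  expect_equal(unname(a_fwd$summary$counts["FOLD2"]),
               unname(a_rev$summary$counts["FOLD1"]))
  expect_equal(unname(a_fwd$summary$counts["OTHER"]),
               unname(a_rev$summary$counts["OTHER"]))
  expect_equal(a_fwd$summary$success_overall, a_rev$summary$success_overall)
})

test_that("assessment summaries are internally consistent", {
  p <- make_toy_pair(seed = 8)
  ens <- make_ensemble(p, n_models = 20, seed = 9)
  a <- assess_pair(p, ens$models, fold_order = "A")
  expect_equal(sum(a$summary$counts), nrow(a$models))
  expect_equal(a$summary$success_overall,
               a$summary$success_fold1 && a$summary$success_fold2)
  expect_true(all(a$models$label ==
                    mapply(classify_model, a$models$tm1, a$models$tm2)))
  # toy pairs are Complex by construction (H->E region swap)
  expect_equal(a$summary$difficulty, "COMPLEX")
})
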