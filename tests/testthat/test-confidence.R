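test_that("confidence fraction counts plDDT >= 70 inclusively", {
  expect_equal(confidence_fraction(c(90, 60, 80, 75)), 75)
  expect_equal(confidence_fraction(rep(70, 5)), 100)
  expect_equal(confidence_fraction(rep(69.9, 5)), 0)
  expect_error(confidence_fraction(numeric(0)), "empty")
})

test_that("category boundaries are inclusive and monotone", {
  expect_equal(confidence_category(85), "GOOD")
  expect_equal(confidence_category(90), "HIGH")
  expect_equal(confidence_category(69), "UNCLASSIFIED")
  expect_equal(confidence_category(70), "MEDIUM")
  expect_equal(confidence_category(80), "GOOD")
  expect_equal(confidence_category(70 - 1e-9), "UNCLASSIFIED")
  expect_equal(confidence_category(90 - 1e-9), "GOOD")
  # monotone in fraction
  lv <- c(UNCLASSIFIED = 0, MEDIUM = 1, GOOD = 2, HIGH = 3)
  cats <- lv[vapply(seq(0, 100, by = 2.5), confidence_category, "")]
  expect_true(all(diff(cats) >= 0))
})

test_that("reranking is a deterministic permutation with the stated tie-breaks", {
  rec <- data.frame(model_id = c("m1", "m2", "m3"),
                    confidence_fraction = c(80, 95, 95),
                    mean_plddt = c(70, 82, 91),
                    stringsAsFactors = FALSE)
  r <- rerank(rec)
  expect_equal(r$model_id, c("m3", "m2", "m1"))
  expect_equal(r$rank, 1:3)
  expect_setequal(r$model_id, rec$model_id)
  expect_identical(rerank(rec), r)   # deterministic across calls
  # full tie falls back to lexicographic id
  tie <- data.frame(model_id = c("b", "a"), confidence_fraction = c(50, 50),
                    mean_plddt = c(60, 60), stringsAsFactors = FALSE)
  expect_equal(rerank(tie)$model_id, c("a", "b"))
})

test_that("tabulation conserves totals and nests rank pools", {
  set.seed(31)
  n <- 17
  rec <- data.frame(model_id = sprintf("m%02d", 1:n),
                    confidence_fraction = round(runif(n, 0, 100), 1),
                    mean_plddt = round(runif(n, 40, 95), 1),
                    stringsAsFactors = FALSE)
  ass <- data.frame(model_id = rec$model_id,
                    label = sample(c("FOLD1", "FOLD2", "OTHER"), n,
                                   replace = TRUE),
                    stringsAsFactors = FALSE)
  tab <- tabulate_categories(rec, ass)$counts
  all_all <- tab[tab$pool == "All" & tab$category == "All", ]
  expect_equal(sum(all_all$n), n)
  # Top1 <= Top10 <= All per (category, label) cell family
  for (cat in unique(tab$category)) for (lb in unique(tab$label)) {
    cell <- function(pool) tab$n[tab$pool == pool & tab$category == cat &
                                   tab$label == lb]
    expect_lte(cell("Top1"), cell("Top10"))
    expect_lte(cell("Top10"), cell("All"))
  }
  # predicted flag is N >= 1
  expect_equal(tab$predicted, tab$n >= 1)

  # small ensembles: Top10 is the whole ensemble
  rec7 <- rec[1:7, ]; ass7 <- ass[1:7, ]
  tab7 <- tabulate_categories(rec7, ass7)$counts
  expect_equal(sum(tab7$n[tab7$pool == "Top10" & tab7$category == "All"]), 7)

  expect_error(tabulate_categories(rec, ass[-1, ]), "missing")
})

test_that("anti-correlated confidence enriches OTHER in the Top1 pool", {
  p <- make_toy_pair(seed = 13)
  ens <- make_ensemble(p, n_models = 60, weights = c(0.5, 0.2, 0.3),
                       polarity = "against", seed = 14)
  a <- assess_pair(p, ens$models, fold_order = "A")
  tab <- tabulate_categories(
    a$models[, c("model_id", "confidence_fraction", "mean_plddt")],
    a$models[, c("model_id", "label")])$counts
  frac_other <- function(pool) {
    sub <- tab[tab$pool == pool & tab$category == "All", ]
    sub$n[sub$label == "OTHER"] / sum(sub$n)
  }
  expect_gt(frac_other("Top1"), frac_other("All"))
})

test_that("exact binomial tails match closed forms and the pmf-sum oracle", {
  expect_equal(binomial_onesided(0, 10, 0.5, "lower"), 2^-10)
  expect_equal(binomial_onesided(0, 10, 0.5, "lower"), 9.765625e-4)
  expect_equal(binomial_onesided(7, 7, 0.3, "upper"), 0.3^7)

  # brute-force pmf enumeration with choose() arithmetic
  pmf_oracle <- function(k, n, p0, tail) {
    ks <- if (tail == "lower") 0:k else k:n
    sum(choose(n, ks) * p0^ks * (1 - p0)^(n - ks))
  }
  expect_equal(binomial_onesided(3, 8, 0.25, "lower"),
               pmf_oracle(3, 8, 0.25, "lower"), tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(1:40, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_onesided(k, n, p0, "lower"),
                 pmf_oracle(k, n, p0, "lower"), tolerance = 1e-10)
    # complement identity P(X <= k) + P(X >= k+1) = 1
    if (k < n)
      expect_equal(binomial_onesided(k, n, p0, "lower") +
                     binomial_onesided(k + 1, n, p0, "upper"), 1,
                   tolerance = 1e-12)
  }
  expect_error(binomial_onesided(5, 3, 0.5), "k <= n")
  expect_error(binomial_onesided(1, 3, 1.2), "p0")
})
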