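# Core dual-conformation analysis: fold ordering, per-model classification,
# success, difficulty and false-positive statistics.

#' Construct a fold-switch pair
#'
#' Bundles the two experimental reference structures of one fold-switching
#' protein with its fold-switching region, given in the author numbering of
#' each reference (the two region specs must cover the same number of
#' residues).
#'
#' @param pair_id Identifier.
#' @param ref_A,ref_B `fs_structure` reference conformations.
#' @param fs_region_A,fs_region_B Author-numbered region specs (strings like
#'   `"11-66"` or integer vectors), one per reference.
#' @param is_amyloid_or_swap Logical; amyloids and domain-swapped pairs are
#'   labelled Complex regardless of geometry.
#' @param in_training_roster Named logical (`A`, `B`) or single logical.
#' @param ground_state `"A"`, `"B"`, `"isoenergetic"` or `"unknown"`.
#' @return Object of class `fold_switch_pair`.
#' @export
fold_switch_pair <- function(pair_id, ref_A, ref_B, fs_region_A, fs_region_B,
                             is_amyloid_or_swap = FALSE,
                             in_training_roster = c(A = NA, B = NA),
                             ground_state = "unknown") {
  ra <- parse_region(fs_region_A); rb <- parse_region(fs_region_B)
  na <- length(region_res_index(ref_A, ra))
  nb <- length(region_res_index(ref_B, rb))
  if (na != nb)
    stop("fold-switching regions cover different residue counts: ",
         na, " (A) vs ", nb, " (B)")
  if (na == 0) stop("fold-switching region matches no residues")
  obj <- list(pair_id = pair_id, ref_A = ref_A, ref_B = ref_B,
              fs_region_A = ra, fs_region_B = rb,
              is_amyloid_or_swap = isTRUE(is_amyloid_or_swap),
              in_training_roster = in_training_roster,
              ground_state = match.arg(ground_state,
                                       c("unknown", "A", "B", "isoenergetic")),
              fold_order = NULL)
  class(obj) <- "fold_switch_pair"
  obj
}

#' @export
print.fold_switch_pair <- function(x, ...) {
  cat("fold_switch_pair:", x$pair_id, "\n")
  cat("  ref A:", x$ref_A$id, " region",
      paste(range(x$fs_region_A), collapse = "-"), "\n")
  cat("  ref B:", x$ref_B$id, " region",
      paste(range(x$fs_region_B), collapse = "-"), "\n")
  if (!is.null(x$fold_order))
    cat("  Fold1 =", x$fold_order, "\n")
  invisible(x)
}

# region TM of one model against both references of a pair
pair_region_tms <- function(pair, model) {
  c(A = tm_score(model, pair$ref_A, region = pair$fs_region_A)$tm,
    B = tm_score(model, pair$ref_B, region = pair$fs_region_B)$tm)
}

#' Order the two experimental folds from a baseline prediction run
#'
#' The reference with the higher fold-switching-region TM-score in a majority
#' of the baseline models (at least 3 of 5 for the standard five-model run)
#' becomes Fold1; the other becomes Fold2. An exact tie in per-model winners
#' falls back to the larger mean region TM-score over the baseline models
#' (flagged in the result).
#'
#' @param pair A `fold_switch_pair`.
#' @param baseline_models List of `fs_structure` predictions (>= 1).
#' @return List with `fold1` (`"A"` or `"B"`), `wins_A`, `wins_B`,
#'   `mean_tm_A`, `mean_tm_B`, `tie_break` (logical).
#' @export
assign_fold_order <- function(pair, baseline_models) {
  if (length(baseline_models) == 0)
    stop("no baseline models; set the pair's fold_order explicitly")
  tms <- t(vapply(baseline_models, function(m) pair_region_tms(pair, m),
                  numeric(2)))
  wins_A <- sum(tms[, "A"] > tms[, "B"])
  wins_B <- sum(tms[, "B"] > tms[, "A"])
  tie <- wins_A == wins_B
  fold1 <- if (!tie) {
    if (wins_A > wins_B) "A" else "B"
  } else {
    if (mean(tms[, "A"]) >= mean(tms[, "B"])) "A" else "B"
  }
  list(fold1 = fold1, wins_A = wins_A, wins_B = wins_B,
       mean_tm_A = mean(tms[, "A"]), mean_tm_B = mean(tms[, "B"]),
       tie_break = tie)
}

#' Classify one prediction from its two region TM-scores
#'
#' A model is assigned to Fold1 when its fold-switching-region TM-score to
#' the Fold1 reference exceeds the threshold and the Fold2 score does not
#' (and vice versa). When both exceed the threshold, the larger score wins.
#' Scores at or below the threshold on both sides give `"OTHER"`
#' (experimentally unobserved); equality with the threshold counts as not
#' exceeding it.
#'
#' @param tm1,tm2 Region TM-scores against Fold1 and Fold2, in `[0, 1]`.
#' @param tau Threshold, default 0.6.
#' @return `"FOLD1"`, `"FOLD2"` or `"OTHER"`.
#' @export
classify_model <- function(tm1, tm2, tau = 0.6) {
  stopifnot(tm1 >= 0, tm1 <= 1, tm2 >= 0, tm2 <= 1)
  if (tm1 > tau && tm2 > tau) {
    if (tm1 >= tm2) "FOLD1" else "FOLD2"
  } else if (tm1 > tau) "FOLD1"
  else if (tm2 > tau) "FOLD2"
  else "OTHER"
}

#' Per-conformation and overall prediction success
#'
#' A conformation counts as predicted when at least one model in the
#' ensemble is assigned to it (\eqn{N_{ij} \ge 1}); the pair is an overall
#' success when both conformations are predicted.
#'
#' @param labels Character vector of `"FOLD1"`/`"FOLD2"`/`"OTHER"` labels.
#' @return List with logical `fold1`, `fold2`, `overall`.
#' @export
pair_success <- function(labels) {
  stopifnot(length(labels) > 0)
  s1 <- sum(labels == "FOLD1") >= 1
  s2 <- sum(labels == "FOLD2") >= 1
  list(fold1 = s1, fold2 = s2, overall = s1 && s2)
}

#' Success rate over a set of fold-switch pairs
#'
#' Fraction of pairs for which both experimental conformations were
#' predicted at least once.
#'
#' @param overall_success Logical vector, one entry per pair.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(overall_success) {
  stopifnot(length(overall_success) > 0)
  mean(as.logical(overall_success))
}

#' Label a pair Easy or Complex
#'
#' A pair is Complex when it is an amyloid or domain-swapped case, or when
#' the whole-structure backbone RMSD between the two experimental folds
#' exceeds `wrmsd_cut` (10 Angstrom), or when the fold-switching-region
#' TM-score between them falls below `fstm_cut` (0.5); otherwise Easy.
#' Either geometric criterion suffices by default (`conjunction = "or"`).
#'
#' @param wrmsd Whole-structure backbone RMSD between the two folds, Angstrom.
#' @param fstm Region TM-score between the two experimental folds.
#' @param is_amyloid_or_swap Logical.
#' @param wrmsd_cut,fstm_cut Thresholds.
#' @param conjunction `"or"` (default) or `"and"` for the geometric criteria.
#' @return `"EASY"` or `"COMPLEX"`.
#' @export
label_difficulty <- function(wrmsd, fstm, is_amyloid_or_swap = FALSE,
                             wrmsd_cut = 10, fstm_cut = 0.5,
                             conjunction = c("or", "and")) {
  conjunction <- match.arg(conjunction)
  stopifnot(wrmsd >= 0, fstm >= 0, fstm <= 1)
  geo <- if (conjunction == "or") (wrmsd > wrmsd_cut) || (fstm < fstm_cut)
         else (wrmsd > wrmsd_cut) && (fstm < fstm_cut)
  if (isTRUE(is_amyloid_or_swap) || geo) "COMPLEX" else "EASY"
}

#' False-positive rate among confident predictions
#'
#' Fraction of confident models (mean plDDT at or above `plddt_cut`) that
#' match neither experimental fold (label `"OTHER"`). Returns `NA` when no
#' model is confident.
#'
#' @param labels Model labels.
#' @param mean_plddt Mean plDDT per model.
#' @param plddt_cut Confidence cutoff, default 70.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
false_positive_rate <- function(labels, mean_plddt, plddt_cut = 70) {
  stopifnot(length(labels) == length(mean_plddt))
  conf <- mean_plddt >= plddt_cut
  if (!any(conf)) return(NA_real_)
  sum(conf & labels == "OTHER") / sum(conf)
}

#' Match PDB chains against a training-set roster file
#'
#' The roster is a plain-text file of whitespace-separated `pdbid_chain`
#' tokens (in the style of OpenFold's `duplicate_pdb_chains.txt`). Matching
#' is case-insensitive on the four-character PDB id and case-sensitive on
#' the chain.
#'
#' @param pdb_chain_ids Character vector like `"2oug_C"`.
#' @param roster_path Path to the roster file.
#' @return Logical vector, one flag per query.
#' @export
match_training_roster <- function(pdb_chain_ids, roster_path) {
  if (!file.exists(roster_path)) stop("roster file not found: ", roster_path)
  toks <- scan(roster_path, what = character(), quiet = TRUE)
  split_tok <- function(x) {
    p <- regmatches(x, regexec("^([0-9A-Za-z]{4})_(.+)$", x))[[1]]
    if (length(p) != 3) c(NA, NA) else c(tolower(p[2]), p[3])
  }
  ros <- vapply(toks, split_tok, character(2))
  ros_key <- paste(ros[1, ], ros[2, ], sep = "_")
  q <- vapply(pdb_chain_ids, split_tok, character(2))
  paste(q[1, ], q[2, ], sep = "_") %in% ros_key
}

#' Assess a prediction ensemble against both folds of a pair
#'
#' The central per-pair analysis: every model is compared to both reference
#' conformations over the fold-switching region (TM-score and backbone
#' RMSD), classified as FOLD1/FOLD2/OTHER, and summarized into success,
#' difficulty, and false-positive statistics.
#'
#' @param pair A `fold_switch_pair`.
#' @param models Named list of `fs_structure` predictions.
#' @param fold_order `"A"` or `"B"` naming which reference is Fold1; if
#'   `NULL`, `baseline_models` (defaulting to the first up-to-5 models) are
#'   used via [assign_fold_order()].
#' @param baseline_models Optional models for fold ordering.
#' @param tau Classification TM threshold, default 0.6.
#' @param plddt_region Optional author-numbered region for the mean-plDDT
#'   computation (by default all residues' CA values are averaged).
#' @return Object of class `dualfold_assessment`: `models` data frame
#'   (model_id, tm1, tm2, rmsd1, rmsd2, mean_plddt, confidence_fraction,
#'   category, label) and `summary` list (counts, success flags, difficulty,
#'   false-positive rate, fold order).
#' @export
assess_pair <- function(pair, models, fold_order = NULL,
                        baseline_models = NULL, tau = 0.6,
                        plddt_region = NULL) {
  stopifnot(inherits(pair, "fold_switch_pair"), length(models) >= 1)
  if (is.null(names(models)))
    names(models) <- sprintf("model_%03d", seq_along(models))
  if (is.null(fold_order)) {
    if (is.null(baseline_models))
      baseline_models <- models[seq_len(min(5, length(models)))]
    fold_order <- assign_fold_order(pair, baseline_models)$fold1
  }
  ref1 <- if (fold_order == "A") pair$ref_A else pair$ref_B
  ref2 <- if (fold_order == "A") pair$ref_B else pair$ref_A
  reg1 <- if (fold_order == "A") pair$fs_region_A else pair$fs_region_B
  reg2 <- if (fold_order == "A") pair$fs_region_B else pair$fs_region_A

  rows <- lapply(names(models), function(mid) {
    m <- models[[mid]]
    t1 <- tm_score(m, ref1, region = reg1)
    t2 <- tm_score(m, ref2, region = reg2)
    r1 <- suppressWarnings(rmsd_backbone(m, ref1, region = reg1))
    r2 <- suppressWarnings(rmsd_backbone(m, ref2, region = reg2))
    pl <- extract_plddt(m)
    plm <- if (is.null(plddt_region)) pl
           else pl[m$residues$resno %in% parse_region(plddt_region)]
    data.frame(model_id = mid, tm1 = t1$tm, tm2 = t2$tm,
               rmsd1 = r1, rmsd2 = r2,
               mean_plddt = mean(plm),
               confidence_fraction = confidence_fraction(pl),
               label = classify_model(t1$tm, t2$tm, tau = tau),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$category <- vapply(tab$confidence_fraction, confidence_category, "")

  wrmsd <- suppressWarnings(rmsd_backbone(pair$ref_A, pair$ref_B))
  fstm <- tm_score(pair$ref_A, pair$ref_B, region = pair$fs_region_B)$tm
  succ <- pair_success(tab$label)
  summary <- list(
    pair_id = pair$pair_id,
    fold_order = fold_order,
    n_models = nrow(tab),
    counts = c(FOLD1 = sum(tab$label == "FOLD1"),
               FOLD2 = sum(tab$label == "FOLD2"),
               OTHER = sum(tab$label == "OTHER")),
    success_fold1 = succ$fold1, success_fold2 = succ$fold2,
    success_overall = succ$overall,
    wrmsd = wrmsd, fstm = fstm,
    difficulty = label_difficulty(wrmsd, fstm, pair$is_amyloid_or_swap),
    false_positive_rate = false_positive_rate(tab$label, tab$mean_plddt),
    tau = tau)
  out <- list(pair = pair, models = tab, summary = summary)
  class(out) <- "dualfold_assessment"
  out
}

#' @export
print.dualfold_assessment <- function(x, ...) {
  s <- x$summary
  cat("dualfold_assessment:", s$pair_id, "(", s$n_models, "models )\n")
  cat(sprintf("  Fold1 = ref %s | difficulty %s (wRMSD %.1f A, fsTM %.3f)\n",
              s$fold_order, s$difficulty, s$wrmsd, s$fstm))
  cat(sprintf("  counts: FOLD1 %d, FOLD2 %d, OTHER %d\n",
              s$counts["FOLD1"], s$counts["FOLD2"], s$counts["OTHER"]))
  cat(sprintf("  success: Fold1 %s, Fold2 %s, overall %s\n",
              s$success_fold1, s$success_fold2, s$success_overall))
  if (!is.na(s$false_positive_rate))
    cat(sprintf("  false-positive rate (mean plDDT >= 70): %.3f\n",
                s$false_positive_rate))
  invisible(x)
}

#' @export
summary.dualfold_assessment <- function(object, ...) object$summary

#' Scatter of region TM-scores against both folds
#'
#' The classic dual-fold diagnostic: each model is a point at
#' (TM-score1, TM-score2), with the classification threshold drawn on both
#' axes.
#'
#' @param x A `dualfold_assessment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dualfold_assessment <- function(x, ...) {
  tab <- x$models
  cols <- c(FOLD1 = "#2166ac", FOLD2 = "#b2182b", OTHER = "grey50")
  graphics::plot(tab$tm1, tab$tm2, xlim = c(0, 1), ylim = c(0, 1),
                 col = cols[tab$label], pch = 19,
                 xlab = "region TM-score vs Fold1",
                 ylab = "region TM-score vs Fold2",
                 main = x$summary$pair_id, ...)
  graphics::abline(h = x$summary$tau, v = x$summary$tau, lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
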