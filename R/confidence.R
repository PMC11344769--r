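# plDDT-based confidence categories, reranking, Top1/Top10/All tabulation
# and the exact one-sided binomial test used for enrichment checks.

#' Percentage of confident residues
#'
#' Fraction (as a percent) of residues with plDDT at or above `cut`
#' (a residue scoring exactly 70 counts as confident).
#'
#' @param plddts Per-residue plDDT values (0-100).
#' @param cut Confidence cutoff, default 70.
#' @return Percent in `[0, 100]`.
#' @export
confidence_fraction <- function(plddts, cut = 70) {
  if (length(plddts) == 0) stop("empty plDDT vector")
  100 * sum(plddts >= cut) / length(plddts)
}

#' Confidence category of a model
#'
#' Categories follow the fraction of residues with plDDT >= 70:
#' Medium (>= 70%), Good (>= 80%), High (>= 90%); the highest threshold met
#' is reported, below 70% the model is unclassified. All boundaries are
#' inclusive.
#'
#' @param fraction Percent of confident residues, in `[0, 100]`.
#' @return `"HIGH"`, `"GOOD"`, `"MEDIUM"` or `"UNCLASSIFIED"`.
#' @export
confidence_category <- function(fraction) {
  stopifnot(fraction >= 0, fraction <= 100)
  if (fraction >= 90) "HIGH"
  else if (fraction >= 80) "GOOD"
  else if (fraction >= 70) "MEDIUM"
  else "UNCLASSIFIED"
}

#' Rerank models by percentage of confident residues
#'
#' Orders models by descending confidence fraction; ties are broken by
#' descending mean plDDT, then lexicographic model id, making Top1/Top10
#' pools fully deterministic.
#'
#' @param records Data frame with columns `model_id`, `confidence_fraction`,
#'   `mean_plddt`.
#' @return The data frame reordered, with a `rank` column added.
#' @export
rerank <- function(records) {
  stopifnot(nrow(records) > 0)
  ord <- order(-records$confidence_fraction, -records$mean_plddt,
               records$model_id, method = "radix")
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

rank_pool <- function(ranked, pool) {
  switch(pool,
         Top1 = ranked[seq_len(min(1, nrow(ranked))), , drop = FALSE],
         Top10 = ranked[seq_len(min(10, nrow(ranked))), , drop = FALSE],
         All = ranked)
}

#' Tabulate labels by rank pool and confidence category
#'
#' Counts \eqn{N_{ij}} of models per conformation label within each rank
#' pool (Top1, Top10, All) and confidence category (All, Medium, Good,
#' High; category pools are cumulative, e.g. "Medium" contains every model
#' with at least Medium confidence). A conformation is flagged predicted in
#' a cell when its count is >= 1.
#'
#' @param records Data frame with `model_id`, `confidence_fraction`,
#'   `mean_plddt` (ranked internally via [rerank()]).
#' @param assessments Data frame with `model_id` and `label`.
#' @return Object of class `fs_tabulation`: `counts` data frame (pool,
#'   category, label, n, predicted) and the ranked records.
#' @export
tabulate_categories <- function(records, assessments) {
  unmatched <- setdiff(records$model_id, assessments$model_id)
  if (length(unmatched) > 0)
    stop("assessments missing for model(s): ",
         paste(unmatched, collapse = ", "))
  ranked <- rerank(records)
  ranked$label <- assessments$label[match(ranked$model_id,
                                          assessments$model_id)]
  cat_floor <- c(All = 0, Medium = 70, Good = 80, High = 90)
  labels <- c("FOLD1", "FOLD2", "OTHER")
  rows <- list()
  for (pool in c("Top1", "Top10", "All")) {
    sub <- rank_pool(ranked, pool)
    for (cname in names(cat_floor)) {
      csub <- sub[sub$confidence_fraction >= cat_floor[[cname]], , drop = FALSE]
      for (lb in labels) {
        n <- sum(csub$label == lb)
        rows[[length(rows) + 1]] <- data.frame(
          pool = pool, category = cname, label = lb, n = n,
          predicted = n >= 1, stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(counts = do.call(rbind, rows), ranked = ranked)
  class(out) <- "fs_tabulation"
  out
}

#' @export
print.fs_tabulation <- function(x, ...) {
  wide <- stats::reshape(
    x$counts[x$counts$category == "All", c("pool", "label", "n")],
    idvar = "pool", timevar = "label", direction = "wide")
  names(wide) <- sub("^n\\.", "", names(wide))
  cat("fs_tabulation (category = All):\n")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Exact one-sided binomial test
#'
#' Exact tail sums of the binomial pmf: lower tail is
#' \eqn{P(X \le k)}, upper tail \eqn{P(X \ge k)} under
#' \eqn{X \sim \mathrm{Bin}(n, p_0)}.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Trials.
#' @param p0 Null success probability in `(0, 1)`.
#' @param tail `"lower"` or `"upper"`.
#' @return The exact p-value.
#' @export
binomial_onesided <- function(k, n, p0, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (!(n >= 0 && k >= 0 && k <= n)) stop("need 0 <= k <= n")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
  if (tail == "lower") stats::pbinom(k, n, p0)
  else stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
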