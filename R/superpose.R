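# Rigid-body superposition and similarity metrics.
#
# The assessed predictions share their sequence with the experimental
# references, so residue correspondences are built by identity (author
# numbering), and tm_score() optimizes the superposition only -- no
# sequence-independent structural alignment is attempted.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' \eqn{\sqrt{\sum_i \|P_i - (R Q_i + t)\|^2 / n}} over rigid motions of `Q`.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3), `Q` is moved onto `P`.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3), and the minimal `rmsd` in Angstrom.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have equal length")
  if (nrow(P) < 3) stop("need at least 3 points for superposition")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)            # sum over i of q_i p_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1                # degenerate (planar/collinear) input
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cp - as.vector(R %*% cq)
  Qf <- Qc %*% t(R)                 # centered fit
  rmsd <- sqrt(sum((Pc - Qf)^2) / nrow(P))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

apply_transform <- function(X, tr) {
  sweep(as.matrix(X) %*% t(tr$rotation), 2, tr$translation, "+")
}

#' TM-score distance scale d0
#'
#' The standard length-dependent normalization distance
#' \eqn{d_0(L) = 1.24 (L - 15)^{1/3} - 1.8}, floored at 0.5 Angstrom so that
#' short fold-switching regions remain scorable.
#'
#' @param L Normalization length (residues), `L >= 1`.
#' @return d0 in Angstrom, always `>= 0.5`.
#' @export
tm_d0 <- function(L) {
  stopifnot(L >= 1)
  ifelse(L > 15, pmax(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5), 0.5)
}

#' Residue correspondence between two same-sequence structures
#'
#' Pairs residues of `A` and `B` by author numbering (number + insertion
#' code). Pairs whose one-letter residue types disagree (neither being `X`)
#' are dropped with a warning. Both residues must have a CA atom.
#'
#' @param A,B `fs_structure` objects.
#' @return Data frame of class `fs_correspondence` with internal indices
#'   (`a_idx`, `b_idx`) and author numbers (`a_resno`, `b_resno`).
#' @export
correspondence <- function(A, B) {
  ra <- A$residues; rb <- B$residues
  ca_a <- unique(A$atoms$res_index[A$atoms$elety == "CA"])
  ca_b <- unique(B$atoms$res_index[B$atoms$elety == "CA"])
  ra <- ra[ra$res_index %in% ca_a, , drop = FALSE]
  rb <- rb[rb$res_index %in% ca_b, , drop = FALSE]
  m <- match(ra$author, rb$author)
  keep <- !is.na(m)
  out <- data.frame(a_idx = ra$res_index[keep], b_idx = rb$res_index[m[keep]],
                    a_resno = ra$resno[keep], b_resno = rb$resno[m[keep]],
                    stringsAsFactors = FALSE)
  aa_a <- ra$aa1[keep]; aa_b <- rb$aa1[m[keep]]
  bad <- aa_a != aa_b & aa_a != "X" & aa_b != "X"
  if (any(bad)) {
    warning(sum(bad), " residue pair(s) with mismatched residue type dropped",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no residue correspondence between structures")
  class(out) <- c("fs_correspondence", "data.frame")
  out
}

#' Restrict a correspondence to an author-numbered region
#'
#' @param corr An `fs_correspondence`.
#' @param region Region spec (see [parse_region()]).
#' @param side `"A"` or `"B"`: which side's author numbering the region is in.
#' @return The filtered correspondence, order preserved.
#' @export
region_restrict <- function(corr, region, side = c("B", "A")) {
  side <- match.arg(side)
  region <- parse_region(region)
  keep <- if (side == "A") corr$a_resno %in% region else corr$b_resno %in% region
  out <- corr[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("region has no aligned residues")
  out
}

ca_coords <- function(model, res_index) {
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  m <- match(res_index, ca$res_index)
  if (anyNA(m))
    stop("missing CA for residue(s): ",
         paste(model$residues$author[res_index[is.na(m)]], collapse = ", "))
  cbind(ca$x[m], ca$y[m], ca$z[m])
}

# deterministic superposition seeds: the full correspondence plus contiguous
# fragments of length ~n/2 and ~n/4 (min 4), tiled across the chain
tm_seeds <- function(n) {
  lens <- unique(pmin(n, pmax(4, c(n, floor(n / 2), floor(n / 4)))))
  seeds <- list()
  for (len in lens) {
    starts <- unique(c(seq(1, n - len + 1, by = max(1, floor(len / 2))),
                       n - len + 1))
    for (s in starts) seeds[[length(seeds) + 1]] <- s:(s + len - 1)
  }
  unique(seeds)
}

#' TM-score between two structures over a residue correspondence
#'
#' Computes the template-modeling score
#' \eqn{\mathrm{TM} = \max \frac{1}{L_{norm}} \sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' over superpositions of the mobile structure `A` onto the reference `B`.
#' Superpositions are seeded from the full correspondence and from contiguous
#' fragments (length n/2 and n/4, minimum 4); each seed is refined by
#' iteratively re-superposing on the residues whose deviation falls below an
#' inclusion cutoff that starts at d0 and grows by a factor 1.5 whenever fewer
#' than 4 residues qualify, until the included set reaches a fixed point
#' (50-iteration cap). Exact score ties keep the earliest seed.
#'
#' @param A Mobile structure (typically the prediction).
#' @param B Reference structure; `L_norm` defaults to the number of reference
#'   residues in the assessed region, i.e. the score is normalized by the
#'   reference.
#' @param region Optional author-numbered region (reference numbering) to
#'   restrict the assessment to, e.g. the fold-switching region.
#' @param corr Optional precomputed [correspondence()].
#' @param L_norm Optional explicit normalization length.
#' @return List of class `fs_metric`: `tm`, `rmsd` (Kabsch-minimal CA RMSD
#'   over the full correspondence), `n_aligned`, `L_norm`, `d0`, `transform`.
#' @export
tm_score <- function(A, B, region = NULL, corr = NULL, L_norm = NULL) {
  if (is.null(corr)) corr <- correspondence(A, B)
  if (!is.null(region)) corr <- region_restrict(corr, region, side = "B")
  n <- nrow(corr)
  if (n == 0) stop("empty correspondence")
  if (is.null(L_norm)) {
    L_norm <- if (is.null(region)) n_residues(B)
              else length(region_res_index(B, region))
  }
  P <- ca_coords(B, corr$b_idx)     # fixed reference
  Q <- ca_coords(A, corr$a_idx)     # mobile
  d0v <- tm_d0(L_norm)
  min_core <- min(4L, n)

  best <- list(tm = -Inf, transform = NULL)
  for (seed in tm_seeds(n)) {
    S <- seed
    tr <- NULL
    for (it in seq_len(50)) {
      tr <- kabsch(P[S, , drop = FALSE], Q[S, , drop = FALSE])
      di <- sqrt(rowSums((P - apply_transform(Q, tr))^2))
      cutoff <- d0v
      S2 <- which(di < cutoff)
      while (length(S2) < min_core) {
        cutoff <- cutoff * 1.5
        S2 <- which(di < cutoff)
      }
      if (length(S2) == length(S) && all(S2 == S)) break
      S <- S2
    }
    di <- sqrt(rowSums((P - apply_transform(Q, tr))^2))
    tm <- sum(1 / (1 + (di / d0v)^2)) / L_norm
    if (tm > best$tm + 1e-12) best <- list(tm = tm, transform = tr)
  }
  full <- kabsch(P, Q)
  out <- list(tm = best$tm, rmsd = full$rmsd, n_aligned = n, L_norm = L_norm,
              d0 = d0v, transform = best$transform,
              normalized_by = "reference")
  class(out) <- "fs_metric"
  out
}

#' @export
print.fs_metric <- function(x, ...) {
  cat(sprintf("TM-score %.4f (n_aligned %d, L_norm %d, d0 %.3f A); CA RMSD %.3f A\n",
              x$tm, x$n_aligned, x$L_norm, x$d0, x$rmsd))
  invisible(x)
}

#' Kabsch-minimal backbone RMSD over corresponding residues
#'
#' RMSD over all atoms of the requested backbone set across the
#' correspondence, after optimal rigid superposition. Residue pairs missing
#' any requested atom on either side are dropped with a warning.
#'
#' @param A,B `fs_structure` objects.
#' @param region Optional author-numbered region (reference `B` numbering).
#' @param corr Optional precomputed correspondence.
#' @param atom_set Backbone atoms to include (default N, CA, C, O).
#' @return RMSD in Angstrom.
#' @export
rmsd_backbone <- function(A, B, region = NULL, corr = NULL,
                          atom_set = c("N", "CA", "C", "O")) {
  if (is.null(corr)) corr <- correspondence(A, B)
  if (!is.null(region)) corr <- region_restrict(corr, region, side = "B")
  ga <- atom_lookup(A, atom_set); gb <- atom_lookup(B, atom_set)
  Pl <- list(); Ql <- list(); dropped <- 0
  for (k in seq_len(nrow(corr))) {
    xa <- ga[[as.character(corr$a_idx[k])]]
    xb <- gb[[as.character(corr$b_idx[k])]]
    if (is.null(xa) || is.null(xb)) { dropped <- dropped + 1; next }
    Ql[[length(Ql) + 1]] <- xa; Pl[[length(Pl) + 1]] <- xb
  }
  if (dropped > 0)
    warning(dropped, " residue pair(s) incomplete for atom set; dropped",
            call. = FALSE)
  P <- do.call(rbind, Pl); Q <- do.call(rbind, Ql)
  if (is.null(P) || nrow(P) < 3) stop("fewer than 3 atoms after filtering")
  kabsch(P, Q)$rmsd
}

# per-residue coordinate blocks for a fixed atom set; NULL when incomplete
atom_lookup <- function(model, atom_set) {
  at <- model$atoms[model$atoms$elety %in% atom_set, , drop = FALSE]
  at <- at[order(at$res_index, match(at$elety, atom_set)), , drop = FALSE]
  xyz <- cbind(at$x, at$y, at$z)
  blocks <- split(seq_len(nrow(at)), at$res_index)
  out <- list()
  for (ri in names(blocks)) {
    rows <- blocks[[ri]]
    if (length(rows) == length(atom_set))
      out[[ri]] <- xyz[rows, , drop = FALSE]
  }
  out
}
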