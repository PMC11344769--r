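# AF2Rank-style template preparation: strip predictions/references to a
# sequence-agnostic backbone template and combine confidence scores into a
# composite used to rank the two folds of a pair.

TEMPLATE_ATOMS <- c("N", "CA", "C", "O", "CB")

# ideal CB direction from the backbone local frame; the direction is built
# from the N-CA and C-CA vectors and normalized to the canonical 1.522 A
# CA-CB bond length, so the construction is exactly rigid-motion covariant
ideal_cb <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  dir <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  ca + 1.522 * dir / sqrt(sum(dir^2))
}

#' Strip a structure to an AF2Rank-style template
#'
#' Removes every atom beyond the backbone-plus-CB set \{N, CA, C, O, CB\},
#' constructs an ideal beta carbon for glycines (masking their identity) and
#' for any other residue lacking one, and standardizes selenium residues:
#' MSE becomes MET (SE renamed SD) and SEC becomes CYS (SE renamed SG).
#' Residues missing any of N/CA/C are dropped with a warning.
#'
#' @param structure An `fs_structure`.
#' @param add_missing_cb Construct CB wherever absent (default `TRUE`; the
#'   glycine construction is always applied).
#' @return An `fs_structure` restricted to template atoms, with a
#'   `template_provenance` field describing the edits.
#' @export
strip_to_template <- function(structure, add_missing_cb = TRUE) {
  at <- structure$atoms
  # standardize selenium residues first
  mse <- at$resid == "MSE"; sec <- at$resid == "SEC"
  at$elety[mse & at$elety == "SE"] <- "SD"
  at$elety[sec & at$elety == "SE"] <- "SG"
  at$elesy[(mse | sec) & at$elesy == "SE"] <- "S"
  at$resid[mse] <- "MET"
  at$resid[sec] <- "CYS"
  at <- at[at$elety %in% TEMPLATE_ATOMS, , drop = FALSE]

  keep_rows <- list(); notes <- character()
  for (ri in structure$residues$res_index) {
    sub <- at[at$res_index == ri, , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% sub$elety)) {
      warning("residue ", structure$residues$author[
        structure$residues$res_index == ri],
        " missing backbone N/CA/C; dropped", call. = FALSE)
      next
    }
    if (!"CB" %in% sub$elety && add_missing_cb) {
      g <- function(a) unlist(sub[sub$elety == a, c("x", "y", "z")])
      cb <- ideal_cb(g("N"), g("CA"), g("C"))
      row <- sub[sub$elety == "CA", , drop = FALSE]
      row$elety <- "CB"; row$elesy <- "C"
      row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
      sub <- rbind(sub, row)
      notes <- c(notes, "CB-added")
    }
    sub <- sub[order(match(sub$elety, TEMPLATE_ATOMS)), , drop = FALSE]
    keep_rows[[length(keep_rows) + 1]] <- sub
  }
  if (length(keep_rows) == 0) stop("no residue with complete backbone")
  atoms <- do.call(rbind, keep_rows)
  kept_idx <- unique(atoms$res_index)
  residues <- structure$residues[
    structure$residues$res_index %in% kept_idx, , drop = FALSE]
  residues$resid[residues$resid == "MSE"] <- "MET"
  residues$resid[residues$resid == "SEC"] <- "CYS"
  residues$aa1 <- aa_one(residues$resid)
  # reindex contiguously
  remap <- stats::setNames(seq_along(kept_idx), kept_idx)
  atoms$res_index <- remap[as.character(atoms$res_index)]
  residues$res_index <- remap[as.character(residues$res_index)]
  out <- structure
  out$atoms <- atoms
  out$residues <- residues
  out$sequence <- paste(residues$aa1, collapse = "")
  out$template_provenance <- paste(
    c("stripped", unique(notes), "standardized"), collapse = ",")
  out
}

#' AF2Rank composite score
#'
#' Combines plDDT (0-100), pTM (0-1) and the TM-score between the output
#' model and its template into a single quality score, by default their
#' product with plDDT rescaled to 0-1:
#' \eqn{(plDDT/100)^a \cdot pTM^b \cdot TM^c} with `a = b = c = 1`. The more
#' confident the model and the closer to the experimental structure, the
#' higher the score.
#'
#' @param plddt Mean plDDT in `[0, 100]`.
#' @param ptm Predicted TM-score in `[0, 1]`.
#' @param tm_out_template TM-score between output model and template.
#' @param weights Exponents `c(a, b, c)`, default `c(1, 1, 1)`.
#' @return List of class `fs_composite`: the three inputs, `composite`, and
#'   the formula used.
#' @export
composite_score <- function(plddt, ptm, tm_out_template,
                            weights = c(1, 1, 1)) {
  if (plddt < 0 || plddt > 100) stop("plddt must be in [0, 100]")
  if (ptm < 0 || ptm > 1) stop("ptm must be in [0, 1]")
  if (tm_out_template < 0 || tm_out_template > 1)
    stop("tm_out_template must be in [0, 1]")
  comp <- (plddt / 100)^weights[1] * ptm^weights[2] *
    tm_out_template^weights[3]
  out <- list(plddt = plddt, ptm = ptm, tm_out_template = tm_out_template,
              composite = comp,
              formula = sprintf("(plddt/100)^%g * ptm^%g * tm^%g",
                                weights[1], weights[2], weights[3]))
  class(out) <- "fs_composite"
  out
}

#' Rank the two folds of a pair by composite score
#'
#' @param score_ground,score_excited `fs_composite` scores from the runs
#'   templated on the ground- and excited-state conformations.
#' @return List with `preferred` (`"ground"`, `"excited"` or `"undecided"`
#'   on an exact tie) and the signed `margin`
#'   (ground composite minus excited composite).
#' @export
rank_fold_pair <- function(score_ground, score_excited) {
  g <- score_ground$composite; e <- score_excited$composite
  margin <- g - e
  preferred <- if (margin > 0) "ground" else if (margin < 0) "excited"
               else "undecided"
  list(preferred = preferred, margin = margin)
}
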