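# MSA parsing (aligned FASTA and A3M) and SPEACH-style alanine masking:
# for a sliding window along the fold-switching region, every residue in
# spatial contact with the window -- but sequence-distant from it -- is
# mutated to alanine in all homolog rows, leaving the target row untouched.

read_fasta_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not FASTA/A3M: first line is not a header in ", path)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  data.frame(id = ids, aligned = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (all rows equal length) and A3M, where lowercase
#' letters are insertions relative to the target and do not occupy alignment
#' columns. The first record is the target. The returned `column_map` sends
#' each target sequence position to its alignment (match-state) column.
#'
#' @param path Alignment file.
#' @param format `"auto"` (A3M when the extension is `.a3m` or any row
#'   carries lowercase insertions), `"a3m"` or `"fasta"`.
#' @return Object of class `fs_msa`: `target_id`, `target_sequence`
#'   (ungapped), `rows` data frame (`id`, `aligned`), `column_map`,
#'   `format`.
#' @export
read_msa <- function(path, format = c("auto", "a3m", "fasta")) {
  format <- match.arg(format)
  rows <- read_fasta_records(path)
  if (format == "auto") {
    a3mish <- tolower(tools::file_ext(path)) == "a3m" ||
      any(grepl("[a-z]", rows$aligned))
    format <- if (a3mish) "a3m" else "fasta"
  }
  n_match <- vapply(rows$aligned, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch == "-" | (ch %in% LETTERS))
  }, integer(1))
  if (format == "fasta") {
    if (length(unique(nchar(rows$aligned))) != 1)
      stop("ragged alignment: rows of unequal length in ", path)
  } else {
    if (length(unique(n_match)) != 1)
      stop("inconsistent match-state column counts in A3M ", path)
  }
  tchars <- strsplit(rows$aligned[1], "")[[1]]
  is_match <- tchars == "-" | tchars %in% LETTERS
  match_col <- cumsum(is_match)
  target_sequence <- paste(tchars[tchars %in% LETTERS], collapse = "")
  column_map <- match_col[is_match & tchars %in% LETTERS]
  out <- list(target_id = rows$id[1], target_sequence = target_sequence,
              rows = rows, column_map = column_map, format = format)
  class(out) <- "fs_msa"
  out
}

#' @export
print.fs_msa <- function(x, ...) {
  cat("fs_msa:", x$target_id, "|", nrow(x$rows), "rows |",
      nchar(x$target_sequence), "target residues |", x$format, "\n")
  invisible(x)
}

#' Sliding windows along a region
#'
#' Contiguous windows of `w` residues moved by `step` from the beginning to
#' the end of the (author-numbered, contiguous) region.
#'
#' @param region Region spec covering at least `w` residues.
#' @param w Window width, default 11.
#' @param step Increment, default 1.
#' @return List of integer vectors (each one window's author numbers).
#' @export
sliding_windows <- function(region, w = 11, step = 1) {
  region <- parse_region(region)
  if (length(region) < w)
    stop("region (", length(region), " residues) shorter than window w = ",
         w, "; use a smaller w")
  starts <- seq(1, length(region) - w + 1, by = step)
  lapply(starts, function(s) region[s:(s + w - 1)])
}

#' Residues in spatial contact with a window
#'
#' A residue qualifies when any of its heavy atoms lies within `cutoff` of
#' any heavy atom of any window residue, and it is more than `seq_exclusion`
#' residues away in primary sequence from every window residue (so window
#' residues and their immediate neighbours are never returned).
#'
#' @param structure `fs_structure` covering the window.
#' @param window Author-numbered window (vector or region spec).
#' @param cutoff Distance cutoff, Angstrom (default 4.0).
#' @param seq_exclusion Primary-sequence exclusion (default 4: residues
#'   within 4 positions of the window are excluded, boundary included).
#' @return Sorted integer vector of contacting author residue numbers.
#' @export
contact_positions <- function(structure, window, cutoff = 4.0,
                              seq_exclusion = 4) {
  window <- parse_region(window)
  have <- unique(structure$atoms$resno)
  if (!all(window %in% have))
    stop("window residue(s) missing from structure: ",
         paste(setdiff(window, have), collapse = ", "))
  at <- structure$atoms
  wsel <- at$resno %in% window
  W <- cbind(at$x[wsel], at$y[wsel], at$z[wsel])
  cand <- setdiff(have, window)
  cand <- cand[vapply(cand, function(p) min(abs(p - window)) > seq_exclusion,
                      logical(1))]
  hits <- vapply(cand, function(p) {
    sel <- at$resno == p
    X <- cbind(at$x[sel], at$y[sel], at$z[sel])
    d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
    min(d2) <= cutoff^2 + 1e-12
  }, logical(1))
  sort(cand[hits])
}

#' Mask MSA columns to alanine
#'
#' For each target position in `positions`, the corresponding alignment
#' column has every non-gap character converted to `'A'` in every row
#' except the target. Gaps and A3M lowercase insertions are untouched;
#' non-standard letters (B, Z, X) are masked like any other residue.
#'
#' @param msa An `fs_msa`.
#' @param positions Target sequence positions (1-based) to mask.
#' @return Object of class `fs_masked_msa`: the masked `rows`, the parent's
#'   target/format fields, and `masked_positions`.
#' @export
mask_msa <- function(msa, positions) {
  positions <- sort(unique(as.integer(positions)))
  L <- nchar(msa$target_sequence)
  if (length(positions) > 0 && (min(positions) < 1 || max(positions) > L))
    stop("mask positions outside target length ", L)
  cols <- msa$column_map[positions]
  if (anyNA(cols)) {
    warning("skipping position(s) unmapped in the target row", call. = FALSE)
    cols <- cols[!is.na(cols)]
  }
  rows <- msa$rows
  if (nrow(rows) > 1 && length(cols) > 0) {
    for (r in 2:nrow(rows)) {
      ch <- strsplit(rows$aligned[r], "")[[1]]
      is_match <- ch == "-" | ch %in% LETTERS
      pos_in_row <- which(is_match)[cols]
      pos_in_row <- pos_in_row[!is.na(pos_in_row)]
      sub <- ch[pos_in_row]
      ch[pos_in_row] <- ifelse(sub %in% LETTERS, "A", sub)
      rows$aligned[r] <- paste(ch, collapse = "")
    }
  }
  out <- list(target_id = msa$target_id,
              target_sequence = msa$target_sequence,
              rows = rows, column_map = msa$column_map,
              format = msa$format, masked_positions = positions)
  class(out) <- c("fs_masked_msa", "fs_msa")
  out
}

#' Collapse byte-identical masked alignments
#'
#' Distinct sliding windows sometimes induce identical alanine masks; only
#' the earliest is kept. Idempotent and order-stable.
#'
#' @param masked List of `fs_masked_msa`.
#' @return The unique sublist, earliest-first.
#' @export
dedupe_masked <- function(masked) {
  if (length(masked) == 0) return(masked)
  keys <- vapply(masked, function(m)
    paste(m$rows$aligned, collapse = "\n"), "")
  masked[!duplicated(keys)]
}

#' Write an alignment in A3M/FASTA form
#'
#' Rows are emitted verbatim under their headers, so
#' `read_msa(write_a3m(m))` reproduces them exactly.
#'
#' @param msa An `fs_msa` or `fs_masked_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(msa, path) {
  writeLines(as.vector(rbind(paste0(">", msa$rows$id), msa$rows$aligned)),
             path)
  invisible(path)
}

#' Generate the full set of alanine-masked MSAs for a region
#'
#' Slides an 11-residue window along the fold-switching region; for each
#' window, residues in spatial contact with it (but beyond the
#' primary-sequence exclusion) are converted to alanine in all homolog rows,
#' and duplicate masks are collapsed. Structure author numbering is mapped
#' to target sequence positions via `numbering_offset`
#' (`target_pos = resno - numbering_offset`).
#'
#' @param msa An `fs_msa`.
#' @param structure Reference `fs_structure` defining the contacts
#'   (the Fold1 reference by default in pipeline use).
#' @param region Fold-switching region, author numbering of `structure`.
#' @param w,step Window parameters (defaults 11 and 1).
#' @param cutoff,seq_exclusion Contact parameters (defaults 4.0 Angstrom, 4).
#' @param numbering_offset Offset between structure numbering and target
#'   positions, default 0.
#' @return List of `fs_masked_msa`, one per unique mask, each carrying its
#'   `window` attribute.
#' @export
generate_masked_msas <- function(msa, structure, region, w = 11, step = 1,
                                 cutoff = 4.0, seq_exclusion = 4,
                                 numbering_offset = 0) {
  windows <- sliding_windows(region, w = w, step = step)
  masked <- lapply(windows, function(win) {
    contacts <- contact_positions(structure, win, cutoff = cutoff,
                                  seq_exclusion = seq_exclusion)
    pos <- contacts - numbering_offset
    pos <- pos[pos >= 1 & pos <= nchar(msa$target_sequence)]
    m <- mask_msa(msa, pos)
    m$window <- win
    m
  })
  dedupe_masked(masked)
}
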