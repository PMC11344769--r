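# Structural probes: normalized B-factor flexibility, contact maps and
# their comparison, coevolution-pair overlays, residue distances, and
# windowed mean plDDT.

#' Normalized B-factor flexibility profile
#'
#' Normalizes per-residue B-factors over a chain,
#' \eqn{BF_{norm} = (BF - \mu_{BF}) / \sigma_{BF}}, using the sample (n-1)
#' standard deviation. Residues with \eqn{BF_{norm} \ge 2} are flagged
#' flexible.
#'
#' @param model An `fs_structure`.
#' @param atom Atom whose B-factor represents the residue (default `"CA"`);
#'   `"all"` averages the B-factors of all of a residue's atoms.
#' @param flex_cut Flexibility threshold on the normalized value, default 2.
#' @return Object of class `fs_flexibility`: data frame `profile` (`resno`,
#'   `author`, `bf`, `bf_norm`, `flexible`) plus `mu_bf`, `sigma_bf`,
#'   `atom`, `sd_convention`.
#' @export
normalize_bfactors <- function(model, atom = "CA", flex_cut = 2.0) {
  if (atom == "all") {
    bf <- tapply(model$atoms$b, model$atoms$res_index, mean)
    bf <- as.numeric(bf[as.character(model$residues$res_index)])
  } else {
    sel <- model$atoms[model$atoms$elety == atom, , drop = FALSE]
    m <- match(model$residues$res_index, sel$res_index)
    if (anyNA(m))
      stop("residue(s) without ", atom, " atom: ",
           paste(model$residues$author[is.na(m)], collapse = ", "))
    bf <- sel$b[m]
  }
  if (length(bf) < 2) stop("need at least 2 residues to normalize")
  mu <- mean(bf); sg <- stats::sd(bf)
  if (sg == 0) stop("degenerate input: constant B-factors (sd = 0)")
  z <- (bf - mu) / sg
  out <- list(profile = data.frame(resno = model$residues$resno,
                                   author = model$residues$author,
                                   bf = bf, bf_norm = z,
                                   flexible = z >= flex_cut,
                                   stringsAsFactors = FALSE),
              mu_bf = mu, sigma_bf = sg, atom = atom,
              flex_cut = flex_cut, sd_convention = "sample (n-1)")
  class(out) <- "fs_flexibility"
  out
}

#' @export
print.fs_flexibility <- function(x, ...) {
  cat(sprintf("fs_flexibility: %d residues, mu = %.2f, sigma = %.2f (%s), %d flexible (BF_norm >= %.1f)\n",
              nrow(x$profile), x$mu_bf, x$sigma_bf, x$sd_convention,
              sum(x$profile$flexible), x$flex_cut))
  invisible(x)
}

#' Flexibility summary over a region
#'
#' Reports both readings of region flexibility: whether any residue in the
#' region is flexible (region-level) and the fraction of flexible residues
#' (residue-level).
#'
#' @param profile An `fs_flexibility`.
#' @param region Author-numbered region spec.
#' @return List with `max_bf_norm`, `any_flexible`, `fraction_flexible`,
#'   `n_region`.
#' @export
region_flexibility <- function(profile, region) {
  region <- parse_region(region)
  sub <- profile$profile[profile$profile$resno %in% region, , drop = FALSE]
  if (nrow(sub) == 0) stop("region has no residues in the profile")
  list(max_bf_norm = max(sub$bf_norm),
       any_flexible = any(sub$flexible),
       fraction_flexible = mean(sub$flexible),
       n_region = nrow(sub))
}

contact_atom_coords <- function(model, atom_mode) {
  if (atom_mode == "heavy") {
    at <- model$atoms
  } else if (atom_mode == "CB") {
    # CB, falling back to CA for glycine (or any CB-less residue)
    at <- model$atoms[model$atoms$elety %in% c("CA", "CB"), , drop = FALSE]
    has_cb <- unique(at$res_index[at$elety == "CB"])
    at <- at[at$elety == "CB" |
               (at$elety == "CA" & !(at$res_index %in% has_cb)), ,
             drop = FALSE]
  } else {
    at <- model$atoms[model$atoms$elety == atom_mode, , drop = FALSE]
  }
  at
}

#' Residue-residue contact map for one or two chains
#'
#' Intrachain contacts require a minimum sequence separation and are stored
#' with `i < j`; contacts between the two chains of a dimer are unrestricted
#' and tagged intermolecular.
#'
#' @param models A single `fs_structure` or a list of two (dimer).
#' @param cutoff Distance cutoff, Angstrom (default 8).
#' @param atom_mode `"CB"` (CA for glycine; default), `"CA"`, or `"heavy"`
#'   (minimum over all heavy-atom pairs).
#' @param min_seq_sep Minimum `|i - j|` for intrachain pairs (default 5).
#' @return Object of class `fs_contact_map`: data frame `contacts`
#'   (`i`, `j`, `chain_i`, `chain_j`, `kind`, `dist`) plus the parameter
#'   metadata.
#' @export
contact_map <- function(models, cutoff = 8, atom_mode = c("CB", "CA", "heavy"),
                        min_seq_sep = 5) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(cutoff > 0)
  if (inherits(models, "fs_structure")) models <- list(models)
  rows <- list()
  min_dist <- function(atA, atB, ri, rj) {
    X <- cbind(atA$x[atA$resno == ri], atA$y[atA$resno == ri],
               atA$z[atA$resno == ri])
    Y <- cbind(atB$x[atB$resno == rj], atB$y[atB$resno == rj],
               atB$z[atB$resno == rj])
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    sqrt(max(min(d2), 0))
  }
  for (ci in seq_along(models)) {
    at <- contact_atom_coords(models[[ci]], atom_mode)
    resnos <- sort(unique(at$resno))
    for (a in seq_along(resnos)) for (b in seq_len(length(resnos))) {
      if (b <= a) next
      ri <- resnos[a]; rj <- resnos[b]
      if (abs(ri - rj) < min_seq_sep) next
      d <- min_dist(at, at, ri, rj)
      if (d <= cutoff)
        rows[[length(rows) + 1]] <- data.frame(
          i = ri, j = rj, chain_i = models[[ci]]$chain_id,
          chain_j = models[[ci]]$chain_id, kind = "intramolecular",
          dist = d, stringsAsFactors = FALSE)
    }
  }
  if (length(models) == 2) {
    atA <- contact_atom_coords(models[[1]], atom_mode)
    atB <- contact_atom_coords(models[[2]], atom_mode)
    for (ri in sort(unique(atA$resno))) for (rj in sort(unique(atB$resno))) {
      d <- min_dist(atA, atB, ri, rj)
      if (d <= cutoff)
        rows[[length(rows) + 1]] <- data.frame(
          i = ri, j = rj, chain_i = models[[1]]$chain_id,
          chain_j = models[[2]]$chain_id, kind = "intermolecular",
          dist = d, stringsAsFactors = FALSE)
    }
  } else if (length(models) > 2) {
    stop("contact_map supports one chain or a two-chain dimer")
  }
  contacts <- if (length(rows)) do.call(rbind, rows)
              else data.frame(i = integer(), j = integer(),
                              chain_i = character(), chain_j = character(),
                              kind = character(), dist = numeric())
  out <- list(contacts = contacts, cutoff = cutoff, atom_mode = atom_mode,
              min_seq_sep = min_seq_sep)
  class(out) <- "fs_contact_map"
  out
}

#' @export
print.fs_contact_map <- function(x, ...) {
  cat(sprintf("fs_contact_map: %d contacts (%d intermolecular), cutoff %.1f A, %s atoms, min |i-j| %d\n",
              nrow(x$contacts), sum(x$contacts$kind == "intermolecular"),
              x$cutoff, x$atom_mode, x$min_seq_sep))
  invisible(x)
}

contact_keys <- function(cm) {
  with(cm$contacts, paste(chain_i, i, chain_j, j, kind, sep = "|"))
}

#' Compare two contact maps
#'
#' Exact set partition of the contact pairs into contacts unique to each map
#' and contacts common to both (the upper/lower-diagonal comparison used to
#' contrast a predicted structure with an experimental one).
#'
#' @param A,B `fs_contact_map` objects; a warning is raised when their
#'   cutoff/atom-mode metadata differ.
#' @return List with `unique_A`, `unique_B`, `common` (data frames) and
#'   `counts`.
#' @export
compare_contact_maps <- function(A, B) {
  if (A$cutoff != B$cutoff || A$atom_mode != B$atom_mode ||
      A$min_seq_sep != B$min_seq_sep)
    warning("comparing contact maps with different parameters", call. = FALSE)
  ka <- contact_keys(A); kb <- contact_keys(B)
  list(unique_A = A$contacts[!(ka %in% kb), , drop = FALSE],
       unique_B = B$contacts[!(kb %in% ka), , drop = FALSE],
       common = A$contacts[ka %in% kb, , drop = FALSE],
       counts = c(unique_A = sum(!(ka %in% kb)),
                  unique_B = sum(!(kb %in% ka)),
                  common = sum(ka %in% kb)))
}

#' Load coevolution residue pairs
#'
#' Reads a TSV of `(i, j, score)` rows (1-based author numbering) as
#' produced by coevolution-analysis tools; pairs are canonicalized to
#' `i < j` and duplicates collapsed keeping the maximum score.
#'
#' @param path TSV file (optionally with a header line).
#' @param seq_length Optional sequence length for validation.
#' @return Data frame with `i`, `j`, `score`.
#' @export
load_coevolution_pairs <- function(path, seq_length = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("[A-Za-z]", strsplit(lines[1], "\t|\\s+")[[1]][1]))
    lines <- lines[-1]
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "\t|\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 3 || anyNA(v[1:3]))
      stop("malformed coevolution row at line ", k, ": '", lines[k], "'")
    data.frame(i = as.integer(v[1]), j = as.integer(v[2]), score = v[3])
  })
  out <- do.call(rbind, rows)
  swap <- out$j < out$i
  tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
  if (!is.null(seq_length) && any(out$i < 1 | out$j > seq_length))
    stop("coevolution pair outside sequence length ", seq_length)
  key <- paste(out$i, out$j)
  out <- out[order(key, -out$score), , drop = FALSE]
  out <- out[!duplicated(paste(out$i, out$j)), , drop = FALSE]
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance between two residues' atoms
#'
#' @param model An `fs_structure`.
#' @param resA,resB Author residue numbers.
#' @param atom Atom name (default `"CA"`).
#' @return Euclidean distance in Angstrom.
#' @export
residue_distance <- function(model, resA, resB, atom = "CA") {
  grab <- function(r) {
    sel <- model$atoms$resno == r & model$atoms$elety == atom
    if (!any(sel))
      stop("atom ", atom, " of residue ", r, " not found in ", model$id)
    unlist(model$atoms[which(sel)[1], c("x", "y", "z")])
  }
  sqrt(sum((grab(resA) - grab(resB))^2))
}

#' Mean CA plDDT over an author-numbered region
#'
#' Restricting the average to a folded region (e.g. residues 25-76 of a
#' partly disordered chain) avoids the downward bias of disordered tails.
#'
#' @param model An `fs_structure` with plDDT in the B-factor column.
#' @param region Region spec.
#' @return Mean plDDT.
#' @export
mean_plddt_window <- function(model, region) {
  pl <- extract_plddt(model)
  sel <- model$residues$resno %in% parse_region(region)
  if (!any(sel)) stop("region matches no residues")
  mean(pl[sel])
}
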