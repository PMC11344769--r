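# Structure reading/writing and per-residue backbone + confidence access.
#
# Internal representation ("fs_structure"): a flat atom table plus a residue
# table. Internal residue indices are 1-based and contiguous in file order;
# author numbering (resno + insertion code) is kept alongside and is what every
# user-facing region specification refers to.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", MSE = "M", SEC = "U")

aa_one <- function(resid3) {
  out <- unname(AA3[resid3])
  out[is.na(out)] <- "X"
  out
}

#' Read a macromolecular structure chain
#'
#' Parses a PDB or mmCIF file into a per-residue structure object. Alternate
#' locations are resolved to the highest-occupancy conformer (ties go to the
#' alphabetically first altloc identifier). HETATM residues are dropped except
#' selenomethionine (MSE) and selenocysteine (SEC), which are retained as
#' ordinary residues so they can later be standardized during template
#' preparation.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param chain Author chain identifier. If `NULL` and the file holds a single
#'   chain, that chain is used; otherwise an error lists the available chains.
#' @param model_index 1-based model number for multi-model (e.g. NMR) files.
#' @param format `"auto"` (by file extension), `"pdb"` or `"cif"`.
#' @param id Identifier stored on the returned object; defaults to
#'   `basename(path)` plus the chain.
#' @return An object of class `fs_structure`: a list with `id`, `chain_id`,
#'   `source_format`, an `atoms` data frame (one row per atom after altloc
#'   resolution), a `residues` data frame (`res_index`, `resno`, `ins`,
#'   `author`, `resid`, `aa1`) and the derived one-letter `sequence`.
#' @export
read_structure <- function(path, chain = NULL, model_index = 1,
                           format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "cif") {
    at <- read_mmcif_atoms(path, model_index)
  } else {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = model_index > 1, rm.alt = FALSE,
                      verbose = FALSE),
      error = function(e) stop("could not parse pdb file '", path,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    at <- pdb$atom
    if (model_index > 1) {
      if (nrow(pdb$xyz) < model_index)
        stop("model_index ", model_index, " exceeds ", nrow(pdb$xyz),
             " models in ", path)
      xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    }
  }
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("multiple chains present; choose one of: ",
           paste(chains, collapse = ", "))
    chain <- chains[1]
  }
  if (!chain %in% chains)
    stop("chain not found: '", chain, "' (available: ",
         paste(chains, collapse = ", "), ")")
  at <- at[at$chain == chain, , drop = FALSE]
  keep <- at$type == "ATOM" | at$resid %in% c("MSE", "SEC")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' has no polymer atoms")

  at$ins <- ifelse(is.na(at$insert) | at$insert == " ", "", at$insert)
  at$alt <- ifelse(is.na(at$alt) | at$alt == " ", "", at$alt)
  at$o[is.na(at$o)] <- 1

  # altloc resolution: per residue+atom keep highest occupancy, ties by altloc id
  key <- paste(at$resno, at$ins, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$ins, at$elety, sep = "\r")), , drop = FALSE]

  rkey <- paste(at$resno, at$ins, sep = "\r")
  res_index <- match(rkey, unique(rkey))
  atoms <- data.frame(
    res_index = res_index,
    resno = at$resno, ins = at$ins, resid = at$resid,
    elety = at$elety,
    elesy = if (!is.null(at$elesy)) at$elesy else substr(at$elety, 1, 1),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b), o = at$o,
    stringsAsFactors = FALSE
  )
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(
    res_index = atoms$res_index[first],
    resno = atoms$resno[first], ins = atoms$ins[first],
    author = paste0(atoms$resno[first], atoms$ins[first]),
    resid = atoms$resid[first],
    aa1 = aa_one(atoms$resid[first]),
    stringsAsFactors = FALSE
  )
  out <- list(
    id = if (is.null(id)) paste0(basename(path), ":", chain) else id,
    chain_id = chain, source_format = toupper(format),
    atoms = atoms, residues = residues,
    sequence = paste(residues$aa1, collapse = "")
  )
  class(out) <- "fs_structure"
  out
}

#' @export
print.fs_structure <- function(x, ...) {
  cat("fs_structure:", x$id, "\n")
  cat("  chain", x$chain_id, "|", nrow(x$residues), "residues |",
      nrow(x$atoms), "atoms |", x$source_format, "\n")
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat("  sequence:", seq, "\n")
  invisible(x)
}

n_residues <- function(model) nrow(model$residues)

#' Per-residue plDDT confidence from the B-factor column
#'
#' Predicted structures from the AlphaFold family store the per-residue plDDT
#' confidence (0-100) in the B-factor column of the CA atom. Some mmCIF
#' exports use a 0-1 scale instead; when the chain maximum is <= 1 the values
#' are multiplied by 100 (overridable via `rescale`). Output is clipped to
#' [0, 100].
#'
#' @param model An `fs_structure`.
#' @param rescale `"auto"` (detect the 0-1 dialect), `"none"`, or `"force"`.
#' @return Numeric vector of per-residue plDDT values named by author
#'   residue numbering.
#' @export
extract_plddt <- function(model, rescale = c("auto", "none", "force")) {
  rescale <- match.arg(rescale)
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  miss <- setdiff(model$residues$res_index, ca$res_index)
  if (length(miss) > 0)
    stop("residue(s) without CA atom: ",
         paste(model$residues$author[model$residues$res_index %in% miss],
               collapse = ", "))
  v <- ca$b[match(model$residues$res_index, ca$res_index)]
  if ((rescale == "auto" && max(v) <= 1.0) || rescale == "force") v <- v * 100
  v <- pmin(pmax(v, 0), 100)
  names(v) <- model$residues$author
  v
}

#' Ordered backbone coordinates with a per-residue completeness mask
#'
#' Collects coordinates of the requested atom set residue by residue.
#' Residues missing any requested atom are flagged incomplete, excluded from
#' the coordinate list, and reported with a warning.
#'
#' @param model An `fs_structure`.
#' @param atom_set Character vector drawn from N, CA, C, O, CB.
#' @return List with `coords` (n x 3 matrix, atoms of complete residues in
#'   residue order then `atom_set` order), `mask` (logical per residue),
#'   `res_index` of the complete residues, and `atom_set`.
#' @export
backbone_coords <- function(model, atom_set = c("N", "CA", "C", "O")) {
  if (length(atom_set) == 0) stop("atom_set must be nonempty")
  at <- model$atoms[model$atoms$elety %in% atom_set, , drop = FALSE]
  counts <- table(factor(at$res_index, levels = model$residues$res_index))
  # count distinct atom names per residue (duplicates impossible post-altloc)
  mask <- as.vector(counts) == length(atom_set)
  if (any(!mask)) {
    for (a in model$residues$author[!mask])
      warning("residue ", a, " incomplete for atom set {",
              paste(atom_set, collapse = ","), "}; excluded", call. = FALSE)
  }
  keep_idx <- model$residues$res_index[mask]
  at <- at[at$res_index %in% keep_idx, , drop = FALSE]
  at <- at[order(at$res_index, match(at$elety, atom_set)), , drop = FALSE]
  list(coords = cbind(x = at$x, y = at$y, z = at$z), mask = mask,
       res_index = keep_idx, atom_set = atom_set)
}

#' Write a structure to PDB or mmCIF
#'
#' Round-trips through [read_structure()]: residue names, author numbering
#' (including insertion codes), coordinates (3 decimals) and B-factors
#' (2 decimals) are preserved.
#'
#' @param model An `fs_structure`.
#' @param path Output file path.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(cbind(a$x, a$y, a$z))),
                     type = ifelse(a$resid %in% c("MSE", "SEC"), "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = model$chain_id,
                     insert = ifelse(a$ins == "", NA, a$ins),
                     o = a$o, b = a$b, elesy = a$elesy)
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site reader: parses the loop_ block into the same
# column layout bio3d's PDB reader yields, so the downstream path is shared.
read_mmcif_atoms <- function(path, model_index = 1) {
  lines <- readLines(path)
  fields <- character(); data_rows <- character(); in_loop <- FALSE
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^loop_", ln)) {
      # peek: is this the atom_site loop?
      j <- i + 1
      fl <- character()
      while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
        fl <- c(fl, trimws(lines[j])); j <- j + 1
      }
      if (any(grepl("^_atom_site\\.", fl))) {
        fields <- sub("^_atom_site\\.", "", fl)
        while (j <= length(lines)) {
          dl <- trimws(lines[j])
          if (dl == "" || grepl("^(#|_|loop_|data_)", dl)) break
          data_rows <- c(data_rows, dl); j <- j + 1
        }
        in_loop <- TRUE
      }
      i <- j
    } else i <- i + 1
    if (in_loop) break
  }
  if (!in_loop || length(data_rows) == 0)
    stop("could not parse cif file '", path, "': no atom_site loop found",
         call. = FALSE)
  toks <- strsplit(data_rows, "\\s+")
  bad <- which(lengths(toks) != length(fields))
  if (length(bad) > 0)
    stop("could not parse cif file '", path, "': atom_site row ", bad[1],
         " has ", length(toks[[bad[1]]]), " tokens, expected ",
         length(fields), call. = FALSE)
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  blank <- function(v) ifelse(is.na(v) | v %in% c("?", "."), "", v)
  at <- data.frame(
    type = get("group_PDB"),
    elety = get("auth_atom_id", "label_atom_id"),
    alt = blank(get("label_alt_id")),
    resid = get("auth_comp_id", "label_comp_id"),
    chain = get("auth_asym_id", "label_asym_id"),
    resno = as.integer(get("auth_seq_id", "label_seq_id")),
    insert = blank(get("pdbx_PDB_ins_code")),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    o = suppressWarnings(as.numeric(get("occupancy"))),
    b = suppressWarnings(as.numeric(get("B_iso_or_equiv"))),
    elesy = get("type_symbol"),
    model_num = suppressWarnings(as.integer(get("pdbx_PDB_model_num"))),
    stringsAsFactors = FALSE)
  if (anyNA(at$x) || anyNA(at$resno))
    stop("could not parse cif file '", path,
         "': non-numeric coordinates or residue numbers", call. = FALSE)
  models <- unique(at$model_num)
  if (!all(is.na(models))) {
    if (model_index > length(models))
      stop("model_index ", model_index, " exceeds ", length(models),
           " models in ", path)
    at <- at[is.na(at$model_num) | at$model_num == models[model_index], ,
             drop = FALSE]
  }
  at
}

# Minimal mmCIF writer: one atom_site loop, enough for lossless round-trip
# of the fields fs_structure carries.
write_mmcif <- function(model, path) {
  a <- model$atoms
  grp <- ifelse(a$resid %in% c("MSE", "SEC"), "HETATM", "ATOM")
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", model$id)),
    "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_comp_id",
      "label_asym_id", "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
      "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv", "auth_asym_id",
      "pdbx_PDB_model_num")),
    sprintf("%-6s %-5d %-2s %-4s %-3s %-2s %-5d %-2s %8.3f %8.3f %8.3f %6.2f %6.2f %-2s 1",
            grp, seq_len(nrow(a)), a$elesy, a$elety, a$resid,
            model$chain_id, a$resno, ifelse(a$ins == "", "?", a$ins),
            a$x, a$y, a$z, a$o, a$b, model$chain_id),
    "#")
  writeLines(lines, path)
  invisible(path)
}

# Author-numbered region specifications -------------------------------------

#' Parse an author-numbered region specification
#'
#' Regions are written as inclusive ranges in author numbering, e.g.
#' `"11-66"` or `"5-20,30-41"`. Returns the sorted set of author residue
#' numbers (insertion-coded residues are matched through their base number).
#'
#' @param spec Region string, or a numeric vector passed through unchanged.
#' @return Integer vector of author residue numbers.
#' @export
parse_region <- function(spec) {
  if (is.numeric(spec)) return(sort(unique(as.integer(spec))))
  parts <- strsplit(gsub("\\s", "", spec), ",")[[1]]
  out <- unlist(lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (length(m) == 3) seq(as.integer(m[2]), as.integer(m[3]))
    else if (grepl("^-?[0-9]+$", p)) as.integer(p)
    else stop("bad region token: '", p, "'")
  }))
  sort(unique(out))
}

# residue indices (internal) of a model falling in an author-numbered region
region_res_index <- function(model, region) {
  region <- parse_region(region)
  model$residues$res_index[model$residues$resno %in% region]
}
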