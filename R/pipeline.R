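# Pipeline orchestration: simulate a complete fixture directory, run the
# end-to-end assessment over a pair registry, run the masking stage, and run
# the structural probes. Configuration is a flat key/value list (or a YAML
# file of one); every default equals the analysis' standard threshold and
# all effective values are echoed into the run manifest.

default_config <- function() {
  list(tau = 0.6, plddt_cut = 70, medium = 70, good = 80, high = 90,
       flex_cut = 2.0, wrmsd_cut = 10, fstm_cut = 0.5,
       mask_w = 11, mask_step = 1, mask_cutoff = 4.0, mask_seq_exclusion = 4,
       contact_cutoff = 8, contact_atom_mode = "CB", contact_min_seq_sep = 5,
       seed = 1)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  cfg
}

#' Write a complete synthetic fixture directory
#'
#' Generates toy fold-switch pairs with prediction ensembles and a toy MSA,
#' and writes them in the on-disk layout the assessment pipeline consumes:
#' a pair registry TSV, reference PDBs, per-pair model PDBs with plDDT in
#' the B-factor column, an A3M alignment per pair, and a ground-truth JSON.
#'
#' @param dir Output directory (created).
#' @param n_pairs Number of toy pairs.
#' @param n_models Models per pair.
#' @param weights Mixture weights (ref A, ref B, other).
#' @param polarity plDDT polarity, `"with"` or `"against"` correctness.
#' @param seed Master seed.
#' @param length,fs_region Toy-pair geometry (defaults 60 residues,
#'   region 20-45).
#' @return The registry path, invisibly.
#' @export
simulate_fixture <- function(dir, n_pairs = 1, n_models = 25,
                             weights = c(0.6, 0.1, 0.3),
                             polarity = "with", seed = 1,
                             length = 60, fs_region = "20-45") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- list()
  for (p in seq_len(n_pairs)) {
    pid <- sprintf("pair%02d", p)
    pair <- make_toy_pair(length = length, fs_region = fs_region,
                          seed = derive_seed(seed, p), pair_id = pid)
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    write_structure(pair$ref_A, file.path(pdir, "refA.pdb"))
    write_structure(pair$ref_B, file.path(pdir, "refB.pdb"))
    ens <- make_ensemble(pair, n_models = n_models, weights = weights,
                         polarity = polarity,
                         seed = derive_seed(seed, 1000 + p))
    mdir <- file.path(pdir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (mid in names(ens$models))
      write_structure(ens$models[[mid]], file.path(mdir, paste0(mid, ".pdb")))
    msa <- make_toy_msa(pair$ref_A$sequence, n_rows = 8,
                        seed = derive_seed(seed, 2000 + p),
                        target_id = pid)
    write_a3m(msa, file.path(pdir, "msa.a3m"))
    jsonlite::write_json(ens$truth, file.path(pdir, "truth.json"),
                         dataframe = "rows")
    reg[[p]] <- data.frame(
      pair_id = pid,
      pdbA = file.path(pid, "refA.pdb"), chainA = "A",
      pdbB = file.path(pid, "refB.pdb"), chainB = "A",
      fs_region_A = fs_region, fs_region_B = fs_region,
      is_amyloid_or_swap = FALSE, ground_state = "unknown",
      model_dir = file.path(pid, "models"),
      stringsAsFactors = FALSE)
  }
  registry <- do.call(rbind, reg)
  reg_path <- file.path(dir, "registry.tsv")
  utils::write.table(registry, reg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(reg_path)
}

read_registry <- function(path) {
  if (!file.exists(path)) stop("registry not found: ", path)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "pdbA", "chainA", "pdbB", "chainB",
            "fs_region_A", "fs_region_B")
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0)
    stop("registry missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(reg) == 0) stop("empty registry: ", path)
  reg
}

#' Run the end-to-end dual-fold assessment over a registry
#'
#' For every pair in the registry: read both references and the prediction
#' ensemble, compute region TM-scores/RMSDs against both folds, classify
#' each model, rerank by confidence, and tabulate Top1/Top10/All counts.
#' Failures are isolated per pair and recorded as skips (exit code 2 when
#' any pair was skipped, 0 otherwise).
#'
#' @param config List or YAML path. Recognized keys: `registry` (TSV path;
#'   relative `pdbA`/`pdbB`/`model_dir` entries resolve against its
#'   directory), `out_dir`, plus the threshold keys (`tau`, ...).
#' @return Invisibly, a report bundle: `per_model` data frame, `pairs`
#'   (per-pair summaries), `aggregate` list, `skips`, `exit_code`,
#'   `manifest`.
#' @export
run_assess <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$registry)) stop("config needs 'registry'")
  reg <- read_registry(cfg$registry)
  base <- dirname(cfg$registry)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))

  per_model <- list(); pairs <- list(); skips <- list(); tabs <- list()
  for (k in seq_len(nrow(reg))) {
    row <- reg[k, ]
    res <- tryCatch({
      ref_A <- read_structure(resolve(row$pdbA), chain = row$chainA)
      ref_B <- read_structure(resolve(row$pdbB), chain = row$chainB)
      pair <- fold_switch_pair(row$pair_id, ref_A, ref_B,
                               row$fs_region_A, row$fs_region_B,
                               is_amyloid_or_swap =
                                 isTRUE(row$is_amyloid_or_swap))
      mdir <- resolve(row$model_dir)
      files <- sort(list.files(mdir, pattern = "\\.(pdb|cif)$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no models found in ", mdir)
      models <- lapply(files, read_structure)
      names(models) <- sub("\\.(pdb|cif)$", "", basename(files))
      ass <- assess_pair(pair, models, tau = cfg$tau)
      tab <- tabulate_categories(
        ass$models[, c("model_id", "confidence_fraction", "mean_plddt")],
        ass$models[, c("model_id", "label")])
      list(ass = ass, tab = tab)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skips[[length(skips) + 1]] <- data.frame(
        pair_id = row$pair_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
      message("skipping pair ", row$pair_id, ": ", conditionMessage(res))
      next
    }
    pm <- res$ass$models
    pm$pair_id <- row$pair_id
    per_model[[length(per_model) + 1]] <- pm
    pairs[[row$pair_id]] <- res$ass$summary
    tabs[[row$pair_id]] <- res$tab
  }
  if (length(pairs) == 0) stop("all pairs failed; nothing to report")

  succ <- vapply(pairs, function(s) s$success_overall, logical(1))
  fpr <- vapply(pairs, function(s) s$false_positive_rate, numeric(1))
  aggregate <- list(
    n_pairs = length(pairs),
    n_skipped = length(skips),
    success_rate = success_rate(succ),
    success_fold1 = mean(vapply(pairs, function(s) s$success_fold1,
                                logical(1))),
    success_fold2 = mean(vapply(pairs, function(s) s$success_fold2,
                                logical(1))),
    difficulty = table(vapply(pairs, function(s) s$difficulty, "")),
    mean_false_positive_rate =
      if (all(is.na(fpr))) NA_real_ else mean(fpr, na.rm = TRUE))

  bundle <- list(per_model = do.call(rbind, per_model),
                 pairs = pairs, tabulations = tabs, aggregate = aggregate,
                 skips = if (length(skips)) do.call(rbind, skips) else NULL,
                 exit_code = if (length(skips)) 2L else 0L,
                 manifest = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(bundle$per_model,
                       file.path(cfg$out_dir, "per_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(aggregate = aggregate[names(aggregate) != "difficulty"],
           difficulty = as.list(aggregate$difficulty),
           pairs = pairs,
           skips = bundle$skips,
           manifest = cfg),
      file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE,
      force = TRUE, digits = NA)
  }
  invisible(bundle)
}

#' Run the alanine-masking stage
#'
#' Windows -> contacts -> mask -> dedupe -> write: emits one A3M per unique
#' mask plus a manifest TSV (window, masked positions, output file).
#'
#' @param config List or YAML path with keys `msa` (A3M/FASTA path),
#'   `structure` (PDB/mmCIF path), `chain`, `region`, `out_dir`, and
#'   optionally the masking parameter keys (`mask_w`, `mask_step`,
#'   `mask_cutoff`, `mask_seq_exclusion`).
#' @return Invisibly, the manifest data frame.
#' @export
run_mask <- function(config) {
  cfg <- load_config(config)
  for (key in c("msa", "structure", "region", "out_dir"))
    if (is.null(cfg[[key]])) stop("config needs '", key, "'")
  msa <- read_msa(cfg$msa)
  structure <- read_structure(cfg$structure, chain = cfg$chain)
  masked <- generate_masked_msas(
    msa, structure, cfg$region, w = cfg$mask_w, step = cfg$mask_step,
    cutoff = cfg$mask_cutoff, seq_exclusion = cfg$mask_seq_exclusion)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(masked), function(k) {
    m <- masked[[k]]
    fname <- sprintf("mask_%03d.a3m", k)
    write_a3m(m, file.path(cfg$out_dir, fname))
    data.frame(window = paste(range(m$window), collapse = "-"),
               n_masked = length(m$masked_positions),
               masked_positions = paste(m$masked_positions, collapse = ","),
               file = fname, stringsAsFactors = FALSE)
  }))
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Run the structural probes
#'
#' Computes flexibility profiles for every input structure, a contact-map
#' comparison when exactly two are given, optional residue-distance probes
#' and mean-plDDT windows; failures are isolated per item and recorded.
#'
#' @param config List or YAML path. Keys: `structures` (character vector of
#'   paths, or list of `path`/`chain` pairs), `out_dir`; optional
#'   `distance_probes` (list of `resA`/`resB`/`atom`), `plddt_region`,
#'   and the contact-map parameter keys.
#' @return Invisibly, a list with `flexibility`, `contact_comparison`,
#'   `distances`, `mean_plddt`, `errors`.
#' @export
run_probe <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$structures)) stop("config needs 'structures'")
  specs <- lapply(cfg$structures, function(s) {
    if (is.character(s)) list(path = s, chain = NULL) else s
  })
  errors <- list()
  note <- function(item, e) {
    errors[[length(errors) + 1]] <<- data.frame(
      item = item, reason = conditionMessage(e), stringsAsFactors = FALSE)
  }
  models <- list()
  for (s in specs) {
    m <- tryCatch(read_structure(s$path, chain = s$chain),
                  error = function(e) { note(s$path, e); NULL })
    if (!is.null(m)) models[[m$id]] <- m
  }
  flex <- lapply(models, function(m) {
    tryCatch(normalize_bfactors(m)$profile,
             error = function(e) { note(paste0("flexibility:", m$id), e); NULL })
  })
  cmp <- NULL
  if (length(models) == 2) {
    maps <- lapply(models, contact_map, cutoff = cfg$contact_cutoff,
                   atom_mode = cfg$contact_atom_mode,
                   min_seq_sep = cfg$contact_min_seq_sep)
    cmp <- compare_contact_maps(maps[[1]], maps[[2]])
  }
  dists <- NULL
  if (!is.null(cfg$distance_probes)) {
    dists <- do.call(rbind, lapply(cfg$distance_probes, function(p) {
      do.call(rbind, lapply(names(models), function(id) {
        d <- tryCatch(residue_distance(models[[id]], p$resA, p$resB,
                                       atom = if (is.null(p$atom)) "CA"
                                              else p$atom),
                      error = function(e) { note(paste0("distance:", id), e)
                                            NA_real_ })
        data.frame(structure = id, resA = p$resA, resB = p$resB,
                   dist = d, stringsAsFactors = FALSE)
      }))
    }))
  }
  plw <- NULL
  if (!is.null(cfg$plddt_region)) {
    plw <- vapply(models, function(m)
      tryCatch(mean_plddt_window(m, cfg$plddt_region),
               error = function(e) { note(paste0("plddt:", m$id), e)
                                     NA_real_ }),
      numeric(1))
  }
  out <- list(flexibility = flex, contact_comparison = cmp,
              distances = dists, mean_plddt = plw,
              errors = if (length(errors)) do.call(rbind, errors) else NULL)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out, file.path(cfg$out_dir, "probes.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  invisible(out)
}
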