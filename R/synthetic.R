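# Synthetic fixtures: ideal-geometry toy backbones, fold-switch pairs,
# prediction ensembles with planted label mixtures and confidence polarity,
# and toy MSAs. Everything is deterministic under an explicit seed; derived
# per-model seeds fan out from the master seed through a fixed counter
# scheme.

AA1TO3 <- stats::setNames(names(AA3)[1:20], unname(AA3)[1:20])

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# counter scheme for per-item seeds derived from a master seed
derive_seed <- function(seed, counter) {
  (as.numeric(seed) * 131071 + counter) %% 2147483629
}

# NeRF atom placement: position d with |c-d| = bond, angle(b,c,d) = ang,
# torsion(a,b,c,d) = tor (degrees)
nerf_place <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

# canonical backbone torsions per secondary-structure state
ss_torsions <- function(ss_char) {
  switch(ss_char,
         H = c(phi = -57, psi = -47),
         E = c(phi = -139, psi = 135),
         C = c(phi = stats::runif(1, -160, -50),
               psi = stats::runif(1, -60, 170)),
         stop("invalid secondary-structure character: '", ss_char,
              "' (use H, E or C)"))
}

#' Build an ideal-geometry backbone from a secondary-structure string
#'
#' Chains N, CA, C, O atoms with ideal bond lengths and angles and canonical
#' backbone dihedrals: helix (phi, psi) = (-57, -47), strand (-139, +135),
#' coil randomized within the broad allowed region (phi in [-160, -50],
#' psi in [-60, 170]) under the seed. Deterministic given `seed`.
#'
#' @param ss String of `H`/`E`/`C` characters, one per residue.
#' @param seed Integer seed (drives coil torsions and the default sequence).
#' @param sequence Optional one-letter amino-acid sequence (default: random).
#' @param id,chain Identifier and chain id for the returned structure.
#' @param bfactor Per-residue B-factor values (recycled; default 0).
#' @return An `fs_structure` with residues numbered from 1.
#' @export
make_ideal_backbone <- function(ss, seed = 1, sequence = NULL,
                                id = "toy", chain = "A", bfactor = 0) {
  ssc <- strsplit(ss, "")[[1]]
  n <- length(ssc)
  if (n == 0) stop("empty secondary-structure string")
  if (!all(ssc %in% c("H", "E", "C")))
    stop("invalid secondary-structure character: '",
         paste(setdiff(ssc, c("H", "E", "C")), collapse = ""), "'")
  with_seed(seed, {
    if (is.null(sequence))
      sequence <- paste(sample(names(AA1TO3), n, replace = TRUE),
                        collapse = "")
    tor <- t(vapply(ssc, ss_torsions, numeric(2)))

    xyz <- matrix(NA_real_, nrow = 4 * n, ncol = 3)  # N, CA, C, O per residue
    idx <- function(i, k) 4 * (i - 1) + k            # k: 1=N 2=CA 3=C 4=O
    # first residue laid in the xy-plane
    xyz[idx(1, 1), ] <- c(0, 0, 0)
    xyz[idx(1, 2), ] <- c(1.458, 0, 0)
    a <- 111.2 * pi / 180
    xyz[idx(1, 3), ] <- xyz[idx(1, 2), ] +
      1.525 * c(-cos(a), sin(a), 0)
    for (i in seq_len(n)) {
      if (i > 1) {
        xyz[idx(i, 1), ] <- nerf_place(xyz[idx(i - 1, 1), ],
                                       xyz[idx(i - 1, 2), ],
                                       xyz[idx(i - 1, 3), ],
                                       1.329, 116.2, tor[i - 1, "psi"])
        xyz[idx(i, 2), ] <- nerf_place(xyz[idx(i - 1, 2), ],
                                       xyz[idx(i - 1, 3), ],
                                       xyz[idx(i, 1), ],
                                       1.458, 121.7, 180)
        xyz[idx(i, 3), ] <- nerf_place(xyz[idx(i - 1, 3), ],
                                       xyz[idx(i, 1), ],
                                       xyz[idx(i, 2), ],
                                       1.525, 111.2, tor[i, "phi"])
      }
      xyz[idx(i, 4), ] <- nerf_place(xyz[idx(i, 1), ],
                                     xyz[idx(i, 2), ],
                                     xyz[idx(i, 3), ],
                                     1.231, 120.8, tor[i, "psi"] + 180)
    }
    seq1 <- strsplit(sequence, "")[[1]]
    if (length(seq1) != n) stop("sequence length must match ss length")
    resid3 <- unname(AA1TO3[seq1])
    if (anyNA(resid3)) stop("sequence contains non-standard letters")
    bf <- rep_len(bfactor, n)
    atoms <- data.frame(
      res_index = rep(seq_len(n), each = 4),
      resno = rep(seq_len(n), each = 4), ins = "",
      resid = rep(resid3, each = 4),
      elety = rep(c("N", "CA", "C", "O"), n),
      elesy = rep(c("N", "C", "C", "O"), n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      b = rep(bf, each = 4), o = 1, stringsAsFactors = FALSE)
    residues <- data.frame(res_index = seq_len(n), resno = seq_len(n),
                           ins = "", author = as.character(seq_len(n)),
                           resid = resid3, aa1 = seq1,
                           stringsAsFactors = FALSE)
    out <- list(id = id, chain_id = chain, source_format = "SYNTH",
                atoms = atoms, residues = residues, sequence = sequence,
                ss = ss)
    class(out) <- "fs_structure"
    out
  })
}

#' Generate a toy fold-switch pair
#'
#' Two ideal-geometry references share one sequence; their
#' secondary-structure strings are identical outside the fold-switching
#' region and differ throughout it (helix in fold A, strand in fold B by
#' default). Coil torsions are resampled (new seeds) until the region
#' TM-score between the two references falls below 0.5, so the pair is a
#' genuine fold switch by the assessment's own measure.
#'
#' @param length Chain length in residues (default 60).
#' @param fs_region Region spec, default `"20-45"`.
#' @param seed Integer seed.
#' @param region_ss Length-2 character: secondary structure of the region in
#'   fold A and fold B (default `c("H", "E")`).
#' @param max_attempts Resampling cap (default 20).
#' @param pair_id Identifier.
#' @return A `fold_switch_pair` whose two references are synthetic; the
#'   region spec is identical on both sides.
#' @export
make_toy_pair <- function(length = 60, fs_region = "20-45", seed = 1,
                          region_ss = c("H", "E"), max_attempts = 20,
                          pair_id = "toy_pair") {
  region <- parse_region(fs_region)
  if (min(region) < 1 || max(region) > length)
    stop("fs_region outside chain")
  flank <- rep("C", length)
  # flanks: alternating short helix/strand blocks shared by both folds
  blocks <- rep(c("H", "E"), length.out = ceiling(length / 6))
  for (k in seq_along(blocks)) {
    lo <- (k - 1) * 6 + 2; hi <- min(k * 6 - 1, length)
    if (lo <= hi) flank[lo:hi] <- blocks[k]
  }
  ss_A <- flank; ss_A[region] <- region_ss[1]
  ss_B <- flank; ss_B[region] <- region_ss[2]
  sequence <- with_seed(derive_seed(seed, 1),
                        paste(sample(names(AA1TO3), length, replace = TRUE),
                              collapse = ""))
  # crystal-like per-residue B-factors (mean ~30 A^2) so flexibility
  # normalization has realistic spread
  bfac <- with_seed(derive_seed(seed, 3),
                    pmax(stats::rnorm(length, 30, 10), 2))
  for (attempt in seq_len(max_attempts)) {
    sA <- derive_seed(seed, 100 + attempt)
    sB <- derive_seed(seed, 200 + attempt)
    ref_A <- make_ideal_backbone(paste(ss_A, collapse = ""), seed = sA,
                                 sequence = sequence, bfactor = bfac,
                                 id = paste0(pair_id, "_refA"))
    ref_B <- make_ideal_backbone(paste(ss_B, collapse = ""), seed = sB,
                                 sequence = sequence, bfactor = bfac,
                                 id = paste0(pair_id, "_refB"))
    fstm <- tm_score(ref_A, ref_B, region = region)$tm
    if (fstm < 0.5)
      return(fold_switch_pair(pair_id, ref_A, ref_B, region, region,
                              is_amyloid_or_swap = FALSE))
  }
  stop("could not build a pair with region TM < 0.5 in ", max_attempts,
       " attempts; try a larger region")
}

#' Perturb a structure to a target backbone RMSD
#'
#' Adds isotropic Gaussian displacements to every atom, rescaled so that the
#' Kabsch-minimal backbone RMSD to the input lies within 5% of
#' `target_rmsd`. Deterministic given `seed`; `target_rmsd = 0` returns the
#' model unchanged.
#'
#' @param model An `fs_structure`.
#' @param target_rmsd Target RMSD in Angstrom.
#' @param seed Integer seed.
#' @return The perturbed `fs_structure`.
#' @export
perturb <- function(model, target_rmsd, seed = 1) {
  stopifnot(target_rmsd >= 0)
  if (target_rmsd == 0) return(model)
  with_seed(seed, {
    X <- as.matrix(model$atoms[, c("x", "y", "z")])
    noise <- matrix(stats::rnorm(length(X)), ncol = 3)
    out <- model
    for (it in 1:8) {
      achieved <- kabsch(X, X + noise)$rmsd
      if (abs(achieved - target_rmsd) <= 0.05 * target_rmsd) break
      noise <- noise * (target_rmsd / achieved)
    }
    Y <- X + noise
    out$atoms$x <- Y[, 1]; out$atoms$y <- Y[, 2]; out$atoms$z <- Y[, 3]
    out
  })
}

#' Generate a synthetic prediction ensemble with planted labels
#'
#' Each model is drawn from a three-class mixture: perturbed copies of
#' reference A ("FOLD1"), perturbed copies of reference B ("FOLD2"), or an
#' independently generated decoy ("OTHER") built from a shuffled
#' secondary-structure string so decoys stay protein-like. Per-residue
#' plDDT profiles are drawn per class from Gaussians and planted in the
#' B-factor column; with polarity `"with"` the correct classes receive high
#' confidence, with `"against"` the decoys do (emulating confidence metrics
#' that select against experimentally observed conformations).
#'
#' @param pair A `fold_switch_pair` (typically from [make_toy_pair()]).
#' @param n_models Ensemble size.
#' @param weights Mixture weights for (ref A, ref B, other); must sum to 1.
#' @param noise Target backbone RMSD of the perturbed fold copies, Angstrom
#'   (default 0.5, a typical near-native model deviation).
#' @param plddt_high,plddt_low Mean/sd pairs for the confident and
#'   unconfident plDDT classes (defaults `c(85, 8)` and `c(55, 10)`).
#' @param polarity `"with"` (confidence tracks correctness) or `"against"`.
#' @param seed Integer master seed.
#' @return List with `models` (named list of `fs_structure`) and `truth`
#'   (data frame `model_id`, `class`), plus the spec echoed.
#' @export
make_ensemble <- function(pair, n_models = 500,
                          weights = c(0.6, 0.1, 0.3), noise = 0.5,
                          plddt_high = c(85, 8), plddt_low = c(55, 10),
                          polarity = c("with", "against"), seed = 1) {
  polarity <- match.arg(polarity)
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9, noise >= 0)
  classes <- with_seed(derive_seed(seed, 2),
                       sample(c("FOLD1", "FOLD2", "OTHER"), n_models,
                              replace = TRUE, prob = weights))
  nres <- n_residues(pair$ref_A)
  ss_base <- strsplit(pair$ref_A$ss, "")[[1]]
  models <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    si <- derive_seed(seed, 1000 + i)
    m <- switch(classes[i],
      FOLD1 = perturb(pair$ref_A, noise, seed = si),
      FOLD2 = perturb(pair$ref_B, noise, seed = si),
      OTHER = {
        ss_dec <- with_seed(si, paste(sample(ss_base), collapse = ""))
        decoy <- make_ideal_backbone(ss_dec, seed = derive_seed(si, 1),
                                     sequence = pair$ref_A$sequence,
                                     id = sprintf("decoy_%04d", i))
        perturb(decoy, noise, seed = derive_seed(si, 2))
      })
    confident <- if (polarity == "with") classes[i] != "OTHER"
                 else classes[i] == "OTHER"
    pars <- if (confident) plddt_high else plddt_low
    pl <- with_seed(derive_seed(si, 3),
                    pmin(pmax(stats::rnorm(nres, pars[1], pars[2]), 0), 100))
    m$atoms$b <- pl[m$atoms$res_index]
    m$id <- sprintf("model_%04d", i)
    models[[i]] <- m
  }
  names(models) <- sprintf("model_%04d", seq_len(n_models))
  list(models = models,
       truth = data.frame(model_id = names(models), class = classes,
                          stringsAsFactors = FALSE),
       spec = list(n_models = n_models, weights = weights, noise = noise,
                   plddt_high = plddt_high, plddt_low = plddt_low,
                   polarity = polarity, seed = seed))
}

#' Generate a toy MSA around a target sequence
#'
#' Homolog rows are copies of the target with i.i.d. substitutions at
#' `mutation_rate` and occasional gaps at `gap_rate`; the target row is
#' exact. Deterministic given `seed`.
#'
#' @param target Target sequence (1-letter).
#' @param n_rows Total rows including the target (>= 1).
#' @param mutation_rate Per-position substitution probability.
#' @param gap_rate Per-position gap probability in homolog rows.
#' @param seed Integer seed.
#' @param target_id Header of the target row.
#' @return An `fs_msa` (aligned-FASTA style, no insertions).
#' @export
make_toy_msa <- function(target, n_rows, mutation_rate = 0.1,
                         gap_rate = 0.02, seed = 1, target_id = "target") {
  stopifnot(n_rows >= 1, mutation_rate >= 0, mutation_rate <= 1)
  tch <- strsplit(target, "")[[1]]
  L <- length(tch)
  rows <- with_seed(seed, {
    lapply(seq_len(max(0, n_rows - 1)), function(r) {
      ch <- tch
      mut <- stats::runif(L) < mutation_rate
      ch[mut] <- vapply(which(mut), function(p) {
        sample(setdiff(names(AA1TO3), tch[p]), 1)
      }, "")
      gap <- stats::runif(L) < gap_rate
      ch[gap] <- "-"
      paste(ch, collapse = "")
    })
  })
  df <- data.frame(id = c(target_id,
                          sprintf("homolog_%03d", seq_len(n_rows - 1))[
                            seq_len(max(0, n_rows - 1))]),
                   aligned = c(target, unlist(rows)),
                   stringsAsFactors = FALSE)
  out <- list(target_id = target_id, target_sequence = target,
              rows = df, column_map = seq_len(L), format = "fasta")
  class(out) <- "fs_msa"
  out
}
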