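## Staged scoring: molecule filter -> decoration decomposition -> 2D scaffold
## dissimilarity + 3D shape/color similarity -> weighted harmonic mean.

#' Reward configuration
#'
#' Defaults follow the method's standard settings: fuzziness `alpha = 0.9`,
#' shape/color weights `w_s = 1.0`, `w_c = 1.2`, 2D/3D weights `w_2D = 1.5`,
#' `w_3D = 1.0`, partial reward 0.3 for designs containing a strict subset of
#' the decorations, and up to 32 conformers per enumerated stereoisomer.
#' Filter thresholds default to "reasonably above" the reference molecule's
#' own descriptors: its molecular weight + 100 g/mol, rotatable bonds + 3,
#' stereocenters + 2 (set when the reference pack is built; any explicit
#' value here overrides that).
#'
#' @param alpha Fuzziness for decoration matching, in (0, 1].
#' @param w_s,w_c Shape and pharmacophore-color weights of the conformer
#'   score.
#' @param w_2d,w_3d Weights of the final harmonic mean.
#' @param partial_reward Reward for designs matching a strict nonempty subset
#'   of decorations.
#' @param mw_max,rotatable_max,stereocenter_max Molecule-filter thresholds
#'   (`NA` = derive from the reference).
#' @param max_conformers_per_isomer Conformer ensemble cap per stereoisomer.
#' @param macrocycle_min_ring Ring size at and above which a molecule is
#'   treated as a macrocycle and excluded from 3D scoring.
#' @param align_starts Number of starting orientations for rigid alignment.
#' @param conformer_seed Seed for conformer torsion sampling.
#' @param score3d_fun Optional replacement for the 3D scoring stage, a
#'   `function(mol, ref, cfg)` returning a score in `[0, 1]`. Used to swap
#'   scorer backends or to run 2D-only campaigns.
#' @return Object of class `reward_config`.
#' @export
reward_config <- function(alpha = 0.9, w_s = 1.0, w_c = 1.2,
                          w_2d = 1.5, w_3d = 1.0, partial_reward = 0.3,
                          mw_max = NA_real_, rotatable_max = NA_integer_,
                          stereocenter_max = NA_integer_,
                          max_conformers_per_isomer = 32L,
                          macrocycle_min_ring = 10L,
                          align_starts = 10L,
                          conformer_seed = 42L,
                          score3d_fun = NULL) {
  stopifnot(alpha > 0, alpha <= 1, w_s > 0, w_c > 0, w_2d > 0, w_3d > 0,
            partial_reward > 0, max_conformers_per_isomer >= 1)
  structure(list(
    alpha = alpha, w_s = w_s, w_c = w_c, w_2d = w_2d, w_3d = w_3d,
    partial_reward = partial_reward, mw_max = mw_max,
    rotatable_max = rotatable_max, stereocenter_max = stereocenter_max,
    max_conformers_per_isomer = as.integer(max_conformers_per_isomer),
    macrocycle_min_ring = as.integer(macrocycle_min_ring),
    align_starts = as.integer(align_starts),
    conformer_seed = as.integer(conformer_seed),
    score3d_fun = score3d_fun
  ), class = "reward_config")
}

#' Bundle a reference molecule for scoring
#'
#' Precomputes everything scoring needs about the reference: its parsed
#' structure, the reference scaffold obtained by exact self-decomposition
#' (`alpha = 1`; the reference must decompose perfectly against its own
#' decorations), its scaffold fingerprint, and filter thresholds derived from
#' its descriptors. The bioactive conformer can be supplied as an SDF file
#' (one 3D record) or generated in place for synthetic tasks.
#'
#' @param smiles Reference molecule SMILES.
#' @param decorations List of `decoration` objects or fragment SMILES.
#' @param conformer Optional `conformer` object or path to an SDF file with
#'   the bioactive 3D pose. Without it only 2D scoring is possible.
#' @param cfg A [reward_config()]; thresholds left `NA` are filled in from
#'   the reference descriptors.
#' @return Object of class `reference_pack`.
#' @export
reference_pack <- function(smiles, decorations, conformer = NULL,
                           cfg = reward_config()) {
  mol <- as_molecule(smiles)
  decorations <- lapply(decorations, function(d) {
    if (inherits(d, "decoration")) d else decoration(d)
  })
  dec0 <- find_scaffold(mol, decorations, alpha = 1)
  if (dec0$success_score < 1 || is.null(dec0$scaffold)) {
    stop("the reference molecule does not decompose exactly against its own ",
         "decorations (success score ", format(dec0$success_score), ")",
         call. = FALSE)
  }
  props <- properties(mol)
  if (is.na(cfg$mw_max)) cfg$mw_max <- props$molecular_weight + 100
  if (is.na(cfg$rotatable_max)) cfg$rotatable_max <- props$rotatable_bonds + 3L
  if (is.na(cfg$stereocenter_max)) {
    cfg$stereocenter_max <- props$stereocenters + 2L
  }
  if (is.character(conformer)) conformer <- read_ref_conformer(conformer)
  structure(list(
    mol = mol, decorations = decorations, scaffold = dec0$scaffold,
    scaffold_fp = ecfp(dec0$scaffold), conformer = conformer,
    properties = props, cfg = cfg
  ), class = "reference_pack")
}

#' @export
print.reference_pack <- function(x, ...) {
  cat("<reference pack> ", x$mol$smiles, "\n", sep = "")
  cat("  scaffold: ", x$scaffold$smiles, "  (", length(x$decorations),
      " decorations)\n", sep = "")
  cat("  filter: MW <= ", round(x$cfg$mw_max, 1), ", rotatable <= ",
      x$cfg$rotatable_max, ", stereocenters <= ", x$cfg$stereocenter_max,
      "\n", sep = "")
  invisible(x)
}

#' Molecule filter
#'
#' Rejects designs whose molecular weight, rotatable-bond count or
#' stereocenter count exceeds the configured thresholds. Filtered designs
#' receive no reward.
#'
#' @param mol A `molecule` or SMILES.
#' @param cfg A [reward_config()] with thresholds set.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
molecule_filter <- function(mol, cfg) {
  p <- properties(as_molecule(mol))
  !(p$molecular_weight > cfg$mw_max ||
      p$rotatable_bonds > cfg$rotatable_max ||
      p$stereocenters > cfg$stereocenter_max)
}

#' 2D scaffold dissimilarity
#'
#' Jaccard distance between the 2048-bit radius-3 circular fingerprints of
#' two scaffolds (attachment dummies retained on both sides). The greater the
#' score, the less similar the scaffolds -- a high value is a genuine
#' scaffold hop.
#'
#' @param design_scaffold,ref_scaffold Scaffold `molecule`s as returned by
#'   [find_scaffold()].
#' @return Distance in `[0, 1]`.
#' @export
score_2d <- function(design_scaffold, ref_scaffold) {
  a <- as_molecule(design_scaffold)
  b <- as_molecule(ref_scaffold)
  if (nrow(a$atoms) == 0L || nrow(b$atoms) == 0L) {
    stop("empty scaffold", call. = FALSE)
  }
  jaccard_distance(ecfp(a), ecfp(b))
}

#' Final reward: weighted harmonic mean of the 2D and 3D scores
#'
#' `S_F = (w_2D + w_3D) / (w_2D / S_2D + w_3D / S_3D)`. The harmonic mean
#' ensures that optimizing one score cannot come at the expense of the other;
#' if either input is 0 the reward is 0 (the continuous limit).
#'
#' @param s2d,s3d Scores in `[0, 1]`.
#' @param cfg A [reward_config()] supplying `w_2d`, `w_3d`.
#' @return Final reward in `[0, 1]`.
#' @export
final_reward <- function(s2d, s3d, cfg = reward_config()) {
  stopifnot(s2d >= 0, s2d <= 1, s3d >= 0, s3d <= 1)
  if (s2d == 0 || s3d == 0) return(0)
  (cfg$w_2d + cfg$w_3d) / (cfg$w_2d / s2d + cfg$w_3d / s3d)
}

#' Score a design against a reference
#'
#' The staged pipeline: (1) molecule filter -- failures score 0; (2) scaffold
#' decomposition -- no decoration matched scores 0, a strict subset earns the
#' partial reward and skips 3D scoring entirely; (3) designs containing all
#' decorations are scored by the 2D scaffold distance, the 3D conformer
#' overlay (best conformer over all stereoisomers), and their weighted
#' harmonic mean.
#'
#' @param design A `molecule` or SMILES string.
#' @param reference A [reference_pack()].
#' @param cfg Optional [reward_config()]; defaults to the pack's.
#' @return Object of class `reward_breakdown`: `filtered`, `success_score`,
#'   `s2d`, `s3d` (both `NA` unless fully decomposed), `final`, and the
#'   design scaffold SMILES when available.
#' @export
score_design <- function(design, reference, cfg = NULL) {
  stopifnot(inherits(reference, "reference_pack"))
  if (is.null(cfg)) cfg <- reference$cfg
  mol <- if (inherits(design, "molecule")) design else parse_molecule(design)
  if (is.null(mol)) {
    return(breakdown(filtered = FALSE, success_score = 0, final = 0,
                     valid = FALSE))
  }
  if (!molecule_filter(mol, cfg)) {
    return(breakdown(filtered = TRUE, success_score = NA_real_, final = 0))
  }
  dec <- find_scaffold(mol, reference$decorations, alpha = cfg$alpha)
  if (dec$success_score == 0) {
    return(breakdown(filtered = FALSE, success_score = 0, final = 0))
  }
  if (dec$success_score < 1) {
    return(breakdown(filtered = FALSE, success_score = dec$success_score,
                     final = cfg$partial_reward))
  }
  s2d <- jaccard_distance(ecfp(dec$scaffold), reference$scaffold_fp)
  s3d <- if (!is.null(cfg$score3d_fun)) {
    cfg$score3d_fun(mol, reference$conformer, cfg)
  } else if (is.null(reference$conformer)) {
    stop("reference pack has no bioactive conformer and no score3d_fun ",
         "override is configured", call. = FALSE)
  } else {
    best_conformer_score(mol, reference$conformer, cfg)
  }
  breakdown(filtered = FALSE, success_score = 1, s2d = s2d, s3d = s3d,
            final = final_reward(s2d, s3d, cfg),
            scaffold_smiles = dec$scaffold$smiles)
}

breakdown <- function(filtered, success_score, s2d = NA_real_,
                      s3d = NA_real_, final, valid = TRUE,
                      scaffold_smiles = NA_character_) {
  structure(list(filtered = filtered, success_score = success_score,
                 s2d = s2d, s3d = s3d, final = final, valid = valid,
                 scaffold_smiles = scaffold_smiles),
            class = "reward_breakdown")
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat("<reward> final = ", format(x$final, digits = 4), sep = "")
  if (!x$valid) cat("  (invalid SMILES)")
  else if (x$filtered) cat("  (molecule filter)")
  else cat("  [S_s = ", format(x$success_score, digits = 3),
           if (!is.na(x$s2d)) paste0(", S_2D = ", format(x$s2d, digits = 3)),
           if (!is.na(x$s3d)) paste0(", S_3D = ", format(x$s3d, digits = 3)),
           "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Score a table of designs
#'
#' Vectorized [score_design()] with per-canonical-SMILES caching; returns one
#' row per design.
#'
#' @param smiles Character vector of design SMILES.
#' @param reference A [reference_pack()].
#' @param cfg Optional [reward_config()].
#' @param cache Optional environment used to memoize breakdowns across calls
#'   (scoring dominates the cost of a reinforcement-learning run).
#' @return `data.frame` with columns `smiles`, `canonical`, `valid`,
#'   `filtered`, `success_score`, `s2d`, `s3d`, `final`.
#' @export
score_designs <- function(smiles, reference, cfg = NULL, cache = NULL) {
  rows <- lapply(smiles, function(s) {
    can <- canonicalize(s)
    if (is.na(can)) {
      b <- breakdown(filtered = FALSE, success_score = 0, final = 0,
                     valid = FALSE)
    } else if (!is.null(cache) && !is.null(cache[[can]])) {
      b <- cache[[can]]
    } else {
      b <- score_design(can, reference, cfg)
      if (!is.null(cache)) cache[[can]] <- b
    }
    data.frame(smiles = s, canonical = if (is.na(can)) NA_character_ else can,
               valid = b$valid, filtered = b$filtered,
               success_score = b$success_score, s2d = b$s2d, s3d = b$s3d,
               final = b$final, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
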