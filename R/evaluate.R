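## Design-set analysis: Scaled Shannon Entropy scaffold diversity, scaffold
## retrieval curves, distance panels against the reference, and the
## post-processing quality-filter panel.

#' Scaled Shannon Entropy of scaffold classes
#'
#' `SSE = (-sum_i p_i log2 p_i) / log2 n` where `p_i` are the class
#' proportions over `n` designs. The denominator is the log of the number of
#' designs (not classes): this is the only normalization with the boundary
#' behavior SSE = 0 when all scaffolds are identical and SSE = 1 when all
#' are distinct.
#'
#' @param class_counts Integer vector (or table) of per-class counts.
#' @return SSE in `[0, 1]`.
#' @export
sse <- function(class_counts) {
  counts <- as.numeric(class_counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("SSE is undefined for fewer than two designs",
                  call. = FALSE)
  p <- counts / n
  h <- -sum(p * log2(p))
  h / log2(n) + 0  # normalize IEEE negative zero for the one-class case
}

#' Cyclic-substructure classes of a design set
#'
#' Maps each design to its Bemis-Murcko cyclic-substructure class (acyclic
#' designs share the reserved class).
#'
#' @param smiles Character vector of design SMILES.
#' @return Named table of class counts (invalid SMILES dropped).
#' @export
scaffold_classes <- function(smiles) {
  cls <- vapply(smiles, function(s) {
    m <- parse_molecule(s)
    if (is.null(m)) NA_character_ else bm_framework(m)$cyclic_class
  }, character(1))
  table(cls[!is.na(cls)])
}

#' Scaffold retrieval curve
#'
#' Ranks Bemis-Murcko frameworks by production frequency and accumulates:
#' after the i-th design (most-produced scaffolds first), the curve gives
#' the fraction of unique frameworks seen. A set dominated by one scaffold
#' is flat; a set of all-unique scaffolds follows the diagonal.
#'
#' @param smiles Character vector of design SMILES.
#' @return `data.frame` with `frac_designs` and `frac_scaffolds`, ending at
#'   (1, 1).
#' @export
retrieval_curve <- function(smiles) {
  fw <- vapply(smiles, function(s) {
    m <- parse_molecule(s)
    if (is.null(m)) NA_character_ else framework_key(m$smiles)
  }, character(1))
  fw <- fw[!is.na(fw)]
  if (length(fw) == 0L) stop("no valid designs", call. = FALSE)
  counts <- sort(table(fw), decreasing = TRUE)
  k <- length(counts)
  n <- length(fw)
  seen <- rep(seq_len(k), times = as.integer(counts))
  data.frame(frac_designs = seq_len(n) / n,
             frac_scaffolds = cummax(seen) / k)
}

## -- quality filters ----------------------------------------------------------

pains_catalog <- function() {
  path <- system.file("extdata", "pains_smarts.txt", package = "scaffhop")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "pains_smarts.txt")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  stats::setNames(vapply(parts, `[[`, character(1), 1),
                  vapply(parts, `[[`, character(1), 2))
}

matches_smarts <- function(mol, smarts) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(mol$smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(rep(FALSE, length(smarts)))
  vapply(smarts, function(q) {
    n <- tryCatch(suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, q, uniqueMatches = TRUE)),
      error = function(e) 0)
    as.numeric(n)[1] > 0
  }, logical(1))
}

#' Synthetic-accessibility heuristic
#'
#' A transparent complexity score on a 1-10 scale combining molecule size,
#' ring-system complexity (fused ring atoms), stereocenters, macrocycles and
#' formal charges. It is a package-native heuristic: higher means harder to
#' make; the quality filter's default threshold is 6.
#'
#' @param mol A `molecule` or SMILES.
#' @return Numeric score (>= 1).
#' @export
accessibility_score <- function(mol) {
  mol <- as_molecule(mol)
  n <- mol$n_heavy
  ring_atoms <- sum(mol$atoms$in_ring)
  b <- mol$bonds
  # atoms participating in >2 ring bonds sit at ring fusions
  ring_deg <- integer(nrow(mol$atoms))
  for (i in which(b$in_ring)) {
    ring_deg[b$a1[i]] <- ring_deg[b$a1[i]] + 1L
    ring_deg[b$a2[i]] <- ring_deg[b$a2[i]] + 1L
  }
  fused <- sum(ring_deg > 2L)
  stereo <- length(stereocenter_indices(mol))
  macro <- max_min_ring_size(mol) >= 10
  1 + 0.15 * max(0, n - 10) + 0.5 * fused + 0.6 * stereo +
    (if (macro) 2 else 0) + 0.3 * sum(mol$atoms$charge != 0)
}

ring_aromaticity_ok <- function(mol) {
  rings <- conformer_rings(list(elem = mol$atoms$elem, bonds = mol$bonds))
  for (ring in rings) {
    ar <- mol$atoms$arom[ring]
    if (any(ar) && !all(ar)) return(FALSE)
  }
  TRUE
}

#' Post-processing quality filter
#'
#' Applies the quality rule panel to a design set and reports per-rule
#' elimination counts: (1) exact decoration inclusion, checked by the
#' scaffold decomposition at `alpha = 1` -- designs generated under fuzzy
#' matching may carry decoration variants and fail here; (2) absence of
#' pan-assay interference (PAINS) substructures, against a compact catalog
#' of well-known patterns; (3) synthetic accessibility below a threshold
#' ([accessibility_score()]); (4) ring aromaticity (no partially aromatic
#' ring perception). Rules are independent predicates, so the retained set
#' does not depend on their order.
#'
#' @param smiles Character vector of design SMILES.
#' @param decorations List of `decoration`s (or fragment SMILES).
#' @param sa_threshold Accessibility threshold (default 6).
#' @return List with `passed` (character vector of surviving canonical
#'   SMILES) and `counts` (named eliminations per rule, plus `invalid` and
#'   `n_input`).
#' @export
quality_filter <- function(smiles, decorations, sa_threshold = 6) {
  decorations <- lapply(decorations, function(d) {
    if (inherits(d, "decoration")) d else decoration(d)
  })
  catalog <- pains_catalog()
  counts <- c(invalid = 0L, decoration_inclusion = 0L, pains = 0L,
              accessibility = 0L, ring_aromaticity = 0L)
  passed <- character(0)
  for (s in smiles) {
    mol <- parse_molecule(s)
    if (is.null(mol)) {
      counts["invalid"] <- counts["invalid"] + 1L
      next
    }
    ok <- TRUE
    if (find_scaffold(mol, decorations, alpha = 1)$success_score < 1) {
      counts["decoration_inclusion"] <- counts["decoration_inclusion"] + 1L
      ok <- FALSE
    }
    if (any(matches_smarts(mol, unname(catalog)))) {
      counts["pains"] <- counts["pains"] + 1L
      ok <- FALSE
    }
    if (accessibility_score(mol) > sa_threshold) {
      counts["accessibility"] <- counts["accessibility"] + 1L
      ok <- FALSE
    }
    if (!ring_aromaticity_ok(mol)) {
      counts["ring_aromaticity"] <- counts["ring_aromaticity"] + 1L
      ok <- FALSE
    }
    if (ok) passed <- c(passed, mol$smiles)
  }
  list(passed = passed, counts = c(counts, n_input = length(smiles)))
}

## -- distance panel -----------------------------------------------------------

#' Distance and diversity panel for a design set
#'
#' Computes, against the reference: the full-molecule Jaccard distance
#' (plain circular fingerprints, no dummies) and the scaffold Jaccard
#' distance (scaffolds via decomposition at `alpha`, dummies retained), each
#' as mean and standard deviation; plus validity/uniqueness counts and the
#' Scaled Shannon Entropy over cyclic-substructure classes.
#'
#' @param smiles Character vector of design SMILES.
#' @param reference A [reference_pack()].
#' @param alpha Fuzziness for the scaffold decomposition (default the
#'   pack's).
#' @return Object of class `diversity_report`.
#' @export
distance_panel <- function(smiles, reference, alpha = NULL) {
  stopifnot(inherits(reference, "reference_pack"))
  if (is.null(alpha)) alpha <- reference$cfg$alpha
  ref_fp <- ecfp(reference$mol)
  mol_d <- numeric(0)
  sca_d <- numeric(0)
  n_valid <- 0L
  no_scaffold <- 0L
  canon <- character(0)
  for (s in smiles) {
    mol <- parse_molecule(s)
    if (is.null(mol)) next
    n_valid <- n_valid + 1L
    canon <- c(canon, mol$smiles)
    mol_d <- c(mol_d, jaccard_distance(ecfp(mol), ref_fp))
    dec <- find_scaffold(mol, reference$decorations, alpha = alpha)
    if (!is.null(dec$scaffold)) {
      sca_d <- c(sca_d, jaccard_distance(ecfp(dec$scaffold),
                                         reference$scaffold_fp))
    } else {
      no_scaffold <- no_scaffold + 1L
    }
  }
  cls <- scaffold_classes(canon)
  structure(list(
    n_input = length(smiles), n_valid = n_valid,
    unique_fraction = if (n_valid > 0L) length(unique(canon)) / n_valid
                      else NA_real_,
    sse = if (n_valid >= 2L) sse(cls) else NA_real_,
    molecule_distance = c(mean = mean(mol_d), sd = stats::sd(mol_d)),
    scaffold_distance = c(mean = if (length(sca_d)) mean(sca_d) else
      NA_real_, sd = if (length(sca_d) > 1L) stats::sd(sca_d) else NA_real_),
    n_without_scaffold = no_scaffold,
    class_counts = cls
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity report>  ", x$n_valid, "/", x$n_input, " valid, ",
      "unique fraction ", round(x$unique_fraction, 3), "\n", sep = "")
  cat("  scaffold diversity (SSE): ", round(x$sse, 3), " over ",
      length(x$class_counts), " cyclic class(es)\n", sep = "")
  cat("  molecule distance: ", round(x$molecule_distance["mean"], 3),
      " +/- ", round(x$molecule_distance["sd"], 3), "\n", sep = "")
  cat("  scaffold distance: ", round(x$scaffold_distance["mean"], 3),
      " +/- ", round(x$scaffold_distance["sd"], 3),
      "  (", x$n_without_scaffold, " without decomposition)\n", sep = "")
  invisible(x)
}
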