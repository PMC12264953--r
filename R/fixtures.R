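## Synthetic toy chemistry for testing and desk-scale experiments:
## references with known decompositions, design sets with controlled
## decoration inclusion, toy corpora for language-model training, and
## conformer pairs for overlay tests. Everything is regenerated from
## (seed, parameters) alone; nothing is stored on disk.

# Ring cores with two substitution slots, written as SMILES templates where
# {X} and {Y} are replaced by substituent bodies in branch position.
.scaffold_templates <- c(
  benzene_para = "c1cc({X})ccc1{Y}",
  benzene_meta = "c1cc({X})cc({Y})c1",
  pyridine = "c1cc({X})cnc1{Y}",
  thiophene = "c1c({X})csc1{Y}",
  furan = "c1c({X})coc1{Y}",
  cyclohexane = "C1CC({X})CCC1{Y}",
  cyclopentane = "C1CC({X})CC1{Y}",
  pyrazole = "c1c({X})n({Y})nc1",
  pyrimidine = "c1nc({X})ncc1{Y}",
  methylbenzene = "c1c(C)c({X})ccc1{Y}"
)

# substituent bodies (a decoration fragment "*CC" has body "CC")
.substituent_bodies <- c("C", "CC", "CN", "CO", "OC", "CCC", "CCN", "CCO",
                         "C(C)C", "N", "O", "F")

fill_template <- function(template, x, y) {
  s <- sub("{X}", x, template, fixed = TRUE)
  sub("{Y}", y, s, fixed = TRUE)
}

dec_body <- function(dec) {
  # attachment-ready body: the fragment SMILES with its dummy removed; valid
  # for the simple chain decorations used in fixtures
  gsub("\\[\\*\\]|\\*", "", dec$fragment_smiles)
}

#' Build a deterministic fixture task
#'
#' A synthetic scaffold-hopping study: a reference molecule (ethyl +
#' aminomethyl decorations on a para-benzene scaffold), design sets with
#' controlled decoration inclusion (positives carry both decorations on
#' varied ring scaffolds, partials a strict subset, negatives none), and a
#' combinatorial toy SMILES corpus for language-model training. Every
#' positive design is verified at construction to decompose perfectly at
#' `alpha = 1`.
#'
#' @param seed RNG seed; the task is byte-identical per seed.
#' @param n_corpus Approximate corpus size (default 1000).
#' @param with_conformer Also generate a synthetic "bioactive" 3D pose of
#'   the reference (requires obabel; default `FALSE`).
#' @return Object of class `fixture_task`: `reference` (SMILES),
#'   `decorations`, `positive_designs`, `partial_designs`,
#'   `negative_designs`, `corpus`, and optionally `conformer`.
#' @export
make_task <- function(seed = 42L, n_corpus = 1000L, with_conformer = FALSE) {
  set.seed(seed)
  decorations <- list(decoration("*CC"), decoration("*CN"))
  reference <- canonicalize("CCc1ccc(CN)cc1")
  bodies <- vapply(decorations, dec_body, character(1))

  positives <- character(0)
  for (tmpl in .scaffold_templates) {
    for (ord in list(c(1, 2), c(2, 1))) {
      s <- fill_template(tmpl, bodies[ord[1]], bodies[ord[2]])
      can <- canonicalize(s)
      if (!is.na(can)) positives <- c(positives, can)
    }
  }
  positives <- unique(positives)
  keep <- vapply(positives, function(s) {
    find_scaffold(s, decorations, alpha = 1)$success_score == 1
  }, logical(1))
  positives <- positives[keep]
  if (length(positives) < 5L) {
    stop("fixture construction failed: too few verified positive designs")
  }

  others <- setdiff(.substituent_bodies, bodies)
  partials <- character(0)
  for (tmpl in .scaffold_templates[1:6]) {
    for (b in bodies) {
      for (o in others[1:4]) {
        can <- canonicalize(fill_template(tmpl, b, o))
        if (!is.na(can)) partials <- c(partials, can)
      }
    }
  }
  partials <- unique(setdiff(partials, positives))
  keep <- vapply(partials, function(s) {
    ss <- find_scaffold(s, decorations, alpha = 1)$success_score
    ss > 0 && ss < 1
  }, logical(1))
  partials <- partials[keep]

  negatives <- character(0)
  for (tmpl in .scaffold_templates[1:6]) {
    for (o1 in others[1:3]) {
      for (o2 in others[4:6]) {
        can <- canonicalize(fill_template(tmpl, o1, o2))
        if (!is.na(can)) negatives <- c(negatives, can)
      }
    }
  }
  chains <- c("CCO", "CCCO", "CCCC", "CCOC", "CC(C)O", "CCCN(C)C",
              "COCCOC", "CC(=O)OC", "CCS", "OCCO")
  negatives <- unique(c(negatives, vapply(chains, canonicalize,
                                          character(1))))
  keep <- vapply(negatives, function(s) {
    find_scaffold(s, decorations, alpha = 1)$success_score == 0
  }, logical(1))
  negatives <- negatives[keep]

  # combinatorial corpus: substituted ring cores + simple chains
  corpus <- character(0)
  for (tmpl in .scaffold_templates) {
    for (x in .substituent_bodies) {
      for (y in .substituent_bodies) {
        corpus <- c(corpus, fill_template(tmpl, x, y))
      }
    }
  }
  corpus <- unique(vapply(corpus, canonicalize, character(1)))
  corpus <- corpus[!is.na(corpus)]
  corpus <- c(corpus, negatives, positives, partials)
  corpus <- unique(corpus)
  if (length(corpus) > n_corpus) {
    corpus <- c(
      positives,  # keep the full-decoration family present
      base::sample(setdiff(corpus, positives),
                   n_corpus - length(positives))
    )
  }
  corpus <- base::sample(corpus)  # fixed-seed shuffle

  task <- structure(list(
    reference = reference, decorations = decorations,
    positive_designs = positives, partial_designs = partials,
    negative_designs = negatives, corpus = corpus, seed = seed
  ), class = "fixture_task")
  if (with_conformer) {
    ens <- generate_conformers(reference, max_n = 1L, seed = seed)
    if (length(ens) == 0L) stop("could not embed the reference molecule")
    task$conformer <- ens[[1]]
  }
  task
}

#' @export
print.fixture_task <- function(x, ...) {
  cat("<fixture task> reference ", x$reference, "\n", sep = "")
  cat("  ", length(x$positive_designs), " positives, ",
      length(x$partial_designs), " partials, ",
      length(x$negative_designs), " negatives; corpus ",
      length(x$corpus), " SMILES\n", sep = "")
  invisible(x)
}

#' A reference conformer and a rigid-body-moved copy
#'
#' Embeds a small rigid molecule in 3D and returns the pose together with a
#' randomly rotated and translated copy -- the canonical fixture for overlay
#' identity and invariance tests.
#'
#' @param seed RNG seed.
#' @param smiles Molecule to embed (default toluene).
#' @return List with `reference` and `moved` conformers, plus the applied
#'   `rotation` and `translation`.
#' @export
make_conformer_pair <- function(seed = 42L, smiles = "Cc1ccccc1") {
  ens <- generate_conformers(smiles, max_n = 1L, seed = seed)
  if (length(ens) == 0L) stop("embedding failed for ", smiles)
  ref <- ens[[1]]
  set.seed(seed)
  rot <- rotation_from_vec(stats::runif(3, -pi, pi))
  trans <- stats::runif(3, -20, 20)
  list(reference = ref, moved = transform_conformer(ref, rot, trans),
       rotation = rot, translation = trans)
}

#' Design panels with controlled scaffold-class structure
#'
#' `make_homogeneous_panel()` returns `n` distinct molecules sharing one
#' cyclic-substructure class (alkyl benzenes); `make_distinct_panel()`
#' returns `n` molecules with pairwise distinct classes (varied ring systems
#' and ring-system combinations), both verified at construction. These
#' exercise the boundary behavior of the Scaled Shannon Entropy.
#'
#' @param n Panel size (default 50).
#' @return Character vector of canonical SMILES.
#' @export
make_homogeneous_panel <- function(n = 50L) {
  out <- vapply(seq_len(n), function(i) {
    canonicalize(paste0(paste(rep("C", i), collapse = ""), "c1ccccc1"))
  }, character(1))
  stopifnot(!anyNA(out), !anyDuplicated(out))
  cls <- unique(vapply(out, function(s) bm_framework(s)$cyclic_class,
                       character(1)))
  stopifnot(length(cls) == 1L)
  out
}

.ring_cores <- c(
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1",
  "c1ccccc1", "c1ccncc1", "c1ccnnc1", "c1cncnc1", "c1ccoc1", "c1ccsc1",
  "c1cc[nH]c1", "c1cnc[nH]1", "c1cn[nH]c1", "c1ocnc1", "c1scnc1",
  "C1CCOC1", "C1CCOCC1", "C1CCNC1", "C1CCNCC1", "C1CNCCN1", "C1COCCN1",
  "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1", "c1ccc2occc2c1",
  "c1ccc2sccc2c1", "C1CCC2CCCCC2C1", "c1ccc2ncncc2c1", "C1CC2CCC1CC2"
)

#' @rdname make_homogeneous_panel
#' @export
make_distinct_panel <- function(n = 50L) {
  singles <- .ring_cores
  # disconnected two-ring-system molecules give pairwise-combined classes
  combos <- character(0)
  for (i in seq_along(.ring_cores)) {
    for (j in seq_len(i - 1L)) {
      combos <- c(combos, paste0(.ring_cores[i], ".", .ring_cores[j]))
    }
  }
  cand <- unique(c(singles, combos))
  out <- character(0)
  seen_cls <- character(0)
  for (s in cand) {
    can <- canonicalize(s)
    if (is.na(can)) next
    cls <- bm_framework(can)$cyclic_class
    if (cls %in% seen_cls || cls == .no_cyclic_class) next
    out <- c(out, can)
    seen_cls <- c(seen_cls, cls)
    if (length(out) == n) break
  }
  if (length(out) < n) {
    stop("could not assemble ", n, " distinct cyclic classes (got ",
         length(out), ")")
  }
  out
}

#' Write fixture files for the command-line interface
#'
#' Emits the task's corpus, design and decoration SMILES files (and the
#' reference conformer SDF when present) into a directory.
#'
#' @param task A [make_task()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_task_files <- function(task, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(task$corpus, file.path(dir, "corpus.smi"))
  writeLines(vapply(task$decorations, function(d) d$fragment_smiles,
                    character(1)),
             file.path(dir, "decorations.smi"))
  writeLines(task$reference, file.path(dir, "reference.smi"))
  writeLines(c(task$positive_designs, task$partial_designs,
               task$negative_designs), file.path(dir, "designs.smi"))
  if (!is.null(task$conformer)) {
    write_conformers_sdf(list(task$conformer),
                         file.path(dir, "reference_conformer.sdf"))
  }
  invisible(dir)
}
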