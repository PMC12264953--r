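## Chemistry primitives backed by OpenBabel (ChemmineR / ChemmineOB):
## canonicalization, molecular graphs, circular fingerprints, Bemis-Murcko
## frameworks and the descriptors used by the molecule filter.

# Parse/score caches live for the session; keyed by input string.
.sh_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, text)),
    error = function(e) ""
  )
  if (!is.character(out) || length(out) != 1L) "" else out
}

#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to the fixed canonical dialect used throughout the
#' package (OpenBabel canonical SMILES). Canonicalization is idempotent:
#' `canonicalize(canonicalize(x))` equals `canonicalize(x)`.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string, or `NA_character_` if the input is not
#'   a parseable, chemically valid molecule (e.g. unclosed rings, hypervalent
#'   atoms, empty input).
#' @export
canonicalize <- function(smiles) {
  mol <- parse_molecule(smiles)
  if (is.null(mol)) NA_character_ else mol$smiles
}

ob_canonical <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(NA_character_)
  }
  s <- trimws(smiles)
  # reject whitespace inside the SMILES body (name columns are handled upstream)
  if (grepl("[[:space:]]", s)) return(NA_character_)
  out <- ob_convert("SMI", "CAN", paste0(s, "\n"))
  out <- sub("[\t\n].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

## -- SMILES tokenization (shared with the language-model vocabulary) --------

.token_regex <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|Si|Se|se|@@|[BCNOPSFIbcnops*]|",
  "%[0-9]{2}|[0-9]|[-=#:/\\\\().+])"
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the token alphabet used by the language model:
#' bracket atoms, two-character elements (Cl, Br, Si, Se), organic-subset
#' atoms, ring-closure digits (including `%nn`), bonds and branch symbols.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens, or `NULL` if some part of the string
#'   cannot be tokenized.
#' @export
smiles_tokens <- function(smiles) {
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr(.token_regex, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(smiles)) return(NULL)
  toks
}

## -- molecular graph construction -------------------------------------------

# Standard maximum valences; NA means "no check" (dummies, metals).
.max_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
  Cl = 1, Br = 1, I = 1, Se = 6
)

.atomic_mass <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Br = 79.904, I = 126.904,
  Se = 78.971
)

.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1, Si = 4, Se = 2)

parse_chg_lines <- function(molblock_lines, n_atoms) {
  charge <- integer(n_atoms)
  chg <- grep("^M  CHG", molblock_lines, value = TRUE)
  for (line in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)), "[[:space:]]+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) {
      idx <- f[2 * i]
      charge[idx] <- f[2 * i + 1]
    }
  }
  charge
}

parse_mol2_atoms <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)
  b0 <- grep("^@<TRIPOS>BOND", lines)
  if (!length(a0)) return(NULL)
  ends <- grep("^@<TRIPOS>", lines)
  a_end <- min(c(ends[ends > a0[1]], length(lines) + 1L)) - 1L
  at <- lines[(a0[1] + 1L):a_end]
  at <- at[nzchar(trimws(at))]
  fields <- lapply(strsplit(trimws(at), "[[:space:]]+"), identity)
  type <- vapply(fields, function(f) f[6], character(1))
  arom_bond <- matrix(integer(0), ncol = 2)
  if (length(b0)) {
    b_end <- min(c(ends[ends > b0[1]], length(lines) + 1L)) - 1L
    bt <- lines[(b0[1] + 1L):b_end]
    bt <- bt[nzchar(trimws(bt))]
    bf <- strsplit(trimws(bt), "[[:space:]]+")
    ar <- vapply(bf, function(f) identical(f[4], "ar"), logical(1))
    if (any(ar)) {
      arom_bond <- t(vapply(bf[ar], function(f) as.integer(f[2:3]), integer(2)))
    }
  }
  list(arom_atom = grepl("\\.ar$", type), arom_bond = arom_bond,
       elem = vapply(fields, function(f) sub("\\..*$", "", f[6]), character(1)))
}

ring_membership <- function(n_atoms, bonds) {
  in_ring_atom <- logical(n_atoms)
  in_ring_bond <- logical(nrow(bonds))
  if (nrow(bonds) == 0L || n_atoms < 3L) {
    return(list(atom = in_ring_atom, bond = in_ring_bond))
  }
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  ring_atoms <- unique(c(bonds$a1[in_ring_bond], bonds$a2[in_ring_bond]))
  in_ring_atom[ring_atoms] <- TRUE
  list(atom = in_ring_atom, bond = in_ring_bond)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the package's internal molecule representation: canonical SMILES,
#' an atom table (element, aromaticity, formal charge, implicit hydrogens,
#' degree, ring membership), and a bond table with kekulized bond orders.
#' Results are cached per input string.
#'
#' @param smiles A single SMILES string.
#' @param use_cache Memoize the result in the session cache (default); pass
#'   `FALSE` for throwaway structures.
#' @return An object of class `molecule`, or `NULL` when the input is not a
#'   valid molecule. Dummy atoms (`*`) are supported and excluded from the
#'   heavy-atom count.
#' @export
parse_molecule <- function(smiles, use_cache = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    return(NULL)
  }
  if (!use_cache) return(build_molecule(smiles))
  key <- paste0("m:", smiles)
  hit <- .sh_cache[[key]]
  if (!is.null(hit)) return(if (isFALSE(hit)) NULL else hit)

  mol <- build_molecule(smiles)
  cache_put(key, if (is.null(mol)) FALSE else mol)
  mol
}

# Bounded memoization: long campaigns parse tens of thousands of transient
# structures; once the cache grows past the bound it is simply reset.
cache_put <- function(key, value) {
  n <- .sh_cache[["..n"]]
  if (is.null(n)) n <- 0L
  if (n > 8000L) {
    rm(list = ls(.sh_cache, all.names = TRUE), envir = .sh_cache)
    n <- 0L
  }
  .sh_cache[["..n"]] <- n + 1L
  .sh_cache[[key]] <- value
  invisible(value)
}

# A bracket atom whose explicit hydrogen count alone exceeds the element's
# maximum valence (charge-adjusted) cannot exist regardless of bonding.
bracket_h_valid <- function(can) {
  toks <- smiles_tokens(can)
  if (is.null(toks)) return(TRUE)
  for (tk in grep("^\\[", toks, value = TRUE)) {
    m <- regmatches(tk, regexec(
      "^\\[([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?([+-][0-9]*)?\\]$",
      tk))[[1]]
    if (length(m) == 0L) next
    elem <- m[3]
    elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
    if (!elem %in% names(.max_valence)) next
    h <- if (nzchar(m[5])) {
      if (nzchar(m[6])) as.integer(m[6]) else 1L
    } else 0L
    chg <- if (nzchar(m[7])) {
      sgn <- if (substr(m[7], 1, 1) == "+") 1L else -1L
      mag <- if (nchar(m[7]) > 1L) as.integer(substring(m[7], 2)) else 1L
      sgn * mag
    } else 0L
    if (h > .max_valence[[elem]] + abs(chg)) return(FALSE)
  }
  TRUE
}

build_molecule <- function(smiles) {
  can <- ob_canonical(smiles)
  if (is.na(can)) return(NULL)
  if (!bracket_h_valid(can)) return(NULL)

  molblock <- ob_convert("SMI", "SDF", paste0(can, "\n"))
  mol2 <- ob_convert("SMI", "MOL2", paste0(can, "\n"))
  if (!nzchar(molblock) || !nzchar(mol2)) return(NULL)
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L) return(NULL)

  atom_lines <- lines[5:(4 + n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  if (n_bonds > 0L) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- order <- integer(0)
  }
  charge <- parse_chg_lines(lines, n_atoms)

  m2 <- parse_mol2_atoms(mol2)
  if (is.null(m2) || length(m2$arom_atom) != n_atoms) return(NULL)
  elem[elem %in% c("R", "R#", "Du", "A")] <- "*"
  arom <- m2$arom_atom

  bonds <- data.frame(a1 = a1, a2 = a2, order = order)
  # aromatic bonds from the mol2 table (kekulized orders kept alongside)
  barom <- logical(nrow(bonds))
  if (nrow(m2$arom_bond) > 0L && nrow(bonds) > 0L) {
    key_b <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    key_m <- paste(pmin(m2$arom_bond[, 1], m2$arom_bond[, 2]),
                   pmax(m2$arom_bond[, 1], m2$arom_bond[, 2]))
    # SYBYL also types delocalized carboxylate bonds "ar"; a truly aromatic
    # bond needs both endpoint atoms aromatic as well
    barom <- (key_b %in% key_m) & arom[bonds$a1] & arom[bonds$a2]
  }
  bonds$arom <- barom

  degree <- integer(n_atoms)
  vsum <- numeric(n_atoms)
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
      degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
      vsum[bonds$a1[i]] <- vsum[bonds$a1[i]] + bonds$order[i]
      vsum[bonds$a2[i]] <- vsum[bonds$a2[i]] + bonds$order[i]
    }
  }

  # standard-valence check (OpenBabel itself is permissive about hypervalence)
  nH <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    e <- elem[i]
    if (e == "*") next
    mx <- unname(.max_valence[e])
    dv <- unname(.default_valence[e])
    allowed <- if (is.na(mx)) Inf else mx + abs(charge[i])
    if (vsum[i] > allowed) return(NULL)
    if (!is.na(dv)) {
      # N+ fills to 4 bonds, O- to 1; S may expand to its observed valence
      fill <- switch(e,
        N = 3 + charge[i], P = 3 + charge[i],
        O = 2 + charge[i], S = max(2 + charge[i], min(vsum[i], 6)),
        C = 4, B = 3, dv
      )
      nH[i] <- max(0, fill - vsum[i])
    }
  }

  rings <- ring_membership(n_atoms, bonds)
  atoms <- data.frame(
    elem = elem, arom = arom, charge = charge, nH = nH,
    degree = degree, in_ring = rings$atom, is_dummy = elem == "*",
    stringsAsFactors = FALSE
  )
  bonds$in_ring <- rings$bond

  structure(
    list(
      smiles = can,
      atoms = atoms,
      bonds = bonds,
      n_heavy = sum(elem != "*" & elem != "H")
    ),
    class = "molecule"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$smiles, "  (", x$n_heavy, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

as_molecule <- function(x) {
  if (inherits(x, "molecule")) return(x)
  mol <- parse_molecule(x)
  if (is.null(mol)) stop("not a valid molecule: ", x, call. = FALSE)
  mol
}

## -- MOL block emission for derived fragments --------------------------------

# Emit a V2000 molblock for an atom subset of a molecule (optionally with
# extra dummy atoms bonded to given partners), and return its canonical
# SMILES via OpenBabel. Used by scaffold extraction, cleavage and framework
# computation; no SMILES string is ever assembled by hand.
subgraph_smiles <- function(mol, atom_idx, dummy_partners = integer(0),
                            drop_bonds = NULL) {
  atom_idx <- sort(unique(atom_idx))
  n_keep <- length(atom_idx)
  if (n_keep == 0L) return(NA_character_)
  remap <- integer(nrow(mol$atoms))
  remap[atom_idx] <- seq_len(n_keep)
  bonds <- mol$bonds
  keep_b <- bonds$a1 %in% atom_idx & bonds$a2 %in% atom_idx
  if (!is.null(drop_bonds) && nrow(drop_bonds) > 0L) {
    key_b <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    key_d <- paste(pmin(drop_bonds[, 1], drop_bonds[, 2]),
                   pmax(drop_bonds[, 1], drop_bonds[, 2]))
    keep_b <- keep_b & !(key_b %in% key_d)
  }
  bsub <- bonds[keep_b, , drop = FALSE]
  n_dummy <- length(dummy_partners)
  n_atoms <- n_keep + n_dummy
  n_bonds <- nrow(bsub) + n_dummy

  elem <- c(mol$atoms$elem[atom_idx], rep("*", n_dummy))
  lines <- c(
    "", " scaffhop", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms, n_bonds)
  )
  for (i in seq_len(n_atoms)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, elem[i]))
  }
  if (nrow(bsub) > 0L) {
    for (i in seq_len(nrow(bsub))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                remap[bsub$a1[i]], remap[bsub$a2[i]],
                                bsub$order[i]))
    }
  }
  if (n_dummy > 0L) {
    for (i in seq_len(n_dummy)) {
      lines <- c(lines, sprintf("%3d%3d  1  0  0  0  0",
                                remap[dummy_partners[i]], n_keep + i))
    }
  }
  chg <- which(mol$atoms$charge[atom_idx] != 0L)
  for (i in chg) {
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i,
                              mol$atoms$charge[atom_idx][i]))
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- ob_convert("SDF", "CAN", paste(lines, collapse = "\n"))
  out <- sub("[\t\n].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

## -- fingerprints ------------------------------------------------------------

# deterministic integer mixing below 2^31 (exact in doubles)
.hash_mix <- function(a, b) (a * 1000003 + b) %% 2147483629

.elem_codes <- c("*", "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                 "Se", "Br", "I")

#' Extended-connectivity fingerprint
#'
#' Computes a circular (Morgan-style) fingerprint: iterated neighborhood
#' hashing of atom invariants (element, charge, hydrogen count, heavy
#' degree, ring membership, aromaticity) out to the given radius, with every
#' intermediate identifier folded onto `nbits` bits. The fingerprint is
#' computed on the canonical structure, so it is invariant to the atom
#' ordering of the input SMILES. Dummy attachment atoms in scaffolds
#' participate (they mark attachment points, and reference and design
#' scaffolds carry them symmetrically).
#'
#' @param mol A `molecule` or SMILES string.
#' @param radius Circular neighborhood radius (default 3).
#' @param nbits Folded fingerprint length (default 2048).
#' @return An object of class `ecfp` with fields `on_bits` (0-based sorted
#'   integer bit indices), `radius` and `nbits`.
#' @export
ecfp <- function(mol, radius = 3L, nbits = 2048L) {
  mol <- as_molecule(mol)
  stopifnot(radius >= 0L, nbits >= 1L)
  key <- paste0("fp:", radius, ":", nbits, ":", mol$smiles)
  hit <- .sh_cache[[key]]
  if (!is.null(hit)) return(hit)
  fp <- structure(list(on_bits = compute_ecfp_bits(mol, radius, nbits),
                       radius = as.integer(radius),
                       nbits = as.integer(nbits)),
                  class = "ecfp")
  cache_put(key, fp)
  fp
}

compute_ecfp_bits <- function(mol, radius, nbits) {
  a <- mol$atoms
  n <- nrow(a)
  ecode <- match(a$elem, .elem_codes)
  ecode[is.na(ecode)] <- 100 + vapply(a$elem[is.na(ecode)], function(e) {
    sum(utf8ToInt(e))
  }, numeric(1))
  heavy_deg <- integer(n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    heavy_deg[b$a1[i]] <- heavy_deg[b$a1[i]] + 1L
    heavy_deg[b$a2[i]] <- heavy_deg[b$a2[i]] + 1L
  }
  inv <- rep(17, n)
  feats <- list(ecode, a$charge + 10, a$nH, heavy_deg,
                as.integer(a$in_ring), as.integer(a$arom))
  for (f in feats) inv <- .hash_mix(inv, f)

  adj <- adjacency_list(mol)
  bl <- bond_lookup(mol)
  ids <- inv
  all_ids <- inv
  if (radius >= 1L && n > 1L) {
    for (r in seq_len(radius)) {
      new_ids <- numeric(n)
      for (i in seq_len(n)) {
        nbrs <- adj[[i]]
        h <- .hash_mix(r, ids[i])
        if (length(nbrs) > 0L) {
          pair <- vapply(nbrs, function(j) {
            bd <- get_bond(bl, i, j)
            bcode <- if (bd$arom) 4 else bd$order
            .hash_mix(bcode, ids[j])
          }, numeric(1))
          for (p in sort(pair)) h <- .hash_mix(h, p)
        }
        new_ids[i] <- h
      }
      ids <- new_ids
      all_ids <- c(all_ids, new_ids)
    }
  }
  sort(unique(as.integer(all_ids %% nbits)))
}

#' Jaccard (Tanimoto) distance between fingerprints
#'
#' `1 - |a ∩ b| / |a ∪ b|` over the on-bit sets. This single formula
#' is used wherever the package needs a 2D dissimilarity.
#'
#' @param a,b `ecfp` fingerprints (non-empty bit sets).
#' @return Distance in `[0, 1]`; 0 iff the bit sets are identical.
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(inherits(a, "ecfp"), inherits(b, "ecfp"))
  if (length(a$on_bits) == 0L && length(b$on_bits) == 0L) {
    stop("Jaccard distance is undefined for two empty fingerprints")
  }
  inter <- length(intersect(a$on_bits, b$on_bits))
  uni <- length(union(a$on_bits, b$on_bits))
  1 - inter / uni
}

## -- Bemis-Murcko frameworks -------------------------------------------------

.no_cyclic_class <- "no cyclic substructure(s)"

#' Bemis-Murcko framework of a molecule
#'
#' Prunes side chains (iteratively removing singly-bonded terminal atoms,
#' keeping atoms attached by double or triple bonds) to leave ring systems
#' plus their linkers. The `cyclic_class` is the canonical form of the
#' framework's cyclic substructures (ring atoms only, linkers removed), used
#' as the class label for scaffold-diversity statistics; acyclic molecules
#' all map to the single reserved class `"no cyclic substructure(s)"`.
#'
#' @param mol A `molecule` or SMILES string.
#' @return List with `framework_smiles` (empty string for acyclic molecules)
#'   and `cyclic_class`.
#' @export
bm_framework <- function(mol) {
  mol <- as_molecule(mol)
  key <- paste0("bm:", mol$smiles)
  hit <- .sh_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- compute_bm(mol)
  cache_put(key, res)
  res
}

compute_bm <- function(mol) {
  if (!any(mol$atoms$in_ring)) {
    return(list(framework_smiles = "", cyclic_class = .no_cyclic_class))
  }
  keep <- rep(TRUE, nrow(mol$atoms))
  bonds <- mol$bonds
  repeat {
    deg <- integer(nrow(mol$atoms))
    ordmax <- numeric(nrow(mol$atoms))
    act <- bonds$a1 %in% which(keep) & bonds$a2 %in% which(keep)
    for (i in which(act)) {
      deg[bonds$a1[i]] <- deg[bonds$a1[i]] + 1L
      deg[bonds$a2[i]] <- deg[bonds$a2[i]] + 1L
    }
    # terminal atoms attached by a single bond are side-chain atoms
    term <- which(keep & deg <= 1L)
    drop <- term[vapply(term, function(a) {
      bi <- which(act & (bonds$a1 == a | bonds$a2 == a))
      length(bi) == 0L || all(bonds$order[bi] == 1L)
    }, logical(1))]
    drop <- setdiff(drop, which(mol$atoms$in_ring))
    if (length(drop) == 0L) break
    keep[drop] <- FALSE
  }
  fw_idx <- which(keep)
  fw_smiles <- subgraph_smiles(mol, fw_idx)
  ring_idx <- which(mol$atoms$in_ring)
  cls <- subgraph_smiles(mol, ring_idx)
  # canonical per-component form, sorted, dot-joined, for a stable class label
  comps <- sort(method = "radix", vapply(strsplit(cls, ".", fixed = TRUE)[[1]], function(s) {
    out <- ob_canonical(s)
    if (is.na(out)) s else out
  }, character(1)))
  list(framework_smiles = if (is.na(fw_smiles)) "" else fw_smiles,
       cyclic_class = paste(unique(comps), collapse = "."))
}

## -- descriptors -------------------------------------------------------------

#' Molecular descriptors used by the molecule filter
#'
#' Molecular weight (g/mol, average atomic masses, implicit hydrogens
#' included), rotatable-bond count (non-ring single bonds between two
#' non-terminal heavy atoms, triple-bond-adjacent bonds excluded) and the
#' number of potential tetrahedral stereocenters.
#'
#' @param mol A `molecule` or SMILES string.
#' @return Named list: `molecular_weight`, `rotatable_bonds`, `stereocenters`.
#' @export
properties <- function(mol) {
  mol <- as_molecule(mol)
  mass <- sum(vapply(seq_len(nrow(mol$atoms)), function(i) {
    e <- mol$atoms$elem[i]
    if (e == "*") return(0)
    m <- unname(.atomic_mass[e])
    (if (is.na(m)) 0 else m) + mol$atoms$nH[i] * .atomic_mass[["H"]]
  }, numeric(1)))
  list(
    molecular_weight = mass,
    rotatable_bonds = count_rotatable(mol),
    stereocenters = length(stereocenter_indices(mol))
  )
}

count_rotatable <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  triple_adjacent <- unique(c(b$a1[b$order == 3L], b$a2[b$order == 3L]))
  ok <- b$order == 1L & !b$in_ring &
    mol$atoms$degree[b$a1] > 1L & mol$atoms$degree[b$a2] > 1L &
    !(b$a1 %in% triple_adjacent) & !(b$a2 %in% triple_adjacent) &
    !mol$atoms$is_dummy[b$a1] & !mol$atoms$is_dummy[b$a2]
  sum(ok)
}

# Deterministic hash of the branch seen from `root` walking away from
# `center`; used to decide whether an atom's substituents are all distinct.
branch_signature <- function(mol, center, root, max_depth = 12L) {
  adj <- adjacency_list(mol)
  sig <- character(0)
  level <- root
  seen <- c(center, root)
  depth <- 0L
  repeat {
    lab <- sort(method = "radix", paste0(mol$atoms$elem[level], "/", mol$atoms$charge[level],
                       "/", mol$atoms$nH[level], "/", mol$atoms$arom[level]))
    sig <- c(sig, paste(lab, collapse = ","))
    nxt <- setdiff(unique(unlist(adj[level])), seen)
    depth <- depth + 1L
    if (length(nxt) == 0L || depth >= max_depth) break
    seen <- c(seen, nxt)
    level <- nxt
  }
  paste(sig, collapse = "|")
}

adjacency_list <- function(mol) {
  key <- paste0("adj:", mol$smiles)
  hit <- .sh_cache[[key]]
  if (!is.null(hit)) return(hit)
  adj <- vector("list", nrow(mol$atoms))
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  cache_put(key, adj)
  adj
}

stereocenter_indices <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  cand <- which(a$elem == "C" & !a$arom & a$degree %in% c(3L, 4L) &
                  a$nH <= 1L)
  if (length(cand) == 0L) return(integer(0))
  has_multi <- unique(c(b$a1[b$order > 1L], b$a2[b$order > 1L]))
  cand <- setdiff(cand, has_multi)
  adj <- adjacency_list(mol)
  out <- integer(0)
  for (at in cand) {
    nbrs <- adj[[at]]
    if (length(nbrs) + a$nH[at] != 4L) next
    sigs <- vapply(nbrs, function(nb) branch_signature(mol, at, nb),
                   character(1))
    if (anyDuplicated(sigs) == 0L) out <- c(out, at)
  }
  out
}

# Smallest-ring size through each ring bond; used for the macrocycle check.
max_min_ring_size <- function(mol) {
  b <- mol$bonds
  ring_b <- which(b$in_ring)
  if (length(ring_b) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(mol$atoms)) {
    g <- igraph::add_vertices(g, nrow(mol$atoms) - igraph::vcount(g))
  }
  sizes <- vapply(ring_b, function(i) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(b$a1[i], b$a2[i])))
    d <- igraph::distances(g2, v = b$a1[i], to = b$a2[i])[1, 1]
    if (is.infinite(d)) Inf else d + 1
  }, numeric(1))
  max(sizes[is.finite(sizes)], 0)
}
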