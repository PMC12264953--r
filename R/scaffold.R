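## Fuzzy decoration matching and scaffold extraction.
##
## A "decoration" is a peripheral substructure with a single attachment point
## (a dummy atom). Given a design molecule and the reference decorations, the
## decomposition algorithm (1) finds the largest common connected substructure
## between each decoration and the design, letting the dummy atom stand for
## any non-peripheral heavy atom, (2) prefers the most peripheral placement,
## (3) test-cleaves the bond at the attachment and checks the cleaved fragment
## size against an alpha-controlled window around the reference decoration
## size, and (4) if every decoration matched, cuts all fragments off and
## returns the remaining scaffold with one dummy atom per attachment site.

#' Construct a decoration
#'
#' @param fragment_smiles SMILES of a fragment containing exactly one dummy
#'   atom (`*` or `[*]`) marking the attachment point.
#' @return Object of class `decoration` with the parsed fragment and `n_r`,
#'   the heavy-atom count excluding the dummy.
#' @export
decoration <- function(fragment_smiles) {
  mol <- parse_molecule(fragment_smiles)
  if (is.null(mol)) stop("invalid decoration SMILES: ", fragment_smiles,
                         call. = FALSE)
  nd <- sum(mol$atoms$is_dummy)
  if (nd != 1L) {
    stop("a decoration must contain exactly one dummy atom, found ", nd,
         call. = FALSE)
  }
  if (mol$n_heavy < 1L) stop("decoration has no heavy atoms", call. = FALSE)
  structure(list(mol = mol, n_r = mol$n_heavy,
                 fragment_smiles = mol$smiles),
            class = "decoration")
}

#' @export
print.decoration <- function(x, ...) {
  cat("<decoration> ", x$fragment_smiles, "  (n_r = ", x$n_r, ")\n", sep = "")
  invisible(x)
}

#' Read decorations from a SMILES file
#'
#' One fragment per line, dummy atom written as `*` or `[*]`; an optional
#' whitespace-separated name column is ignored.
#'
#' @param path Path to the decorations file.
#' @return List of `decoration` objects.
#' @export
read_decorations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(sub("[[:space:]].*$", "", lines), decoration)
}

#' Decoration size window
#'
#' The cleaved-fragment size window around a reference decoration of `n_r`
#' atoms: minimum `n_r * alpha`, maximum `n_r / alpha`. Integer sizes are
#' permitted on the closed interval (both bounds inclusive), so for
#' `n_r = 10, alpha = 0.8` fragments of 8 to 12 atoms pass.
#'
#' @param n_r Heavy-atom count of the reference decoration (>= 1).
#' @param alpha Fuzziness parameter in (0, 1]; `alpha = 1` permits only the
#'   exact size.
#' @return List with `m_r`, `M_r` and the integer vector `permitted_sizes`.
#' @export
size_bounds <- function(n_r, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  stopifnot(n_r >= 1)
  m_r <- n_r * alpha
  M_r <- n_r / alpha
  eps <- 1e-9
  sizes <- seq.int(ceiling(m_r - eps), floor(M_r + eps))
  list(m_r = m_r, M_r = M_r, permitted_sizes = sizes)
}

size_ok <- function(n_d, bounds) {
  eps <- 1e-9
  n_d >= bounds$m_r - eps & n_d <= bounds$M_r + eps
}

## -- labeled subgraph monomorphism search ------------------------------------

atom_compatible <- function(pat, des, pi, di) {
  pat$elem[pi] == des$elem[di] &&
    pat$arom[pi] == des$arom[di] &&
    pat$charge[pi] == des$charge[di] &&
    pat$in_ring[pi] == des$in_ring[di] &&
    !des$is_dummy[di]
}

bond_compatible <- function(pb, db) {
  if (pb$arom || db$arom) pb$arom == db$arom else pb$order == db$order
}

bond_lookup <- function(mol) {
  key <- paste0("bl:", mol$smiles)
  hit <- .sh_cache[[key]]
  if (!is.null(hit)) return(hit)
  env <- new.env(parent = emptyenv())
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    k <- paste(min(b$a1[i], b$a2[i]), max(b$a1[i], b$a2[i]))
    env[[k]] <- list(order = b$order[i], arom = b$arom[i],
                     in_ring = b$in_ring[i])
  }
  cache_put(key, env)
  env
}

get_bond <- function(lookup, i, j) lookup[[paste(min(i, j), max(i, j))]]

# All injective, adjacency-preserving (non-induced) embeddings of the pattern
# subset `sub` (atom indices of pat_mol) into the design. Pattern atoms are
# visited in BFS order from `root` so each new atom is constrained by an
# already-mapped neighbor.
subgraph_embeddings <- function(pat_mol, sub, root, design, forbidden) {
  pa <- pat_mol$atoms
  da <- design$atoms
  pl <- bond_lookup(pat_mol)
  dl <- bond_lookup(design)
  padj <- adjacency_list(pat_mol)
  dadj <- adjacency_list(design)

  # BFS order over the subset
  ord <- root
  seen <- root
  while (length(ord) < length(sub)) {
    frontier <- unique(unlist(lapply(ord, function(a) {
      intersect(padj[[a]], sub)
    })))
    nxt <- setdiff(frontier, seen)
    if (length(nxt) == 0L) return(list())  # subset not connected
    ord <- c(ord, nxt)
    seen <- c(seen, nxt)
  }

  results <- list()
  map <- integer(length(ord))
  recurse <- function(k) {
    if (k > length(ord)) {
      results[[length(results) + 1L]] <<- stats::setNames(map, ord)
      return(invisible(NULL))
    }
    p <- ord[k]
    prev <- ord[seq_len(k - 1L)]
    anchors <- intersect(padj[[p]], prev)
    cands <- if (k == 1L) {
      which(!da$is_dummy)
    } else {
      # candidates adjacent to the image of the first mapped pattern neighbor
      a0 <- anchors[1]
      dadj[[map[match(a0, ord)]]]
    }
    for (d in cands) {
      if (d %in% forbidden || d %in% map[seq_len(k - 1L)]) next
      if (!atom_compatible(pa, da, p, d)) next
      ok <- TRUE
      for (a in anchors) {
        pb <- get_bond(pl, p, a)
        db <- get_bond(dl, d, map[match(a, ord)])
        if (is.null(db) || !bond_compatible(pb, db)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[k] <<- d
      recurse(k + 1L)
      map[k] <<- 0L
    }
    invisible(NULL)
  }
  recurse(1L)
  results
}

# Connected subsets of `atoms` (adjacency via mol) that contain `root`,
# of exactly `size` members.
connected_subsets <- function(mol, atoms, root, size) {
  adj <- adjacency_list(mol)
  results <- list()
  grow <- function(current, candidates, banned) {
    if (length(current) == size) {
      results[[length(results) + 1L]] <<- current
      return(invisible(NULL))
    }
    cands <- candidates
    banned_local <- banned
    while (length(cands) > 0L) {
      v <- cands[1]
      cands <- cands[-1]
      new_cand <- setdiff(intersect(adj[[v]], atoms),
                          c(current, v, cands, banned_local))
      grow(c(current, v), c(cands, new_cand), banned_local)
      banned_local <- c(banned_local, v)
    }
    invisible(NULL)
  }
  init <- setdiff(intersect(adj[[root]], atoms), root)
  grow(root, init, integer(0))
  results
}

## -- fuzzy matching -----------------------------------------------------------

#' Fuzzily match a decoration in a design
#'
#' Searches for the largest common connected substructure between the
#' decoration and the design that includes the attachment dummy. A match is
#' accepted only if the dummy's counterpart in the design is connected by a
#' single (non-ring, non-aromatic) bond, has degree greater than 1, the
#' matched atoms are disjoint from `used_atoms`, and the matched portion
#' covers at least `alpha` times the decoration's heavy-atom count.
#'
#' @param design A `molecule` (or SMILES).
#' @param dec A `decoration`.
#' @param used_atoms Atom indices already claimed by previously accepted
#'   matches.
#' @param alpha Fuzziness parameter in (0, 1].
#' @param all If `TRUE`, return every candidate match at the maximal common
#'   substructure size (for peripheral selection); otherwise the selected
#'   match after peripheral selection and cleavage checking.
#' @return A match object (list), a list of them when `all = TRUE`, or `NULL`
#'   when the decoration has no acceptable match.
#' @export
fuzzy_match <- function(design, dec, used_atoms = integer(0), alpha = 0.9,
                        all = FALSE) {
  design <- as_molecule(design)
  stopifnot(inherits(dec, "decoration"))
  cands <- fuzzy_candidates(design, dec, used_atoms, alpha)
  if (all) return(cands)
  if (length(cands) == 0L) return(NULL)
  accept_candidate(design, dec, cands, used_atoms, alpha)
}

fuzzy_candidates <- function(design, dec, used_atoms, alpha) {
  pat <- dec$mol
  dummy <- which(pat$atoms$is_dummy)
  attach <- adjacency_list(pat)[[dummy]]
  if (length(attach) != 1L) return(list())
  heavy <- setdiff(seq_len(nrow(pat$atoms)), dummy)
  min_size <- max(1L, ceiling(alpha * dec$n_r - 1e-9))
  dl <- bond_lookup(design)
  dadj <- adjacency_list(design)

  for (size in seq.int(dec$n_r, min_size)) {
    subs <- connected_subsets(pat, heavy, attach, size)
    found <- list()
    for (s in subs) {
      embs <- subgraph_embeddings(pat, s, attach, design, used_atoms)
      for (emb in embs) {
        img_attach <- unname(emb[match(attach, as.integer(names(emb)))])
        image <- unname(emb)
        # dummy counterpart: a design neighbor of the attachment image,
        # outside the matched image, single non-aromatic bond, degree > 1
        for (p in dadj[[img_attach]]) {
          if (p %in% image || p %in% used_atoms) next
          if (design$atoms$is_dummy[p]) next
          if (design$atoms$degree[p] <= 1L) next
          db <- get_bond(dl, img_attach, p)
          if (db$arom || db$order != 1L) next
          found[[length(found) + 1L]] <- list(
            decoration = dec,
            matched_atom_indices = sort(image),
            attachment_image = img_attach,
            dummy_partner_index = p,
            mcs_size = size
          )
        }
      }
    }
    if (length(found) > 0L) return(unique_candidates(found))
  }
  list()
}

unique_candidates <- function(cands) {
  keys <- vapply(cands, function(m) {
    paste(paste(m$matched_atom_indices, collapse = ","),
          m$attachment_image, m$dummy_partner_index, sep = "|")
  }, character(1))
  cands[!duplicated(keys)]
}

#' Select the most peripheral candidate match
#'
#' Among candidate matches of one decoration, picks the one whose cleavage
#' leaves the largest number of atoms on the scaffold side of the cut bond
#' (i.e. the most peripheral placement). Ties are broken deterministically by
#' the smallest minimum matched canonical atom index.
#'
#' @param matches Non-empty list of candidate matches (see [fuzzy_match()]).
#' @param design The design `molecule`.
#' @return The selected candidate.
#' @export
select_peripheral <- function(matches, design) {
  if (length(matches) == 0L) stop("no candidate matches", call. = FALSE)
  design <- as_molecule(design)
  info <- lapply(matches, function(m) cleave_components(design, m))
  remainder <- vapply(info, function(x) {
    if (is.null(x)) -1L else length(x$remainder_atoms)
  }, integer(1))
  tie <- vapply(matches, function(m) min(m$matched_atom_indices), integer(1))
  ord <- order(-remainder, tie)
  matches[[ord[1]]]
}

# Components of the design after cutting the cleavage bond; NULL when the cut
# does not split the molecule in two (ring bond).
cleave_components <- function(design, match) {
  b <- design$bonds
  i <- match$attachment_image
  p <- match$dummy_partner_index
  drop <- !((b$a1 == i & b$a2 == p) | (b$a1 == p & b$a2 == i))
  g <- igraph::graph_from_edgelist(
    as.matrix(b[drop, c("a1", "a2"), drop = FALSE]), directed = FALSE)
  if (igraph::vcount(g) < nrow(design$atoms)) {
    g <- igraph::add_vertices(g, nrow(design$atoms) - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  if (comp$membership[i] == comp$membership[p]) return(NULL)
  frag <- which(comp$membership == comp$membership[i])
  rem <- which(comp$membership == comp$membership[p])
  if (length(frag) + length(rem) != nrow(design$atoms)) return(NULL)
  list(fragment_atoms = frag, remainder_atoms = rem)
}

#' Test-cleave a matched decoration off a design
#'
#' Cuts the single bond between the matched substructure and its dummy
#' counterpart. Succeeds only when the cut yields exactly two chemically
#' valid fragments (a ring bond cannot be cleaved).
#'
#' @param design The design `molecule`.
#' @param match A candidate match from [fuzzy_match()].
#' @return List with `fragment` and `remainder` molecules, the cleaved
#'   fragment's heavy-atom count `n_d` and `fragment_atoms`; or `NULL` on
#'   failure.
#' @export
cleave <- function(design, match) {
  design <- as_molecule(design)
  comps <- cleave_components(design, match)
  if (is.null(comps)) return(NULL)
  frag_smiles <- subgraph_smiles(design, comps$fragment_atoms)
  rem_smiles <- subgraph_smiles(design, comps$remainder_atoms)
  if (is.na(frag_smiles) || is.na(rem_smiles)) return(NULL)
  # candidate cleavages are throwaway structures; do not fill the cache
  frag <- parse_molecule(frag_smiles, use_cache = FALSE)
  rem <- parse_molecule(rem_smiles, use_cache = FALSE)
  if (is.null(frag) || is.null(rem)) return(NULL)
  n_d <- sum(!design$atoms$is_dummy[comps$fragment_atoms])
  list(fragment = frag, remainder = rem, n_d = n_d,
       fragment_atoms = comps$fragment_atoms)
}

# Walk candidates in peripheral order until one passes cleavage + size check.
accept_candidate <- function(design, dec, cands, used_atoms, alpha) {
  bounds <- size_bounds(dec$n_r, alpha)
  remaining <- cands
  while (length(remaining) > 0L) {
    best <- select_peripheral(remaining, design)
    keep <- vapply(remaining, function(m) !identical(m, best), logical(1))
    remaining <- remaining[keep]
    cl <- cleave(design, best)
    if (is.null(cl)) next
    if (any(cl$fragment_atoms %in% used_atoms)) next
    if (!size_ok(cl$n_d, bounds)) next
    best$n_d <- cl$n_d
    best$fragment_atoms <- cl$fragment_atoms
    best$fragment <- cl$fragment
    return(best)
  }
  NULL
}

## -- full decomposition -------------------------------------------------------

#' Decompose a design into scaffold and decorations
#'
#' Iterates the reference decorations (largest first), fuzzily matching and
#' cleaving each. The success score is the fraction of decorations matched.
#' When every decoration matched (score 1), the scaffold -- the design minus
#' all cleaved fragments, with one dummy atom per attachment site -- is
#' returned.
#'
#' @param design A `molecule` or SMILES string.
#' @param decorations List of `decoration` objects (or fragment SMILES).
#' @param alpha Fuzziness parameter in (0, 1]; default 0.9.
#' @return Object of class `scaffold_decomposition`: `success_score`,
#'   `matches`, and `scaffold` (a `molecule`, or `NULL` when the score is
#'   below 1).
#' @export
find_scaffold <- function(design, decorations, alpha = 0.9) {
  design <- as_molecule(design)
  if (inherits(decorations, "decoration")) decorations <- list(decorations)
  decorations <- lapply(decorations, function(d) {
    if (inherits(d, "decoration")) d else decoration(d)
  })
  if (length(decorations) == 0L) stop("at least one decoration is required",
                                      call. = FALSE)
  ord <- order(-vapply(decorations, function(d) d$n_r, numeric(1)))
  used <- integer(0)
  matches <- list()
  n_ok <- 0L
  for (d in decorations[ord]) {
    m <- fuzzy_match(design, d, used_atoms = used, alpha = alpha)
    if (!is.null(m)) {
      n_ok <- n_ok + 1L
      used <- c(used, m$fragment_atoms)
      matches[[length(matches) + 1L]] <- m
    }
  }
  s_s <- n_ok / length(decorations)
  scaffold <- NULL
  if (s_s == 1) {
    keep <- setdiff(seq_len(nrow(design$atoms)), used)
    partners <- vapply(matches, function(m) m$dummy_partner_index, integer(1))
    smi <- subgraph_smiles(design, keep, dummy_partners = partners)
    if (!is.na(smi)) scaffold <- parse_molecule(smi)
    if (is.null(scaffold)) s_s <- (length(decorations) - 1L) /
        length(decorations)  # defensive: unextractable scaffold
  }
  structure(list(success_score = s_s, matches = matches, scaffold = scaffold,
                 design = design, alpha = alpha),
            class = "scaffold_decomposition")
}

#' @export
print.scaffold_decomposition <- function(x, ...) {
  cat("<scaffold decomposition>\n")
  cat("  design:       ", x$design$smiles, "\n", sep = "")
  cat("  success score:", format(x$success_score, digits = 4), "\n")
  if (!is.null(x$scaffold)) {
    cat("  scaffold:     ", x$scaffold$smiles, "\n", sep = "")
  }
  invisible(x)
}
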