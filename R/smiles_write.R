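## SMILES emission from the internal molecular graph: randomized (non-canonical)
## enumeration for transfer-learning augmentation, and stereo-annotated
## variants for stereoisomer enumeration. Aromatic systems are written in
## lowercase aromatic form; correctness is established by the canonical
## round-trip property canonicalize(emit(mol)) == mol$smiles.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

atom_token <- function(mol, i, stereo = NULL) {
  e <- mol$atoms$elem[i]
  chg <- mol$atoms$charge[i]
  arom <- mol$atoms$arom[i]
  st <- if (!is.null(stereo)) stereo[as.character(i)] else NA_character_
  if (e == "*") return("*")
  sym <- if (arom && tolower(e) %in% .aromatic_organic) tolower(e) else e
  # aromatic N/P with a hydrogen must spell it out ([nH], pyrrole-type)
  arom_h <- arom && sym %in% c("n", "p") && mol$atoms$nH[i] > 0L
  needs_bracket <- chg != 0L || !is.na(st) || arom_h ||
    !(e %in% .organic_subset)
  if (!needs_bracket) return(sym)
  h <- mol$atoms$nH[i]
  paste0("[", sym,
         if (!is.na(st)) st else "",
         if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
         if (chg > 0L) paste0("+", if (chg > 1L) chg else "") else "",
         if (chg < 0L) paste0("-", if (chg < -1L) -chg else "") else "",
         "]")
}

# aromatic bonds are implicit between lowercase atoms; kekulized orders are
# only spelled out on non-aromatic bonds
bond_token <- function(order, arom = FALSE) {
  if (arom) "" else switch(order, "", "=", "#")
}

#' Write a SMILES string from a molecular graph
#'
#' Emits a kekulized SMILES by depth-first traversal. With `randomize = TRUE`
#' the traversal root and neighbor order are drawn from R's random number
#' stream, producing the randomized SMILES enumerations used for data
#' augmentation; the emitted string always canonicalizes back to the
#' molecule's canonical form. `stereo` assigns tetrahedral symbols
#' (`"@"`/`"@@"`) to atom indices, which is how stereoisomers are enumerated.
#'
#' @param mol A `molecule`.
#' @param randomize Randomize traversal (uses the current RNG state).
#' @param stereo Optional named character vector mapping atom index to
#'   `"@"` or `"@@"`.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol, randomize = FALSE, stereo = NULL) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  bl <- bond_lookup(mol)
  comp_out <- character(0)
  visited <- logical(n)

  # ring-closure bookkeeping
  ring_digit <- 0L
  open_ring <- list()  # key "i j" -> digit
  ring_at <- vector("list", n)  # atom -> list of (digit, order)

  ## first pass per component: DFS to find spanning tree + back edges
  while (any(!visited)) {
    roots <- which(!visited)
    root <- if (randomize) roots[sample.int(length(roots), 1L)] else roots[1]

    tree_children <- vector("list", n)
    back_edges <- list()
    stack <- root
    parent <- rep(NA_integer_, n)
    seen <- logical(n)
    seen[root] <- TRUE
    order_visit <- integer(0)
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      order_visit <- c(order_visit, v)
      nbrs <- adj[[v]]
      nbrs <- nbrs[!is.na(nbrs)]
      if (randomize && length(nbrs) > 1L) nbrs <- sample(nbrs)
      for (w in nbrs) {
        if (!seen[w]) {
          seen[w] <- TRUE
          parent[w] <- v
          tree_children[[v]] <- c(tree_children[[v]], w)
          stack <- c(stack, w)
        } else if (!identical(parent[v], w)) {
          k <- paste(min(v, w), max(v, w))
          if (is.null(open_ring[[k]])) {
            ring_digit <- ring_digit + 1L
            open_ring[[k]] <- ring_digit
            bd <- get_bond(bl, v, w)
            ring_at[[v]] <- c(ring_at[[v]], list(list(d = ring_digit,
                                                      o = bd$order,
                                                      ar = bd$arom)))
            ring_at[[w]] <- c(ring_at[[w]], list(list(d = ring_digit,
                                                      o = bd$order,
                                                      ar = bd$arom)))
          }
        }
      }
    }
    # DFS stack gives reversed child order; re-reverse for stable output
    tree_children <- lapply(tree_children, rev)

    emit <- function(v, incoming_bond) {
      out <- if (is.null(incoming_bond)) "" else
        bond_token(incoming_bond$order, incoming_bond$arom)
      out <- paste0(out, atom_token(mol, v, stereo))
      for (rc in ring_at[[v]]) {
        d <- rc$d
        tok <- if (d > 9L) paste0("%", d) else as.character(d)
        out <- paste0(out, bond_token(rc$o, rc$ar), tok)
        # bond symbol on the opening side only is sufficient; emitting on
        # both sides is also legal SMILES, so keep it simple and symmetric
      }
      kids <- tree_children[[v]]
      if (length(kids) > 0L) {
        for (i in seq_along(kids)) {
          w <- kids[i]
          inner <- emit(w, get_bond(bl, v, w))
          if (i < length(kids)) {
            out <- paste0(out, "(", inner, ")")
          } else {
            out <- paste0(out, inner)
          }
        }
      }
      out
    }
    comp_out <- c(comp_out, emit(root, NULL))
    visited[seen] <- TRUE
  }
  paste(comp_out, collapse = ".")
}

#' Randomized SMILES enumerations of a molecule
#'
#' @param mol A `molecule` or SMILES.
#' @param n Number of strings to draw (duplicates possible for small
#'   molecules).
#' @return Character vector of SMILES, each canonicalizing to the input.
#' @export
randomized_smiles <- function(mol, n = 10L) {
  mol <- as_molecule(mol)
  vapply(seq_len(n), function(i) write_smiles(mol, randomize = TRUE),
         character(1))
}
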