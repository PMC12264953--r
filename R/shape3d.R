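## 3D scoring backend: conformer ensembles (deterministic OpenBabel embedding
## + seeded torsion sampling + MMFF94 minimization) and rigid-overlay scoring
## with Gaussian volume "shape" and typed pharmacophore "color" similarity.
## The backend contract is behavioral: scores live in [0, 1], self-overlay
## scores 1, and scores are invariant to rigid motion of the probe pose --
## any scorer satisfying the contract can be swapped in via
## `reward_config(score3d_fun = ...)`.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable is required for 3D scoring ",
                       "but was not found on PATH", call. = FALSE)
  p
}

run_obabel <- function(args) {
  out <- suppressWarnings(system2(obabel_path(), args, stdout = TRUE,
                                  stderr = FALSE))
  invisible(out)
}

## -- SDF record parsing (V2000, fixed-width fields) ---------------------------

parse_sdf_text <- function(lines) {
  recs <- list()
  start <- 1L
  delim <- which(lines == "$$$$")
  if (length(delim) == 0L) delim <- length(lines)
  for (d in delim) {
    block <- lines[start:d]
    start <- d + 1L
    if (length(block) < 5L) next
    counts <- block[4]
    n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(n_atoms) || n_atoms < 1L) next
    al <- block[5:(4 + n_atoms)]
    xyz <- cbind(as.numeric(substr(al, 1, 10)),
                 as.numeric(substr(al, 11, 20)),
                 as.numeric(substr(al, 21, 30)))
    elem <- trimws(substr(al, 32, 34))
    if (!is.na(n_bonds) && n_bonds > 0L) {
      bl <- block[(5 + n_atoms):(4 + n_atoms + n_bonds)]
      bonds <- data.frame(a1 = as.integer(substr(bl, 1, 3)),
                          a2 = as.integer(substr(bl, 4, 6)),
                          order = as.integer(substr(bl, 7, 9)))
    } else {
      bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                          order = integer(0))
    }
    charge <- parse_chg_lines(block, n_atoms)
    recs[[length(recs) + 1L]] <- list(elem = elem, xyz = xyz, bonds = bonds,
                                      charge = charge)
  }
  recs
}

conformer_from_record <- function(rec, parent_smiles = NA_character_,
                                  isomer_tag = "") {
  structure(list(elem = rec$elem, xyz = rec$xyz, bonds = rec$bonds,
                 charge = rec$charge, parent_smiles = parent_smiles,
                 isomer_tag = isomer_tag),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", sum(x$elem != "H"), " heavy + ",
      sum(x$elem == "H"), " H atoms", sep = "")
  if (nzchar(x$isomer_tag)) cat("  [", x$isomer_tag, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a reference bioactive conformer from an SDF file
#'
#' Reads the first record of an SDF file containing a 3D pose. Explicit
#' hydrogens are added (with coordinates) if absent, since donor typing
#' relies on them.
#'
#' @param path Path to an SDF file.
#' @return A `conformer` object.
#' @export
read_ref_conformer <- function(path) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  run_obabel(c(shQuote(path), "-O", shQuote(tmp), "-h"))
  recs <- parse_sdf_text(readLines(tmp, warn = FALSE))
  if (length(recs) == 0L) stop("no parseable SDF record in ", path,
                               call. = FALSE)
  conformer_from_record(recs[[1]])
}

#' Write a conformer ensemble to a multi-record SDF file
#'
#' @param conformers List of `conformer` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_conformers_sdf <- function(conformers, path) {
  out <- character(0)
  for (cf in conformers) {
    n_a <- length(cf$elem)
    n_b <- nrow(cf$bonds)
    rec <- c(cf$isomer_tag, " scaffhop", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b))
    for (i in seq_len(n_a)) {
      rec <- c(rec, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        cf$xyz[i, 1], cf$xyz[i, 2], cf$xyz[i, 3], cf$elem[i]))
    }
    for (i in seq_len(n_b)) {
      rec <- c(rec, sprintf("%3d%3d%3d  0  0  0  0", cf$bonds$a1[i],
                            cf$bonds$a2[i], cf$bonds$order[i]))
    }
    chg <- which(cf$charge != 0L)
    for (i in chg) rec <- c(rec, sprintf("M  CHG  1 %3d %3d", i,
                                         cf$charge[i]))
    out <- c(out, rec, "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

## -- stereoisomer enumeration -------------------------------------------------

#' Enumerate tetrahedral stereoisomers
#'
#' Detects potential tetrahedral stereocenters (sp3 carbons with four
#' distinct substituent branches) and enumerates all assignments; a molecule
#' without centers maps to itself. At most `max_centers` centers are
#' enumerated (2^k growth); double-bond geometry is not enumerated.
#'
#' @param mol A `molecule` or SMILES.
#' @param max_centers Enumeration cap.
#' @return Character vector of SMILES, one per stereoisomer.
#' @export
enumerate_stereoisomers <- function(mol, max_centers = 5L) {
  mol <- as_molecule(mol)
  centers <- stereocenter_indices(mol)
  if (length(centers) == 0L) return(mol$smiles)
  centers <- centers[seq_len(min(length(centers), max_centers))]
  k <- length(centers)
  grid <- expand.grid(rep(list(c("@", "@@")), k), stringsAsFactors = FALSE)
  out <- vapply(seq_len(nrow(grid)), function(r) {
    st <- stats::setNames(unlist(grid[r, ]), as.character(centers))
    write_smiles(mol, stereo = st)
  }, character(1))
  unique(out)
}

## -- conformer generation -----------------------------------------------------

# Base 3D embedding. The OpenBabel builder's rotor search is not seedable,
# so embeddings are cached per SMILES: within a session, repeated ensemble
# generation for the same structure is reproducible. Torsion sampling on top
# of the base pose is driven by R's seeded RNG.
.embed_cache <- new.env(parent = emptyenv())

embed_3d <- function(smiles) {
  key <- paste0("e3d:", smiles)
  hit <- .embed_cache[[key]]
  if (!is.null(hit)) return(if (isFALSE(hit)) NULL else hit)
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)))
  writeLines(smiles, smi)
  run_obabel(c(shQuote(smi), "-O", shQuote(sdf), "--gen3d"))
  recs <- if (file.exists(sdf)) parse_sdf_text(readLines(sdf, warn = FALSE))
          else list()
  rec <- if (length(recs) == 0L) NULL else recs[[1]]
  if (!is.null(rec) && all(abs(rec$xyz) < 1e-8)) rec <- NULL
  .embed_cache[[key]] <- if (is.null(rec)) FALSE else rec
  rec
}

# rotatable torsions in an embedded structure: non-ring single bonds between
# heavy atoms that each carry at least one further heavy neighbor
find_torsions <- function(rec) {
  heavy <- rec$elem != "H"
  b <- rec$bonds
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(rec$elem)) {
    g <- igraph::add_vertices(g, length(rec$elem) - igraph::vcount(g))
  }
  br <- as.integer(igraph::bridges(g))
  deg_h <- vapply(seq_along(rec$elem), function(i) {
    nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    sum(heavy[nb])
  }, integer(1))
  cand <- which(b$order == 1L & seq_len(nrow(b)) %in% br &
                  heavy[b$a1] & heavy[b$a2] &
                  deg_h[b$a1] > 1L & deg_h[b$a2] > 1L)
  lapply(cand, function(i) {
    # far side of the bond = atoms disconnected from a1 when the bond is cut
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(b$a1[i], b$a2[i])))
    comp <- igraph::components(g2)$membership
    list(a = b$a1[i], b = b$a2[i],
         moving = which(comp == comp[b$a2[i]]))
  })
}

rotate_about_axis <- function(xyz, p0, axis, theta) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) return(xyz)
  k <- axis / nrm
  v <- sweep(xyz, 2, p0)
  cosb <- cos(theta); sinb <- sin(theta)
  vk <- v %*% k
  rot <- v * cosb +
    cbind(k[2] * v[, 3] - k[3] * v[, 2],
          k[3] * v[, 1] - k[1] * v[, 3],
          k[1] * v[, 2] - k[2] * v[, 1]) * sinb +
    outer(as.vector(vk), k) * (1 - cosb)
  sweep(rot, 2, -p0)
}

has_clash <- function(rec, min_dist = 0.75) {
  heavy <- which(rec$elem != "H")
  if (length(heavy) < 2L) return(FALSE)
  d <- as.matrix(stats::dist(rec$xyz[heavy, , drop = FALSE]))
  bonded <- matrix(FALSE, length(heavy), length(heavy))
  idx <- match(seq_along(rec$elem), heavy)
  for (i in seq_len(nrow(rec$bonds))) {
    a <- idx[rec$bonds$a1[i]]; b2 <- idx[rec$bonds$a2[i]]
    if (!is.na(a) && !is.na(b2)) bonded[a, b2] <- bonded[b2, a] <- TRUE
  }
  diag(d) <- Inf
  d[bonded] <- Inf
  min(d) < 1.5  # non-bonded heavy atoms closer than 1.5 A = clash
}

#' Generate a geometry-optimized conformer ensemble
#'
#' For each enumerated stereoisomer: a deterministic 3D embedding, followed
#' by seeded random torsion sampling of the rotatable bonds and MMFF94
#' minimization of every pose. Macrocyclic molecules (any smallest ring of
#' `macrocycle_min_ring` atoms or more) are excluded from 3D scoring and
#' yield an empty ensemble with a reason attribute; embedding failures yield
#' an empty ensemble.
#'
#' @param mol A `molecule` or SMILES.
#' @param max_n Maximum conformers per stereoisomer (default 32).
#' @param seed RNG seed for torsion sampling (default 42).
#' @param cfg Optional [reward_config()] for the macrocycle threshold.
#' @return List of `conformer` objects (possibly empty; see attribute
#'   `reason`).
#' @export
generate_conformers <- function(mol, max_n = 32L, seed = 42L, cfg = NULL) {
  mol <- as_molecule(mol)
  min_ring <- if (!is.null(cfg)) cfg$macrocycle_min_ring else 10L
  if (max_min_ring_size(mol) >= min_ring) {
    return(structure(list(), reason = "macrocycle"))
  }
  isomers <- enumerate_stereoisomers(mol)
  out <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (tag_i in seq_along(isomers)) {
    base <- embed_3d(isomers[tag_i])
    if (is.null(base)) next
    tors <- find_torsions(base)
    poses <- list(base)
    if (length(tors) > 0L) {
      tries <- 0L
      while (length(poses) < max_n && tries < max_n * 4L) {
        tries <- tries + 1L
        rec <- base
        for (t in tors) {
          theta <- sample(c(-120, -60, 60, 120, 180), 1L) * pi / 180 +
            stats::runif(1, -0.26, 0.26)
          rec$xyz <- {
            xyz <- rec$xyz
            moved <- rotate_about_axis(
              xyz[t$moving, , drop = FALSE], xyz[t$a, ],
              xyz[t$b, ] - xyz[t$a, ], theta)
            xyz[t$moving, ] <- moved
            xyz
          }
        }
        if (!has_clash(rec)) poses[[length(poses) + 1L]] <- rec
      }
    }
    poses <- poses[seq_len(min(length(poses), max_n))]
    poses <- minimize_poses(poses)
    for (p in poses) {
      out[[length(out) + 1L]] <- conformer_from_record(
        p, parent_smiles = mol$smiles, isomer_tag = paste0("iso", tag_i))
    }
  }
  out
}

minimize_poses <- function(recs) {
  if (length(recs) == 0L) return(recs)
  confs <- lapply(recs, conformer_from_record)
  inp <- tempfile(fileext = ".sdf")
  outp <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(inp, outp)))
  write_conformers_sdf(confs, inp)
  run_obabel(c(shQuote(inp), "-O", shQuote(outp), "--minimize",
               "--ff", "MMFF94", "--steps", "250"))
  mini <- if (file.exists(outp)) parse_sdf_text(readLines(outp, warn = FALSE))
          else list()
  if (length(mini) != length(recs)) return(recs)  # fall back to unminimized
  mini
}

## -- pharmacophore features ---------------------------------------------------

.vdw_radius <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                 B = 1.92, Si = 2.10, Se = 1.90)

conformer_rings <- function(cf) {
  b <- cf$bonds
  if (nrow(b) == 0L) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(cf$elem)) {
    g <- igraph::add_vertices(g, length(cf$elem) - igraph::vcount(g))
  }
  mst <- igraph::mst(g)
  extra <- igraph::difference(g, mst)
  el <- igraph::as_edgelist(extra)
  rings <- list()
  if (nrow(el) > 0L) {
    for (i in seq_len(nrow(el))) {
      path <- igraph::shortest_paths(mst, from = el[i, 1],
                                     to = el[i, 2])$vpath[[1]]
      rings[[length(rings) + 1L]] <- as.integer(path)
    }
  }
  rings
}

# Rule-based typing on the 3D structure; explicit hydrogens expected.
conformer_features <- function(cf) {
  elem <- cf$elem
  heavy <- which(elem != "H")
  b <- cf$bonds
  nbrs <- function(i) c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  has_h <- vapply(seq_along(elem), function(i) any(elem[nbrs(i)] == "H"),
                  logical(1))
  types <- character(0)
  pos <- matrix(numeric(0), ncol = 3)
  add <- function(t, p) {
    types <<- c(types, t)
    pos <<- rbind(pos, p)
  }
  dbl <- unique(c(b$a1[b$order == 2L], b$a2[b$order == 2L]))
  for (i in heavy) {
    e <- elem[i]
    nb <- nbrs(i)
    nb_heavy <- nb[elem[nb] != "H"]
    if (e %in% c("N", "O")) {
      if (has_h[i] && cf$charge[i] <= 0L) add("donor", cf$xyz[i, ])
      if (cf$charge[i] <= 0L && !(e == "N" && length(nb_heavy) > 2L)) {
        add("acceptor", cf$xyz[i, ])
      }
    }
    if (cf$charge[i] > 0L) add("cation", cf$xyz[i, ])
    if (cf$charge[i] < 0L) add("anion", cf$xyz[i, ])
    if (e %in% c("C", "S", "Cl", "Br", "I", "F")) {
      polar_nb <- any(elem[nb_heavy] %in% c("N", "O")) ||
        any(cf$charge[nb_heavy] != 0L)
      if (!polar_nb && !(i %in% dbl)) add("hydrophobe", cf$xyz[i, ])
    }
  }
  # aromatic-like rings: 5/6-rings whose atoms are all unsaturated or O/N/S
  for (ring in conformer_rings(cf)) {
    if (!(length(ring) %in% c(5L, 6L))) next
    sp2ish <- vapply(ring, function(i) {
      i %in% dbl || elem[i] %in% c("N", "O", "S")
    }, logical(1))
    if (all(sp2ish)) add("ring", colMeans(cf$xyz[ring, , drop = FALSE]))
  }
  list(types = types, pos = pos)
}

## -- Gaussian overlap scoring -------------------------------------------------

# Grant-Pickup style first-order Gaussian volume overlap between two sets of
# heavy atoms.
.gp_p <- 2.7
.gp_kappa <- 2.41798793102

gaussian_overlap <- function(xyz_a, alpha_a, xyz_b, alpha_b) {
  if (nrow(xyz_a) == 0L || nrow(xyz_b) == 0L) return(0)
  aa <- outer(alpha_a, alpha_b, "+")
  prod_ab <- outer(alpha_a, alpha_b, "*")
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * xyz_a %*% t(xyz_b)
  sum(.gp_p^2 * (pi / aa)^1.5 * exp(-(prod_ab / aa) * d2))
}

atom_alphas <- function(elem) {
  r <- unname(.vdw_radius[elem])
  r[is.na(r)] <- 1.7
  .gp_kappa / r^2
}

shape_tanimoto <- function(xyz_p, al_p, xyz_r, al_r, o_pp = NULL,
                           o_rr = NULL) {
  o_pr <- gaussian_overlap(xyz_p, al_p, xyz_r, al_r)
  if (is.null(o_pp)) o_pp <- gaussian_overlap(xyz_p, al_p, xyz_p, al_p)
  if (is.null(o_rr)) o_rr <- gaussian_overlap(xyz_r, al_r, xyz_r, al_r)
  max(0, min(1, o_pr / (o_pp + o_rr - o_pr)))
}

.color_sigma <- 1.0

color_tanimoto <- function(feat_p, feat_r, pos_p = NULL) {
  if (is.null(pos_p)) pos_p <- feat_p$pos
  if (length(feat_p$types) == 0L && length(feat_r$types) == 0L) return(1)
  if (length(feat_p$types) == 0L || length(feat_r$types) == 0L) return(0)
  al <- .gp_kappa / .color_sigma^2
  types <- union(feat_p$types, feat_r$types)
  o_pr <- o_pp <- o_rr <- 0
  for (t in types) {
    ip <- feat_p$types == t
    ir <- feat_r$types == t
    if (any(ip)) {
      o_pp <- o_pp + gaussian_overlap(pos_p[ip, , drop = FALSE],
                                      rep(al, sum(ip)),
                                      pos_p[ip, , drop = FALSE],
                                      rep(al, sum(ip)))
    }
    if (any(ir)) {
      o_rr <- o_rr + gaussian_overlap(feat_r$pos[ir, , drop = FALSE],
                                      rep(al, sum(ir)),
                                      feat_r$pos[ir, , drop = FALSE],
                                      rep(al, sum(ir)))
    }
    if (any(ip) && any(ir)) {
      o_pr <- o_pr + gaussian_overlap(pos_p[ip, , drop = FALSE],
                                      rep(al, sum(ip)),
                                      feat_r$pos[ir, , drop = FALSE],
                                      rep(al, sum(ir)))
    }
  }
  max(0, min(1, o_pr / (o_pp + o_rr - o_pr)))
}

rotation_from_vec <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

principal_axes <- function(xyz) {
  c0 <- colMeans(xyz)
  xc <- sweep(xyz, 2, c0)
  if (nrow(xc) < 3L) return(diag(3))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  ev
}

starting_rotations <- function(xyz_p, xyz_r, n_starts = 10L) {
  ap <- principal_axes(xyz_p)
  ar <- principal_axes(xyz_r)
  base <- ar %*% t(ap)
  flips <- list(diag(c(1, 1, 1)), diag(c(1, -1, -1)),
                diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  rots <- lapply(flips, function(f) ar %*% f %*% t(ap))
  extra <- list(c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2),
                c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))
  for (e in extra) rots[[length(rots) + 1L]] <- rotation_from_vec(e) %*% base
  rots[seq_len(min(length(rots), max(1L, n_starts)))]
}

#' Rigidly align a probe conformer to a reference and score the overlay
#'
#' The probe is rigidly rotated/translated to maximize the weighted
#' combination of Gaussian-volume shape similarity and typed pharmacophore
#' ("color") similarity, starting from principal-axes alignments. Both
#' similarities are overlap Tanimotos in `[0, 1]`; the conformer score is
#' their weighted mean `rho = (S_S * w_s + S_C * w_c) / (w_s + w_c)`.
#'
#' @param probe,ref `conformer` objects; `ref` is the fixed bioactive pose.
#' @param cfg A [reward_config()] supplying `w_s`, `w_c` and `align_starts`.
#' @return List with `shape`, `color` and `rho`.
#' @export
align_and_score <- function(probe, ref, cfg = reward_config()) {
  stopifnot(inherits(probe, "conformer"), inherits(ref, "conformer"))
  if (length(probe$elem) == 0L) stop("empty probe conformer", call. = FALSE)
  hp <- probe$elem != "H"
  hr <- ref$elem != "H"
  xyz_p0 <- probe$xyz[hp, , drop = FALSE]
  xyz_r <- ref$xyz[hr, , drop = FALSE]
  al_p <- atom_alphas(probe$elem[hp])
  al_r <- atom_alphas(ref$elem[hr])
  cen_p <- colMeans(xyz_p0)
  cen_r <- colMeans(xyz_r)
  xyz_p0 <- sweep(xyz_p0, 2, cen_p)
  xyz_rc <- sweep(xyz_r, 2, cen_r)

  feat_p <- conformer_features(probe)
  feat_r <- conformer_features(ref)
  fp0 <- if (length(feat_p$types)) sweep(feat_p$pos, 2, cen_p) else
    feat_p$pos
  feat_rc <- feat_r
  if (length(feat_r$types)) feat_rc$pos <- sweep(feat_r$pos, 2, cen_r)

  o_pp <- gaussian_overlap(xyz_p0, al_p, xyz_p0, al_p)
  o_rr <- gaussian_overlap(xyz_rc, al_r, xyz_rc, al_r)

  objective <- function(par) {
    R <- rotation_from_vec(par[1:3])
    t0 <- par[4:6]
    xp <- sweep(xyz_p0 %*% t(R), 2, -t0)
    s <- shape_tanimoto(xp, al_p, xyz_rc, al_r, o_pp, o_rr)
    cpos <- if (length(feat_p$types)) sweep(fp0 %*% t(R), 2, -t0) else fp0
    co <- color_tanimoto(feat_p, feat_rc, pos_p = cpos)
    -(cfg$w_s * s + cfg$w_c * co)
  }

  best <- NULL
  for (R0 in starting_rotations(xyz_p0, xyz_rc, cfg$align_starts)) {
    # axis-angle vector of the starting rotation
    tr <- (sum(diag(R0)) - 1) / 2
    theta <- acos(max(-1, min(1, tr)))
    v0 <- if (theta < 1e-8) c(0, 0, 0) else {
      ax <- c(R0[3, 2] - R0[2, 3], R0[1, 3] - R0[3, 1], R0[2, 1] - R0[1, 2])
      nax <- sqrt(sum(ax^2))
      if (nax < 1e-8) c(theta, 0, 0) else ax / nax * theta
    }
    fit <- stats::optim(c(v0, 0, 0, 0), objective, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-7))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  R <- rotation_from_vec(best$par[1:3])
  t0 <- best$par[4:6]
  xp <- sweep(xyz_p0 %*% t(R), 2, -t0)
  shape <- shape_tanimoto(xp, al_p, xyz_rc, al_r, o_pp, o_rr)
  cpos <- if (length(feat_p$types)) sweep(fp0 %*% t(R), 2, -t0) else fp0
  color <- color_tanimoto(feat_p, feat_rc, pos_p = cpos)
  list(shape = shape, color = color,
       rho = (shape * cfg$w_s + color * cfg$w_c) / (cfg$w_s + cfg$w_c))
}

#' 3D reward: best conformer over the whole ensemble
#'
#' Generates the conformer ensemble of a design (all stereoisomers) and
#' returns the maximal conformer score `rho` against the reference pose --
#' the greedy "no hits lost" choice. An empty ensemble (macrocycle or
#' embedding failure) scores 0.
#'
#' @param mol A `molecule` or SMILES.
#' @param ref Reference `conformer`.
#' @param cfg A [reward_config()].
#' @return `S_3D` in `[0, 1]`.
#' @export
best_conformer_score <- function(mol, ref, cfg = reward_config()) {
  mol <- as_molecule(mol)
  ens <- generate_conformers(mol, max_n = cfg$max_conformers_per_isomer,
                             seed = cfg$conformer_seed, cfg = cfg)
  if (length(ens) == 0L) return(0)
  max(vapply(ens, function(cf) align_and_score(cf, ref, cfg)$rho,
             numeric(1)))
}

#' Apply a rigid-body transform to a conformer
#'
#' Utility for invariance testing and pose manipulation.
#'
#' @param cf A `conformer`.
#' @param rot 3x3 rotation matrix.
#' @param trans Length-3 translation vector.
#' @return The transformed `conformer`.
#' @export
transform_conformer <- function(cf, rot = diag(3), trans = c(0, 0, 0)) {
  cf$xyz <- sweep(cf$xyz %*% t(rot), 2, -trans)
  cf
}
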