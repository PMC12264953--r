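# The fuzzy decoration-matching decomposition algorithm.

test_that("size bounds reproduce the fuzzy decoration window", {
  sb <- size_bounds(10, 0.8)
  expect_equal(sb$m_r, 8)
  expect_equal(sb$M_r, 12.5)
  expect_equal(range(sb$permitted_sizes), c(8L, 12L))

  sb1 <- size_bounds(5, 1.0)
  expect_equal(sb1$m_r, 5)
  expect_equal(sb1$M_r, 5)
  expect_equal(sb1$permitted_sizes, 5L)

  expect_equal(size_bounds(6, 0.9)$permitted_sizes, 6L)
  expect_error(size_bounds(5, 0))
  expect_error(size_bounds(5, 1.2))
})

test_that("fuzzy matching honors the attachment conditions", {
  et <- decoration("*CC")
  m <- fuzzy_match("CCc1ccc(CN)cc1", et, alpha = 1)
  expect_false(is.null(m))
  expect_equal(m$n_d, 2L)
  expect_true(m$dummy_partner_index %in%
                which(parse_molecule("CCc1ccc(CN)cc1")$atoms$in_ring))

  # substructure absent
  expect_null(fuzzy_match("c1ccccc1", et, alpha = 1))
  # dummy partner would have degree <= 1
  expect_null(fuzzy_match("CC", et, alpha = 1))
  # atoms already claimed are not rematched
  used <- m$fragment_atoms
  expect_null(fuzzy_match("CCc1ccc(CN)cc1", et, used_atoms = used,
                          alpha = 1))
})

test_that("peripheral selection prefers the outermost placement", {
  et <- decoration("*CC")
  # symmetric para-diethylbenzene: deterministic tie-break
  cands <- fuzzy_match("CCc1ccc(CC)cc1", et, alpha = 1, all = TRUE)
  expect_gte(length(cands), 2L)
  sel <- select_peripheral(cands, "CCc1ccc(CC)cc1")
  tie <- vapply(cands, function(x) min(x$matched_atom_indices), integer(1))
  expect_equal(min(sel$matched_atom_indices), min(tie))

  # hexane: the terminal ethyl leaves more atoms on the scaffold side
  selh <- fuzzy_match("CCCCCC", et, alpha = 1)
  expect_equal(selh$n_d, 2L)
  expect_true(all(selh$fragment_atoms %in% c(1L, 2L, 5L, 6L)))
})

test_that("cleavage yields two valid fragments and fails on ring bonds", {
  et <- decoration("*CC")
  m <- fuzzy_match("CCc1ccc(CN)cc1", et, alpha = 1)
  cl <- cleave("CCc1ccc(CN)cc1", m)
  expect_equal(cl$n_d, 2L)
  expect_equal(cl$fragment$smiles, canonicalize("CC"))
  expect_equal(cl$remainder$n_heavy, 8L)

  # a cut inside the ring cannot split the molecule in two
  benz <- parse_molecule("c1ccccc1")
  fake <- list(attachment_image = 1L, dummy_partner_index = 2L)
  expect_null(cleave(benz, fake))
})

test_that("full decomposition returns the success score and scaffold", {
  decs <- list(decoration("*CC"), decoration("*CN"))
  fs <- find_scaffold("CCc1ccc(CN)cc1", decs, alpha = 0.9)
  expect_equal(fs$success_score, 1)
  expect_equal(fs$scaffold$smiles, canonicalize("*c1ccc(*)cc1"))
  expect_equal(sum(fs$scaffold$atoms$is_dummy), 2L)

  part <- find_scaffold("CCc1ccc(CN)cc1",
                        list(decoration("*CC"), decoration("*C(=O)O")))
  expect_equal(part$success_score, 0.5)
  expect_null(part$scaffold)

  none <- find_scaffold("c1ccccc1", decs)
  expect_equal(none$success_score, 0)
})

test_that("constructed designs reconstruct their scaffold exactly", {
  task <- shared_task()
  for (s in task$positive_designs) {
    fs <- find_scaffold(s, task$decorations, alpha = 1)
    expect_equal(fs$success_score, 1)
    expect_false(is.null(fs$scaffold))
    expect_equal(sum(fs$scaffold$atoms$is_dummy), length(task$decorations))
    # scaffold + fragments partition the design atoms
    frag_atoms <- unlist(lapply(fs$matches, function(m) m$fragment_atoms))
    expect_equal(anyDuplicated(frag_atoms), 0L)
    expect_equal(fs$scaffold$n_heavy + length(frag_atoms),
                 fs$design$n_heavy)
  }
})

test_that("success score is monotone non-increasing in alpha", {
  task <- shared_task()
  designs <- c(task$positive_designs[1:6], task$partial_designs[1:6],
               "CCCCc1ccc(CN)cc1", "CCCc1ccc(CCN)cc1")
  alphas <- c(1, 0.9, 0.7, 0.5, 0.3)
  for (s in designs) {
    ss <- vapply(alphas, function(a) {
      find_scaffold(s, task$decorations, alpha = a)$success_score
    }, numeric(1))
    expect_true(all(diff(ss) >= -1e-12),
                info = paste("alpha monotonicity violated for", s))
  }
})

test_that("the reference self-decomposes to the reference scaffold", {
  task <- shared_task()
  fs <- find_scaffold(task$reference, task$decorations, alpha = 1)
  expect_equal(fs$success_score, 1)
  expect_equal(fs$scaffold$smiles, canonicalize("*c1ccc(*)cc1"))
})

test_that("decorations are read from SMILES files", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("*CC ethyl", "[*]CN aminomethyl", "# comment"), f)
  decs <- read_decorations(f)
  expect_length(decs, 2L)
  expect_equal(decs[[1]]$n_r, 2L)
  expect_error(decoration("CC"))       # no dummy
  expect_error(decoration("*C*"))      # two dummies
})
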