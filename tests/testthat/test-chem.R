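# Chemistry primitives: canonicalization, fingerprints, frameworks,
# descriptors.

test_that("canonicalization parses valid molecules and rejects garbage", {
  m <- parse_molecule("c1ccccc1")
  expect_s3_class(m, "molecule")
  expect_equal(m$n_heavy, 6L)
  expect_true(all(m$atoms$arom))

  expect_true(is.na(canonicalize("C1CC")))      # unclosed ring
  expect_true(is.na(canonicalize("")))
  expect_true(is.na(canonicalize("not smiles")))
  expect_true(is.na(canonicalize("C(C)(C)(C)(C)C")))  # pentavalent carbon
  expect_true(is.na(canonicalize("[NH5]")))
})

test_that("canonicalization is idempotent across the fixture pool", {
  pool <- head(fixture_smiles_pool(), 100)
  for (s in pool) {
    can <- canonicalize(s)
    expect_false(is.na(can))
    expect_identical(canonicalize(can), can)
  }
})

test_that("fingerprints are canonical-structure invariants", {
  a <- ecfp("CCc1ccc(CN)cc1")
  b <- ecfp("NCc1ccc(cc1)CC")   # same molecule, permuted atom order
  expect_identical(a$on_bits, b$on_bits)
  expect_equal(a$radius, 3L)
  expect_equal(a$nbits, 2048L)
  expect_true(length(a$on_bits) > 0)
  expect_true(all(a$on_bits >= 0 & a$on_bits < 2048))

  # dummies participate symmetrically in scaffold fingerprints
  s1 <- ecfp("*c1ccc(*)cc1")
  s2 <- ecfp("*c1ccc(cc1)*")
  expect_identical(s1$on_bits, s2$on_bits)

  expect_gt(length(ecfp("C")$on_bits), 0)  # even methane has bits
})

test_that("Jaccard distance matches set arithmetic and is a metric", {
  expect_equal(jaccard_distance(as_fp(c(1, 2, 3)), as_fp(c(2, 3, 4))), 0.5)
  expect_equal(jaccard_distance(as_fp(1:5), as_fp(1:5)), 0)
  expect_equal(jaccard_distance(as_fp(1:3), as_fp(4:6)), 1)
  expect_error(jaccard_distance(as_fp(integer(0)), as_fp(integer(0))))

  set.seed(11)
  for (i in 1:40) {
    a <- as_fp(random_bitset(sample(1:10, 1)))
    b <- as_fp(random_bitset(sample(1:10, 1)))
    cc <- as_fp(random_bitset(sample(1:10, 1)))
    dab <- jaccard_distance(a, b)
    expect_equal(dab, jaccard_distance(b, a))           # symmetry
    expect_true(dab >= 0 && dab <= 1)
    expect_lte(jaccard_distance(a, cc),
               dab + jaccard_distance(b, cc) + 1e-12)   # triangle
    expect_equal(jaccard_distance(a, a), 0)             # identity
  }
})

test_that("Bemis-Murcko frameworks prune side chains", {
  expect_equal(bm_framework("Cc1ccccc1")$framework_smiles, "c1ccccc1")
  expect_equal(bm_framework("CCCCCC")$cyclic_class,
               "no cyclic substructure(s)")
  expect_equal(bm_framework("CCc1ccccc1")$cyclic_class,
               bm_framework("Cc1ccccc1")$cyclic_class)
  # idempotence: the framework of a framework is itself
  fw <- bm_framework("CCc1ccc(CN)cc1")$framework_smiles
  expect_equal(bm_framework(fw)$framework_smiles, fw)
})

test_that("descriptors match hand-computed values", {
  p <- properties("O")
  expect_equal(p$molecular_weight, 18.02, tolerance = 1e-3)
  expect_equal(properties("CCCC")$rotatable_bonds, 1L)
  pb <- properties("c1ccccc1")
  expect_equal(pb$rotatable_bonds, 0L)
  expect_equal(pb$stereocenters, 0L)
  expect_equal(properties("CC(N)C(O)CC")$stereocenters, 2L)
})

test_that("SMILES emission round-trips through canonicalization", {
  set.seed(5)
  pool <- head(fixture_smiles_pool(), 40)
  for (s in pool) {
    m <- parse_molecule(s)
    for (k in 1:3) {
      r <- write_smiles(m, randomize = TRUE)
      expect_identical(canonicalize(r), m$smiles)
    }
  }
})
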