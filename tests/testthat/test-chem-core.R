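test_that("canonicalization maps equal molecules to equal strings and is idempotent", {
  expect_identical(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  expect_identical(canonicalize(canonicalize(BIPHENYL)), canonicalize(BIPHENYL))
  # kekulized and aromatic notations of several fixture-style molecules agree
  pairs <- list(
    c("c1ccncc1", "C1=CC=NC=C1"),
    c("Cc1ccccc1", "CC1=CC=CC=C1")
  )
  for (p in pairs) expect_identical(canonicalize(p[1]), canonicalize(p[2]))
  expect_error(canonicalize("not_a_smiles"), "parse")
  # vectorized and order-preserving
  v <- canonicalize(c("c1ccccc1", "c1ccncc1"))
  expect_length(v, 2L)
  expect_false(v[1] == v[2])
})

test_that("aromatic C-H site inventory matches known molecules and the SMARTS count", {
  expect_length(aromatic_ch_sites(BENZENE), 6L)
  expect_length(aromatic_ch_sites(BIPHENYL), 10L)
  expect_length(aromatic_ch_sites(PYRIDINE), 5L)
  expect_length(aromatic_ch_sites(TOLUENE), 5L)
  # cross-check against Open Babel's aromaticity perception on library molecules
  smiles <- library_smiles(toy_library())[1:40]
  mine <- vapply(smiles, function(s) length(aromatic_ch_sites(s)), numeric(1))
  ob <- tadfscreen:::ob_smarts_count(smiles, "[cH]")
  expect_equal(unname(mine), as.numeric(ob))
})

test_that("mean aromatic C-H count is the arithmetic mean over the library", {
  expect_equal(mean_aromatic_ch(c(BENZENE, BIPHENYL)), 8.0)
  expect_equal(mean_aromatic_ch(BENZENE), 6.0)
  # 4:1 biphenyl/benzene mixture
  expect_equal(mean_aromatic_ch(c(rep(BIPHENYL, 4), BENZENE)), 9.2)
  expect_error(mean_aromatic_ch(character(0)), "empty")
})

test_that("fingerprints are deterministic, binary and structure-sensitive", {
  f <- fingerprint(c(BENZENE, BENZENE, BIPHENYL))
  expect_equal(dim(f), c(3L, 2048L))
  expect_true(all(f %in% c(0L, 1L)))
  expect_identical(f[1, ], f[2, ])
  expect_gt(sum(f[1, ] != f[3, ]), 0L)
  expect_gt(sum(f[1, ]), 0L)
  expect_identical(f[3, ], fingerprint(BIPHENYL)[1, ])
})

test_that("tanimoto similarity has the set-overlap semantics", {
  v <- c(1, 0, 1, 1, 0)
  expect_equal(tanimoto(v, v), 1.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(numeric(4), numeric(4)), 0.0)  # empty vs empty
  # symmetry and bounds on random binary vectors
  set.seed(42)
  for (i in 1:20) {
    a <- rbinom(64, 1, 0.3)
    b <- rbinom(64, 1, 0.3)
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("Murcko cores strip substituents and genericize elements and bonds", {
  sk <- skeletons(TOLUENE)
  expect_identical(sk$common_core, canonicalize(BENZENE))
  expect_identical(sk$generic_core, canonicalize("C1CCCCC1"))
  # a decorated phenyl-dihydroacridine-type molecule reduces to the known
  # common/generic core pair
  sk2 <- skeletons("COc1ccc(N2c3ccccc3Nc3ccccc32)cc1C#N")
  expect_identical(sk2$common_core, canonicalize("c1ccc(N2c3ccccc3Nc3ccccc32)cc1"))
  expect_identical(sk2$generic_core,
                   canonicalize("C1CCC(C2C3CCCCC3CC3CCCCC32)CC1"))
  # scaffolds are scaffold-stable (fixed point)
  again <- skeletons(sk2$common_core)
  expect_identical(again$common_core, sk2$common_core)
  # exocyclic double-bonded atoms on linkers are retained in the common core
  sk3 <- skeletons("Cc1ccc(S(=O)(=O)c2ccccc2)cc1")
  expect_identical(sk3$common_core, canonicalize("O=S(=O)(c1ccccc1)c1ccccc1"))
  expect_error(skeletons("CCO"), "ring")
})

test_that("skeleton frequency tables count cores and conserve molecule counts", {
  lib <- c(rep(TOLUENE, 3), "Oc1ccccc1")
  tab <- skeleton_frequencies(lib, "common")
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$core, canonicalize(BENZENE))
  expect_equal(tab$count, 4L)
  # singleton library
  tab1 <- skeleton_frequencies(BIPHENYL, "common")
  expect_equal(tab1$count, 1L)
  # acyclic molecules are skipped with a warning and recorded
  expect_warning(tab2 <- skeleton_frequencies(c(TOLUENE, "CCO"), "common"),
                 "acyclic")
  expect_equal(sum(tab2$count), 1L)
  expect_equal(attr(tab2, "n_skipped"), 1L)
})

test_that("generic cores coarsen the common-core partition on a real library", {
  smiles <- library_smiles(toy_library())[1:60]
  cores <- tadfscreen:::skeletons_batch(smiles)
  expect_false(anyNA(cores$common_core))
  # counts conserve library size
  com <- skeleton_frequencies(smiles, "common")
  gen <- skeleton_frequencies(smiles, "generic")
  expect_equal(sum(com$count), length(smiles))
  expect_equal(sum(gen$count), length(smiles))
  # every common core maps to exactly one generic core (never splits)
  map <- unique(cores[, c("common_core", "generic_core")])
  expect_false(anyDuplicated(map$common_core) > 0)
  # each generic-core count is the sum over its common-core preimages
  merged <- merge(com, map, by.x = "core", by.y = "common_core")
  sums <- tapply(merged$count, merged$generic_core, sum)
  expect_equal(sort(as.integer(sums)), sort(gen$count))
})

test_that("synthetic accessibility scores are deterministic, bounded and ordered", {
  s1 <- sas_score(BENZENE)
  expect_identical(s1, sas_score(BENZENE))
  # benzene is easier than a fused pentacyclic DA compound
  penta <- couple("[*]n1c2ccccc2c2cc(-n3c4ccccc4c4ccccc43)ccc21",
                  "[*]c1ccc2c(c1)C(=O)c1ccccc12")
  expect_lt(s1, sas_score(penta))
  # all fixture fragments (phenyl-capped) score within the 1..10 scale
  fr <- toy_fragments()
  caps <- vapply(c(fr$donors, fr$acceptors), function(f) couple(f, "[*]c1ccccc1"),
                 character(1))
  s <- sas_score(caps)
  expect_true(all(s >= 1 & s <= 10))
})
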