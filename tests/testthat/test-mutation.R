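test_that("the ten standard mutation labels carry the documented settings", {
  expect_equal(mutation_spec("Sub1")$max_sites, 1L)
  expect_equal(mutation_spec("Sub2")$max_sites, 2L)
  expect_identical(mutation_spec("Sub2")$kind, "aromatic_N_swap")
  expect_identical(mutation_spec("Sub5")$groups, "OMe")
  expect_identical(mutation_spec("Sub9")$groups, c("CN", "OMe"))
  for (lab in paste0("Sub", 3:10)) {
    expect_equal(mutation_spec(lab)$max_sites, 1L)
  }
  expect_error(mutation_spec("Sub11"), "Sub1")
})

test_that("single-site mutants are exhaustive, deduplicated and parent-free", {
  # benzene: all six sites equivalent
  expect_identical(single_site_mutants(BENZENE, mutation_spec("Sub1")),
                   canonicalize(PYRIDINE))
  expect_identical(single_site_mutants(BENZENE, mutation_spec("Sub3")),
                   canonicalize("Fc1ccccc1"))
  expect_setequal(single_site_mutants(BENZENE, mutation_spec("Sub7")),
                  canonicalize(c("Fc1ccccc1", "COc1ccccc1")))
  # pyridine: three distinct diazines
  diazines <- single_site_mutants(PYRIDINE, mutation_spec("Sub1"))
  expect_length(diazines, 3L)
  expect_setequal(diazines,
                  canonicalize(c("c1ccnnc1", "c1cncnc1", "c1cnccn1")))
  # parent never present
  expect_false(canonicalize(BENZENE) %in%
                 single_site_mutants(BENZENE, mutation_spec("Sub4")))
})

test_that("multi-site mutants equal the bitmask brute-force enumeration", {
  # benzene under the fast N mutation: pyridine + three diazines
  sub2 <- multi_site_mutants(BENZENE, mutation_spec("Sub2"))
  expect_length(sub2, 4L)
  oracle <- setdiff(bitmask_mutants_oracle(BENZENE, "N", max_sites = 2L),
                    canonicalize(BENZENE))
  expect_setequal(sub2, oracle)
  # max_sites = 1 collapses to the single-site operator
  expect_setequal(multi_site_mutants(TOLUENE, mutation_spec("Sub2"), max_sites = 1L),
                  single_site_mutants(TOLUENE, mutation_spec("Sub1")))
  # a mixed-group spec against the same oracle on a less symmetric molecule
  got <- single_site_mutants("Fc1ccccn1", mutation_spec("Sub9"))
  want <- setdiff(bitmask_mutants_oracle("Fc1ccccn1", c("CN", "OMe"), max_sites = 1L),
                  canonicalize("Fc1ccccn1"))
  expect_setequal(got, want)
})

test_that("terminal substitution consumes exactly one aromatic C-H per site", {
  parent_count <- length(aromatic_ch_sites(BIPHENYL))
  for (spec in list(mutation_spec("Sub3"), mutation_spec("Sub5"), mutation_spec("Sub6"))) {
    kids <- single_site_mutants(BIPHENYL, spec)
    for (kid in kids) {
      expect_equal(length(aromatic_ch_sites(kid)), parent_count - 1L)
    }
  }
  # the N swap also removes one site
  for (kid in single_site_mutants(BIPHENYL, mutation_spec("Sub1"))) {
    expect_equal(length(aromatic_ch_sites(kid)), parent_count - 1L)
  }
})

test_that("exhaustive subset substitution matches the independent pattern-orbit count", {
  # pyridine with F: 2^5 patterns; orbit count from the automorphism group
  got <- substitution_subsets(PYRIDINE, "F")
  expect_equal(length(got), burnside_pattern_count(PYRIDINE))
  # parent (empty subset) is included
  expect_true(canonicalize(PYRIDINE) %in% got)
  # naphthalene with F as a second, fused-ring case
  naph <- "c1ccc2ccccc2c1"
  expect_equal(length(substitution_subsets(naph, "F")),
               burnside_pattern_count(naph))
})

test_that("offspring libraries retain parents, record provenance and respect the cap", {
  parents <- mol_library(canonicalize(c(BENZENE)), generation = 0L, cap = 1000L)
  kids <- offspring_library(parents, mutation_spec("Sub3"), cap = 1000L, seed = 1L)
  expect_equal(kids$generation, 1L)
  expect_setequal(library_smiles(kids), canonicalize(c(BENZENE, "Fc1ccccc1")))
  row <- kids$records[kids$records$smiles == canonicalize("Fc1ccccc1"), ]
  expect_identical(row$parent_smiles, canonicalize(BENZENE))
  expect_identical(row$mutation_label, "Sub3")
  expect_equal(row$generation_born, 1L)
  # capped growth keeps all parents and is seed-deterministic
  base <- toy_library(cap = 60L)
  g1a <- offspring_library(base, mutation_spec("Sub3"), cap = 100L, seed = 5L)
  g1b <- offspring_library(base, mutation_spec("Sub3"), cap = 100L, seed = 5L)
  expect_lte(length(g1a), 100L)
  expect_true(all(library_smiles(base) %in% library_smiles(g1a)))
  expect_identical(library_smiles(g1a), library_smiles(g1b))
  expect_error(offspring_library(base, mutation_spec("Sub3"), cap = 10L), "cap")
})
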