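test_that("training selection is a seeded uniform sample of the stated size", {
  lib <- library_smiles(toy_library())
  s1 <- select_random_training(lib, 0.10, seed = 3L)
  s2 <- select_random_training(lib, 0.10, seed = 3L)
  s3 <- select_random_training(lib, 0.10, seed = 4L)
  expect_length(s1, floor(0.10 * length(lib)))
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(all(s1 %in% lib))
  # floor with minimum 1
  expect_length(select_random_training(lib[1:5], 0.10, seed = 1L), 1L)
  # loop-level floor for surrogate trainability
  expect_length(select_random_training(lib[1:50], 0.10, seed = 1L, min_size = 20L), 20L)
  expect_error(select_random_training(character(0), 0.1), "empty")
  expect_error(select_random_training(lib, 1.5), "fraction")
})

test_that("top-fraction selection takes the smallest gaps with deterministic ties", {
  gaps <- setNames(c(0.1, 0.5, 0.9, seq(0.2, 0.8, length.out = 7)),
                   paste0("m", 1:10))
  expect_identical(select_top_fraction(gaps, 0.10), "m1")
  # all equal: lexicographically first name wins
  eq <- setNames(rep(0.3, 5), c("d", "b", "e", "a", "c"))
  expect_identical(select_top_fraction(eq, 0.2), "a")
  # input order does not matter
  shuffled <- eq[c(3, 1, 5, 2, 4)]
  expect_identical(select_top_fraction(shuffled, 0.2), "a")
  # selection arithmetic at scale
  big <- setNames(runif(1000), sprintf("s%04d", 1:1000))
  expect_length(select_top_fraction(big, 0.10), 100L)
})

test_that("material abundance is the fraction of gaps under the threshold", {
  expect_equal(material_abundance(c(rep(0.1, 10), rep(0.5, 990))), 0.010)
  expect_equal(material_abundance(rep(0.3, 5)), 0)
  expect_equal(material_abundance(rep(0.01, 5)), 1)
  # strict inequality at the boundary
  expect_equal(material_abundance(c(0.15, 0.149)), 0.5)
  expect_error(material_abundance(numeric(0)), "empty")
})

test_that("the energy sieve partitions with green boundaries", {
  v <- c(a = 3.00, b = 2.65, c = 2.00, d = 2.80, e = 2.50, f = 2.81, g = 2.49)
  col <- energy_sieve(v)
  expect_identical(as.character(col),
                   c("blue", "green", "red", "green", "green", "blue", "red"))
  expect_equal(sum(table(col)), length(v))
})

test_that("optimal-molecule accumulation has set-union semantics", {
  acc <- accumulate_optimal(character(0),
                            setNames(c(rep(0.1, 10), rep(0.5, 10)), paste0("x", 1:20)))
  expect_length(acc, 10L)
  # re-adding the same molecules leaves the size unchanged
  acc2 <- accumulate_optimal(acc, setNames(rep(0.1, 10), paste0("x", 1:10)))
  expect_length(acc2, 10L)
  # disjoint additions are cumulative
  acc3 <- accumulate_optimal(acc2, setNames(rep(0.05, 73), paste0("y", 1:73)))
  expect_length(acc3, 83L)
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(evolution_config(select_fraction = 1.5), "select_fraction")
  expect_error(evolution_config(train_fraction = 0), "train_fraction")
  expect_error(evolution_config(sieve_blue_min_eV = 2.4, sieve_red_max_eV = 2.5),
               "sieve")
  expect_error(evolution_config(mutation = "Sub11"), "Sub1")
  cfg <- evolution_config()
  expect_equal(cfg$library_cap, 1000L)
  expect_equal(cfg$optimal_gap_threshold_eV, 0.15)
})

test_that("a short evolution run satisfies the loop invariants", {
  fr <- toy_fragments(15L, 18L, seed = 1L)
  cfg <- evolution_config(mutation = "Sub3", library_cap = 300L,
                          max_generations = 3L, seed = 1L)
  res <- run_evolution(cfg, fr)
  rep <- res$reports
  # one report per generation incl. generation 0
  expect_equal(nrow(rep), 4L)
  expect_identical(rep$n_g, 0:3)
  # sieve partitions the library
  expect_equal(rep$n_blue + rep$n_green + rep$n_red, rep$n_tot)
  # accumulated optimal count is non-decreasing
  expect_true(all(diff(rep$n_acc_opt_mols) >= 0))
  # abundance within [0, 1]; caps respected
  expect_true(all(rep$omega_MA >= 0 & rep$omega_MA <= 1))
  expect_true(all(rep$n_tot <= cfg$library_cap))
  # similarity diagnostics defined from generation 1 on
  expect_true(is.na(rep$delta_MSPR[1]))
  expect_true(all(!is.na(rep$delta_MSPR[-1])))
  expect_true(all(rep$delta_MSPR[-1] >= 0 & rep$delta_MSPR[-1] <= 1))
  # parents persist: each generation's library contains the previous top picks
  expect_true(all(vapply(seq_len(3), function(g) {
    prev <- library_smiles(res$libraries[[g]])
    cur <- library_smiles(res$libraries[[g + 1]])
    length(intersect(prev, cur)) >= 1
  }, logical(1))))
  # skeleton tables accompany every generation
  expect_length(res$skeleton_tables, 4L)
  expect_equal(sum(res$skeleton_tables[[1]]$common$count), rep$n_tot[1])
})

test_that("convergence targets stop the loop early", {
  fr <- toy_fragments(15L, 18L, seed = 1L)
  cfg <- evolution_config(mutation = "Sub3", library_cap = 300L,
                          max_generations = 6L, target_n_acc = 1L, seed = 1L)
  res <- run_evolution(cfg, fr)
  expect_lt(nrow(res$reports), 7L)
  expect_gte(utils::tail(res$reports$n_acc_opt_mols, 1), 1L)
})

test_that("library mean aromatic C-H does not grow under substitutive evolution", {
  res <- study_run()
  ach <- res$reports$n_aCH_mean
  expect_lt(utils::tail(ach, 1), ach[1])
})
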