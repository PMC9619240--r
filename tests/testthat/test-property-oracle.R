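test_that("the synthetic oracle is deterministic and structure-sensitive", {
  a <- synthetic_oracle(c(BENZENE, BIPHENYL))
  b <- synthetic_oracle(c(BENZENE, BIPHENYL))
  expect_identical(a, b)
  expect_true(all(a$status == "ok"))
  # one added F lowers the gap by w_sub plus the bounded noise difference
  p <- oracle_params()
  g0 <- synthetic_oracle(BIPHENYL)$gap
  g1 <- synthetic_oracle("Fc1ccc(-c2ccccc2)cc1")$gap
  expect_lt(abs((g0 - g1) - p$w_sub), 2 * p$a_noise + 1e-12)
  # clamped within bounds on a wide range of structures
  smiles <- library_smiles(toy_library())
  o <- synthetic_oracle(smiles)
  expect_true(all(o$gap >= p$gap_min & o$gap <= p$gap_max))
  expect_true(all(o$e_s1 >= p$s_min & o$e_s1 <= p$s_max))
})

test_that("the oracle gap declines monotonically with substitution up to the noise", {
  p <- oracle_params()
  chain <- c("c1ccc(-c2ccccc2)cc1", "Fc1ccc(-c2ccccc2)cc1",
             "Fc1ccc(-c2ccc(F)cc2)cc1", "Fc1cc(F)c(-c2ccc(F)cc2)cc1")
  gaps <- synthetic_oracle(chain)$gap
  expect_true(all(diff(gaps) < 2 * p$a_noise))
  expect_lt(gaps[4], gaps[1])
})

test_that("a seeded fixture generation-0 library brackets the intended starting mean", {
  fr <- fixture_fragments(30L, 43L, seed = 1L)
  lib <- enumerate_da_library(fr, cap = 1000L, seed = 1L)
  o <- synthetic_oracle(library_smiles(lib))
  expect_gte(mean(o$gap), 0.55)
  expect_lte(mean(o$gap), 0.80)
})

test_that("completeness gating enforces the 0.80 geometry and 0.90 property ratios", {
  smiles <- library_smiles(toy_library())[1:100]
  # the synthetic oracle always succeeds
  res <- evaluate_batch(smiles, oracle_engine())
  expect_equal(nrow(res), 100L)
  expect_true(all(res$status == "ok"))
  # a stub failing 25% of geometries trips the geometry gate
  geom_stub <- function(s) {
    out <- synthetic_oracle(s)
    out$status[seq_len(25)] <- "geometry_failed"
    out
  }
  expect_error(evaluate_batch(smiles, geom_stub), class = "tadf_completeness_error")
  expect_error(evaluate_batch(smiles, geom_stub), "0.750")
  # a stub failing 15% of properties only passes geometry but fails the
  # property gate (0.85 < 0.90)
  prop_stub <- function(s) {
    out <- synthetic_oracle(s)
    out$status[seq_len(15)] <- "property_failed"
    out
  }
  expect_error(evaluate_batch(smiles, prop_stub), class = "tadf_completeness_error")
  # exactly 10% property failures sit on the boundary and pass; nothing is
  # dropped
  prop_ok <- function(s) {
    out <- synthetic_oracle(s)
    out$status[seq_len(10)] <- "property_failed"
    out
  }
  res2 <- evaluate_batch(smiles, prop_ok)
  expect_equal(nrow(res2), length(smiles))
  expect_equal(sum(res2$status == "ok"), 90L)
})

test_that("the csv engine looks up properties and flags missing molecules", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(smiles = c(BENZENE, PYRIDINE),
                    gap_eV = c(0.5, 0.4), e_s1_eV = c(3.2, 3.0))
  write.csv(tab, path, row.names = FALSE)
  eng <- csv_engine(path)
  out <- eng(c(PYRIDINE, BIPHENYL))
  expect_equal(out$gap[1], 0.4)
  expect_identical(out$status, c("ok", "geometry_failed"))
})

test_that("Kabsch RMSD removes rigid motions and matches closed-form cases", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.2, 0.9))
  expect_equal(kabsch_rmsd(a, a), 0)
  expect_equal(kabsch_rmsd(a, sweep(a, 2, c(-5, 5, 5), "+")), 0)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(kabsch_rmsd(a, a %*% t(rot)), 0, tolerance = 1e-8)
  # two segments of lengths 1 and 2: optimal superposition leaves RMSD 0.5
  expect_equal(kabsch_rmsd(rbind(c(0, 0, 0), c(1, 0, 0)),
                           rbind(c(0, 0, 0), c(0, 2, 0))), 0.5)
  # symmetry
  set.seed(11)
  b <- a + matrix(rnorm(12, sd = 0.1), 4)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-10)
  expect_error(kabsch_rmsd(a, a[1:3, ]), "shape")
})

test_that("Kabsch RMSD agrees with a rotation-grid brute force on random clouds", {
  grid_rmsd <- function(a, b, n = 24L) {
    a <- sweep(a, 2, colMeans(a))
    b <- sweep(b, 2, colMeans(b))
    angles <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    best <- Inf
    for (al in angles) for (be in angles) for (ga in angles) {
      rz <- rbind(c(cos(al), -sin(al), 0), c(sin(al), cos(al), 0), c(0, 0, 1))
      ry <- rbind(c(cos(be), 0, sin(be)), c(0, 1, 0), c(-sin(be), 0, cos(be)))
      rx <- rbind(c(1, 0, 0), c(0, cos(ga), -sin(ga)), c(0, sin(ga), cos(ga)))
      r <- rz %*% ry %*% rx
      best <- min(best, sqrt(sum((a - b %*% t(r))^2) / nrow(a)))
    }
    best
  }
  set.seed(3)
  for (i in 1:3) {
    a <- matrix(rnorm(15), 5)
    b <- matrix(rnorm(15), 5)
    k <- kabsch_rmsd(a, b)
    g <- grid_rmsd(a, b)
    expect_lte(k, g + 1e-9)   # the grid cannot beat the analytic optimum
    expect_lt(g - k, 1e-2)    # and approaches it on a 24^3 grid
  }
})
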