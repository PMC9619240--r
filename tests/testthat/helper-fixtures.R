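# Shared fixtures. The end-to-end toy evolution runs are expensive, so they
# are computed once per test session and cached in an environment that all
# test files share.

.fixture_env <- new.env(parent = emptyenv())

# Canonical SMILES of a few reference molecules used across tests.
BENZENE <- "c1ccccc1"
BIPHENYL <- "c1ccc(-c2ccccc2)cc1"
PYRIDINE <- "c1ccncc1"
TOLUENE <- "Cc1ccccc1"

toy_fragments <- function(n_d = 18L, n_a = 20L, seed = 1L) {
  key <- sprintf("frag_%d_%d_%d", n_d, n_a, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- fixture_fragments(n_d, n_a, seed)
  }
  .fixture_env[[key]]
}

# A small deduplicated DA library for module-level tests.
toy_library <- function(cap = 120L, seed = 1L) {
  key <- sprintf("lib_%d_%d", cap, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- enumerate_da_library(toy_fragments(), cap = cap, seed = seed)
  }
  .fixture_env[[key]]
}

# The study-scale evolution run shared by the loop-invariant and acceptance
# tests: fixture fragments (30 donors, 43 acceptors), synthetic oracle,
# Sub3, cap 1000, 6 generations, seed 1.
study_run <- function(which = c("first", "second")) {
  which <- match.arg(which)
  key <- paste0("study_run_", which)
  if (is.null(.fixture_env[[key]])) {
    fr <- fixture_fragments(30L, 43L, seed = 1L)
    cfg <- evolution_config(mutation = "Sub3", library_cap = 1000L,
                            max_generations = 6L, seed = 1L)
    .fixture_env[[key]] <- run_evolution(cfg, fr, engine = oracle_engine())
  }
  .fixture_env[[key]]
}

# Brute-force bitmask enumeration of substitution patterns: every subset of
# the molecule's aromatic CH sites (optionally bounded in size), each site
# receiving each allowed op, deduplicated via canonicalize(). Independent
# of the mutation engine's combn/assignment machinery.
bitmask_mutants_oracle <- function(smiles, ops, max_sites = 1L,
                                   include_parent = FALSE) {
  mol <- tadfscreen:::mol_from_smiles(smiles)
  sites <- tadfscreen:::aromatic_ch_sites_mol(mol)
  k <- length(sites)
  out <- character(0)
  for (mask in seq_len(2^k) - 1L) {
    chosen <- sites[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    if (length(chosen) > max_sites) next
    if (length(chosen) == 0L) {
      if (include_parent) out <- c(out, canonicalize(smiles))
      next
    }
    assigns <- expand.grid(rep(list(ops), length(chosen)), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(assigns))) {
      m2 <- tadfscreen:::apply_mutation_mol(mol, chosen, as.character(assigns[r, ]))
      smi <- tadfscreen:::mols_to_smiles(list(m2))
      if (!is.na(smi)) out <- c(out, smi)
    }
  }
  unique(out)
}

# Orbit count of F-substitution patterns on a molecule's aromatic CH sites
# via Burnside's lemma over the automorphism group of the element-labelled
# molecular graph (computed with igraph/BLISS, independent of SMILES
# canonicalization).
burnside_pattern_count <- function(smiles) {
  mol <- tadfscreen:::mol_from_smiles(smiles)
  g <- igraph::graph_from_data_frame(
    mol$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elem))
  )
  colors <- as.integer(factor(paste(mol$elem, tadfscreen:::implicit_h(mol))))
  gens <- igraph::automorphism_group(g, colors = colors)
  perms <- list(seq_along(mol$elem))
  # close the generator set under composition (groups here are tiny)
  repeat {
    new <- list()
    keys <- vapply(perms, paste, character(1), collapse = ",")
    for (p in perms) for (gen in gens) {
      q <- as.integer(gen)[p]
      k <- paste(q, collapse = ",")
      if (!(k %in% keys)) {
        new <- c(new, list(q))
        keys <- c(keys, k)
      }
    }
    if (length(new) == 0L) break
    perms <- c(perms, new)
  }
  sites <- tadfscreen:::aromatic_ch_sites_mol(mol)
  total <- sum(vapply(perms, function(p) {
    # cycles of the permutation restricted to the substitutable sites
    sub <- match(p[sites], sites)
    seen <- logical(length(sites))
    n_cyc <- 0L
    for (i in seq_along(sites)) {
      if (!seen[i]) {
        n_cyc <- n_cyc + 1L
        j <- i
        while (!seen[j]) {
          seen[j] <- TRUE
          j <- sub[j]
        }
      }
    }
    2^n_cyc
  }, numeric(1)))
  total / length(perms)
}
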