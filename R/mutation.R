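#' Structural mutation specifications
#'
#' The ten mutation operators act on aromatic C-H positions. Two kinds
#' exist: the ring carbon is swapped to an aromatic nitrogen (`Sub1` slow,
#' one position per offspring; `Sub2` fast, up to two positions), or the
#' terminal hydrogen is replaced by a substituent group. `Sub3`-`Sub6` use a
#' single group (F, CN, OMe, NMe2); `Sub7`-`Sub10` offer a choice of two
#' groups (F|OMe, F|NMe2, CN|OMe, CN|NMe2), one group per mutated site.
#'
#' @param label one of `"Sub1"`..`"Sub10"`, or a custom spec via the other
#'   arguments.
#' @param kind `"aromatic_N_swap"` or `"terminal_substitution"` (filled in
#'   automatically for the standard labels).
#' @param groups substituent group names from `F`, `CN`, `OMe`, `NMe2`
#'   (empty for N swaps).
#' @param max_sites maximum number of positions mutated in one offspring.
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(label, kind = NULL, groups = NULL, max_sites = NULL) {
  standard <- list(
    Sub1  = list(kind = "aromatic_N_swap",       groups = character(0),  max_sites = 1L),
    Sub2  = list(kind = "aromatic_N_swap",       groups = character(0),  max_sites = 2L),
    Sub3  = list(kind = "terminal_substitution", groups = "F",           max_sites = 1L),
    Sub4  = list(kind = "terminal_substitution", groups = "CN",          max_sites = 1L),
    Sub5  = list(kind = "terminal_substitution", groups = "OMe",         max_sites = 1L),
    Sub6  = list(kind = "terminal_substitution", groups = "NMe2",        max_sites = 1L),
    Sub7  = list(kind = "terminal_substitution", groups = c("F", "OMe"),   max_sites = 1L),
    Sub8  = list(kind = "terminal_substitution", groups = c("F", "NMe2"),  max_sites = 1L),
    Sub9  = list(kind = "terminal_substitution", groups = c("CN", "OMe"),  max_sites = 1L),
    Sub10 = list(kind = "terminal_substitution", groups = c("CN", "NMe2"), max_sites = 1L)
  )
  if (label %in% names(standard)) {
    def <- standard[[label]]
    kind <- kind %||% def$kind
    groups <- groups %||% def$groups
    max_sites <- max_sites %||% def$max_sites
  } else if (is.null(kind) || is.null(max_sites)) {
    stop("unknown mutation label '", label, "'; use one of ",
         paste(names(standard), collapse = ", "),
         " or give kind/groups/max_sites explicitly")
  }
  kind <- match.arg(kind, c("aromatic_N_swap", "terminal_substitution"))
  groups <- as.character(groups %||% character(0))
  bad <- setdiff(groups, names(substituent_tables()))
  if (length(bad) > 0L) {
    stop("unknown substituent group(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(substituent_tables()), collapse = ", "))
  }
  if (kind == "terminal_substitution" && length(groups) == 0L) {
    stop("terminal substitution requires at least one group")
  }
  if (max_sites < 1L) stop("max_sites must be >= 1")
  structure(list(label = label, kind = kind, groups = groups,
                 max_sites = as.integer(max_sites)),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation_spec> %s: %s%s, max %d site(s) per offspring\n",
              x$label, x$kind,
              if (length(x$groups)) paste0(" [", paste(x$groups, collapse = "|"), "]") else "",
              x$max_sites))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Attachment tables for the substituent groups: atoms appended to the
# mutated site, bonds relative to the new atoms (index 0 = the site).
substituent_tables <- function() {
  list(
    F    = list(elem = "F",               bonds = data.frame(a1 = 0L, a2 = 1L, order = 1L)),
    CN   = list(elem = c("C", "N"),       bonds = data.frame(a1 = c(0L, 1L), a2 = c(1L, 2L), order = c(1L, 3L))),
    OMe  = list(elem = c("O", "C"),       bonds = data.frame(a1 = c(0L, 1L), a2 = c(1L, 2L), order = c(1L, 1L))),
    NMe2 = list(elem = c("N", "C", "C"),  bonds = data.frame(a1 = c(0L, 1L, 1L), a2 = c(1L, 2L, 3L), order = c(1L, 1L, 1L)))
  )
}

# Apply one mutation assignment to a mol: sites is an integer vector of
# aromatic CH atom indices, ops a parallel character vector ("N" for the
# ring swap or a substituent group name).
apply_mutation_mol <- function(mol, sites, ops) {
  tables <- substituent_tables()
  for (k in seq_along(sites)) {
    site <- sites[k]
    op <- ops[k]
    if (op == "N") {
      mol$elem[site] <- "N"
    } else {
      tab <- tables[[op]]
      offset <- length(mol$elem)
      mol$elem <- c(mol$elem, tab$elem)
      mol$coords <- rbind(mol$coords, matrix(0, nrow = length(tab$elem), ncol = 3))
      nb <- tab$bonds
      a1 <- ifelse(nb$a1 == 0L, site, nb$a1 + offset)
      a2 <- ifelse(nb$a2 == 0L, site, nb$a2 + offset)
      mol$bonds <- rbind(mol$bonds, data.frame(a1 = a1, a2 = a2, order = nb$order))
    }
  }
  mol
}

#' Single-site mutants of a molecule
#'
#' Applies the mutation at every aromatic C-H position (one position per
#' offspring), with every allowed group, then canonicalizes and
#' deduplicates. Products that fail sanitization are dropped; the parent is
#' never part of the output.
#'
#' @param smiles parent SMILES.
#' @param spec a [mutation_spec].
#' @return character vector of unique canonical offspring SMILES (possibly
#'   empty when no aromatic C-H remains).
#' @examples
#' single_site_mutants("c1ccccc1", mutation_spec("Sub1"))  # pyridine
#' @export
single_site_mutants <- function(smiles, spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  multi_site_mutants(smiles, spec, max_sites = 1L)
}

#' Multi-site mutants of a molecule
#'
#' Union of all offspring with 1 to `max_sites` aromatic C-H positions
#' mutated simultaneously (each position at most once; for multi-group
#' specs every assignment of groups to the chosen positions is formed).
#'
#' @inheritParams single_site_mutants
#' @param max_sites overrides `spec$max_sites` when given.
#' @return character vector of unique canonical offspring SMILES.
#' @export
multi_site_mutants <- function(smiles, spec, max_sites = NULL) {
  stopifnot(inherits(spec, "mutation_spec"))
  max_sites <- as.integer(max_sites %||% spec$max_sites)
  parent_canonical <- canonicalize(smiles)
  mol <- mol_from_smiles(smiles)
  sites <- aromatic_ch_sites_mol(mol)
  if (length(sites) == 0L) return(character(0))
  ops <- if (spec$kind == "aromatic_N_swap") "N" else spec$groups
  mutants <- list()
  for (k in seq_len(min(max_sites, length(sites)))) {
    combos <- utils::combn(sites, k, simplify = FALSE)
    assignments <- expand_assignments(ops, k)
    for (cmb in combos) {
      for (asg in assignments) {
        mutants[[length(mutants) + 1L]] <- apply_mutation_mol(mol, cmb, asg)
      }
    }
  }
  out <- mols_to_smiles(mutants)
  out <- unique(out[!is.na(out)])
  setdiff(out, parent_canonical)
}

# All length-k sequences over the op alphabet.
expand_assignments <- function(ops, k) {
  if (length(ops) == 1L) return(list(rep(ops, k)))
  grid <- do.call(expand.grid, c(rep(list(ops), k), stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
}

#' Exhaustive substitution over all site subsets
#'
#' Enumerates the full closure of a single-group substitution: every subset
#' of the molecule's aromatic C-H positions (including the empty subset,
#' i.e. the parent) is substituted with the group, and the products are
#' canonically deduplicated. On a molecule with k sites this walks all 2^k
#' position-labelled patterns; symmetry-equivalent patterns collapse to one
#' canonical structure.
#'
#' @param smiles parent SMILES.
#' @param group a substituent group name (`"F"`, `"CN"`, `"OMe"`, `"NMe2"`)
#'   or `"N"` for the ring swap.
#' @return character vector of unique canonical SMILES, parent included.
#' @examples
#' \dontrun{
#' length(substitution_subsets("c1ccc(-c2ccccc2)cc1", "F"))  # 210
#' }
#' @export
substitution_subsets <- function(smiles, group = "F") {
  mol <- mol_from_smiles(smiles)
  sites <- aromatic_ch_sites_mol(mol)
  k <- length(sites)
  if (k > 20L) stop("refusing exhaustive enumeration over ", k, " sites (2^k patterns)")
  mutants <- vector("list", 2^k)
  for (m in seq_len(2^k) - 1L) {
    chosen <- sites[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    mutants[[m + 1L]] <- apply_mutation_mol(mol, chosen, rep(group, length(chosen)))
  }
  out <- mols_to_smiles(mutants)
  unique(out[!is.na(out)])
}

#' Offspring library: parents plus their mutants
#'
#' Builds the next generation: the parent molecules are retained in full
#' (the accumulation property of the evolution loop) and joined by all
#' mutants of all parents. When the union exceeds the cap, offspring are
#' uniformly subsampled with the seed while every parent is kept.
#'
#' @param parents a [mol_library] (or character vector) of parent
#'   molecules.
#' @param spec a [mutation_spec].
#' @param cap maximum library size; must be at least the parent count.
#' @param seed integer seed for offspring subsampling.
#' @return a [mol_library] with generation one above the parents'.
#' @export
offspring_library <- function(parents, spec, cap = 1000L, seed = 1L) {
  stopifnot(inherits(spec, "mutation_spec"))
  parent_smiles <- library_smiles(parents)
  if (length(parent_smiles) == 0L) stop("parent set must be non-empty")
  parent_gen <- if (inherits(parents, "mol_library")) parents$generation else 0L
  if (cap < length(parent_smiles)) {
    stop("cap ", cap, " is smaller than the parent count ", length(parent_smiles))
  }
  kids <- lapply(parent_smiles, function(p) multi_site_mutants(p, spec))
  kid_df <- data.frame(
    smiles = unlist(kids, use.names = FALSE),
    parent_smiles = rep(parent_smiles, lengths(kids)),
    stringsAsFactors = FALSE
  )
  kid_df <- kid_df[!kid_df$smiles %in% parent_smiles, , drop = FALSE]
  kid_df <- kid_df[!duplicated(kid_df$smiles), , drop = FALSE]
  n_room <- cap - length(parent_smiles)
  if (nrow(kid_df) > n_room) {
    kid_df <- kid_df[order(kid_df$smiles), , drop = FALSE]
    pick <- with_seed(seed, sample(nrow(kid_df), n_room))
    kid_df <- kid_df[pick, , drop = FALSE]
  }
  prev <- if (inherits(parents, "mol_library")) parents$records else NULL
  gen <- parent_gen + 1L
  mol_library(
    smiles = c(parent_smiles, kid_df$smiles),
    generation = gen,
    cap = cap,
    generation_born = c(
      if (!is.null(prev)) prev$generation_born else rep(parent_gen, length(parent_smiles)),
      rep(gen, nrow(kid_df))
    ),
    parent_smiles = c(
      if (!is.null(prev)) prev$parent_smiles else rep(NA_character_, length(parent_smiles)),
      kid_df$parent_smiles
    ),
    mutation_label = c(
      if (!is.null(prev)) prev$mutation_label else rep("enumeration", length(parent_smiles)),
      rep(spec$label, nrow(kid_df))
    )
  )
}
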