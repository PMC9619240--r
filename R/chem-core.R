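#' Canonicalize SMILES strings
#'
#' Maps every SMILES to its unique canonical form (Open Babel canonical
#' SMILES), so that two representations of the same molecule compare equal
#' as strings. Canonicalization is idempotent and is the deduplication key
#' used throughout the package.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize(c("C1=CC=CC=C1", "c1ccccc1"))
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- ob_batch_convert(smiles, from = "SMI", to = "CAN")
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("cannot parse SMILES: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  out
}

#' Aromatic C-H sites of a molecule
#'
#' Returns the atom indices (in the molecule's kekulized connection table)
#' of aromatic carbons that carry exactly one hydrogen. These are the
#' substitutable positions for the structural mutations: a ring C-H can be
#' swapped to a ring nitrogen or have its hydrogen replaced by a terminal
#' group.
#'
#' A carbon qualifies when it sits in a ring, takes part in a double bond
#' (the kekulized signature of an sp2 ring position) and has exactly one
#' implicit hydrogen. On the package's aromatic building-block space this
#' matches the toolkit's aromaticity perception, which the test suite
#' cross-checks against `[cH]` SMARTS counts.
#'
#' @param smiles a single SMILES string.
#' @return integer vector of atom indices; its length is the molecule's
#'   aromatic C-H count (`n_aCH`).
#' @examples
#' length(aromatic_ch_sites("c1ccccc1"))              # 6
#' length(aromatic_ch_sites("c1ccc(-c2ccccc2)cc1"))   # 10
#' @export
aromatic_ch_sites <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- mol_from_smiles(smiles)
  aromatic_ch_sites_mol(mol)
}

aromatic_ch_sites_mol <- function(mol) {
  if (length(mol$elem) == 0L) return(integer(0))
  ring <- ring_atoms(mol)
  if (!any(ring)) return(integer(0))
  h <- implicit_h(mol)
  has_double <- rep(FALSE, length(mol$elem))
  dd <- mol$bonds[mol$bonds$order >= 2L, , drop = FALSE]
  has_double[unique(c(dd$a1, dd$a2))] <- TRUE
  # on the kekulized table an aromatic CH is a ring carbon carrying one
  # double bond and one hydrogen; sp3-bridged polycycles (fluorene,
  # dihydroacridine) keep their benzo CH sites this way
  which(mol$elem == "C" & ring & has_double & h == 1)
}

#' Mean aromatic C-H count of a library
#'
#' Arithmetic mean of the per-molecule aromatic C-H counts over a library
#' (`n_aCH`). The mean falls as mutation generations consume substitutable
#' positions.
#'
#' @param library a [mol_library] object, or a character vector of SMILES.
#' @return the mean count (full precision; round to one decimal for
#'   reporting).
#' @export
mean_aromatic_ch <- function(library) {
  smiles <- library_smiles(library)
  if (length(smiles) == 0L) stop("empty library: mean aromatic C-H is undefined")
  mean(aromatic_ch_counts(smiles))
}

# Batched aromatic C-H counts with an optional cross-call cache env.
aromatic_ch_counts <- function(smiles, cache = NULL) {
  uniq <- unique(smiles)
  todo <- if (is.null(cache)) uniq else uniq[!vapply(uniq, exists, logical(1), envir = cache)]
  if (length(todo) > 0L) {
    blocks <- ob_smiles_to_molblocks(todo)
    counts <- vapply(seq_along(todo), function(i) {
      if (is.na(blocks[i])) stop("cannot parse SMILES: ", todo[i])
      length(aromatic_ch_sites_mol(parse_molblock(blocks[i])))
    }, numeric(1))
    if (is.null(cache)) {
      all_counts <- stats::setNames(counts, todo)
      return(unname(all_counts[smiles]))
    }
    for (i in seq_along(todo)) assign(todo[i], counts[i], envir = cache)
  }
  if (is.null(cache)) {
    return(vapply(smiles, function(s) length(aromatic_ch_sites(s)), numeric(1)))
  }
  vapply(smiles, get, numeric(1), envir = cache)
}

#' Circular fingerprints (ECFP) for molecules
#'
#' Binary extended-connectivity fingerprints of radius 2 (the conventional
#' ECFP4 configuration), computed by Open Babel and folded to a fixed
#' length. Deterministic: identical SMILES always map to identical bit
#' vectors.
#'
#' @param smiles character vector of valid SMILES.
#' @param nbits fingerprint length in bits; must divide 4096. Default 2048.
#' @return 0/1 integer matrix with one row per molecule (rownames are the
#'   input SMILES).
#' @export
fingerprint <- function(smiles, nbits = 2048L) {
  stopifnot(is.character(smiles))
  ob_ecfp(smiles, nbits = as.integer(nbits))
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection-over-union of two equal-length binary vectors. Defined as 0
#' when both vectors are all-zero (two empty bit sets are not considered
#' similar).
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in \[0, 1\]; 1 for identical non-zero vectors.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ: ", length(a), " vs ", length(b))
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

# Tanimoto matrix between the rows of two binary matrices.
tanimoto_matrix <- function(A, B) {
  A <- matrix(as.numeric(A), nrow = nrow(A))
  B <- matrix(as.numeric(B), nrow = nrow(B))
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  s <- ifelse(un == 0, 0, inter / un)
  s
}

#' Murcko skeleton decomposition
#'
#' Decomposes a molecule into its Murcko framework: the ring systems plus
#' the linker atoms connecting them, with all acyclic substituents removed.
#' Two cores are returned: the *common core* keeps element identities and
#' bond orders (atoms double-bonded directly to the framework, such as
#' sulfonyl oxygens, are retained); the *generic core* additionally erases
#' that information by turning every atom into carbon and every bond into a
#' single bond, so that only the connectivity pattern remains.
#'
#' @param smiles a single SMILES string; the molecule must contain a ring.
#' @return list with elements `common_core` and `generic_core`, both
#'   canonical SMILES.
#' @examples
#' skeletons("Cc1ccccc1")  # common: benzene; generic: C1CCCCC1
#' @export
skeletons <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- mol_from_smiles(smiles)
  core <- murcko_core_mol(mol)
  if (is.null(core)) stop("molecule has no ring; Murcko skeleton is undefined: ", smiles)
  common <- mols_to_smiles(list(core))
  generic_mol <- core
  generic_mol$elem[] <- "C"
  generic_mol$bonds$order <- 1L
  generic <- mols_to_smiles(list(generic_mol))
  if (is.na(common) || is.na(generic)) stop("skeleton extraction failed for: ", smiles)
  list(common_core = common, generic_core = generic)
}

# Batched skeleton decomposition: one row per input SMILES with columns
# common_core / generic_core (NA for acyclic molecules). All Open Babel
# round trips are batched; `cache` (an environment) memoises across calls.
skeletons_batch <- function(smiles, cache = NULL) {
  if (length(smiles) == 0L) {
    return(data.frame(smiles = character(0), common_core = character(0),
                      generic_core = character(0), stringsAsFactors = FALSE))
  }
  uniq <- unique(smiles)
  todo <- if (is.null(cache)) uniq else uniq[!vapply(uniq, exists, logical(1), envir = cache)]
  if (length(todo) > 0L) {
    blocks <- ob_smiles_to_molblocks(todo)
    if (anyNA(blocks)) stop("cannot parse SMILES: ", todo[which(is.na(blocks))[1]])
    cores <- lapply(blocks, function(b) murcko_core_mol(parse_molblock(b)))
    cyclic <- !vapply(cores, is.null, logical(1))
    common <- rep(NA_character_, length(todo))
    generic <- rep(NA_character_, length(todo))
    if (any(cyclic)) {
      common[cyclic] <- mols_to_smiles(cores[cyclic])
      generic_mols <- lapply(cores[cyclic], function(m) {
        m$elem[] <- "C"
        m$bonds$order <- 1L
        m
      })
      generic[cyclic] <- mols_to_smiles(generic_mols)
    }
    if (is.null(cache)) {
      i <- match(smiles, todo)
      return(data.frame(smiles = smiles, common_core = common[i],
                        generic_core = generic[i], stringsAsFactors = FALSE))
    }
    for (i in seq_along(todo)) {
      assign(todo[i], c(common[i], generic[i]), envir = cache)
    }
  }
  pairs <- vapply(smiles, get, character(2), envir = cache)
  data.frame(smiles = smiles, common_core = pairs[1, ], generic_core = pairs[2, ],
             stringsAsFactors = FALSE)
}

# Framework atoms of a mol: rings + linkers (iterative pruning of terminal
# atoms), plus atoms attached to the kept set by a double/triple bond.
# Returns the induced sub-molecule, or NULL for acyclic molecules.
murcko_core_mol <- function(mol) {
  na <- length(mol$elem)
  if (!any(ring_atoms(mol))) return(NULL)
  keep <- rep(TRUE, na)
  ring <- ring_atoms(mol)
  repeat {
    b <- mol$bonds[keep[mol$bonds$a1] & keep[mol$bonds$a2], , drop = FALSE]
    d <- tabulate(c(b$a1, b$a2), na)
    leaf <- which(keep & d <= 1L & !ring)
    if (length(leaf) == 0L) break
    keep[leaf] <- FALSE
  }
  # re-attach atoms multiply bonded straight onto the framework (e.g. the
  # oxygens of a sulfonyl linker)
  mb <- mol$bonds[mol$bonds$order >= 2L, , drop = FALSE]
  extra <- c(mb$a1[keep[mb$a2] & !keep[mb$a1]], mb$a2[keep[mb$a1] & !keep[mb$a2]])
  keep[extra] <- TRUE
  induced_mol(mol, which(keep))
}

#' Skeleton frequency table of a library
#'
#' Counts how many library molecules share each Murcko core. Acyclic
#' molecules carry no skeleton and are skipped (with a warning recording
#' how many).
#'
#' @param library a [mol_library] or character vector of SMILES.
#' @param core_kind `"common"` (elements and bonds kept) or `"generic"`
#'   (connectivity only).
#' @return data.frame with columns `core` and `count`, sorted by
#'   decreasing count; counts sum to the number of non-skipped molecules.
#'   The number of skipped acyclic molecules is in attribute `n_skipped`.
#' @export
skeleton_frequencies <- function(library, core_kind = c("common", "generic"),
                                 cache = NULL) {
  core_kind <- match.arg(core_kind)
  smiles <- library_smiles(library)
  cores <- skeletons_batch(smiles, cache = cache)
  per_mol <- stats::setNames(
    if (core_kind == "common") cores$common_core else cores$generic_core,
    smiles
  )
  skipped <- sum(is.na(per_mol))
  if (skipped > 0L) {
    warning(skipped, " acyclic molecule(s) skipped in skeleton decomposition")
  }
  tab <- sort(table(per_mol[!is.na(per_mol)]), decreasing = TRUE)
  out <- data.frame(core = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- skipped
  out
}
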