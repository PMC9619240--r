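#' Molecule libraries
#'
#' A `mol_library` is a generation-indexed set of molecule records keyed by
#' canonical SMILES (no duplicates) and capped in size. Records carry
#' provenance: the generation a molecule first appeared in, its parent and
#' the mutation that produced it.
#'
#' @param smiles character vector of canonical SMILES (must be unique).
#' @param generation non-negative integer generation index.
#' @param cap positive integer library size cap.
#' @param generation_born,parent_smiles,mutation_label optional per-molecule
#'   provenance vectors.
#' @return an object of class `mol_library`.
#' @export
mol_library <- function(smiles, generation = 0L, cap = 1000L,
                        generation_born = NULL, parent_smiles = NULL,
                        mutation_label = NULL) {
  if (anyDuplicated(smiles)) stop("library records must have unique canonical SMILES")
  if (length(smiles) > cap) stop("library size ", length(smiles), " exceeds cap ", cap)
  n <- length(smiles)
  records <- data.frame(
    smiles = smiles,
    generation_born = if (is.null(generation_born)) rep(as.integer(generation), n) else as.integer(generation_born),
    parent_smiles = if (is.null(parent_smiles)) rep(NA_character_, n) else parent_smiles,
    mutation_label = if (is.null(mutation_label)) rep("enumeration", n) else mutation_label,
    stringsAsFactors = FALSE
  )
  structure(list(generation = as.integer(generation), records = records,
                 cap = as.integer(cap)),
            class = "mol_library")
}

#' @export
print.mol_library <- function(x, ...) {
  cat(sprintf("<mol_library> generation %d: %d molecules (cap %d)\n",
              x$generation, nrow(x$records), x$cap))
  invisible(x)
}

#' @export
length.mol_library <- function(x) nrow(x$records)

# SMILES vector from a library or a plain character vector.
library_smiles <- function(library) {
  if (inherits(library, "mol_library")) library$records$smiles
  else if (is.character(library)) library
  else stop("expected a mol_library or a character vector of SMILES")
}

#' Fragment sets with attachment points
#'
#' Donor and acceptor fragments are SMILES carrying exactly one dummy-atom
#' attachment marker (`[*]`). Coupling replaces the two dummies by one
#' single bond.
#'
#' @param donors,acceptors character vectors of fragment SMILES, each with
#'   exactly one `[*]` attachment point.
#' @param name optional set name.
#' @return an object of class `fragment_set`.
#' @export
fragment_set <- function(donors, acceptors, name = "fragments") {
  check_fragments <- function(x, what) {
    n_attach <- vapply(gregexpr("\\*", x), function(m) sum(m > 0), numeric(1))
    if (any(n_attach != 1)) {
      stop(what, " fragments must carry exactly one attachment point [*]: ",
           paste(x[n_attach != 1], collapse = ", "))
    }
    canon <- canonicalize(x)
    if (anyDuplicated(canon)) {
      stop("duplicate ", what, " fragments after canonicalization: ",
           paste(x[duplicated(canon)], collapse = ", "))
    }
    canon
  }
  structure(list(donors = check_fragments(donors, "donor"),
                 acceptors = check_fragments(acceptors, "acceptor"),
                 name = name),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> '%s': %d donors, %d acceptors\n",
              x$name, length(x$donors), length(x$acceptors)))
  invisible(x)
}

#' Couple two fragments into a donor-acceptor molecule
#'
#' Joins two fragments at their attachment points with a single bond: the
#' two `[*]` dummies are removed and their anchor atoms bonded. The join is
#' symmetric, so `couple(d, a)` and `couple(a, d)` give the same canonical
#' SMILES.
#'
#' @param donor,acceptor fragment SMILES, each with exactly one `[*]`.
#' @return canonical SMILES of the coupled molecule.
#' @examples
#' couple("[*]c1ccccc1", "[*]c1ccccc1")  # biphenyl
#' @export
couple <- function(donor, acceptor) {
  out <- couple_batch(donor, acceptor)
  if (is.na(out)) stop("coupling failed for: ", donor, " + ", acceptor)
  out
}

# Vectorized coupling (recycled pairs); NA where the product fails to
# sanitize.
couple_batch <- function(donors, acceptors) {
  n <- max(length(donors), length(acceptors))
  donors <- rep_len(donors, n)
  acceptors <- rep_len(acceptors, n)
  dm <- lapply(unique(donors), fragment_mol)
  names(dm) <- unique(donors)
  am <- lapply(unique(acceptors), fragment_mol)
  names(am) <- unique(acceptors)
  joined <- lapply(seq_len(n), function(i) join_fragment_mols(dm[[donors[i]]], am[[acceptors[i]]]))
  mols_to_smiles(joined)
}

# Parse a fragment and locate its attachment: returns the mol with the
# dummy removed and attr "anchor" = index of the anchor atom.
fragment_mol <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  dummy <- which(mol$elem %in% c("*", "R", "R#", "Du"))
  if (length(dummy) != 1L) {
    stop("fragment must have exactly one attachment point [*]: ", smiles,
         " (found ", length(dummy), ")")
  }
  nb <- c(mol$bonds$a2[mol$bonds$a1 == dummy], mol$bonds$a1[mol$bonds$a2 == dummy])
  if (length(nb) != 1L) stop("attachment dummy must have exactly one neighbour: ", smiles)
  keep <- setdiff(seq_along(mol$elem), dummy)
  out <- induced_mol(mol, keep)
  attr(out, "anchor") <- match(nb, keep)
  out
}

join_fragment_mols <- function(a, b) {
  offset <- length(a$elem)
  bonds <- rbind(
    a$bonds,
    data.frame(a1 = b$bonds$a1 + offset, a2 = b$bonds$a2 + offset, order = b$bonds$order),
    data.frame(a1 = attr(a, "anchor"), a2 = attr(b, "anchor") + offset, order = 1L)
  )
  structure(list(elem = c(a$elem, b$elem),
                 coords = rbind(a$coords, b$coords),
                 bonds = bonds),
            class = "tadf_mol")
}

#' Enumerate the generation-0 donor-acceptor library
#'
#' Forms every donor x acceptor coupling, deduplicates by canonical SMILES,
#' and caps the library with a seeded uniform subsample when the unique
#' product count exceeds the cap.
#'
#' @param fragments a [fragment_set].
#' @param cap maximum library size (default 1000).
#' @param seed integer seed for the subsampling.
#' @return a [mol_library] at generation 0.
#' @export
enumerate_da_library <- function(fragments, cap = 1000L, seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (cap < 1L) stop("cap must be a positive integer")
  if (length(fragments$donors) == 0L || length(fragments$acceptors) == 0L) {
    stop("fragment lists must be non-empty")
  }
  grid <- expand.grid(d = fragments$donors, a = fragments$acceptors,
                      stringsAsFactors = FALSE)
  products <- couple_batch(grid$d, grid$a)
  products <- unique(products[!is.na(products)])
  if (length(products) > cap) {
    products <- sort(products)  # order-independent before sampling
    products <- with_seed(seed, sample(products, cap))
  }
  mol_library(products, generation = 0L, cap = cap)
}

#' Packaged stand-in donor and acceptor fragment pools
#'
#' Returns a fragment set drawn from the pools shipped with the package:
#' typical TADF donors (carbazole, phenoxazine, phenothiazine, acridine and
#' diphenylamine families) and acceptors (cyano-, sulfonyl-, triazine-,
#' benzophenone-type aromatics), each with a single attachment point. These
#' pools are curated stand-ins assembled for this package, not any specific
#' published fragment collection.
#'
#' @param n_donors,n_acceptors how many fragments to draw from each pool.
#' @param seed integer seed controlling which fragments are drawn.
#' @return a [fragment_set].
#' @export
fixture_fragments <- function(n_donors = 30L, n_acceptors = 43L, seed = 1L) {
  donors <- read_smi(system.file("extdata", "donor_pool.smi", package = "tadfscreen"))$smiles
  acceptors <- read_smi(system.file("extdata", "acceptor_pool.smi", package = "tadfscreen"))$smiles
  if (n_donors > length(donors) || n_acceptors > length(acceptors)) {
    stop(sprintf("requested %d donors / %d acceptors but pools hold %d / %d",
                 n_donors, n_acceptors, length(donors), length(acceptors)))
  }
  d <- with_seed(seed, sample(donors, n_donors))
  a <- with_seed(seed + 1L, sample(acceptors, n_acceptors))
  fragment_set(d, a, name = sprintf("fixture-%d", seed))
}

#' Read / write SMILES line files
#'
#' `.smi` files hold one record per line: a SMILES string optionally
#' followed by a whitespace-separated name.
#'
#' @param path file path.
#' @return `read_smi` returns a data.frame with columns `smiles` and
#'   `name`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1L),
    name = vapply(parts, function(p) if (length(p) > 1L) paste(p[-1L], collapse = " ") else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_smi
#' @param smiles character vector of SMILES.
#' @param names optional record names.
#' @export
write_smi <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names)
  writeLines(lines, path)
  invisible(path)
}

#' Export a library with provenance columns
#'
#' @param library a [mol_library].
#' @param path CSV output path.
#' @export
write_library_csv <- function(library, path) {
  stopifnot(inherits(library, "mol_library"))
  utils::write.csv(library$records, path, row.names = FALSE)
  invisible(path)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
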