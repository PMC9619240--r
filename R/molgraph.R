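# Internal molecular-graph representation built from kekulized V2000
# molblocks. Open Babel does the SMILES reading/writing and aromaticity
# perception; this layer exposes the connection table so that site-level
# editing (mutations, scaffold pruning, fragment coupling) stays explicit.

# Parse one V2000 molblock string into a mol object:
# list(elem, coords, bonds = data.frame(a1, a2, order)).
parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("malformed molblock counts line: ", counts)
  atom_lines <- lines[seq.int(5, length.out = na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  coords <- cbind(
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30))
  )
  if (nb > 0L) {
    bond_lines <- lines[seq.int(5 + na, length.out = nb)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  structure(list(elem = elem, coords = coords, bonds = bonds),
            class = "tadf_mol")
}

# Write a mol object back to a V2000 molblock (single record, no $$$$).
# Coordinates are optional; added atoms sit at the origin, which is fine
# because only connectivity is consumed downstream.
write_molblock <- function(mol, title = "") {
  na <- length(mol$elem)
  nb <- nrow(mol$bonds)
  coords <- mol$coords
  if (is.null(coords) || nrow(coords) < na) {
    pad <- matrix(0, nrow = na - ifelse(is.null(coords), 0L, nrow(coords)), ncol = 3)
    coords <- rbind(coords, pad)
  }
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    coords[, 1], coords[, 2], coords[, 3], mol$elem
  )
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  } else character(0)
  paste(c(
    title, "  tadfscreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    atom_lines, bond_lines, "M  END"
  ), collapse = "\n")
}

mol_from_smiles <- function(smiles) {
  block <- ob_smiles_to_molblocks(smiles)
  if (is.na(block)) stop("cannot parse SMILES: ", smiles)
  parse_molblock(block)
}

# Canonical SMILES of mol objects (batch). NA where Open Babel rejects the
# edited structure, which is how sanitization failures are filtered out.
mols_to_smiles <- function(mols) {
  blocks <- vapply(mols, function(m) paste0(write_molblock(m), "\n$$$$"), character(1))
  ob_batch_convert(blocks, from = "SDF", to = "CAN")
}

# Sum of bond orders per atom.
bond_order_sums <- function(mol) {
  na <- length(mol$elem)
  v <- numeric(na)
  if (nrow(mol$bonds) > 0L) {
    s <- tapply(c(mol$bonds$order, mol$bonds$order), c(mol$bonds$a1, mol$bonds$a2), sum)
    v[as.integer(names(s))] <- s
  }
  v
}

# Implicit hydrogen counts under default neutral valences.
implicit_h <- function(mol) {
  v <- bond_order_sums(mol)
  target <- vapply(seq_along(mol$elem), function(i) {
    e <- mol$elem[i]
    switch(e,
      C = 4, N = if (v[i] > 3) 5 else 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
      S = if (v[i] > 4) 6 else if (v[i] > 2) 4 else 2,
      P = if (v[i] > 3) 5 else 3, B = 3, H = 1, Si = 4,
      0)
  }, numeric(1))
  pmax(0, target - v)
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    mol$bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elem))
  )
}

# Logical vector: is each atom part of a ring? (incident to a non-bridge bond)
ring_atoms <- function(mol) {
  na <- length(mol$elem)
  inring <- rep(FALSE, na)
  if (nrow(mol$bonds) == 0L) return(inring)
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  inring[unique(c(mol$bonds$a1[ring_edges], mol$bonds$a2[ring_edges]))] <- TRUE
  inring
}

# Ring-system id per atom (connected components of the ring-bond subgraph);
# NA for acyclic atoms.
ring_systems <- function(mol) {
  na <- length(mol$elem)
  sys <- rep(NA_integer_, na)
  if (nrow(mol$bonds) == 0L) return(sys)
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  if (length(ring_edges) == 0L) return(sys)
  sub <- igraph::subgraph_from_edges(g, ring_edges, delete.vertices = FALSE)
  comp <- igraph::components(sub)
  ring <- rep(FALSE, na)
  ring[unique(c(mol$bonds$a1[ring_edges], mol$bonds$a2[ring_edges]))] <- TRUE
  sys[ring] <- comp$membership[ring]
  sys
}

# Induced sub-molecule on a set of atom indices (bonds inside the set only).
induced_mol <- function(mol, keep) {
  keep <- sort(unique(keep))
  remap <- integer(length(mol$elem))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  structure(list(
    elem = mol$elem[keep],
    coords = mol$coords[keep, , drop = FALSE],
    bonds = data.frame(a1 = remap[b$a1], a2 = remap[b$a2], order = b$order)
  ), class = "tadf_mol")
}
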