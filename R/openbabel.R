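# Thin batch-oriented interface to Open Babel via ChemmineOB.
#
# Open Babel stops a multi-record conversion at the first unreadable record,
# so every batch helper here tags records with integer titles and resumes
# after a failure until all records are accounted for.

# Convert a character vector of single-record inputs (SMILES lines or V2000
# molblocks) to another format, one output record per input. Returns a
# character vector aligned with `records`; failed records are NA.
ob_batch_convert <- function(records, from = c("SMI", "SDF"), to = "CAN") {
  from <- match.arg(from)
  n <- length(records)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  pending <- seq_len(n)
  # A record that Open Babel cannot read aborts the rest of the batch; after
  # each pass, mark the first still-missing record as failed and retry the
  # tail. Each pass accounts for >= 1 record, so this terminates.
  while (length(pending) > 0L) {
    idx <- pending
    input <- switch(from,
      SMI = paste0(paste(records[idx], paste0("tadfid", idx), sep = "\t", collapse = "\n"), "\n"),
      SDF = paste0(paste(vapply(seq_along(idx), function(k) {
        sub("^[^\n]*", paste0("tadfid", idx[k]), records[idx[k]])
      }, character(1)), collapse = "\n"), "\n")
    )
    res <- suppressWarnings(try(
      utils::capture.output(type = "message", val <- ChemmineOB::convertFormat(from, to, input)),
      silent = TRUE
    ))
    val <- if (inherits(res, "try-error")) "" else val
    got <- integer(0)
    if (nzchar(val)) {
      lines <- strsplit(val, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      m <- regmatches(lines, regexpr("tadfid[0-9]+", lines))
      keep <- vapply(lines, function(x) grepl("tadfid[0-9]+", x), logical(1))
      ids <- as.integer(sub("tadfid", "", m))
      vals <- trimws(sub("\ttadfid[0-9]+.*$", "", lines[keep]))
      ok <- !is.na(ids) & nzchar(vals)
      out[ids[ok]] <- vals[ok]
      got <- ids[ok]
    }
    pending <- setdiff(pending, got)
    if (length(pending) > 0L) {
      # first pending record is the one that broke the batch
      pending <- pending[-1L]
    }
  }
  out
}

# SMILES -> V2000 molblocks (kekulized, no explicit hydrogens). Returns a
# character vector of molblock strings (without trailing $$$$), NA on failure.
ob_smiles_to_molblocks <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  pending <- seq_len(n)
  while (length(pending) > 0L) {
    idx <- pending
    input <- paste0(paste(smiles[idx], paste0("tadfid", idx), sep = "\t", collapse = "\n"), "\n")
    res <- suppressWarnings(try(
      utils::capture.output(type = "message", val <- ChemmineOB::convertFormat("SMI", "SDF", input)),
      silent = TRUE
    ))
    val <- if (inherits(res, "try-error")) "" else val
    got <- integer(0)
    if (nzchar(val)) {
      blocks <- strsplit(val, "\\$\\$\\$\\$\n?")[[1]]
      blocks <- blocks[nzchar(trimws(blocks))]
      for (b in blocks) {
        title <- strsplit(b, "\n", fixed = TRUE)[[1]][1]
        id <- suppressWarnings(as.integer(sub("tadfid", "", trimws(title))))
        if (!is.na(id)) {
          out[id] <- b
          got <- c(got, id)
        }
      }
    }
    pending <- setdiff(pending, got)
    if (length(pending) > 0L) pending <- pending[-1L]
  }
  out
}

# Parsed OBMol handles for a vector of (valid) SMILES.
ob_mols <- function(smiles) {
  input <- paste0(paste(smiles, collapse = "\n"), "\n")
  ChemmineOB::forEachMol("SMILES", input, identity)
}

# Count unique matches of one SMARTS pattern across a vector of SMILES.
# Patterns should be written to match a single atom (use recursive SMARTS)
# so that the count equals the number of matching atoms.
ob_smarts_count <- function(smiles, pattern) {
  if (length(smiles) == 0L) return(integer(0))
  mols <- ob_mols(smiles)
  as.integer(ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE))
}

# Extended-connectivity fingerprints via Open Babel's ECFP4 (circular,
# radius 2), decoded from the packed 32-bit words and folded from 4096 to
# `nbits` columns by OR-ing. One row per input SMILES.
ob_ecfp <- function(smiles, nbits = 2048L) {
  if (length(smiles) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = nbits))
  }
  stopifnot(4096L %% nbits == 0L)
  mols <- ob_mols(smiles)
  fp_handle <- get_ecfp_handle()
  words <- t(vapply(
    mols,
    function(m) ChemmineOB:::OBFingerprint_GetFingerprint(fp_handle, m, numeric(1))[[2]],
    integer(128)
  ))
  # reinterpret the signed 32-bit words as unsigned; INT_MIN (0x80000000)
  # arrives as NA_integer_ through the R/C interface
  u <- words + (words < 0) * 2^32
  u[is.na(words)] <- 2^31
  full <- matrix(0L, nrow = length(mols), ncol = 4096L)
  for (b in 0:31) {
    full[, seq.int(b + 1L, 4096L, by = 32L)] <- (u %/% 2^b) %% 2
  }
  folded <- full[, seq_len(nbits), drop = FALSE]
  for (k in seq_len(4096L %/% nbits - 1L)) {
    folded <- folded | full[, k * nbits + seq_len(nbits), drop = FALSE]
  }
  m <- matrix(as.integer(folded), nrow = length(mols), ncol = nbits)
  rownames(m) <- smiles
  m
}

.tadf_env <- new.env(parent = emptyenv())

get_ecfp_handle <- function() {
  h <- .tadf_env$ecfp_handle
  if (is.null(h)) {
    ChemmineOB::convertFormat("SMI", "CAN", "C\n")  # ensure plugins are initialised
    h <- ChemmineOB:::OBFingerprint_FindFingerprint("ECFP4")
    .tadf_env$ecfp_handle <- h
  }
  h
}
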