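#' Intersection count of two libraries
#'
#' Number of canonical SMILES present in both libraries (`n_inter`).
#'
#' @param lib_a,lib_b [mol_library] objects or character vectors of SMILES.
#' @return non-negative integer.
#' @export
intersection_count <- function(lib_a, lib_b) {
  length(intersect(library_smiles(lib_a), library_smiles(lib_b)))
}

#' Group fingerprint similarity between two libraries (MSPR)
#'
#' Computes the maximum-similarity pairing between two compound libraries
#' and the group similarity index: all cross-library Tanimoto similarities
#' are computed on circular fingerprints, then molecule pairs are formed
#' greedily -- the globally most similar unpaired pair is taken repeatedly
#' (ties broken lexicographically on the pair's SMILES) until the smaller
#' library is exhausted. The index is the mean similarity over the pairs;
#' two identical libraries score exactly 1. An assignment-optimal variant
#' (maximizing the mean over all perfect pairings) is available for
#' sensitivity analysis on small libraries.
#'
#' @param lib_a,lib_b non-empty [mol_library] objects or SMILES vectors.
#' @param method `"greedy"` (the default, and the defined index) or
#'   `"optimal"` (exhaustive assignment; sizes up to 9 only).
#' @param fingerprints optional pre-computed fingerprint matrix whose
#'   rownames cover both libraries (avoids recomputation inside the
#'   evolution loop).
#' @return an object of class `pairing_result`: `pairs` (data.frame
#'   `smiles_a`, `smiles_b`, `similarity`), `delta_mspr`, `n_inter`,
#'   `n_tot_a`, `n_tot_b`.
#' @export
mspr_similarity <- function(lib_a, lib_b, method = c("greedy", "optimal"),
                            fingerprints = NULL) {
  method <- match.arg(method)
  sa <- library_smiles(lib_a)
  sb <- library_smiles(lib_b)
  if (length(sa) == 0L || length(sb) == 0L) stop("both libraries must be non-empty")
  if (is.null(fingerprints)) {
    fingerprints <- fingerprint(unique(c(sa, sb)))
  }
  fa <- fingerprints[sa, , drop = FALSE]
  fb <- fingerprints[sb, , drop = FALSE]
  s <- tanimoto_matrix(fa, fb)
  pairs <- switch(method,
    greedy = greedy_pairing(s, sa, sb),
    optimal = optimal_pairing(s, sa, sb)
  )
  structure(list(
    pairs = pairs,
    delta_mspr = mean(pairs$similarity),
    n_inter = intersection_count(sa, sb),
    n_tot_a = length(sa),
    n_tot_b = length(sb),
    method = method
  ), class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("<pairing_result> %d pairs (%s): delta_MSPR = %.3f, n_inter = %d (%d vs %d)\n",
              nrow(x$pairs), x$method, x$delta_mspr, x$n_inter, x$n_tot_a, x$n_tot_b))
  invisible(x)
}

# Greedy global maximum-similarity pairing without replacement. Ties are
# broken by the lexicographic order of (smiles_a, smiles_b) so the result
# does not depend on input ordering.
greedy_pairing <- function(s, sa, sb) {
  n_pairs <- min(length(sa), length(sb))
  ord <- order(-as.vector(s),
               rep(sa, times = length(sb)),
               rep(sb, each = length(sa)))
  used_a <- logical(length(sa))
  used_b <- logical(length(sb))
  ia <- (ord - 1L) %% length(sa) + 1L
  ib <- (ord - 1L) %/% length(sa) + 1L
  out_a <- integer(n_pairs); out_b <- integer(n_pairs)
  k <- 0L
  for (t in seq_along(ord)) {
    i <- ia[t]; j <- ib[t]
    if (!used_a[i] && !used_b[j]) {
      k <- k + 1L
      out_a[k] <- i; out_b[k] <- j
      used_a[i] <- TRUE; used_b[j] <- TRUE
      if (k == n_pairs) break
    }
  }
  data.frame(smiles_a = sa[out_a], smiles_b = sb[out_b],
             similarity = s[cbind(out_a, out_b)],
             stringsAsFactors = FALSE)
}

# Assignment-optimal pairing by exhaustive permutation (diagnostic only).
optimal_pairing <- function(s, sa, sb) {
  swap <- length(sa) > length(sb)
  if (swap) {
    s <- t(s); tmp <- sa; sa <- sb; sb <- tmp
  }
  n <- length(sa); m <- length(sb)
  if (n > 9L) stop("optimal pairing is exhaustive; libraries larger than 9 are not supported")
  perms <- all_injections(n, m)
  means <- vapply(perms, function(p) mean(s[cbind(seq_len(n), p)]), numeric(1))
  best <- perms[[which.max(means)]]
  out <- data.frame(smiles_a = sa, smiles_b = sb[best],
                    similarity = s[cbind(seq_len(n), best)],
                    stringsAsFactors = FALSE)
  if (swap) out <- data.frame(smiles_a = out$smiles_b, smiles_b = out$smiles_a,
                              similarity = out$similarity, stringsAsFactors = FALSE)
  out
}

# All injective maps 1..n -> 1..m as a list of integer vectors.
all_injections <- function(n, m) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, avail) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in avail) rec(c(prefix, v), setdiff(avail, v))
  }
  rec(integer(0), seq_len(m))
  out
}
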