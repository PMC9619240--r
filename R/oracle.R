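#' Parameters of the synthetic property oracle
#'
#' The synthetic oracle is a deterministic, structure-sensitive toy model of
#' the two excited-state properties the screening loop consumes: the
#' singlet-triplet gap and the vertical S1 energy. It exists so that the
#' whole evolution loop can be exercised and tested at desk scale without a
#' quantum-chemistry engine. The gap falls with the number of electron
#' donor/acceptor substituents, ring nitrogens and diarylamine-type donor
#' nitrogens; the S1 energy red-shifts with ring nitrogens and strong donor
#' groups. A small bounded pseudo-noise term, derived from a hash of the
#' canonical SMILES (not from the RNG stream), makes the landscape rugged
#' while keeping results independent of evaluation order.
#'
#' @param g0 baseline gap in eV.
#' @param w_sub gap decrease per terminal substituent (F, CN, OMe, NMe2), eV.
#' @param w_N gap decrease per pyridine-type ring nitrogen, eV.
#' @param w_amine gap decrease per diarylamine-type nitrogen, eV.
#' @param a_noise amplitude of the hash-derived pseudo-noise, eV.
#' @param gap_min,gap_max clamp bounds for the gap, eV.
#' @param s0 baseline S1 energy, eV.
#' @param w_red S1 decrease per red-shifting feature (ring N or strong
#'   donor group), eV.
#' @param s_min,s_max clamp bounds for the S1 energy, eV.
#' @return a list of oracle parameters.
#' @export
oracle_params <- function(g0 = 0.70, w_sub = 0.06, w_N = 0.05, w_amine = 0.10,
                          a_noise = 0.05, gap_min = 0.01, gap_max = 1.5,
                          s0 = 3.30, w_red = 0.08, s_min = 1.50, s_max = 4.00) {
  list(g0 = g0, w_sub = w_sub, w_N = w_N, w_amine = w_amine,
       a_noise = a_noise, gap_min = gap_min, gap_max = gap_max,
       s0 = s0, w_red = w_red, s_min = s_min, s_max = s_max)
}

# Structure features consumed by the oracle, counted by SMARTS matching.
# Single-atom recursive patterns so each feature is counted once.
oracle_features <- function(smiles) {
  data.frame(
    n_F    = ob_smarts_count(smiles, "[F;$(Fc)]"),
    n_CN   = ob_smarts_count(smiles, "[CX2;$(C#N)]"),
    n_OMe  = ob_smarts_count(smiles, "[OX2;$(O(c)[CH3])]"),
    n_NMe2 = ob_smarts_count(smiles, "[NX3;$(N(c)([CH3])[CH3])]"),
    n_ringN = ob_smarts_count(smiles, "[nX2]"),
    n_amine = ob_smarts_count(smiles, "[#7;X3;$([#7](c)c)]")
  )
}

# Deterministic pseudo-noise in [-1, 1] from a string hash.
hash_unit <- function(strings, salt = 0L) {
  mod <- 2147483563
  vapply(strings, function(s) {
    h <- (as.numeric(salt) + 11) %% mod
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% mod
    2 * (h / (mod - 1)) - 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' Synthetic property oracle
#'
#' Deterministically assigns a singlet-triplet gap and an S1 energy to each
#' molecule from counted structural features (see [oracle_params] for the
#' model). Identical canonical SMILES always receive bit-identical values.
#'
#' @param smiles character vector of valid SMILES.
#' @param params oracle parameters from [oracle_params].
#' @return data.frame with columns `smiles`, `gap`, `e_s1` and `status`
#'   (always `"ok"`).
#' @export
synthetic_oracle <- function(smiles, params = oracle_params()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(data.frame(smiles = character(0), gap = numeric(0),
                      e_s1 = numeric(0), status = character(0)))
  }
  canon <- canonicalize(smiles)
  f <- oracle_features(canon)
  n_sub <- f$n_F + f$n_CN + f$n_OMe + f$n_NMe2
  eps_gap <- params$a_noise * hash_unit(canon, salt = 1L)
  eps_s1 <- params$a_noise * hash_unit(canon, salt = 2L)
  gap <- params$g0 - params$w_sub * n_sub - params$w_N * f$n_ringN -
    params$w_amine * f$n_amine + eps_gap
  gap <- pmin(pmax(gap, params$gap_min), params$gap_max)
  n_red <- f$n_ringN + f$n_OMe + f$n_NMe2 + f$n_amine
  e_s1 <- params$s0 - params$w_red * n_red + eps_s1
  e_s1 <- pmin(pmax(e_s1, params$s_min), params$s_max)
  data.frame(smiles = smiles, gap = gap, e_s1 = e_s1, status = "ok",
             stringsAsFactors = FALSE)
}

#' Property engines
#'
#' A property engine is any function taking a character vector of SMILES
#' and returning a data.frame with columns `smiles`, `gap`, `e_s1` and
#' `status` (one of `"ok"`, `"geometry_failed"`, `"property_failed"`).
#' `oracle_engine` wraps the synthetic oracle; `csv_engine` is a file-based
#' stub that looks molecules up in a property table (columns `smiles`,
#' `gap_eV`, `e_s1_eV`, optional `status`) produced by an external
#' quantum-chemistry workflow; molecules missing from the table are
#' reported as `geometry_failed`.
#'
#' @param params oracle parameters for `oracle_engine`.
#' @return a property engine function.
#' @export
oracle_engine <- function(params = oracle_params()) {
  force(params)
  function(smiles) synthetic_oracle(smiles, params)
}

#' @rdname oracle_engine
#' @param path CSV file with the property table for `csv_engine`.
#' @export
csv_engine <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smiles", "gap_eV", "e_s1_eV")
  if (!all(need %in% names(tab))) {
    stop("property table must have columns: ", paste(need, collapse = ", "))
  }
  tab$smiles <- canonicalize(tab$smiles)
  function(smiles) {
    canon <- canonicalize(smiles)
    i <- match(canon, tab$smiles)
    status <- ifelse(is.na(i), "geometry_failed",
                     if (!is.null(tab$status)) tab$status[i] else "ok")
    data.frame(
      smiles = smiles,
      gap = tab$gap_eV[i],
      e_s1 = tab$e_s1_eV[i],
      status = ifelse(is.na(i), "geometry_failed", status),
      stringsAsFactors = FALSE
    )
  }
}

#' Completeness policy for batch property evaluation
#'
#' The screening loop tolerates a fraction of failed molecules per batch:
#' at least `geometry_min_ratio` of the batch must pass geometry
#' preparation and at least `property_min_ratio` of the geometry successes
#' must yield properties; otherwise the batch (and the run) is aborted.
#'
#' @param geometry_min_ratio minimum fraction of successful geometries
#'   (default 0.80).
#' @param property_min_ratio minimum fraction of successful property
#'   evaluations among geometry successes (default 0.90).
#' @return a completeness policy list.
#' @export
completeness_policy <- function(geometry_min_ratio = 0.80,
                                property_min_ratio = 0.90) {
  stopifnot(geometry_min_ratio > 0, geometry_min_ratio <= 1,
            property_min_ratio > 0, property_min_ratio <= 1)
  list(geometry_min_ratio = geometry_min_ratio,
       property_min_ratio = property_min_ratio)
}

#' Evaluate a batch of molecules with completeness gating
#'
#' Runs the engine on every molecule and enforces the completeness policy.
#' No molecule is silently dropped: the returned frame has one row per
#' input, with failures flagged in `status`.
#'
#' @param molecules character vector of SMILES.
#' @param engine a property engine (see [oracle_engine]).
#' @param policy a [completeness_policy].
#' @return data.frame `smiles`, `gap`, `e_s1`, `status`.
#' @export
evaluate_batch <- function(molecules, engine = oracle_engine(),
                           policy = completeness_policy()) {
  if (length(molecules) == 0L) stop("cannot evaluate an empty batch")
  res <- engine(molecules)
  stopifnot(nrow(res) == length(molecules))
  geom_ok <- res$status %in% c("ok", "property_failed")
  r_geom <- mean(geom_ok)
  r_prop <- if (any(geom_ok)) sum(res$status == "ok") / sum(geom_ok) else 0
  if (r_geom < policy$geometry_min_ratio || r_prop < policy$property_min_ratio) {
    stop(structure(class = c("tadf_completeness_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("completeness failure: geometry ratio %.3f (min %.2f), ",
                            "property ratio %.3f (min %.2f)"),
                     r_geom, policy$geometry_min_ratio,
                     r_prop, policy$property_min_ratio),
                     call = sys.call(-1),
                     geometry_ratio = r_geom, property_ratio = r_prop)))
  }
  res
}

#' Kabsch-aligned RMSD of two point sets
#'
#' Minimal root-mean-square deviation between two equally sized,
#' index-corresponded 3D point sets over all rigid rotations and
#' translations (Kabsch superposition via SVD, with the usual determinant
#' correction so only proper rotations are used).
#'
#' @param coords_a,coords_b numeric matrices (n x 3) of Cartesian
#'   coordinates.
#' @return the minimal RMSD (same length units as the inputs).
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) {
    stop("coordinate sets differ in shape: ", nrow(a), "x", ncol(a),
         " vs ", nrow(b), "x", ncol(b))
  }
  if (nrow(a) < 1L) stop("point sets must contain at least one point")
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  h <- t(b) %*% a
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  dd <- diag(c(1, 1, d))
  rot <- sv$v %*% dd %*% t(sv$u)
  br <- b %*% t(rot)
  sqrt(sum((a - br)^2) / nrow(a))
}
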