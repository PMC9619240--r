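#' Evolution run configuration
#'
#' Bundles every control parameter of the selection-and-mutation loop. The
#' defaults are the screening protocol used throughout the package: library
#' cap 1000, 10% of the library evaluated each generation to train the
#' surrogate, top 10% (smallest predicted gap) selected as parents, gap
#' threshold 0.15 eV for an "optimal" molecule, and the emission color
#' sieve at 2.50 / 2.80 eV.
#'
#' @param mutation a [mutation_spec] or a standard label (`"Sub1"`..
#'   `"Sub10"`).
#' @param library_cap maximum library size per generation.
#' @param train_fraction fraction of the library evaluated by the property
#'   engine each generation.
#' @param select_fraction fraction of top-ranked molecules kept as parents.
#' @param optimal_gap_threshold_eV predicted-gap threshold below which a
#'   molecule counts as optimal.
#' @param sieve_blue_min_eV,sieve_red_max_eV S1 boundaries of the color
#'   sieve; the closed interval between them is green.
#' @param max_generations number of mutation generations to run.
#' @param target_n_acc optional convergence target on the accumulated
#'   optimal count.
#' @param target_abundance optional convergence target on the material
#'   abundance.
#' @param convergence how the optional targets combine with the generation
#'   limit: `"any"` stops when any criterion is met, `"all"` only when all
#'   configured criteria hold.
#' @param completeness a [completeness_policy].
#' @param seed integer master seed; named substreams are derived from it so
#'   library sampling, training selection and cap sampling are
#'   independently reproducible.
#' @return an object of class `evolution_config`.
#' @export
evolution_config <- function(mutation = "Sub3", library_cap = 1000L,
                             train_fraction = 0.10, select_fraction = 0.10,
                             optimal_gap_threshold_eV = 0.15,
                             sieve_blue_min_eV = 2.80, sieve_red_max_eV = 2.50,
                             max_generations = 9L, target_n_acc = NULL,
                             target_abundance = NULL,
                             convergence = c("any", "all"),
                             completeness = completeness_policy(),
                             seed = 1L) {
  if (is.character(mutation)) mutation <- mutation_spec(mutation)
  stopifnot(inherits(mutation, "mutation_spec"))
  convergence <- match.arg(convergence)
  if (train_fraction <= 0 || train_fraction > 1) stop("train_fraction must be in (0, 1]")
  if (select_fraction <= 0 || select_fraction > 1) stop("select_fraction must be in (0, 1]")
  if (library_cap < 1L) stop("library_cap must be positive")
  if (optimal_gap_threshold_eV <= 0) stop("optimal_gap_threshold_eV must be positive")
  if (sieve_red_max_eV >= sieve_blue_min_eV) {
    stop("sieve_red_max_eV must be below sieve_blue_min_eV")
  }
  if (max_generations < 0L) stop("max_generations must be >= 0")
  structure(list(
    mutation = mutation, library_cap = as.integer(library_cap),
    train_fraction = train_fraction, select_fraction = select_fraction,
    optimal_gap_threshold_eV = optimal_gap_threshold_eV,
    sieve_blue_min_eV = sieve_blue_min_eV, sieve_red_max_eV = sieve_red_max_eV,
    max_generations = as.integer(max_generations),
    target_n_acc = target_n_acc, target_abundance = target_abundance,
    convergence = convergence, completeness = completeness,
    seed = as.integer(seed)
  ), class = "evolution_config")
}

# Named substreams derived from the master seed (kept below 2^31).
substream_seed <- function(seed, stream) {
  offsets <- c(library = 11L, training = 23L, cap = 37L, model = 53L)
  (as.integer(seed) * 7919L + offsets[[stream]]) %% 2147483647L
}

#' Random training subset of a library
#'
#' Seeded uniform sample without replacement of
#' `max(1, floor(fraction * n))` molecules, used as the quantum-chemistry
#' (or oracle) training set each generation.
#'
#' @param library a [mol_library] or SMILES vector.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @param min_size lower bound on the sample size (capped at the library
#'   size). The evolution loop raises this to the surrogate's minimum
#'   training-set size so that late, shrunken generations remain trainable.
#' @return character vector of selected SMILES.
#' @export
select_random_training <- function(library, fraction = 0.10, seed = 1L,
                                   min_size = 1L) {
  smiles <- library_smiles(library)
  if (length(smiles) == 0L) stop("cannot sample from an empty library")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- min(length(smiles), max(min_size, 1L, floor(fraction * length(smiles))))
  with_seed(seed, sample(smiles, k))
}

#' Top fraction of a library by predicted gap
#'
#' The `max(1, floor(fraction * n))` molecules with the smallest predicted
#' gap. Ties are broken by lexicographic canonical-SMILES order, so the
#' selection depends only on the prediction values, not on input order.
#'
#' @param predictions named numeric vector (names = SMILES, values =
#'   predicted gaps).
#' @param fraction selection fraction in (0, 1].
#' @return character vector of selected SMILES.
#' @export
select_top_fraction <- function(predictions, fraction = 0.10) {
  if (length(predictions) == 0L) stop("empty prediction set")
  k <- max(1L, floor(fraction * length(predictions)))
  ord <- order(predictions, names(predictions))
  names(predictions)[ord[seq_len(k)]]
}

#' Material abundance of a library
#'
#' Fraction of the library whose predicted gap lies strictly below the
#' optimality threshold.
#'
#' @param gaps numeric vector of predicted gaps (eV).
#' @param threshold gap threshold in eV (default 0.15).
#' @return abundance in \[0, 1\].
#' @examples
#' material_abundance(c(rep(0.1, 10), rep(0.5, 990)))  # 0.010
#' @export
material_abundance <- function(gaps, threshold = 0.15) {
  if (length(gaps) == 0L) stop("cannot compute abundance of an empty library")
  mean(gaps < threshold)
}

#' Emission color sieve on S1 energies
#'
#' Partitions molecules into color regions by vertical S1 energy: blue
#' above 2.80 eV, red below 2.50 eV, green in the closed interval between
#' (boundary values are green).
#'
#' @param e_s1_values named numeric vector of S1 energies (eV).
#' @param blue_min,red_max sieve boundaries in eV.
#' @return named factor with levels `blue`, `green`, `red`.
#' @export
energy_sieve <- function(e_s1_values, blue_min = 2.80, red_max = 2.50) {
  color <- ifelse(e_s1_values > blue_min, "blue",
                  ifelse(e_s1_values < red_max, "red", "green"))
  factor(stats::setNames(color, names(e_s1_values)),
         levels = c("blue", "green", "red"))
}

#' Accumulate optimal molecules
#'
#' Set union of the accumulator with every molecule whose predicted gap is
#' below the threshold; the accumulated count is non-decreasing across
#' generations.
#'
#' @param accumulator character vector of already-accumulated SMILES.
#' @param library_gaps named numeric vector of predicted gaps.
#' @param threshold gap threshold in eV.
#' @return updated character vector (unique SMILES).
#' @export
accumulate_optimal <- function(accumulator, library_gaps, threshold = 0.15) {
  union(accumulator, names(library_gaps)[library_gaps < threshold])
}

#' Run the evolutionary screening loop
#'
#' Executes the full generational protocol: build the generation-0
#' donor-acceptor library, then repeat (evaluate a random 10% with the
#' property engine -> fit gap and S1 surrogates -> predict the whole
#' library -> record metrics, sieve colors, skeleton tables and the
#' similarity to the previous generation -> accumulate optimal molecules ->
#' check convergence -> select the top 10% by predicted gap -> mutate into
#' the next library). Fully reproducible for a fixed seed with the
#' synthetic oracle.
#'
#' @param config an [evolution_config].
#' @param fragments a [fragment_set] for the generation-0 enumeration.
#' @param engine a property engine (default: the synthetic oracle).
#' @param keep_libraries keep every generation's library in the result
#'   (default TRUE).
#' @return an object of class `evolution_result`: `reports` (one row per
#'   generation: `n_g`, `n_tot`, `omega_MA`, `n_aCH_mean`, `mean_gap`,
#'   `n_acc_opt_mols`, `n_blue`, `n_green`, `n_red`, `n_inter`,
#'   `delta_MSPR`), `accumulated` (optimal SMILES with their latest
#'   predicted gaps), `skeleton_tables`, `libraries`, `config`.
#' @export
run_evolution <- function(config, fragments, engine = oracle_engine(),
                          keep_libraries = TRUE) {
  stopifnot(inherits(config, "evolution_config"), inherits(fragments, "fragment_set"))
  lib <- enumerate_da_library(fragments, cap = config$library_cap,
                              seed = substream_seed(config$seed, "library"))
  acc <- character(0)
  acc_gap <- numeric(0)
  reports <- vector("list", config$max_generations + 1L)
  skeleton_tables <- vector("list", config$max_generations + 1L)
  libraries <- list()
  fp_cache <- new.env(parent = emptyenv())
  sk_cache <- new.env(parent = emptyenv())
  ach_cache <- new.env(parent = emptyenv())
  prev_smiles <- NULL
  for (g in 0:config$max_generations) {
    smiles <- library_smiles(lib)
    feats <- cached_fingerprints(smiles, fp_cache)
    train <- select_random_training(lib, config$train_fraction,
                                    seed = substream_seed(config$seed, "training") + g,
                                    min_size = 20L)
    evals <- evaluate_batch(train, engine, config$completeness)
    ok <- evals$status == "ok"
    tr_idx <- match(evals$smiles[ok], smiles)
    m_gap <- train_surrogate(feats$features[tr_idx, , drop = FALSE], evals$gap[ok],
                             target = "gap",
                             seed = substream_seed(config$seed, "model") + 2L * g)
    m_s1 <- train_surrogate(feats$features[tr_idx, , drop = FALSE], evals$e_s1[ok],
                            target = "e_s1",
                            seed = substream_seed(config$seed, "model") + 2L * g + 1L)
    pred_gap <- predict_library(m_gap, feats)
    pred_s1 <- predict_library(m_s1, feats)
    sieve <- energy_sieve(pred_s1, config$sieve_blue_min_eV, config$sieve_red_max_eV)
    acc <- accumulate_optimal(acc, pred_gap, config$optimal_gap_threshold_eV)
    new_gaps <- pred_gap[names(pred_gap) %in% acc]
    acc_gap[names(new_gaps)] <- new_gaps
    mspr <- if (!is.null(prev_smiles)) {
      all_fp <- cached_fingerprints(unique(c(prev_smiles, smiles)), fp_cache)$features
      mspr_similarity(prev_smiles, smiles, fingerprints = all_fp)
    } else NULL
    skeleton_tables[[g + 1L]] <- list(
      common = skeleton_frequencies(smiles, "common", cache = sk_cache),
      generic = skeleton_frequencies(smiles, "generic", cache = sk_cache)
    )
    reports[[g + 1L]] <- data.frame(
      n_g = g,
      n_tot = length(smiles),
      omega_MA = material_abundance(pred_gap, config$optimal_gap_threshold_eV),
      n_aCH_mean = mean(aromatic_ch_counts(smiles, cache = ach_cache)),
      mean_gap = mean(pred_gap),
      n_acc_opt_mols = length(acc),
      n_blue = sum(sieve == "blue"),
      n_green = sum(sieve == "green"),
      n_red = sum(sieve == "red"),
      n_inter = if (is.null(mspr)) NA_integer_ else mspr$n_inter,
      delta_MSPR = if (is.null(mspr)) NA_real_ else mspr$delta_mspr
    )
    if (keep_libraries) libraries[[g + 1L]] <- lib
    if (g == config$max_generations || converged(config, g, length(acc),
                                                 reports[[g + 1L]]$omega_MA)) break
    parents <- select_top_fraction(pred_gap, config$select_fraction)
    parent_lib <- subset_library(lib, parents)
    lib <- offspring_library(parent_lib, config$mutation, cap = config$library_cap,
                             seed = substream_seed(config$seed, "cap") + g)
    prev_smiles <- smiles
  }
  done <- !vapply(reports, is.null, logical(1))
  structure(list(
    reports = do.call(rbind, reports[done]),
    accumulated = data.frame(smiles = names(acc_gap),
                             predicted_gap = unname(acc_gap),
                             stringsAsFactors = FALSE),
    skeleton_tables = skeleton_tables[done],
    libraries = libraries,
    config = config
  ), class = "evolution_result")
}

converged <- function(config, g, n_acc, omega) {
  checks <- logical(0)
  if (!is.null(config$target_n_acc)) checks <- c(checks, n_acc >= config$target_n_acc)
  if (!is.null(config$target_abundance)) checks <- c(checks, omega >= config$target_abundance)
  if (length(checks) == 0L) return(FALSE)
  if (config$convergence == "any") any(checks) else all(checks)
}

subset_library <- function(lib, smiles) {
  idx <- match(smiles, lib$records$smiles)
  structure(list(generation = lib$generation,
                 records = lib$records[idx, , drop = FALSE],
                 cap = lib$cap),
            class = "mol_library")
}

cached_fingerprints <- function(smiles, cache) {
  missing <- smiles[!vapply(smiles, exists, logical(1), envir = cache)]
  if (length(missing) > 0L) {
    fp <- fingerprint(missing)
    for (i in seq_along(missing)) assign(missing[i], fp[i, ], envir = cache)
  }
  m <- t(vapply(smiles, get, numeric(2048L), envir = cache))
  rownames(m) <- smiles
  list(features = m, smiles = smiles)
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf("<evolution_result> %s, %d generation(s), %d accumulated optimal molecules\n",
              x$config$mutation$label, nrow(x$reports) - 1L, nrow(x$accumulated)))
  print(x$reports, row.names = FALSE)
  invisible(x)
}
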