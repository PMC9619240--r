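#' Rank accumulated candidates by synthetic accessibility
#'
#' Final ranking of the accumulated optimal molecules: ascending synthetic
#' accessibility score (easiest first), ties broken by ascending predicted
#' gap, then lexicographic SMILES. The screening loop optimizes the gap
#' only; this step sieves out structures that the mutations have made
#' unreasonably hard to synthesize.
#'
#' @param accumulated data.frame with columns `smiles` and `predicted_gap`
#'   (as returned in `evolution_result$accumulated`), or a named numeric
#'   vector of gaps.
#' @param top_k how many candidates to return (all if larger than the
#'   accumulator).
#' @param scorer SAS scorer (see [sas_score]).
#' @return data.frame with columns `rank`, `smiles`, `predicted_gap`,
#'   `sas`.
#' @export
rank_candidates <- function(accumulated, top_k = 9L,
                            scorer = default_sas_scorer()) {
  if (is.numeric(accumulated) && !is.null(names(accumulated))) {
    accumulated <- data.frame(smiles = names(accumulated),
                              predicted_gap = unname(accumulated),
                              stringsAsFactors = FALSE)
  }
  if (!is.data.frame(accumulated) || nrow(accumulated) == 0L) {
    stop("accumulator is empty: nothing to rank")
  }
  stopifnot(all(c("smiles", "predicted_gap") %in% names(accumulated)))
  sas <- sas_score(accumulated$smiles, scorer = scorer)
  ord <- order(sas, accumulated$predicted_gap, accumulated$smiles)
  k <- min(as.integer(top_k), nrow(accumulated))
  sel <- ord[seq_len(k)]
  data.frame(
    rank = seq_len(k),
    smiles = accumulated$smiles[sel],
    predicted_gap = accumulated$predicted_gap[sel],
    sas = sas[sel],
    stringsAsFactors = FALSE
  )
}

#' Write / read a trajectory table
#'
#' Serializes the per-generation report table of an evolution run to CSV
#' and reads it back losslessly.
#'
#' @param reports data.frame of generation reports (see [run_evolution]).
#' @param path CSV file path.
#' @export
write_trajectory <- function(reports, path) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load an evolution configuration file
#'
#' Reads a flat key-value (YAML) configuration file, applies the package
#' defaults for missing keys, validates every value and rejects unknown
#' keys. Energy quantities carry explicit `_eV` suffixes in the file.
#'
#' Recognized keys: `mutation`, `library_cap`, `train_fraction`,
#' `select_fraction`, `optimal_gap_threshold_eV`, `sieve_blue_min_eV`,
#' `sieve_red_max_eV`, `max_generations`, `target_n_acc`,
#' `target_abundance`, `convergence`, `geometry_min_ratio`,
#' `property_min_ratio`, `seed`.
#'
#' @param path configuration file path; an empty file yields the full
#'   default configuration.
#' @return an [evolution_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("mutation", "library_cap", "train_fraction", "select_fraction",
             "optimal_gap_threshold_eV", "sieve_blue_min_eV", "sieve_red_max_eV",
             "max_generations", "target_n_acc", "target_abundance",
             "convergence", "geometry_min_ratio", "property_min_ratio", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; recognized keys: ", paste(known, collapse = ", "))
  }
  policy <- completeness_policy(
    geometry_min_ratio = raw$geometry_min_ratio %||% 0.80,
    property_min_ratio = raw$property_min_ratio %||% 0.90
  )
  evolution_config(
    mutation = raw$mutation %||% "Sub3",
    library_cap = raw$library_cap %||% 1000L,
    train_fraction = raw$train_fraction %||% 0.10,
    select_fraction = raw$select_fraction %||% 0.10,
    optimal_gap_threshold_eV = raw$optimal_gap_threshold_eV %||% 0.15,
    sieve_blue_min_eV = raw$sieve_blue_min_eV %||% 2.80,
    sieve_red_max_eV = raw$sieve_red_max_eV %||% 2.50,
    max_generations = raw$max_generations %||% 9L,
    target_n_acc = raw$target_n_acc,
    target_abundance = raw$target_abundance,
    convergence = raw$convergence %||% "any",
    completeness = policy,
    seed = raw$seed %||% 1L
  )
}
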