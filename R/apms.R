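#' AP-MS scoring configuration
#'
#' Thresholds of the interaction-candidate filter cascade and the
#' enrichment-index ranking.  Defaults are the conventional stringent
#' screen for a nuclear bait: at least 10 bait spectral counts, bait-unique
#' or >= 4-fold enriched over control, >= 2 unique peptides,
#' nuclear/unknown localization, top 50 by enrichment index.
#'
#' @param min_spectra Minimum bait-condition spectral counts (inclusive).
#' @param min_fold Minimum bait/control fold enrichment (inclusive) for
#'   proteins detected in the control.
#' @param min_unique_peptides Minimum unique peptides (inclusive).
#' @param allowed_localizations Localization classes retained.
#' @param top_k Number of top-ranked candidates reported.
#' @param missing_abundance_policy `"impute_min"` (impute the dataset
#'   minimum positive whole-cell abundance and flag the row) or
#'   `"exclude"` (drop proteins without usable abundance).
#' @return A validated list of class `apms_config`.
#' @export
apms_config <- function(min_spectra = 10, min_fold = 4,
                        min_unique_peptides = 2,
                        allowed_localizations = c("nuclear", "unknown"),
                        top_k = 50,
                        missing_abundance_policy = c("impute_min", "exclude")) {
  missing_abundance_policy <- match.arg(missing_abundance_policy)
  if (min_spectra <= 0 || min_fold <= 0 || min_unique_peptides <= 0 ||
      top_k <= 0) {
    abort("all thresholds must be positive")
  }
  bad <- setdiff(allowed_localizations, localization_levels)
  if (length(bad) > 0) abort(sprintf("unknown localization(s): %s",
                                     paste(bad, collapse = ", ")))
  structure(list(min_spectra = min_spectra, min_fold = min_fold,
                 min_unique_peptides = min_unique_peptides,
                 allowed_localizations = allowed_localizations,
                 top_k = as.integer(top_k),
                 missing_abundance_policy = missing_abundance_policy),
            class = "apms_config")
}

#' Normalized spectral abundance factors (NSAF)
#'
#' For each bait-detected protein i (bait_spc > 0),
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)`, with the sum running over
#' all bait-detected proteins in the purification — before any candidate
#' filtering, so later filters cannot change retained proteins' values.
#'
#' @param counts Spectral-count tibble (see [read_spectral_counts()]).
#' @param meta Protein metadata tibble providing `length_aa`.
#' @return A tibble (`accession`, `nsaf`) over bait-detected proteins;
#'   `nsaf` sums to 1.
#' @export
compute_nsaf <- function(counts, meta) {
  detected <- counts[counts$bait_spc > 0, c("accession", "bait_spc")]
  lengths <- setNames(meta$length_aa, meta$accession)
  miss <- setdiff(detected$accession, meta$accession)
  if (length(miss) > 0) {
    abort(sprintf("no length for bait-detected protein(s): %s",
                  paste(head(miss, 10), collapse = ", ")))
  }
  saf <- detected$bait_spc / unname(lengths[detected$accession])
  tibble::tibble(accession = detected$accession, nsaf = saf / sum(saf))
}

#' Spectral-count candidate filter
#'
#' Retains proteins with at least `min_unique_peptides` unique peptides, at
#' least `min_spectra` bait spectral counts, and either no control counts
#' (bait-unique) or a bait/control fold enrichment of at least `min_fold`.
#' All boundaries are inclusive; no pseudocounts are used — bait-unique
#' proteins are a distinct branch, never a division by zero.
#'
#' @param counts Spectral-count tibble.
#' @param config An [apms_config()].
#' @return Character vector of retained accessions (sorted).
#' @export
filter_candidates <- function(counts, config = apms_config()) {
  keep <- counts$unique_peptides >= config$min_unique_peptides &
    counts$bait_spc >= config$min_spectra &
    (counts$control_spc == 0 |
       counts$bait_spc / counts$control_spc >= config$min_fold)
  sort(counts$accession[keep])
}

#' Subcellular-localization filter
#'
#' Retains candidates whose localization class is in
#' `config$allowed_localizations` (default nuclear or unknown).
#'
#' @param candidates Character vector of accessions (or a data frame with an
#'   `accession` column).
#' @param meta Protein metadata tibble.
#' @param config An [apms_config()].
#' @return Character vector of retained accessions (sorted).
#' @export
filter_localization <- function(candidates, meta, config = apms_config()) {
  candidates <- as_accessions(candidates, "candidates")
  loc <- setNames(meta$localization, meta$accession)
  miss <- setdiff(candidates, meta$accession)
  if (length(miss) > 0) {
    abort(sprintf("no localization for candidate(s): %s",
                  paste(head(miss, 10), collapse = ", ")))
  }
  sort(candidates[loc[candidates] %in% config$allowed_localizations])
}

#' Rank candidates by abundance-normalized enrichment index
#'
#' The enrichment index of protein i is `EI_i = NSAF_i / A_i`, its relative
#' abundance within the purification divided by its whole-cell abundance
#' `A_i` in ppm; high values flag proteins captured far above their cellular
#' baseline.  Candidates are sorted by decreasing index (ties broken by
#' accession) and the top `config$top_k` are returned with ranks 1..k.
#' Missing or zero whole-cell abundance is handled per
#' `config$missing_abundance_policy`; imputed rows are flagged.
#'
#' @param candidates Character vector of accessions surviving the filters.
#' @param nsaf NSAF tibble from [compute_nsaf()].
#' @param meta Protein metadata tibble.
#' @param config An [apms_config()].
#' @return A tibble of class `apms_ranking` with columns `rank`,
#'   `accession`, `nsaf`, `abundance_ppm`, `enrichment_index`,
#'   `abundance_imputed`.
#' @export
rank_by_enrichment_index <- function(candidates, nsaf, meta,
                                     config = apms_config()) {
  candidates <- as_accessions(candidates, "candidates")
  tab <- tibble::tibble(accession = candidates) |>
    dplyr::inner_join(nsaf, by = "accession") |>
    dplyr::left_join(meta[c("accession", "abundance_ppm")], by = "accession")
  if (nrow(tab) < length(candidates)) {
    abort(sprintf("no NSAF value for candidate(s): %s",
                  paste(head(setdiff(candidates, nsaf$accession), 10),
                        collapse = ", ")))
  }
  usable <- !is.na(tab$abundance_ppm) & tab$abundance_ppm > 0
  tab$abundance_imputed <- !usable
  if (any(!usable)) {
    if (config$missing_abundance_policy == "exclude") {
      tab <- tab[usable, , drop = FALSE]
    } else {
      pool <- meta$abundance_ppm[!is.na(meta$abundance_ppm) &
                                   meta$abundance_ppm > 0]
      if (length(pool) == 0) {
        abort("cannot impute whole-cell abundance: no positive values in dataset")
      }
      tab$abundance_ppm[!usable] <- min(pool)
    }
  }
  tab$enrichment_index <- tab$nsaf / tab$abundance_ppm
  out <- tab |>
    dplyr::arrange(dplyr::desc(.data$enrichment_index), .data$accession) |>
    head(config$top_k)
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  class(out) <- c("apms_ranking", class(out))
  out
}

#' Full AP-MS interaction-candidate scoring cascade
#'
#' Runs [compute_nsaf()] on the unfiltered purification, applies
#' [filter_candidates()] and [filter_localization()], ranks survivors with
#' [rank_by_enrichment_index()], and joins the spectral-count evidence
#' (bait/control counts, bait-unique flag, fold enrichment).
#'
#' @param counts Spectral-count tibble.
#' @param meta Protein metadata tibble.
#' @param config An [apms_config()].
#' @return A tibble of class `apms_ranking` with columns `rank`,
#'   `accession`, `bait_spc`, `control_spc`, `unique_flag`,
#'   `fold_enrichment` (`NA` for bait-unique proteins), `nsaf`,
#'   `abundance_ppm`, `enrichment_index`, `abundance_imputed`.
#' @export
#' @examples
#' sim <- simulate_apms(sim_config(seed = 7))
#' score_apms(sim$counts, sim$meta)
score_apms <- function(counts, meta, config = apms_config()) {
  nsaf <- compute_nsaf(counts, meta)
  cand <- filter_candidates(counts, config)
  cand <- filter_localization(cand, meta, config)
  ranked <- rank_by_enrichment_index(cand, nsaf, meta, config)
  out <- ranked |>
    dplyr::left_join(counts[c("accession", "bait_spc", "control_spc")],
                     by = "accession") |>
    dplyr::mutate(
      unique_flag = .data$control_spc == 0L,
      fold_enrichment = ifelse(.data$control_spc == 0, NA_real_,
                               .data$bait_spc / .data$control_spc)
    ) |>
    dplyr::select("rank", "accession", "bait_spc", "control_spc",
                  "unique_flag", "fold_enrichment", "nsaf", "abundance_ppm",
                  "enrichment_index", "abundance_imputed")
  class(out) <- c("apms_ranking", class(out))
  attr(out, "config") <- config
  out
}

#' @exportS3Method generics::glance
glance.apms_ranking <- function(x, ...) {
  tibble::tibble(n_ranked = nrow(x),
                 n_unique = sum(x$unique_flag %||% NA),
                 n_imputed = sum(x$abundance_imputed),
                 top_accession = if (nrow(x) > 0) x$accession[1] else NA_character_)
}
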