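#' Term over-representation by the hypergeometric upper tail
#'
#' For each term annotating K of the N background proteins, of which k fall
#' in the n-protein query, the one-sided over-representation p-value is the
#' hypergeometric upper tail `P(X >= k)`.  Terms with raw p below `alpha`
#' are flagged over-represented (matching the conventional p < 0.05 display
#' rule); Benjamini–Hochberg q-values are attached for reporting, not
#' thresholding.  When the query carries directions, `up_fraction` gives
#' the proportion of the term's query proteins that are up-regulated.
#'
#' @param query Character vector of accessions, or a data frame with
#'   `accession` and optionally `direction` columns (e.g. the differential
#'   subset of [call_differential()] output).
#' @param background Character vector of background accessions (the
#'   quantified universe); must contain the query.
#' @param annotations Annotation tibble (`term_id`, `term_name`,
#'   `accession`), e.g. from [read_annotations()] or
#'   [simulate_annotations()].  Annotations outside the background are
#'   dropped; terms annotating nothing in the background are skipped with a
#'   warning.
#' @param alpha Raw p-value display threshold (default 0.05).
#' @return A tibble of class `enrichment_result`, sorted by p-value then
#'   term id, with columns `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `up_fraction`, `over_represented`.
#' @export
go_overrepresentation <- function(query, background, annotations,
                                  alpha = 0.05) {
  directions <- as_directions(query)
  query <- as_accessions(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    abort(sprintf("query protein(s) not in background: %s",
                  paste(head(setdiff(query, background), 10), collapse = ", ")))
  }
  ann <- dplyr::distinct(tibble::as_tibble(annotations),
                         .data$term_id, .data$accession, .keep_all = TRUE)
  skipped <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::filter(!any(.data$accession %in% background)) |>
    dplyr::pull(.data$term_id) |> unique()
  if (length(skipped) > 0) {
    warn(sprintf("skipping %d term(s) with no background annotation",
                 length(skipped)))
  }
  ann <- ann[ann$accession %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(query)
  up_set <- if (!is.null(directions)) {
    names(directions)[directions == "up"]
  } else character(0)

  res <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$accession %in% query),
      k_up = sum(.data$accession %in% up_set & .data$accession %in% query),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      up_fraction = if (is.null(directions)) NA_real_ else
        ifelse(.data$k > 0, .data$k_up / .data$k, NA_real_)
    )
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$over_represented <- res$p_value < alpha
  out <- res |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "k", "K", "n", "N", "p_value",
                  "q_value", "up_fraction", "over_represented")
  class(out) <- c("enrichment_result", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x),
                 n_over_represented = sum(x$over_represented),
                 alpha = attr(x, "alpha"))
}
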