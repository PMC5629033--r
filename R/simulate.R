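#' Simulation configuration
#'
#' Parameters for the synthetic AP-MS and TMT generators.  Defaults emulate
#' the study conditions the analysis stages assume: overdispersed
#' negative-binomial spectral counts with a small set of planted
#' bait-enriched interactors, and TMT log-abundances whose within-group
#' replicate-ratio noise is calibrated so ~90% of replicate ratios fall
#' within 1.3-fold (`tmt_sigma_ratio = log2(1.3)/qnorm(0.95)`).
#'
#' @param n_proteins Number of proteins simulated.
#' @param n_true_interactors Number of planted bait-specific interactors
#'   (AP-MS).
#' @param enrichment_factor Multiplier applied to the bait-condition mean
#'   spectral count of planted interactors (>= 4).
#' @param background_mean Mean background spectral count per condition.
#' @param dispersion Negative-binomial size parameter for spectral counts
#'   (smaller = more overdispersed).  The default 4 reflects counts already
#'   aggregated over replicate runs and gel fractions.
#' @param unique_fraction Fraction of planted interactors drawn with control
#'   mean 0, exercising the uniquely-identified branch of the filter.
#' @param tmt_sigma_ratio Standard deviation of the within-group log2
#'   replicate ratio.  Default `log2(1.3)/qnorm(0.95)` (~0.2301) places 90%
#'   of replicate ratios within ±1.3-fold.
#' @param tmt_base_log2_mean,tmt_base_log2_sd Mean and sd of the per-protein
#'   base log2 reporter abundance.
#' @param n_diff_up,n_diff_down Numbers of planted up-/down-regulated
#'   proteins (TMT).
#' @param diff_log2fc Planted absolute log2 fold change.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500,
                       n_true_interactors = 20,
                       enrichment_factor = 8,
                       background_mean = 5,
                       dispersion = 4,
                       unique_fraction = 0.5,
                       tmt_sigma_ratio = log2(1.3) / qnorm(0.95),
                       tmt_base_log2_mean = 10,
                       tmt_base_log2_sd = 2,
                       n_diff_up = 50,
                       n_diff_down = 50,
                       diff_log2fc = 1,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_true_interactors = as.integer(n_true_interactors),
              enrichment_factor = enrichment_factor,
              background_mean = background_mean,
              dispersion = dispersion,
              unique_fraction = unique_fraction,
              tmt_sigma_ratio = tmt_sigma_ratio,
              tmt_base_log2_mean = tmt_base_log2_mean,
              tmt_base_log2_sd = tmt_base_log2_sd,
              n_diff_up = as.integer(n_diff_up),
              n_diff_down = as.integer(n_diff_down),
              diff_log2fc = diff_log2fc,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1) abort("n_proteins must be >= 1")
  if (cfg$n_true_interactors + cfg$n_diff_up + cfg$n_diff_down > cfg$n_proteins) {
    abort("planted counts exceed n_proteins")
  }
  pos <- c("enrichment_factor", "background_mean", "dispersion",
           "tmt_sigma_ratio", "tmt_base_log2_sd")
  for (p in pos) if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0) {
    abort(sprintf("%s must be positive", p))
  }
  if (cfg$unique_fraction < 0 || cfg$unique_fraction > 1) {
    abort("unique_fraction must be in [0, 1]")
  }
  if (cfg$diff_log2fc < 0) abort("diff_log2fc must be >= 0")
  structure(cfg, class = "sim_config")
}

protein_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Simulate an AP-MS spectral-count experiment with planted interactors
#'
#' Background proteins draw bait and control spectral counts from a
#' negative binomial with mean `background_mean` and size `dispersion`.
#' Planted interactors have their bait mean multiplied by
#' `enrichment_factor`; a fraction `unique_fraction` of them is drawn with
#' control mean 0 (bait-unique).  Planted interactors receive
#' nuclear/unknown localization and low whole-cell abundance (log-uniform
#' 0.1–10 ppm), emulating low-abundance nuclear partners of a
#' transcription-factor bait; background localization is
#' nuclear/unknown/other at 0.3/0.2/0.5 and abundance log-uniform on
#' 0.1–1000 ppm.  Lengths are uniform on 100–3000 aa.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (spectral-count tibble), `meta`
#'   (protein metadata tibble) and `truth` (list of planted accession sets).
#' @export
simulate_apms <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_proteins
  acc <- protein_ids(n)
  planted <- sort(sample(acc, config$n_true_interactors))
  n_unique <- round(config$unique_fraction * length(planted))
  unique_set <- sort(sample(planted, n_unique))

  mu_bait <- rep(config$background_mean, n)
  mu_ctl <- rep(config$background_mean, n)
  is_planted <- acc %in% planted
  mu_bait[is_planted] <- config$background_mean * config$enrichment_factor
  mu_ctl[acc %in% unique_set] <- 0

  bait <- rnbinom(n, size = config$dispersion, mu = mu_bait)
  ctl <- integer(n)
  pos <- mu_ctl > 0
  ctl[pos] <- rnbinom(sum(pos), size = config$dispersion, mu = mu_ctl[pos])

  uniq <- rpois(n, 2)
  uniq[is_planted] <- 2L + rpois(sum(is_planted), 2)

  counts <- tibble::tibble(accession = acc,
                           bait_spc = as.integer(bait),
                           control_spc = as.integer(ctl),
                           unique_peptides = as.integer(uniq))

  loc <- sample(localization_levels, n, replace = TRUE,
                prob = c(0.3, 0.2, 0.5))
  loc[is_planted] <- sample(c("nuclear", "unknown"), sum(is_planted),
                            replace = TRUE, prob = c(0.6, 0.4))
  abund <- 10^runif(n, log10(0.1), log10(1000))
  abund[is_planted] <- 10^runif(sum(is_planted), log10(0.1), log10(10))

  meta <- tibble::tibble(accession = acc,
                         gene_symbol = sprintf("Gene%05d", seq_len(n)),
                         length_aa = as.integer(sample(100:3000, n, replace = TRUE)),
                         localization = loc,
                         abundance_ppm = abund)

  list(counts = counts, meta = meta,
       truth = list(interactors = planted, up = character(0),
                    down = character(0)))
}

#' Simulate a TMT duplicate experiment with planted differential proteins
#'
#' Each protein draws a base log2 abundance from
#' N(`tmt_base_log2_mean`, `tmt_base_log2_sd`); each of the four channels
#' (control and mutant duplicates) adds independent normal noise with sd
#' `tmt_sigma_ratio / sqrt(2)`, so within-group replicate log2 ratios have
#' sd `tmt_sigma_ratio`.  Planted up (down) proteins add (subtract)
#' `diff_log2fc` in both mutant channels.  Abundances are exponentiated to
#' positive reals.
#'
#' @param config A [sim_config()].
#' @return A list with `abundance` (tibble: accession + 4 channels),
#'   `channels` (channel map) and `truth` (planted up/down sets).
#' @export
simulate_tmt <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_proteins
  acc <- protein_ids(n)
  planted <- sample(acc, config$n_diff_up + config$n_diff_down)
  up <- sort(planted[seq_len(config$n_diff_up)])
  down <- sort(setdiff(planted, up))

  base <- rnorm(n, config$tmt_base_log2_mean, config$tmt_base_log2_sd)
  sigma_ch <- config$tmt_sigma_ratio / sqrt(2)
  channels <- tmt_channels()
  m <- matrix(rnorm(n * 4, 0, sigma_ch), nrow = n) + base
  colnames(m) <- channels$channel
  shift <- numeric(n)
  shift[acc %in% up] <- config$diff_log2fc
  shift[acc %in% down] <- -config$diff_log2fc
  mut_cols <- channels$channel[channels$group == "mutant"]
  m[, mut_cols] <- m[, mut_cols] + shift

  abundance <- tibble::as_tibble(2^m)
  abundance <- dplyr::bind_cols(tibble::tibble(accession = acc), abundance)
  list(abundance = abundance, channels = channels,
       truth = list(interactors = character(0), up = up, down = down))
}

#' Simulate a planted-partition functional network
#'
#' Nodes are split into `n_clusters` near-equal communities; each
#' within-community pair is joined with probability `p_within` (edge score
#' uniform on 0.6–1.0) and each between-community pair with probability
#' `p_between` (score uniform on 0.41–0.6), so all simulated edges clear the
#' conventional 0.4 medium-confidence floor.
#'
#' @param n_nodes,n_clusters Graph size and number of planted communities.
#' @param p_within,p_between Edge probabilities, `p_between < p_within`.
#' @param seed Integer seed.
#' @return A list with `edges` (tibble of canonical scored edges) and
#'   `labels` (tibble: accession, cluster).
#' @export
simulate_network <- function(n_nodes, n_clusters, p_within, p_between,
                             seed = 1L) {
  if (!(p_between <= p_within) || p_within > 1 || p_between < 0) {
    abort("need 0 <= p_between <= p_within <= 1")
  }
  withr::local_seed(as.integer(seed))
  acc <- sprintf("N%04d", seq_len(n_nodes))
  lab <- sort(rep_len(seq_len(n_clusters), n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  same <- lab[pairs[1, ]] == lab[pairs[2, ]]
  p <- ifelse(same, p_within, p_between)
  keep <- runif(ncol(pairs)) < p
  score <- ifelse(same, runif(ncol(pairs), 0.6, 1.0),
                  runif(ncol(pairs), 0.41, 0.6))
  edges <- tibble::tibble(protein_a = acc[pairs[1, keep]],
                          protein_b = acc[pairs[2, keep]],
                          combined_score = score[keep])
  list(edges = dplyr::arrange(edges, .data$protein_a, .data$protein_b),
       labels = tibble::tibble(accession = acc, cluster = lab))
}

#' Simulate a flat term-to-protein annotation table
#'
#' Every term annotates background proteins independently at `base_rate`.
#' The first `enriched_terms` terms annotate proteins of `diff_set` at
#' `min(1, odds * base_rate)` instead, planting over-representation signal.
#'
#' @param background Character vector of background accessions.
#' @param diff_set Character vector of differential accessions (subset of
#'   `background`).
#' @param n_terms Total number of terms.
#' @param enriched_terms Number of terms with planted signal.
#' @param odds Fold increase of the annotation rate on `diff_set` (> 1 for
#'   signal).
#' @param base_rate Background annotation probability per (term, protein).
#' @param seed Integer seed.
#' @return A list with `annotations` (tibble: term_id, term_name, accession)
#'   and `enriched_terms` (character vector of planted term ids).
#' @export
simulate_annotations <- function(background, diff_set, n_terms,
                                 enriched_terms, odds, base_rate = 0.1,
                                 seed = 1L) {
  if (!all(diff_set %in% background)) abort("diff_set must be within background")
  if (enriched_terms > n_terms) abort("enriched_terms > n_terms")
  withr::local_seed(as.integer(seed))
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  planted <- term_ids[seq_len(enriched_terms)]
  is_diff <- background %in% diff_set
  rows <- purrr::map(seq_len(n_terms), function(i) {
    p <- rep(base_rate, length(background))
    if (term_ids[i] %in% planted) p[is_diff] <- min(1, odds * base_rate)
    hit <- runif(length(background)) < p
    if (!any(hit)) return(NULL)
    tibble::tibble(term_id = term_ids[i],
                   term_name = sprintf("process %04d", i),
                   accession = background[hit])
  })
  list(annotations = dplyr::bind_rows(rows), enriched_terms = planted)
}
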