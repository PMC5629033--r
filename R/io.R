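#' Read a spectral-count table
#'
#' Reads a delimited protein-level table of bait and control spectral counts
#' (SpC) plus unique-peptide counts, as exported from a search/validation
#' engine.  Column headers are mapped to roles through `col_map`, so tables
#' with arbitrary header names (including converted XLSX supplements) can be
#' ingested after a one-line mapping.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Named character vector mapping roles to header names.
#'   Roles `accession`, `bait_spc`, `control_spc` and `unique_peptides` are
#'   required.
#' @param delim Field delimiter (default tab).
#' @return A tibble with columns `accession`, `bait_spc`, `control_spc`,
#'   `unique_peptides`; counts are non-negative integers and accessions are
#'   unique.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\tbait_spc\tcontrol_spc\tunique_peptides",
#'              "P1\t10\t0\t2", "P2\t40\t10\t3"), f)
#' read_spectral_counts(f)
read_spectral_counts <- function(path,
                                 col_map = c(accession = "accession",
                                             bait_spc = "bait_spc",
                                             control_spc = "control_spc",
                                             unique_peptides = "unique_peptides"),
                                 delim = "\t") {
  need <- c("accession", "bait_spc", "control_spc", "unique_peptides")
  raw <- read_table_checked(path, col_map, need, delim)
  for (col in c("bait_spc", "control_spc", "unique_peptides")) {
    check_whole_number(raw[[col]], col)
    if (anyNA(raw[[col]])) abort(sprintf("column `%s` has missing counts", col))
    raw[[col]] <- as.integer(raw[[col]])
  }
  check_no_duplicates(raw$accession)
  tibble::as_tibble(raw[need])
}

#' Read a protein metadata table
#'
#' Per-protein metadata used by the enrichment-index ranking: sequence length
#' in amino acids, subcellular-localization class (`nuclear`, `unknown`,
#' `other`) and whole-cell abundance in parts per million (PAX-style).
#' An empty abundance field is read as missing (`NA`), never as 0 — 0 is a
#' legal measured value.
#'
#' @inheritParams read_spectral_counts
#' @param col_map Role-to-header map; roles `accession`, `length_aa`,
#'   `localization`, `abundance_ppm` required, `gene_symbol` optional.
#' @return A tibble with columns `accession`, `gene_symbol`, `length_aa`,
#'   `localization`, `abundance_ppm`.
#' @export
read_protein_meta <- function(path,
                              col_map = c(accession = "accession",
                                          gene_symbol = "gene_symbol",
                                          length_aa = "length_aa",
                                          localization = "localization",
                                          abundance_ppm = "abundance_ppm"),
                              delim = "\t") {
  need <- c("accession", "length_aa", "localization", "abundance_ppm")
  raw <- read_table_checked(path, col_map, need, delim)
  if (!"gene_symbol" %in% names(raw)) raw$gene_symbol <- NA_character_
  check_no_duplicates(raw$accession)
  check_whole_number(raw$length_aa, "length_aa", what = "length")
  if (any(raw$length_aa < 1, na.rm = TRUE) || anyNA(raw$length_aa)) {
    abort("`length_aa` must be >= 1 for every protein")
  }
  raw$length_aa <- as.integer(raw$length_aa)
  bad_loc <- setdiff(unique(raw$localization), localization_levels)
  if (length(bad_loc) > 0) {
    abort(sprintf("`localization` must be one of %s; found: %s",
                  paste(localization_levels, collapse = "/"),
                  paste(bad_loc, collapse = ", ")))
  }
  if (any(raw$abundance_ppm < 0, na.rm = TRUE)) {
    abort("`abundance_ppm` must be non-negative where present")
  }
  tibble::as_tibble(raw[c("accession", "gene_symbol", "length_aa",
                          "localization", "abundance_ppm")])
}

#' Channel map for a TMT experiment
#'
#' Builds the channel-to-(group, replicate) map used by all TMT operations.
#'
#' @param control,mutant Character vectors of channel (column) names, in
#'   replicate order.
#' @return A tibble with columns `channel`, `group`, `replicate`.
#' @export
#' @examples
#' tmt_channels(control = c("ctl_1", "ctl_2"), mutant = c("mut_1", "mut_2"))
tmt_channels <- function(control = c("ctl_1", "ctl_2"),
                         mutant = c("mut_1", "mut_2")) {
  ch <- tibble::tibble(
    channel = c(control, mutant),
    group = rep(c("control", "mutant"), c(length(control), length(mutant))),
    replicate = c(seq_along(control), seq_along(mutant))
  )
  validate_channels(ch)
  ch
}

validate_channels <- function(channels) {
  if (!all(c("channel", "group", "replicate") %in% names(channels))) {
    abort("`channels` needs columns channel, group, replicate")
  }
  check_no_duplicates(channels$channel, "channel")
  check_no_duplicates(paste(channels$group, channels$replicate),
                      "(group, replicate) pair")
  n_per <- table(channels$group)
  if (any(n_per < 2)) abort("every group needs at least 2 replicates")
  invisible(channels)
}

validate_tmt <- function(abund, channels) {
  validate_channels(channels)
  missing_ch <- setdiff(channels$channel, names(abund))
  if (length(missing_ch) > 0) {
    abort(sprintf("abundance table lacks channel column(s): %s",
                  paste(missing_ch, collapse = ", ")))
  }
  m <- as.matrix(abund[channels$channel])
  if (any(m < 0, na.rm = TRUE)) abort("TMT abundances must be non-negative")
  check_no_duplicates(abund$accession)
  invisible(abund)
}

#' Read a TMT reporter-abundance matrix
#'
#' @inheritParams read_spectral_counts
#' @param channels Channel map from [tmt_channels()]; all its channel names
#'   must appear as columns in the file.
#' @param accession_col Header of the protein-identifier column.
#' @return A tibble with `accession` plus one numeric column per channel.
#' @export
read_tmt <- function(path, channels, accession_col = "accession",
                     delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!accession_col %in% names(raw)) {
    abort(sprintf("missing required column `%s`", accession_col))
  }
  names(raw)[names(raw) == accession_col] <- "accession"
  out <- tibble::as_tibble(raw[c("accession", intersect(channels$channel, names(raw)))])
  validate_tmt(out, channels)
  out
}

#' Read a functional-association edge table
#'
#' Reads (protein_a, protein_b, combined_score) rows.  The STRING flat-file
#' dialect reports integer scores on 0–1000; under `score_scale = "auto"` the
#' whole column is divided by 1000 whenever any score exceeds 1.  Self-loops
#' are dropped with a warning and unordered duplicate pairs are collapsed
#' keeping the maximum score.
#'
#' @inheritParams read_spectral_counts
#' @param score_scale `"auto"`, `"unit"` (scores already on \[0,1\]) or
#'   `"milli"` (always divide by 1000).
#' @param col_map Role-to-header map for `protein_a`, `protein_b`,
#'   `combined_score`.
#' @return A tibble of canonical (a < b) edges with `combined_score` on
#'   \[0,1\], sorted by endpoints.
#' @export
read_edge_table <- function(path, score_scale = c("auto", "unit", "milli"),
                            col_map = c(protein_a = "protein_a",
                                        protein_b = "protein_b",
                                        combined_score = "combined_score"),
                            delim = "\t") {
  score_scale <- match.arg(score_scale)
  need <- c("protein_a", "protein_b", "combined_score")
  raw <- read_table_checked(path, col_map, need, delim)
  edges <- tibble::as_tibble(raw[need])
  normalize_edges(edges, score_scale)
}

# shared edge hygiene: scaling, self-loop removal, duplicate collapse
normalize_edges <- function(edges, score_scale = "auto") {
  s <- edges$combined_score
  divide <- switch(score_scale,
                   milli = TRUE,
                   auto = any(s > 1, na.rm = TRUE),
                   unit = FALSE)
  if (divide) s <- s / 1000
  if (any(is.na(s)) || any(s < 0 | s > 1)) {
    abort("combined_score outside [0, 1] after scaling")
  }
  edges$combined_score <- s
  loops <- edges$protein_a == edges$protein_b
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  cp <- canonical_pairs(edges$protein_a, edges$protein_b)
  edges$protein_a <- cp$a
  edges$protein_b <- cp$b
  edges |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(combined_score = max(.data$combined_score),
                     .groups = "drop") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Read a flat term-to-protein annotation table
#'
#' @inheritParams read_spectral_counts
#' @param col_map Role-to-header map for `term_id`, `term_name`, `accession`.
#' @return A tibble with unique (term_id, accession) records.
#' @export
read_annotations <- function(path,
                             col_map = c(term_id = "term_id",
                                         term_name = "term_name",
                                         accession = "accession"),
                             delim = "\t") {
  need <- c("term_id", "term_name", "accession")
  raw <- read_table_checked(path, col_map, need, delim)
  out <- dplyr::distinct(tibble::as_tibble(raw[need]),
                         .data$term_id, .data$accession, .keep_all = TRUE)
  out
}

read_table_checked <- function(path, col_map, need, delim) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_roles <- need[!(col_map[need] %in% names(raw)) | is.na(col_map[need])]
  if (length(missing_roles) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(sprintf("%s (header `%s`)", missing_roles,
                                col_map[missing_roles]), collapse = ", ")))
  }
  keep <- col_map[col_map %in% names(raw)]
  out <- raw[unname(keep)]
  names(out) <- names(keep)
  out
}

#' Write pipeline products to an output directory
#'
#' Tabular products are written as TSV with their established column order;
#' functional networks as GraphML and SIF.  A JSON run manifest records the
#' files written, the configuration, a configuration hash and the seed, so a
#' run is fully reconstructable.  Outputs are byte-stable: the same inputs
#' and configuration always produce identical files.
#'
#' @param results Named list of pipeline products (tibbles and/or
#'   `functional_network` objects).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed recorded in the manifest (or `NULL`).
#' @param config List of configuration values recorded (and hashed) in the
#'   manifest.
#' @return A tibble manifest of written files (invisibly written to
#'   `manifest.json` as well).
#' @export
write_reports <- function(results, out_dir, seed = NULL, config = list()) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", out_dir))
  }
  entries <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "functional_network")) {
      gml <- file.path(out_dir, paste0(nm, ".graphml"))
      igraph::write_graph(x$graph, gml, format = "graphml")
      sif <- file.path(out_dir, paste0(nm, ".sif"))
      writeLines(network_sif_lines(x), sif)
      entries[[length(entries) + 1L]] <-
        tibble::tibble(name = nm, file = basename(gml), kind = "graphml")
      entries[[length(entries) + 1L]] <-
        tibble::tibble(name = nm, file = basename(sif), kind = "sif")
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(tibble::as_tibble(x), f, progress = FALSE)
      entries[[length(entries) + 1L]] <-
        tibble::tibble(name = nm, file = basename(f), kind = "tsv")
    } else {
      abort(sprintf("don't know how to write result `%s` (class %s)",
                    nm, paste(class(x), collapse = "/")))
    }
  }
  manifest <- dplyr::bind_rows(entries)
  meta <- list(files = manifest, config = config,
               config_hash = rlang::hash(config), seed = seed)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

network_sif_lines <- function(net) {
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  deg <- igraph::degree(net$graph)
  isolated <- sort(names(deg)[deg == 0])
  lines <- character(0)
  if (nrow(ed) > 0) {
    cp <- canonical_pairs(ed$from, ed$to)
    ord <- order(cp$a, cp$b)
    lines <- paste(cp$a[ord], "pp", cp$b[ord], sep = "\t")
  }
  c(lines, isolated)
}
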