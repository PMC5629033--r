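# internal helpers shared across modules

# accession extraction: accept a character vector or a data frame with an
# `accession` column (optionally carrying a `direction` column)
as_accessions <- function(x, arg = "query") {
  if (is.character(x)) return(unique(x))
  if (is.data.frame(x)) {
    if (!"accession" %in% names(x)) {
      abort(sprintf("`%s` data frame must have an `accession` column", arg))
    }
    return(unique(x$accession))
  }
  abort(sprintf("`%s` must be a character vector or a data frame", arg))
}

# direction lookup from a data frame query (up/down/none); NULL if absent
as_directions <- function(x) {
  if (is.data.frame(x) && all(c("accession", "direction") %in% names(x))) {
    d <- x[!duplicated(x$accession), c("accession", "direction")]
    return(setNames(as.character(d$direction), d$accession))
  }
  NULL
}

# canonical unordered pair ordering for edges
canonical_pairs <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

check_whole_number <- function(x, col, what = "count") {
  if (length(x) == 0) return(invisible(x))
  if (!is.numeric(x)) {
    abort(sprintf("column `%s` must hold non-negative integer %ss", col, what))
  }
  bad <- which(!is.na(x) & (x < 0 | x != floor(x)))
  if (length(bad) > 0) {
    abort(sprintf(
      "column `%s` must hold non-negative integer %ss; offending row(s): %s (value(s) %s)",
      col, what, paste(head(bad, 5), collapse = ", "),
      paste(head(x[bad], 5), collapse = ", ")
    ))
  }
  invisible(x)
}

check_no_duplicates <- function(x, what = "accession") {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %ss: %s", what, paste(head(dup, 10), collapse = ", ")))
  }
  invisible(x)
}

localization_levels <- c("nuclear", "unknown", "other")
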