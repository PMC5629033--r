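#' Normalize TMT channel abundances
#'
#' Under `"total_sum"` each channel column is rescaled so its total equals
#' the mean of the original channel totals; within-channel relative
#' structure (any ratio between two proteins in a channel) is preserved.
#' `"none"` returns the input unchanged.
#'
#' @param abund TMT abundance tibble (`accession` + channel columns).
#' @param channels Channel map from [tmt_channels()].
#' @param method `"total_sum"` or `"none"`.
#' @return The abundance tibble with normalized channel columns.
#' @export
normalize_channels <- function(abund, channels,
                               method = c("total_sum", "none")) {
  method <- match.arg(method)
  validate_tmt(abund, channels)
  if (method == "none") return(abund)
  totals <- vapply(channels$channel, function(ch) sum(abund[[ch]]), numeric(1))
  if (any(totals <= 0)) {
    abort(sprintf("channel(s) with non-positive total: %s",
                  paste(channels$channel[totals <= 0], collapse = ", ")))
  }
  target <- mean(totals)
  for (ch in channels$channel) abund[[ch]] <- abund[[ch]] * target / totals[[ch]]
  abund
}

group_channels <- function(channels, group) {
  g <- channels[channels$group == group, , drop = FALSE]
  if (nrow(g) == 0) abort(sprintf("no channels in group `%s`", group))
  g$channel[order(g$replicate)]
}

#' Replicate concordance within a TMT group
#'
#' Squared Pearson correlation of log10 abundances between the two replicate
#' channels of a group; proteins with a zero abundance in either channel are
#' excluded.
#'
#' @inheritParams normalize_channels
#' @param group `"control"` or `"mutant"`.
#' @return R-squared on \[0, 1\].
#' @export
replicate_concordance <- function(abund, channels, group) {
  validate_tmt(abund, channels)
  ch <- group_channels(channels, group)
  if (length(ch) != 2) abort("replicate concordance needs exactly 2 replicates")
  x <- abund[[ch[1]]]
  y <- abund[[ch[2]]]
  ok <- x > 0 & y > 0
  if (sum(ok) < 3) abort("fewer than 3 proteins with non-zero abundances")
  cor(log10(x[ok]), log10(y[ok]))^2
}

#' Fit the within-group replicate log2-ratio distribution
#'
#' Computes within-group replicate log2 ratios (replicate 1 over
#' replicate 2), bins them with Freedman–Diaconis breaks, and fits a
#' Gaussian `a * exp(-(x - mu)^2 / (2 sigma^2))` to the histogram by
#' nonlinear least squares.  If the fit cannot be obtained (degenerate or
#' non-convergent input) a robust moment estimate (median, 1.4826 * MAD) is
#' used and flagged.  The central-90% half-width `qnorm(0.95) * sigma` and
#' the empirical fraction of ratios within `fold_window`-fold are reported
#' alongside.
#'
#' @inheritParams replicate_concordance
#' @param fold_window Fold window for the empirical coverage fraction
#'   (default 1.3, i.e. ±30%).
#' @return An object of class `ratio_fit` with fields `mu_log2`,
#'   `sigma_log2`, `central90_halfwidth_log2`, `empirical_fraction_within`,
#'   `fold_window`, `n_ratios`, `fallback`, `group`.
#' @export
fit_ratio_distribution <- function(abund, channels, group,
                                   fold_window = 1.3) {
  validate_tmt(abund, channels)
  ch <- group_channels(channels, group)
  if (length(ch) != 2) abort("ratio fit needs exactly 2 replicates")
  x <- abund[[ch[1]]]
  y <- abund[[ch[2]]]
  ok <- x > 0 & y > 0
  r <- log2(x[ok] / y[ok])
  if (length(r) < 3) abort("fewer than 3 usable ratios")

  fit <- fit_gaussian_histogram(r)
  structure(list(
    mu_log2 = fit$mu,
    sigma_log2 = fit$sigma,
    central90_halfwidth_log2 = qnorm(0.95) * fit$sigma,
    empirical_fraction_within = mean(abs(r) < log2(fold_window)),
    fold_window = fold_window,
    n_ratios = length(r),
    fallback = fit$fallback,
    group = group,
    log2_ratios = r
  ), class = "ratio_fit")
}

# Gaussian NLS on an FD-binned histogram, robust fallback on failure
fit_gaussian_histogram <- function(r) {
  robust <- list(mu = median(r), sigma = mad(r), fallback = TRUE)
  if (length(unique(r)) < 3 || stats::IQR(r) == 0) return(robust)
  h <- graphics::hist(r, breaks = "FD", plot = FALSE)
  df <- data.frame(mids = h$mids, counts = h$counts)
  start <- list(a = max(h$counts), mu = median(r), s = max(sd(r), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
                      data = df, start = start,
                      lower = c(a = 0, mu = -Inf, s = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(robust)
  cf <- coef(fit)
  if (!is.finite(cf[["s"]]) || cf[["s"]] <= 0) return(robust)
  list(mu = unname(cf[["mu"]]), sigma = abs(unname(cf[["s"]])),
       fallback = FALSE)
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf(
    "Replicate log2-ratio fit (%s group, n = %d)\n  mu = %.4f, sigma = %.4f%s\n  central 90%% half-width: %.4f log2 (%.3f-fold)\n  fraction within %.2f-fold: %.3f\n",
    x$group, x$n_ratios, x$mu_log2, x$sigma_log2,
    if (x$fallback) " [robust fallback]" else "",
    x$central90_halfwidth_log2, 2^x$central90_halfwidth_log2,
    x$fold_window, x$empirical_fraction_within))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ratio_fit <- function(x, ...) {
  tibble::tibble(term = c("mu_log2", "sigma_log2"),
                 estimate = c(x$mu_log2, x$sigma_log2))
}

#' @exportS3Method generics::glance
glance.ratio_fit <- function(x, ...) {
  tibble::tibble(mu_log2 = x$mu_log2, sigma_log2 = x$sigma_log2,
                 central90_halfwidth_log2 = x$central90_halfwidth_log2,
                 empirical_fraction_within = x$empirical_fraction_within,
                 fold_window = x$fold_window, n_ratios = x$n_ratios,
                 fallback = x$fallback, group = x$group)
}

#' Fold-change threshold from a fitted ratio distribution
#'
#' Inverts the calibration that motivates a fixed ±1.3-fold rule: the fold
#' window containing `coverage` of a centered Gaussian replicate-ratio
#' distribution is `tau = 2^(z * sigma_log2)` with
#' `z = qnorm(1 - (1 - coverage)/2)`.  With `sigma_log2 =
#' log2(1.3)/qnorm(0.95)` and `coverage = 0.9` this returns exactly 1.3.
#'
#' @param fit A `ratio_fit` object, or a numeric `sigma_log2`.
#' @param coverage Central coverage probability in (0, 1), default 0.90.
#' @return The fold threshold `tau` (>= 1).
#' @export
derive_threshold <- function(fit, coverage = 0.90) {
  if (coverage <= 0 || coverage >= 1) abort("coverage must be in (0, 1)")
  sigma <- if (inherits(fit, "ratio_fit")) fit$sigma_log2 else fit
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  2^(qnorm(1 - (1 - coverage) / 2) * sigma)
}

#' Concordant-replicate differential-abundance calls
#'
#' Computes per-replicate mutant/control ratios `r_i = mutant_i / control_i`
#' and classifies each protein: `up` when every ratio is at least
#' `fold_threshold`, `down` when every ratio is at most `1/fold_threshold`,
#' otherwise `none` (both boundaries inclusive).  Proteins with a zero
#' abundance in any channel are marked not evaluable and excluded from the
#' summary counts.
#'
#' @inheritParams normalize_channels
#' @param fold_threshold Fold threshold `tau` (> 1), default 1.3.
#' @param normalization Channel normalization applied first
#'   (see [normalize_channels()]).
#' @param pairing `"indexed"` pairs mutant_i with control_i by replicate
#'   index (default); `"cross"` requires all four cross-ratios to clear the
#'   threshold; `"average"` classifies on the ratio of mean mutant to mean
#'   control abundance.
#' @return A tibble of class `tmt_calls` with columns `accession`,
#'   `control_mean`, `mutant_mean`, `ratio_rep1`, `ratio_rep2`,
#'   `mean_ratio` (geometric), `direction` (`up`/`down`/`none`),
#'   `evaluable`.  Summary counts are available via [glance()].
#' @export
#' @examples
#' sim <- simulate_tmt(sim_config(n_proteins = 1000, seed = 3))
#' calls <- call_differential(sim$abundance, sim$channels)
#' glance(calls)
call_differential <- function(abund, channels, fold_threshold = 1.3,
                              normalization = c("total_sum", "none"),
                              pairing = c("indexed", "cross", "average")) {
  normalization <- match.arg(normalization)
  pairing <- match.arg(pairing)
  if (fold_threshold <= 1) abort("fold_threshold must be > 1")
  abund <- normalize_channels(abund, channels, normalization)
  ctl <- group_channels(channels, "control")
  mut <- group_channels(channels, "mutant")
  if (length(ctl) != 2 || length(mut) != 2) {
    abort("differential calling needs control and mutant duplicates")
  }
  cm <- as.matrix(abund[ctl])
  mm <- as.matrix(abund[mut])
  evaluable <- rowSums(cm <= 0) == 0 & rowSums(mm <= 0) == 0

  r1 <- mm[, 1] / cm[, 1]
  r2 <- mm[, 2] / cm[, 2]
  tau <- fold_threshold
  ratios <- switch(pairing,
    indexed = cbind(r1, r2),
    cross = cbind(mm[, 1] / cm[, 1], mm[, 1] / cm[, 2],
                  mm[, 2] / cm[, 1], mm[, 2] / cm[, 2]),
    average = cbind(rowMeans(mm) / rowMeans(cm)))
  up <- rowSums(ratios < tau) == 0
  down <- rowSums(ratios > 1 / tau) == 0
  direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  direction[!evaluable] <- NA_character_

  out <- tibble::tibble(
    accession = abund$accession,
    control_mean = exp(rowMeans(log(pmax(cm, .Machine$double.xmin)))),
    mutant_mean = exp(rowMeans(log(pmax(mm, .Machine$double.xmin)))),
    ratio_rep1 = r1,
    ratio_rep2 = r2,
    mean_ratio = sqrt(r1 * r2),
    direction = direction,
    evaluable = evaluable
  )
  n_up <- sum(direction == "up", na.rm = TRUE)
  n_down <- sum(direction == "down", na.rm = TRUE)
  class(out) <- c("tmt_calls", class(out))
  attr(out, "summary") <- list(n_proteins = nrow(out),
                               n_evaluated = sum(evaluable),
                               n_total = n_up + n_down,
                               n_up = n_up, n_down = n_down)
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "pairing") <- pairing
  out
}

#' @exportS3Method generics::glance
glance.tmt_calls <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n_proteins = s$n_proteins, n_evaluated = s$n_evaluated,
                 n_total = s$n_total, n_up = s$n_up, n_down = s$n_down,
                 fold_threshold = attr(x, "fold_threshold"))
}
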