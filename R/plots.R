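#' @exportS3Method ggplot2::autoplot
autoplot.tmt_calls <- function(object, ...) {
  df <- object[object$evaluable, , drop = FALSE]
  df$direction <- factor(df$direction, levels = c("none", "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$control_mean),
                                   y = log10(.data$mutant_mean),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(none = "grey60", up = "#d95f02", down = "#1b9e77")) +
    ggplot2::labs(x = "log10 mean control abundance",
                  y = "log10 mean mutant abundance",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ratio_fit <- function(object, bins = 60, ...) {
  df <- data.frame(r = object$log2_ratios)
  grid <- data.frame(x = seq(min(df$r), max(df$r), length.out = 200))
  grid$y <- stats::dnorm(grid$x, object$mu_log2, object$sigma_log2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "#d95f02", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$fold_window),
                        linetype = 2) +
    ggplot2::labs(x = "within-group replicate log2 ratio", y = "density") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.apms_ranking <- function(object, top_n = 25, ...) {
  df <- head(tibble::as_tibble(object), top_n)
  df$accession <- factor(df$accession, levels = rev(df$accession))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$enrichment_index,
                                   y = .data$accession)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$accession),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "#7570b3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "enrichment index (NSAF / ppm abundance)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.functional_network <- function(object, seed = 42, ...) {
  g <- object$graph
  withr::local_seed(as.integer(seed))
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  ed <- igraph::as_data_frame(g, what = "edges")
  pos <- setNames(seq_len(nrow(nodes)), nodes$accession)
  seg <- data.frame(x = nodes$x[pos[ed$from]], y = nodes$y[pos[ed$from]],
                    xend = nodes$x[pos[ed$to]], yend = nodes$y[pos[ed$to]])
  nodes$cluster <- factor(nodes$cluster)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$cluster,
                                     shape = .data$direction), size = 2) +
    ggplot2::scale_shape_manual(
      values = c(up = 16, down = 15, none = 1), na.value = 4) +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, top_n = 20, ...) {
  df <- head(tibble::as_tibble(object), top_n)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$term_name,
                                   fill = .data$up_fraction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::scale_fill_gradient2(low = "#1b9e77", mid = "grey85",
                                  high = "#d95f02", midpoint = 0.5,
                                  limits = c(0, 1), na.value = "grey60") +
    ggplot2::labs(x = "-log10 p", y = NULL, fill = "fraction up") +
    ggplot2::theme_minimal()
}
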