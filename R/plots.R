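#' Heat-map style plot of a pairwise DMR overlap matrix
#'
#' @param mat Matrix from [overlap_matrix()].
#' @return A ggplot object.
#' @export
plot_overlap_matrix <- function(mat) {
  df <- as_tibble(as.data.frame.table(mat, responseName = "percent"))
  names(df)[1:2] <- c("query", "subject")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$query,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$percent), "", sprintf("%.0f", .data$percent))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100), na.value = "grey90") +
    ggplot2::labs(x = "overlaps DMRs of", y = "DMRs of",
                  fill = "% overlap") +
    ggplot2::theme_minimal()
}

#' DMR size distribution plot
#'
#' @param dmrs DMR tibble (or [dmr_size_histogram()] output with `size`,
#'   `n`).
#' @param binwidth Histogram bin width in bp (default 100, the caller's bin
#'   size).
#' @return A ggplot object.
#' @export
plot_dmr_sizes <- function(dmrs, binwidth = 100) {
  sizes <- if (all(c("size", "n") %in% names(dmrs))) {
    tibble(size = rep(dmrs$size, dmrs$n))
  } else {
    tibble(size = dmrs$end - dmrs$start)
  }
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "DMR size (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot: observed vs randomized overlap
#'
#' Dark bars show the observed number of DMRs overlapping each feature
#' class; light bars the randomized mean with a standard-deviation error
#' bar; stars mark classes enriched at the add-one empirical p < 0.01.
#'
#' @param x An [enrichment_test()] result.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x) {
  df <- tidyr::pivot_longer(
    dplyr::select(tidy(x), "feature_class", observed = "observed",
                  randomized = "random_mean"),
    -"feature_class", names_to = "set", values_to = "count"
  )
  err <- dplyr::mutate(tidy(x), set = "randomized")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_class, y = .data$count,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      data = err,
      ggplot2::aes(y = .data$random_mean,
                   ymin = .data$random_mean - .data$random_sd,
                   ymax = .data$random_mean + .data$random_sd),
      width = 0.2, position = ggplot2::position_nudge(x = 0.225)) +
    ggplot2::geom_text(
      data = dplyr::filter(tidy(x), .data$enriched),
      ggplot2::aes(y = .data$observed, label = "*", fill = NULL),
      nudge_x = -0.225, vjust = -0.2, size = 6) +
    ggplot2::scale_fill_manual(values = c(observed = "grey20",
                                          randomized = "grey70")) +
    ggplot2::labs(x = NULL, y = "DMRs overlapping feature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stability category bar plot
#'
#' @param stability A [classify_stability()] result.
#' @return A ggplot object.
#' @export
plot_stability <- function(stability) {
  df <- dplyr::count(
    dplyr::filter(stability, .data$category != "unclassifiable"),
    .data$category)
  df$fraction <- df$n / sum(df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of T2 DMRs") +
    ggplot2::theme_minimal()
}
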