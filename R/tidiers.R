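#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a masked-evaluation result
#'
#' @param x A `masked_eval` object.
#' @param ... Unused.
#' @return The per-marker report tibble (one row per masked marker).
#' @export
tidy.masked_eval <- function(x, ...) x$report

#' One-row summary of a masked-evaluation result
#'
#' @param x A `masked_eval` object.
#' @param min_concordance Merge gate threshold (default 0.8).
#' @param ... Unused.
#' @return Tibble with marker count, mean concordance, mean allelic R^2,
#'   mean info and the merge gate verdict.
#' @export
glance.masked_eval <- function(x, min_concordance = 0.8, ...) {
  g <- mask_gate(x, min_concordance)
  tibble::tibble(
    n_masked = x$n_masked,
    mean_concordance = g$mean_concordance,
    mean_allelic_r2 = mean(x$report$allelic_r2, na.rm = TRUE),
    mean_info = mean(x$report$info[x$report$info != -1], na.rm = TRUE),
    mergeable = g$mergeable)
}

#' Tidy genotype PCA scores
#'
#' @param x A `genotype_pca` object.
#' @param ... Unused.
#' @return Tibble of per-sample principal component scores.
#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' One-row summary of a genotype PCA
#'
#' @param x A `genotype_pca` object.
#' @param ... Unused.
#' @return Tibble with dimensions and leading variance-explained
#'   fractions.
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples, n_markers = x$n_markers,
    n_components = length(x$varexp),
    varexp_pc1 = x$varexp[1],
    varexp_pc2 = if (length(x$varexp) > 1) x$varexp[2] else NA_real_)
}

#' One-row summary of a merged dataset
#'
#' @param x A `merged_dataset` object.
#' @param ... Unused.
#' @return Tibble with marker/sample counts, eligible dataset count,
#'   dropped-label keys and resolved duplicates.
#' @export
glance.merged_dataset <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$gen$markers),
    n_samples = n_samples(x$gen),
    n_datasets = sum(x$gates$eligible),
    n_excluded_datasets = sum(!x$gates$eligible),
    n_dropped_keys = nrow(x$dropped_keys),
    n_duplicate_samples = nrow(x$duplicates))
}

#' Scree / score plots for a genotype PCA
#'
#' @param object A `genotype_pca` object.
#' @param type `"scree"` (variance explained per component, the first
#'   `n_show` shown) or `"scores"` (PC1 vs PC2 scatter).
#' @param n_show Components on the scree plot (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_pca <- function(object, type = c("scree", "scores"),
                                  n_show = 10, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    k <- min(n_show, length(object$varexp))
    df <- tibble::tibble(component = seq_len(k),
                         varexp = object$varexp[seq_len(k)])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                     y = .data$varexp)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::scale_x_continuous(breaks = seq_len(k)) +
      ggplot2::labs(x = "Principal component",
                    y = "Variance explained") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$scores,
                    ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "PC1", y = "PC2") +
      ggplot2::theme_minimal()
  }
}

#' Concordance and allelic R^2 by MAF bin for a masked evaluation
#'
#' @param object A `masked_eval` object.
#' @param bin_width MAF bin width (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.masked_eval <- function(object, bin_width = 0.05, ...) {
  s <- summarize_by_maf(object, bin_width = bin_width)
  long <- tidyr::pivot_longer(
    s, dplyr::any_of(c("mean_concordance", "mean_allelic_r2")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_lo + bin_width / 2,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Minor allele frequency (bin midpoint)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of per-marker info scores
#'
#' @param info Info tibble; -1 sentinels are excluded.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_info_distribution <- function(info, binwidth = 0.05) {
  df <- info[!is.na(info$info) & info$info != -1, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$info)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "Info score", y = "Markers") +
    ggplot2::theme_minimal()
}
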