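#' Plot signature profiles as 96-channel bar panels
#'
#' One row per signature, channels grouped by substitution class — the
#' standard mutational-signature layout.
#'
#' @param W 96 x K signature matrix (columns sum to 1) or a `fixsig_nmf`
#'   fit.
#' @return A ggplot object.
#' @export
plot_signatures <- function(W) {
  if (inherits(W, "fixsig_nmf")) W <- W$W
  df <- tibble::tibble(
    channel = factor(rep(rownames(W), ncol(W)), levels = sbs_channels()),
    class = rep(substr(rownames(W), 3, 5), ncol(W)),
    signature = rep(colnames(W) %||% paste0("S", seq_len(ncol(W))),
                    each = nrow(W)),
    weight = as.vector(W)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$weight,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(signature ~ class, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "trinucleotide channel", y = "probability") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 4))
}

#' @method autoplot fixsig_nmf
#' @export
autoplot.fixsig_nmf <- function(object, ...) plot_signatures(object)

#' Stacked bar plot of signature exposure proportions
#'
#' Mirrors the stacked-proportion layout used to compare signature
#' contributions across change categories or samples.
#'
#' @param exposures A `fixsig_exposures` object, a `fixsig_nmf` fit, or a
#'   K x n exposure matrix.
#' @return A ggplot object.
#' @export
plot_exposures <- function(exposures) {
  H <- if (inherits(exposures, "fixsig_exposures")) exposures$proportions
  else if (inherits(exposures, "fixsig_nmf"))
    sweep(exposures$H, 2, pmax(colSums(exposures$H), 1e-300), "/")
  else as.matrix(exposures)
  df <- tibble::tibble(
    signature = rep(rownames(H) %||% paste0("S", seq_len(nrow(H))), ncol(H)),
    column = rep(colnames(H) %||% as.character(seq_len(ncol(H))),
                 each = nrow(H)),
    proportion = as.vector(H)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$proportion,
                                   fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of changes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a copy-number profile with optional segmentation
#'
#' Bin log-ratios as points, segment means overlaid as horizontal rules.
#'
#' @param profile Output of [normalize_counts()].
#' @param segments Optional output of [segment_profile()].
#' @return A ggplot object.
#' @export
plot_cn_profile <- function(profile, segments = NULL) {
  usable <- profile[!profile$masked, ]
  usable$idx <- seq_len(nrow(usable))
  p <- ggplot2::ggplot(usable, ggplot2::aes(x = .data$idx, y = .data$logratio)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "bin", y = "log2 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start_bin, xend = .data$end_bin,
                   y = .data$mean, yend = .data$mean),
      colour = "red", linewidth = 0.9, inherit.aes = FALSE
    )
  }
  p
}

#' Box plots of qPCR quality metrics by fixative
#'
#' @param metrics The `metrics` tibble of a [qc_report()].
#' @return A ggplot object.
#' @export
plot_qc_metrics <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$fixative, y = .data$value,
                                        fill = .data$fixative)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Mean sensitivity/specificity per fixative with confidence intervals
#'
#' @param summary Output of [summarize_by_fixative()].
#' @return A ggplot object.
#' @export
plot_eval_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$fixative, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(y = "mean across samples (95% CI)") +
    ggplot2::theme_minimal()
}
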