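#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Sequence-logo-style PWM plot
#'
#' Stacked per-position information content split by base - a quick-look
#' logo without glyph scaling.
#'
#' @param object A `pwm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwm <- function(object, ...) {
  d <- tidy(object) |>
    mutate(ic_share = pmax(.data$freq * .data$log_odds, 0))
  ggplot(d, aes(x = .data$position, y = .data$ic_share, fill = .data$base)) +
    geom_col() +
    labs(
      x = "motif position", y = "information (bits)",
      title = paste("consensus:", consensus(object, quiet = TRUE))
    ) +
    theme_minimal()
}

#' Metagene / metaplot profile
#'
#' @param object A `meta_profile` from [metaprofile()].
#' @param ... Unused.
#' @return A ggplot with flank/body boundaries marked.
#' @export
autoplot.meta_profile <- function(object, ...) {
  lay <- attr(object, "layout")
  b1 <- lay$flank_bins + 0.5
  b2 <- lay$flank_bins + lay$body_bins + 0.5
  ggplot(object, aes(x = .data$bin_index, y = .data$mean)) +
    geom_line() +
    geom_vline(xintercept = c(b1, b2), linetype = "dashed") +
    labs(x = "bin (5' flank | scaled body | 3' flank)", y = "mean signal") +
    theme_minimal()
}

#' Volcano-style differential-expression plot
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot of log2 ratio vs -log10 q, called genes highlighted.
#' @export
autoplot.de_result <- function(object, ...) {
  pr <- attr(object, "params")
  ggplot(
    as_tibble(object),
    aes(x = .data$log2_ratio, y = -log10(.data$q), colour = .data$called)
  ) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = pr$min_log2_fold, linetype = "dashed") +
    geom_hline(yintercept = -log10(pr$alpha), linetype = "dashed") +
    labs(x = "log2 (mutant / wild type)", y = "-log10 q") +
    theme_minimal()
}

#' SELEX cycle enrichment plot
#'
#' @param object A `selex_run` from [simulate_selex()].
#' @param ... Unused.
#' @return A ggplot of motif-containing read fraction per cycle.
#' @export
autoplot.selex_run <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$cycle, y = .data$motif_fraction)) +
    geom_line() +
    geom_point() +
    labs(x = "selection cycle", y = "motif-containing fraction") +
    theme_minimal()
}

#' Chromosome-scale methylation track plot
#'
#' @param track A [windowed_track()] tibble.
#' @return A ggplot faceted by chromosome, coloured by context.
#' @export
plot_methylation_track <- function(track) {
  ggplot(
    filter(track, !is.na(.data$level)),
    aes(x = (.data$start + .data$end) / 2, y = .data$level,
      colour = .data$context
    )
  ) +
    geom_line() +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (bp)", y = "weighted methylation level") +
    theme_minimal()
}
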