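#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PWM into a long tibble
#'
#' @param x A `pwm` object.
#' @param ... Unused.
#' @return Tibble: `position`, `base`, `freq`, `log_odds` (bits).
#' @export
tidy.pwm <- function(x, ...) {
  lo <- log_odds_matrix(x)
  tidyr::crossing(position = seq_len(x$width), base = DNA_BASES) |>
    mutate(
      freq = x$freq[cbind(.data$position, match(.data$base, DNA_BASES))],
      log_odds = lo[cbind(.data$position, match(.data$base, DNA_BASES))]
    )
}

#' @rdname tidy.pwm
#' @export
glance.pwm <- function(x, ...) {
  tibble(
    width = x$width,
    consensus = consensus(x, quiet = TRUE),
    information_content = sum(pwm_information_content(x)),
    n_sites = x$n_sites,
    pseudocount = x$pseudocount
  )
}

#' Tidy a motif-discovery fit
#'
#' @param x A `motif_fit` from [discover_motif()].
#' @param ... Unused.
#' @return The per-read best-site table.
#' @export
tidy.motif_fit <- function(x, ...) x$sites

#' @rdname tidy.motif_fit
#' @export
glance.motif_fit <- function(x, ...) {
  tibble(
    width = x$width,
    consensus = consensus(x$pwm, quiet = TRUE),
    gamma = x$gamma,
    loglik = x$loglik,
    iterations = length(x$loglik_trace),
    converged = x$converged,
    no_motif = x$no_motif
  )
}

#' Tidy a differential-expression result
#'
#' @param x A `de_result` from [call_differential_genes()].
#' @param ... Unused.
#' @return The underlying per-gene tibble.
#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  pr <- attr(x, "params")
  tibble(
    n_genes = nrow(x),
    n_called = sum(x$called),
    fraction_called = mean(x$called),
    min_log2_fold = pr$min_log2_fold,
    alpha = pr$alpha,
    use_adjusted = pr$use_adjusted
  )
}
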