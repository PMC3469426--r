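#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rnorm rbinom rpois rnbinom runif setNames sd quantile
#'   median wilcox.test plogis rlnorm
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run code with a private RNG stream so simulators are reproducible without
# clobbering the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

check_dna <- function(seq, allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "invalid character '%s' at position %d of sequence %d",
      substr(seq[i], bad[i], bad[i]), bad[i], i
    ))
  }
  invisible(seq)
}

seq_to_int <- function(seq) {
  # A=1 C=2 G=3 T=4, N/other = NA
  x <- utf8ToInt(seq)
  out <- rep(NA_integer_, length(x))
  out[x == 65L] <- 1L
  out[x == 67L] <- 2L
  out[x == 71L] <- 3L
  out[x == 84L] <- 4L
  out
}

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
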