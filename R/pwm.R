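#' Reverse-complement a DNA string
#'
#' Vectorised over its input. `N` is its own complement.
#'
#' @param seq Character vector of DNA strings over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TACTAGTA") # palindromic: returns itself
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  vapply(
    seq,
    function(s) {
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = ""
      )
    },
    character(1),
    USE.NAMES = FALSE
  )
}

#' Build a position-weight matrix from aligned sites
#'
#' Frequencies are `(count + pseudocount) / (n + 4 * pseudocount)` per
#' position, so every entry is strictly positive whenever `pseudocount > 0`.
#'
#' @param sites Character vector of equal-length DNA strings.
#' @param pseudocount Non-negative smoothing constant added to each base
#'   count. Zero is only valid when every column already contains all four
#'   bases (otherwise log-odds scores are undefined).
#' @param background Length-4 base-probability vector (A, C, G, T);
#'   default uniform.
#' @return An object of class `pwm`: a list with `freq` (w x 4 matrix),
#'   `width`, `pseudocount`, `background` and `n_sites`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, background = rep(0.25, 4)) {
  if (length(sites) < 1) abort("need at least one site")
  check_dna(sites, allow_n = FALSE)
  w <- unique(nchar(sites))
  if (length(w) != 1) abort("sites have ragged lengths; all must match")
  if (w < 1 || w > 32) abort("motif width must be in 1..32")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  counts <- matrix(0L, nrow = w, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (s in sites) {
    idx <- seq_to_int(s)
    for (i in seq_len(w)) counts[i, idx[i]] <- counts[i, idx[i]] + 1L
  }
  n <- length(sites)
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  new_pwm(freq, pseudocount = pseudocount, background = background, n_sites = n)
}

new_pwm <- function(freq, pseudocount = 0, background = rep(0.25, 4),
                    n_sites = NA_integer_) {
  stopifnot(ncol(freq) == 4)
  colnames(freq) <- DNA_BASES
  if (any(abs(rowSums(freq) - 1) > 1e-9)) abort("pwm rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  structure(
    list(
      freq = freq, width = nrow(freq), pseudocount = pseudocount,
      background = setNames(background, DNA_BASES), n_sites = n_sites
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> width %d, consensus %s, IC %.2f bits\n",
    x$width, consensus(x, quiet = TRUE), sum(pwm_information_content(x))
  ))
  print(round(x$freq, 3))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The most frequent base at each position; ties broken by the fixed base
#' order A < C < G < T (a warning reports tied positions).
#'
#' @param pwm A [build_pwm()] object.
#' @param quiet Suppress the tie warning.
#' @return A DNA string of length `pwm$width`.
#' @export
consensus <- function(pwm, quiet = FALSE) {
  stopifnot(inherits(pwm, "pwm"))
  picks <- lapply(seq_len(pwm$width), function(i) {
    row <- pwm$freq[i, ]
    which(row == max(row))
  })
  tied <- vapply(picks, length, integer(1)) > 1
  if (any(tied) && !quiet) {
    warn(sprintf(
      "consensus ties at position(s) %s broken by base order A<C<G<T",
      paste(which(tied), collapse = ", ")
    ))
  }
  paste(DNA_BASES[vapply(picks, function(p) p[1], integer(1))], collapse = "")
}

log_odds_matrix <- function(pwm) {
  if (any(pwm$freq == 0)) {
    abort("pwm has zero frequencies; rebuild with pseudocount > 0 to score")
  }
  log2(sweep(pwm$freq, 2, pwm$background, "/"))
}

pwm_information_content <- function(pwm) {
  # 0 * log(0) = 0 so strict-consensus columns are well-defined
  lo <- suppressWarnings(log2(sweep(pwm$freq, 2, pwm$background, "/")))
  term <- pwm$freq * lo
  term[pwm$freq == 0] <- 0
  rowSums(term)
}

#' Log-odds score of a single window
#'
#' Sum over positions of `log2(freq[i, base] / background[base])`, in bits.
#'
#' @param pwm A `pwm` object.
#' @param window DNA string of length `pwm$width`.
#' @param n_policy How to treat `N`: `"skip"` returns `NA`, `"background"`
#'   scores the position 0 (base drawn from background).
#' @return Score in bits (scalar).
#' @export
log_odds_score <- function(pwm, window, n_policy = c("skip", "background")) {
  n_policy <- match.arg(n_policy)
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(window) != pwm$width) abort("window length must equal pwm width")
  check_dna(window)
  idx <- seq_to_int(window)
  lo <- log_odds_matrix(pwm)
  per_pos <- lo[cbind(seq_len(pwm$width), idx)]
  if (anyNA(per_pos)) {
    if (n_policy == "skip") {
      return(NA_real_)
    }
    per_pos[is.na(per_pos)] <- 0
  }
  sum(per_pos)
}

# Exact distribution of the log-odds score of a random background w-mer,
# by positionwise convolution over scores discretised to `bin` bits.
# Returns integer score axis (units of `bin`) and the upper-tail P(S >= s).
pwm_score_tail <- function(pwm, bin = 1e-3) {
  lo <- log_odds_matrix(pwm)
  si <- round(lo / bin) # w x 4 integer bins
  bg <- pwm$background
  mins <- apply(si, 1, min)
  maxs <- apply(si, 1, max)
  lo_sum <- sum(mins)
  hi_sum <- sum(maxs)
  dist <- 1
  off <- 0 # dist[k] = P(sum == off + k - 1)
  for (i in seq_len(nrow(si))) {
    newlen <- length(dist) + (maxs[i] - mins[i])
    new <- numeric(newlen)
    for (b in 1:4) {
      sh <- si[i, b] - mins[i]
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
    off <- off + mins[i]
  }
  tail <- rev(cumsum(rev(dist)))
  list(
    bin = bin, min_int = lo_sum, max_int = hi_sum, probs = dist, tail = tail
  )
}

tail_lookup <- function(tl, score) {
  s_int <- round(score / tl$bin)
  k <- s_int - tl$min_int + 1
  n <- length(tl$tail)
  p <- numeric(length(score))
  p[k <= 1] <- 1
  # beyond the maximal achievable score: report the smallest attainable word
  # mass (tail at the maximum), never 0
  p[k > n] <- tl$tail[n]
  inside <- k >= 1 & k <= n & !(k <= 1)
  p[inside] <- tl$tail[k[inside]]
  p
}

#' Exact p-value of a PWM score
#'
#' `P(log-odds >= score)` for a random w-mer drawn from the background,
#' computed by dynamic programming over the discretised per-position score
#' distribution. Scores above the maximal achievable score return the mass
#' of the top score bin (so p is never 0; for a uniform background it is at
#' least `4^-w`).
#'
#' @param pwm A `pwm` object.
#' @param score Score in bits (vectorised).
#' @param bin Discretisation step in bits (default 1e-3).
#' @return p-values in (0, 1].
#' @export
score_pvalue <- function(pwm, score, bin = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  tail_lookup(pwm_score_tail(pwm, bin), score)
}

#' Minimal score whose p-value is at most alpha
#'
#' Inverse of [score_pvalue()]: the smallest discretised score `s` with
#' `P(S >= s) <= alpha`.
#'
#' @inheritParams score_pvalue
#' @param alpha Target p-value in (0, 1].
#' @return Threshold score in bits.
#' @export
pvalue_threshold_score <- function(pwm, alpha, bin = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  tl <- pwm_score_tail(pwm, bin)
  ok <- which(tl$tail <= alpha)
  if (length(ok) == 0) {
    abort(sprintf(
      "alpha = %g is unattainable: smallest achievable p is %g",
      alpha, tl$tail[length(tl$tail)]
    ))
  }
  (tl$min_int + ok[1] - 1) * tl$bin
}

# Rolling log-odds scores of every window of `seq` on the given strand.
# Minus-strand windows are scored as the reverse complement of the plus
# window at the same start. Windows containing N score NA under "skip".
window_scores <- function(pwm, seq, strand = "+",
                          n_policy = c("skip", "background")) {
  n_policy <- match.arg(n_policy)
  w <- pwm$width
  L <- nchar(seq)
  if (L < w) {
    return(numeric(0))
  }
  lo <- log_odds_matrix(pwm)
  if (strand == "-") {
    # score of revcomp(window) = sum_j lo[w - j + 1, comp(base_j)]
    lo <- lo[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
    colnames(lo) <- DNA_BASES
  }
  idx <- seq_to_int(seq)
  n_win <- L - w + 1
  scores <- numeric(n_win)
  has_na <- logical(n_win)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_win - 1)]
    contrib <- lo[j, ][b]
    nas <- is.na(contrib)
    if (any(nas)) {
      has_na <- has_na | nas
      contrib[nas] <- 0
    }
    scores <- scores + contrib
  }
  if (n_policy == "skip") scores[has_na] <- NA_real_
  scores
}

#' Scan a sequence for PWM occurrences with exact p-values
#'
#' Every window (on both strands if requested) whose exact score p-value is
#' at most `alpha` is reported. A palindromic motif yields hits on both
#' strands at the same start (both are reported, as scanners such as FIMO
#' do).
#'
#' @param pwm A `pwm` object.
#' @param seq DNA string to scan.
#' @param name Sequence (chromosome) name for the output.
#' @param alpha p-value cutoff (default 0.001).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @param n_policy Treatment of windows containing `N` (see
#'   [log_odds_score()]).
#' @param bin Score discretisation for the p-value DP.
#' @return Tibble of hits: `chrom`, `start` (0-based), `strand`, `score`
#'   (bits), `pvalue`; sorted by start then strand.
#' @export
scan_sequence <- function(pwm, seq, name = "seq", alpha = 0.001,
                          both_strands = TRUE,
                          n_policy = c("skip", "background"), bin = 1e-3) {
  n_policy <- match.arg(n_policy)
  stopifnot(inherits(pwm, "pwm"))
  check_dna(seq)
  empty <- tibble(
    chrom = character(), start = integer(), strand = character(),
    score = double(), pvalue = double()
  )
  if (nchar(seq) < pwm$width) {
    warn(sprintf("sequence '%s' shorter than motif width; no windows", name))
    return(empty)
  }
  tl <- pwm_score_tail(pwm, bin)
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- purrr::map_dfr(strands, function(st) {
    sc <- window_scores(pwm, seq, strand = st, n_policy = n_policy)
    p <- rep(NA_real_, length(sc))
    ok <- !is.na(sc)
    p[ok] <- tail_lookup(tl, sc[ok])
    keep <- which(!is.na(p) & p <= alpha)
    tibble(
      chrom = name, start = keep - 1L, strand = st,
      score = sc[keep], pvalue = p[keep]
    )
  })
  arrange(hits, .data$start, .data$strand)
}

#' Scan every chromosome of a genome
#'
#' @param pwm A `pwm` object.
#' @param genome A [make_genome()] object or named character vector of
#'   sequences.
#' @inheritParams scan_sequence
#' @return Tibble of hits across all chromosomes.
#' @export
scan_genome <- function(pwm, genome, alpha = 0.001, both_strands = TRUE) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$chromosomes else genome
  purrr::imap_dfr(
    as.list(seqs),
    function(s, nm) scan_sequence(pwm, s, name = nm, alpha = alpha,
                                  both_strands = both_strands)
  )
}
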