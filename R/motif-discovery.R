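#' Strand-collapsed k-mer enrichment between read pools
#'
#' Counts every k-mer window in the selected and control pools, pools each
#' k-mer with its reverse complement (one row per canonical pair), applies
#' +1 smoothing and reports the log2 ratio of pool frequencies,
#' selected over control, sorted descending.
#'
#' @param selected_reads,control_reads Character vectors of DNA reads.
#' @param k Word size (<= read length).
#' @return Tibble: `kmer` (canonical representative), `n_selected`,
#'   `n_control`, `log2_enrichment`, sorted by enrichment.
#' @export
kmer_enrichment <- function(selected_reads, control_reads, k) {
  if (length(selected_reads) == 0 || length(control_reads) == 0) {
    abort("both read sets must be nonempty")
  }
  if (k > min(nchar(c(selected_reads, control_reads)))) {
    abort("k exceeds the shortest read length")
  }
  count_pool <- function(reads) {
    x <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(reads), width = k
    )
    colSums(x)
  }
  sel <- count_pool(selected_reads)
  ctl <- count_pool(control_reads)
  kmers <- names(sel)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canonical <- ifelse(kmers <= rc, kmers, rc)
  pool <- tibble(
    canonical = canonical, kmer = kmers,
    n_selected = as.numeric(sel), n_control = as.numeric(ctl)
  ) |>
    group_by(.data$canonical) |>
    summarise(
      n_selected = sum(.data$n_selected),
      n_control = sum(.data$n_control),
      .groups = "drop"
    )
  tot_sel <- sum(pool$n_selected) + nrow(pool)
  tot_ctl <- sum(pool$n_control) + nrow(pool)
  pool |>
    mutate(
      log2_enrichment = log2(((.data$n_selected + 1) / tot_sel) /
        ((.data$n_control + 1) / tot_ctl))
    ) |>
    rename(kmer = "canonical") |>
    arrange(desc(.data$log2_enrichment))
}

# Per-read shuffled copy (base composition preserved) used as the internal
# control pool when seeding motif discovery.
shuffle_reads <- function(reads) {
  vapply(
    reads,
    function(r) {
      paste(sample(strsplit(r, "", fixed = TRUE)[[1]]), collapse = "")
    },
    character(1),
    USE.NAMES = FALSE
  )
}

pwm_from_word <- function(word, match_prob = 0.7) {
  idx <- seq_to_int(word)
  w <- length(idx)
  freq <- matrix((1 - match_prob) / 3, nrow = w, ncol = 4)
  freq[cbind(seq_len(w), idx)] <- match_prob
  new_pwm(freq)
}

# One ZOOPS EM run from a given starting PWM. Each read carries zero or one
# site; site positions are uniform within a read; the background is the
# PWM's background. Returns the fitted model plus its log-likelihood trace.
zoops_em <- function(reads_idx, start_pwm, pseudocount = 0.5,
                     max_iter = 200, tol = 1e-6) {
  w <- start_pwm$width
  bg <- start_pwm$background
  n <- length(reads_idx)
  m <- vapply(reads_idx, length, integer(1)) - w + 1L
  freq <- start_pwm$freq
  gamma <- 0.5
  loglik_trace <- numeric(0)
  obj_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  # background log-probability of each full read (constant across E-steps)
  log_bg_read <- vapply(
    reads_idx, function(ri) sum(log(bg[ri])), numeric(1)
  )
  for (iter in seq_len(max_iter)) {
    lo <- log2(sweep(freq, 2, bg, "/"))
    # odds[i][j] = P(window_j | pwm) / P(window_j | bg), per read
    loglik <- 0
    new_counts <- matrix(pseudocount, nrow = w, ncol = 4,
      dimnames = list(NULL, DNA_BASES)
    )
    z_site_total <- 0
    for (i in seq_len(n)) {
      ri <- reads_idx[[i]]
      mi <- m[i]
      sc <- numeric(mi)
      for (j in seq_len(w)) {
        sc <- sc + lo[j, ][ri[j:(j + mi - 1)]]
      }
      odds <- 2^sc
      denom <- (1 - gamma) + gamma / mi * sum(odds)
      loglik <- loglik + log(denom) + log_bg_read[i]
      z <- gamma / mi * odds / denom # posterior of a site at each start
      z_site_total <- z_site_total + sum(z)
      for (j in seq_len(w)) {
        base <- ri[j:(j + mi - 1)]
        for (b in 1:4) {
          sel <- base == b
          if (any(sel)) new_counts[j, b] <- new_counts[j, b] + sum(z[sel])
        }
      }
    }
    # the quantity EM provably never decreases is the smoothed (MAP)
    # objective: data log-likelihood plus the Dirichlet prior the
    # pseudocount encodes
    obj <- loglik + pseudocount * sum(log(freq))
    loglik_trace <- c(loglik_trace, loglik)
    obj_trace <- c(obj_trace, obj)
    if (obj < prev - 1e-6) {
      abort("EM objective decreased; internal error")
    }
    if (is.finite(prev) && obj - prev < tol) {
      converged <- TRUE
      break
    }
    prev <- obj
    freq <- new_counts / rowSums(new_counts)
    gamma <- min(max(z_site_total / n, 1e-6), 1 - 1e-6)
  }
  list(
    freq = freq, gamma = gamma, loglik = loglik_trace[length(loglik_trace)],
    loglik_trace = loglik_trace, obj_trace = obj_trace, converged = converged
  )
}

#' Discover a motif in a read pool by ZOOPS EM
#'
#' Zero-or-one-occurrence-per-sequence expectation maximisation: each read
#' holds at most one motif site; the E-step computes site-position
#' posteriors under the current PWM against the background, the M-step
#' re-estimates the PWM and the site prevalence. Starts are seeded from the
#' top strand-collapsed k-mers (against a per-read shuffled control) plus
#' random restarts; the highest-likelihood fit wins. When `width` is a
#' vector of candidate widths, the width maximising the per-column-penalised
#' log-likelihood ratio over the background-only model is selected.
#'
#' @param reads Character vector of >= 20 DNA reads.
#' @param width Motif width, or an integer vector of candidate widths.
#' @param restarts Number of random restarts added to the k-mer seeds.
#' @param seed Integer seed; the run is deterministic given it.
#' @param pseudocount M-step smoothing.
#' @param max_iter,tol EM stopping rule.
#' @param width_penalty Penalty per motif column on the log-likelihood
#'   ratio used for width selection; default `log(length(reads))`.
#' @param ic_floor Mean per-column information content (bits) below which
#'   the result is flagged `no_motif`. The default of 1 bit (half a
#'   column's 2-bit maximum) sits well above the 0.3-0.45 bits/column that
#'   ZOOPS EM extracts from motif-free reads by overfitting.
#' @return A list of class `motif_fit`: `pwm`, `sites` (per-read best start
#'   and posterior), `gamma`, `loglik`, `converged`, `no_motif`, `width`.
#' @export
discover_motif <- function(reads, width = 8, restarts = 5, seed = 1,
                           pseudocount = 0.5, max_iter = 200, tol = 1e-6,
                           width_penalty = NULL, ic_floor = 1) {
  if (length(reads) < 20) abort("need at least 20 reads")
  if (any(width < 4)) abort("width must be >= 4")
  check_dna(reads, allow_n = FALSE)
  width_penalty <- width_penalty %||% log(length(reads))
  with_seed(seed, {
    fits <- lapply(width, function(w) {
      discover_motif_one_width(
        reads, w, restarts, pseudocount, max_iter, tol
      )
    })
    # null model: every read fully from the background
    bg_loglik <- sum(nchar(reads)) * log(0.25)
    penalised <- vapply(
      seq_along(width),
      function(i) (fits[[i]]$loglik - bg_loglik) - width_penalty * width[i],
      numeric(1)
    )
    best <- fits[[which.max(penalised)]]
    w <- best$pwm$width
    ic <- mean(pwm_information_content(best$pwm))
    best$no_motif <- ic < ic_floor
    if (best$no_motif) {
      warn(sprintf(
        "mean information content %.2f bits/column below floor %.2f: no motif",
        ic, ic_floor
      ))
    }
    best
  })
}

discover_motif_one_width <- function(reads, w, restarts, pseudocount,
                                     max_iter, tol) {
  reads_idx <- lapply(reads, seq_to_int)
  enr <- kmer_enrichment(reads, shuffle_reads(reads), w)
  seed_words <- utils::head(enr$kmer, 3)
  starts <- lapply(seed_words, pwm_from_word)
  for (r in seq_len(restarts)) {
    i <- sample(length(reads), 1)
    pos <- sample(nchar(reads[i]) - w + 1, 1)
    starts <- c(starts, list(pwm_from_word(substr(reads[i], pos, pos + w - 1))))
  }
  runs <- lapply(starts, function(p0) {
    zoops_em(reads_idx, p0, pseudocount, max_iter, tol)
  })
  best <- runs[[which.max(vapply(runs, function(r) r$loglik, numeric(1)))]]
  pwm <- new_pwm(best$freq, pseudocount = pseudocount,
    n_sites = length(reads)
  )
  sites <- best_sites_table(reads_idx, pwm, best$gamma)
  if (!best$converged) {
    warn(sprintf("EM did not converge in %d iterations (width %d)", max_iter, w))
  }
  structure(
    list(
      pwm = pwm, sites = sites, gamma = best$gamma, loglik = best$loglik,
      loglik_trace = best$loglik_trace, obj_trace = best$obj_trace,
      converged = best$converged, no_motif = FALSE, width = w
    ),
    class = "motif_fit"
  )
}

best_sites_table <- function(reads_idx, pwm, gamma) {
  w <- pwm$width
  bg <- pwm$background
  lo <- log_odds_matrix(pwm)
  purrr::imap_dfr(reads_idx, function(ri, i) {
    mi <- length(ri) - w + 1L
    sc <- numeric(mi)
    for (j in seq_len(w)) sc <- sc + lo[j, ][ri[j:(j + mi - 1)]]
    odds <- 2^sc
    denom <- (1 - gamma) + gamma / mi * sum(odds)
    z <- gamma / mi * odds / denom
    k <- which.max(z)
    tibble(
      read = i, start = k - 1L, score = sc[k], posterior = z[k],
      has_site = sum(z) > 0.5
    )
  })
}

#' @export
print.motif_fit <- function(x, ...) {
  cat(sprintf(
    "<motif_fit> width %d, consensus %s, gamma %.2f, loglik %.1f%s%s\n",
    x$width, consensus(x$pwm, quiet = TRUE), x$gamma, x$loglik,
    if (x$converged) "" else " [not converged]",
    if (x$no_motif) " [no motif]" else ""
  ))
  invisible(x)
}
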