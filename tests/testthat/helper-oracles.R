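# Independent oracles and small fixture builders used across the suite.

# Enumerate the exact score distribution of a PWM over all 4^w words:
# returns scores and word probabilities under the background.
enumerate_pwm_distribution <- function(pwm) {
  lo <- log2(sweep(pwm$freq, 2, pwm$background, "/"))
  scores <- 0
  probs <- 1
  for (i in seq_len(pwm$width)) {
    scores <- as.vector(outer(scores, lo[i, ], `+`))
    probs <- as.vector(outer(probs, pwm$background, `*`))
  }
  list(scores = scores, probs = probs)
}

# Oracle upper-tail p-value by enumeration.
enumerate_pvalue <- function(pwm, score) {
  d <- enumerate_pwm_distribution(pwm)
  sum(d$probs[d$scores >= score])
}

# Enumeration oracle on the same discretised per-position scores the DP
# uses, so agreement is exact up to one bin of the query score.
enumerate_pvalue_discretised <- function(pwm, score, bin = 1e-3) {
  lo <- round(log2(sweep(pwm$freq, 2, pwm$background, "/")) / bin)
  scores <- 0
  probs <- 1
  for (i in seq_len(pwm$width)) {
    scores <- as.vector(outer(scores, lo[i, ], `+`))
    probs <- as.vector(outer(probs, pwm$background, `*`))
  }
  sum(probs[scores >= round(score / bin)])
}

# Random PWM of width w with strictly positive frequencies.
random_pwm <- function(w) {
  g <- matrix(stats::rgamma(w * 4, shape = 1) + 1e-3, nrow = w)
  suvrkit:::new_pwm(g / rowSums(g))
}

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, compute hypergeometric probabilities from log-binomials, and sum
# those not exceeding the observed table's probability (with the customary
# tiny relative slack against ties lost to rounding).
brute_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lp <- function(x) {
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }
  xs <- max(0, c1 - (n - r1)):min(c1, r1)
  p_obs <- exp(lp(a))
  sum(exp(lp(xs))[exp(lp(xs)) <= p_obs * (1 + 1e-7)])
}

# Regex-style context oracle: classify one cytosine by direct string ops.
oracle_context <- function(seq, pos, strand) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (strand == "+") {
    trip <- b[pos + seq_len(3)] # pos is 0-based; triplet starts at the C
  } else {
    idx <- pos + 1 - 0:2
    trip <- ifelse(idx >= 1, comp[b[pmax(idx, 1)]], NA)
    trip[idx < 1] <- NA
  }
  if (is.na(trip[1]) || trip[1] != "C") {
    return("not_c")
  }
  if (is.na(trip[2])) {
    return("incomplete")
  }
  if (trip[2] == "G") {
    return("CG")
  }
  if (is.na(trip[3])) {
    return("incomplete")
  }
  if (trip[3] == "G") "CHG" else "CHH"
}

random_dna <- function(n, len) {
  vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
      collapse = ""
    ),
    character(1)
  )
}

# Reads with the given word planted at a random position in a fraction of
# them.
planted_reads <- function(n, len, word, fraction, seed) {
  withr::with_seed(seed, {
    reads <- random_dna(n, len)
    k <- nchar(word)
    planted <- seq_len(round(fraction * n))
    for (i in planted) {
      pos <- sample(len - k + 1, 1)
      substr(reads[i], pos, pos + k - 1) <- word
    }
    reads
  })
}

# Bin-level noise tracks with planted depletion patches, for the region
# caller: a tiling of `size` bp per chromosome with N(0, sd) scores in both
# genotypes and `effect` added to mutant bins inside each patch.
planted_bin_tracks <- function(patches, size = 2400000, sd = 0.2,
                               effect = -2, seed = 1, bin = 500,
                               step = 250) {
  withr::with_seed(seed, {
    bins <- suvrkit::tile_genome(c(chr1 = size), bin = bin, step = step)
    wt <- dplyr::mutate(bins, score = stats::rnorm(dplyr::n(), 0, sd))
    mut <- dplyr::mutate(bins, score = stats::rnorm(dplyr::n(), 0, sd))
    if (nrow(patches) > 0) {
      mid <- (mut$start + mut$end) / 2
      for (i in seq_len(nrow(patches))) {
        hit <- mut$chrom == patches$chrom[i] &
          mid >= patches$start[i] & mid < patches$end[i]
        mut$score[hit] <- mut$score[hit] + effect
      }
    }
    list(mutant = mut, wildtype = wt)
  })
}

# Non-overlapping patches spaced well apart along one chromosome.
spaced_patches <- function(n, patch_len = 5000, spacing = 100000,
                           offset = 50000) {
  tibble::tibble(
    chrom = "chr1",
    start = as.integer(offset + (seq_len(n) - 1) * spacing),
    end = as.integer(offset + (seq_len(n) - 1) * spacing + patch_len)
  )
}

# Synthetic gene table (no genome needed) for expression tests.
synthetic_gene_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = "chr1",
      start = as.integer((seq_len(n) - 1) * 3000),
      end = as.integer((seq_len(n) - 1) * 3000 + 2000),
      strand = "+",
      baseline_expression = stats::rlnorm(n, meanlog = log(50), sdlog = 1)
    )
  })
}

# Read-midpoint coverage track on a non-overlapping tiling, for metagene
# profiles of mapped read sets.
coverage_track <- function(genome, mapped, bin = 250) {
  bins <- suvrkit::tile_genome(genome, bin = bin, step = bin)
  mid <- (mapped$start + mapped$end) %/% 2
  q <- GenomicRanges::GRanges(mapped$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  s <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  bins$score <- GenomicRanges::countOverlaps(s, q)
  bins
}
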