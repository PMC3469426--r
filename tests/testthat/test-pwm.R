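test_that("reverse_complement handles the palindrome and is an involution", {
  expect_identical(reverse_complement("TACTAGTA"), "TACTAGTA")
  expect_identical(reverse_complement("A"), "T")
  expect_identical(reverse_complement("ACGT"), "ACGT")
  withr::with_seed(11, {
    strs <- random_dna(1000, 17)
    expect_identical(reverse_complement(reverse_complement(strs)), strs)
    expect_identical(nchar(reverse_complement(strs)), nchar(strs))
  })
  expect_error(reverse_complement("ACXG"), "invalid character")
})

test_that("build_pwm counts, smooths and validates", {
  p <- build_pwm(rep("AAAA", 10), pseudocount = 0)
  expect_equal(unname(p$freq[, "A"]), rep(1, 4))

  p2 <- build_pwm(c("AC", "AG"), pseudocount = 0)
  expect_equal(unname(p2$freq[1, "A"]), 1)
  expect_equal(unname(p2$freq[2, c("C", "G")]), c(0.5, 0.5))

  p3 <- build_pwm(rep("A", 10), pseudocount = 1)
  expect_equal(unname(p3$freq[1, "A"]), 11 / 14)

  expect_error(build_pwm(c("AC", "A")), "ragged")

  withr::with_seed(5, {
    for (i in 1:20) {
      p <- build_pwm(random_dna(8, 6), pseudocount = runif(1, 0.1, 2))
      expect_true(all(abs(rowSums(p$freq) - 1) < 1e-9))
    }
  })
})

test_that("consensus picks the modal base with a fixed tie order", {
  p <- build_pwm(rep("TACTAGTA", 20), pseudocount = 0.5)
  expect_identical(consensus(p), "TACTAGTA")

  uniform <- suvrkit:::new_pwm(matrix(0.25, nrow = 4, ncol = 4))
  expect_warning(cs <- consensus(uniform), "tie")
  expect_identical(cs, "AAAA")

  skew <- suvrkit:::new_pwm(matrix(c(0.4, 0.3, 0.2, 0.1), nrow = 1))
  expect_identical(consensus(skew), "A")
})

test_that("log-odds scoring matches hand arithmetic", {
  uniform <- suvrkit:::new_pwm(matrix(0.25, nrow = 6, ncol = 4))
  expect_equal(log_odds_score(uniform, "ACGTAC"), 0)

  freq <- matrix(0.01, nrow = 8, ncol = 4)
  freq[cbind(1:8, suvrkit:::seq_to_int("TACTAGTA"))] <- 0.97
  p <- suvrkit:::new_pwm(freq)
  expect_equal(log_odds_score(p, "TACTAGTA"), 8 * log2(0.97 / 0.25),
    tolerance = 1e-12
  )

  # consensus maximises the score over all words
  d <- enumerate_pwm_distribution(p)
  expect_equal(max(d$scores), log_odds_score(p, consensus(p)))

  # N handling
  expect_true(is.na(log_odds_score(p, "NACTAGTA")))
  expect_equal(
    log_odds_score(p, "NACTAGTA", n_policy = "background"),
    7 * log2(0.97 / 0.25)
  )
})

test_that("score_pvalue agrees with exhaustive enumeration", {
  uniform <- suvrkit:::new_pwm(matrix(0.25, nrow = 5, ncol = 4))
  expect_equal(score_pvalue(uniform, 0), 1)

  strict <- build_pwm(rep("TACTAGTA", 50), pseudocount = 1e-9)
  smax <- log_odds_score(strict, "TACTAGTA")
  expect_equal(score_pvalue(strict, smax), 1 / 4^8, tolerance = 1e-6)
  # above the maximum: the smallest word mass, never 0
  expect_equal(score_pvalue(strict, smax + 10), 1 / 4^8, tolerance = 1e-6)

  withr::with_seed(41, {
    for (i in 1:10) {
      w <- sample(4:7, 1)
      p <- random_pwm(w)
      s <- unname(quantile(enumerate_pwm_distribution(p)$scores, runif(1)))
      bin <- 1e-3
      # exact agreement with enumeration over the same discretised scores
      expect_equal(score_pvalue(p, s, bin = bin),
        enumerate_pvalue_discretised(p, s, bin = bin),
        tolerance = 1e-9
      )
      # and the discretisation error is bounded by w bins on the raw scale
      expect_gte(score_pvalue(p, s), enumerate_pvalue(p, s + (w + 1) * bin) - 1e-12)
      expect_lte(score_pvalue(p, s), enumerate_pvalue(p, s - (w + 1) * bin) + 1e-12)
    }
  })
})

test_that("pvalue_threshold_score inverts score_pvalue", {
  strict <- build_pwm(rep("TACTAGTA", 50), pseudocount = 1e-9)
  # a perfect match is always reported at alpha = 0.001
  expect_lte(
    pvalue_threshold_score(strict, 0.001),
    log_odds_score(strict, "TACTAGTA")
  )

  uniform <- suvrkit:::new_pwm(matrix(0.25, nrow = 4, ncol = 4))
  expect_equal(pvalue_threshold_score(uniform, 1), 0)
  expect_error(pvalue_threshold_score(uniform, 1e-9), "unattainable")

  withr::with_seed(42, {
    for (i in 1:20) {
      p <- random_pwm(sample(4:8, 1))
      a <- 10^runif(1, -3, -0.2)
      thr <- pvalue_threshold_score(p, a)
      expect_lte(score_pvalue(p, thr), a)
      expect_gt(score_pvalue(p, thr - 2e-3), a)
    }
  })
})

test_that("scan_sequence reports planted sites on both strands and sorts", {
  strict <- build_pwm(rep("TACTAGTA", 50), pseudocount = 1e-4)
  seq <- paste0(strrep("A", 40), "TACTAGTA", strrep("C", 40))
  hits <- scan_sequence(strict, seq, name = "chrX", alpha = 1e-4)
  expect_equal(nrow(hits), 2) # palindromic: + and - at the same start
  expect_equal(unique(hits$start), 40L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_true(all(hits$pvalue <= 1e-4))

  # palindromic PWM: hit multisets on the two strands coincide
  withr::with_seed(7, {
    rand <- random_dna(1, 500)
    all_hits <- scan_sequence(strict, rand, alpha = 1)
    plus <- dplyr::filter(all_hits, strand == "+")
    minus <- dplyr::filter(all_hits, strand == "-")
    expect_equal(plus$start, minus$start)
    expect_equal(plus$score, minus$score, tolerance = 1e-9)
  })

  expect_warning(out <- scan_sequence(strict, "ACGT"), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("MEME minimal format round-trips a PWM", {
  p <- build_pwm(c("TACTAGTA", "TACTAGTA", "TACAAGTA", "GACTAGTA"),
    pseudocount = 0.5
  )
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(p, f, name = "tac")
  q <- read_meme(f)
  expect_equal(q$width, p$width)
  expect_equal(unname(q$freq), unname(p$freq), tolerance = 1e-5)
  expect_equal(unname(q$background), unname(p$background))
})
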