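test_that("context classification matches the definitions and an oracle", {
  ctx <- classify_contexts(c(x = "TTCGGA"))
  expect_equal(
    dplyr::filter(ctx, pos == 2, strand == "+")$context, "CG"
  )
  expect_equal(classify_contexts(c(x = "CAGTTT"))$context[1], "CHG")
  expect_equal(classify_contexts(c(x = "CATTTT"))$context[1], "CHH")

  # brute-force oracle on random 50-mers, both strands
  withr::with_seed(17, {
    for (s in random_dna(40, 50)) {
      got <- classify_contexts(setNames(s, "r"))
      for (i in seq_len(nrow(got))) {
        expect_identical(
          got$context[i],
          oracle_context(s, got$pos[i], got$strand[i])
        )
      }
      # every cytosine of either strand is present
      b <- strsplit(s, "")[[1]]
      expect_equal(sum(got$strand == "+"), sum(b == "C"))
      expect_equal(sum(got$strand == "-"), sum(b == "G"))
    }
  })
})

test_that("CG sites pair across strands (palindrome symmetry)", {
  withr::with_seed(23, {
    s <- random_dna(1, 2000)
  })
  ctx <- classify_contexts(setNames(s, "c"))
  plus_cg <- dplyr::filter(ctx, strand == "+", context == "CG")$pos
  minus_cg <- dplyr::filter(ctx, strand == "-", context == "CG")$pos
  expect_equal(length(plus_cg), length(minus_cg))
  expect_equal(sort(plus_cg + 1L), sort(minus_cg))
})

test_that("weighted_level is count-weighted and additive", {
  m <- tibble::tibble(
    chrom = "c", pos = c(10L, 20L), strand = "+", context = "CG",
    meth_count = c(5L, 0L), total_count = c(10L, 10L)
  )
  expect_equal(weighted_level(m, "CG"), 0.25)
  # equal depths: equals the mean of per-site fractions
  expect_equal(weighted_level(m, "CG"), mean(m$meth_count / m$total_count))
  expect_true(is.na(weighted_level(m, "CHH")))

  # additivity over disjoint intervals
  a <- list(chrom = "c", start = 0L, end = 15L)
  b <- list(chrom = "c", start = 15L, end = 30L)
  la <- weighted_level(m, "CG", a)
  lb <- weighted_level(m, "CG", b)
  expect_equal(
    weighted_level(m, "CG", list(chrom = "c", start = 0L, end = 30L)),
    (10 * la + 10 * lb) / 20
  )

  # splitting an interval and recombining changes nothing
  withr::with_seed(5, {
    mm <- tibble::tibble(
      chrom = "c", pos = sort(sample(0:999, 200)), strand = "+",
      context = "CG", meth_count = rbinom(200, 30, 0.4), total_count = 30L
    )
    whole <- weighted_level(mm, "CG", list(chrom = "c", start = 0L, end = 1000L))
    h1 <- dplyr::filter(mm, pos < 500)
    h2 <- dplyr::filter(mm, pos >= 500)
    combined <- (sum(h1$meth_count) + sum(h2$meth_count)) /
      (sum(h1$total_count) + sum(h2$total_count))
    expect_equal(whole, combined)
  })
})

test_that("windowed_track sees a planted unmethylated patch", {
  withr::with_seed(8, {
    pos <- sort(sample(0:49999, 4000))
    level <- ifelse(pos >= 20000 & pos < 30000, 0, 0.8)
    m <- tibble::tibble(
      chrom = "c", pos = pos, strand = "+", context = "CG",
      meth_count = rbinom(4000, 20, level), total_count = 20L
    )
  })
  tr <- windowed_track(m, window = 5000, step = 5000, sizes = c(c = 50000))
  cg <- dplyr::filter(tr, context == "CG")
  inside <- dplyr::filter(cg, start >= 20000, end <= 30000)
  outside <- dplyr::filter(cg, end <= 20000 | start >= 30000)
  expect_true(all(inside$level < 0.05))
  expect_true(all(outside$level > 0.7))
  # constant methylome gives constant windows
  m2 <- dplyr::mutate(m, meth_count = total_count)
  tr2 <- windowed_track(m2, window = 5000, step = 5000, sizes = c(c = 50000))
  expect_true(all(dplyr::filter(tr2, context == "CG")$level == 1))
  # absent context stays missing, not zero
  expect_true(all(is.na(dplyr::filter(tr, context == "CHH")$level)))
})

test_that("methylation metaprofiles are flat for constant methylomes and
           identical for identical genotypes", {
  withr::with_seed(12, {
    pos <- sort(sample(0:29999, 3000))
    m <- tibble::tibble(
      chrom = "c", pos = pos, strand = "+",
      context = sample(c("CG", "CHG", "CHH"), 3000, replace = TRUE),
      meth_count = 8L, total_count = 16L
    )
  })
  feats <- tibble::tibble(
    chrom = "c", start = c(5000L, 15000L), end = c(8000L, 18000L),
    strand = c("+", "-")
  )
  prof <- meth_metaprofile(m, feats, flank = 1000, body_bins = 10,
    flank_bins = 5
  )
  expect_true(all(abs(na.omit(prof$level) - 0.5) < 1e-9))

  # two genotypes simulated identically give identical profiles
  g <- make_genome(seed = 2, n_chrom = 1, chrom_length = 60000,
    n_genes = 8, n_tes = 6
  )
  a <- simulate_methylome(g, depth = 15, seed = 40)
  b <- simulate_methylome(g, depth = 15, seed = 40)
  pa <- meth_metaprofile(a$methylome, g$tes, flank = 500, body_bins = 8,
    flank_bins = 4
  )
  pb <- meth_metaprofile(b$methylome, g$tes, flank = 500, body_bins = 8,
    flank_bins = 4
  )
  expect_identical(pa, pb)
})

test_that("TE-style methylomes are body-high flank-low in CG and CHG", {
  g <- make_genome(seed = 6, n_chrom = 1, chrom_length = 80000,
    n_genes = 6, n_tes = 8, pericentromere_fraction = 0.3,
    te_pericentromere_enrichment = 1
  )
  sim <- simulate_methylome(g, depth = 20, seed = 7)
  peri_tes <- dplyr::semi_join(
    g$tes, g$pericentromeres |> dplyr::select(chrom),
    by = "chrom"
  )
  prof <- meth_metaprofile(sim$methylome, g$tes, flank = 2000,
    body_bins = 10, flank_bins = 5
  )
  for (cx in c("CG", "CHG")) {
    p <- dplyr::filter(prof, context == cx)
    expect_gt(
      mean(p$level[p$part == "body"], na.rm = TRUE),
      mean(p$level[p$part != "body"], na.rm = TRUE)
    )
  }
})

test_that("clone analysis counts converted and unconverted cytosines", {
  ref <- "ACGATTT"
  clones <- c("ACGATTT", "ACGATTT", "ATGATTT") # C site at pos 1: C,C,T
  out <- clone_percent_methylation(ref, clones)
  site <- dplyr::filter(out, pos == 1, strand == "+")
  expect_equal(site$unconverted, 2)
  expect_equal(site$total, 3)
  expect_equal(site$percent, 100 * 2 / 3, tolerance = 1e-9)

  converted <- chartr("C", "T", ref)
  all_conv <- clone_percent_methylation(ref, rep(converted, 4))
  expect_true(all(dplyr::filter(all_conv, strand == "+")$percent == 0))

  all_meth <- clone_percent_methylation(ref, rep(ref, 4))
  expect_true(all(all_meth$percent == 100))

  # a clone base that is neither reference nor conversion product is
  # excluded at that site
  weird <- clone_percent_methylation(ref, c("ACGATTT", "AGGATTT"))
  site2 <- dplyr::filter(weird, pos == 1, strand == "+")
  expect_equal(site2$total, 1)
  expect_equal(attr(weird, "n_mismatch"), 1L)

  expect_error(clone_percent_methylation(ref, "ACG"), "equal length")
})
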