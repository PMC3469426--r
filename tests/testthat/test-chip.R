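test_that("probe log ratios and centring follow the definitions", {
  probes <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
    ip = c(10, 40, 5), input = c(10, 10, 10)
  )
  lr <- probe_log_ratio(probes)
  expect_equal(lr$log_ratio, c(0, 2, -1))

  bad <- dplyr::mutate(probes, ip = c(10, 0, 5))
  expect_error(probe_log_ratio(bad), "chr1:100-150")

  expect_equal(center_scale(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center_scale(c(-1, 0, 1)), c(-1, 0, 1))
  expect_equal(center_scale(c(5, 5)), c(0, 0))
  expect_error(center_scale(3), "at least 2")
})

test_that("tile_genome enumerates half-open bins with a truncated tail", {
  expect_equal(nrow(tile_genome(c(c1 = 500))), 1)
  t1 <- tile_genome(c(c1 = 1250))
  expect_equal(t1$start, c(0L, 250L, 500L, 750L, 1000L))
  expect_equal(t1$end, c(500L, 750L, 1000L, 1250L, 1250L))
  t2 <- tile_genome(c(c1 = 400))
  expect_equal(nrow(t2), 1) # shorter than one bin: single truncated bin
  expect_equal(t2$end, 400L)
  expect_error(tile_genome(c(c1 = 100), bin = 500, step = 600), "step")
})

test_that("aggregate_bins assigns probes by midpoint and keeps gaps missing", {
  bins <- tile_genome(c(c1 = 1000))
  one <- tibble::tibble(
    chrom = "c1", start = 100L, end = 150L, ip = 4, input = 1
  ) |>
    probe_log_ratio()
  agg <- aggregate_bins(one, bins)
  expect_equal(agg$score[1], 2) # midpoint 125 in [0,500)
  expect_true(is.na(agg$score[3]))
  expect_equal(agg$n_probes[1], 1L)

  empty <- aggregate_bins(one[0, ], bins)
  expect_true(all(is.na(empty$score)))

  # midpoint on a step boundary lands in exactly the bins containing it
  boundary <- tibble::tibble(
    chrom = "c1", start = 225L, end = 275L, ip = 2, input = 1
  ) |>
    probe_log_ratio()
  aggb <- aggregate_bins(boundary, bins)
  expect_equal(aggb$n_probes, c(1L, 1L, 0L, 0L)) # mid 250 in [0,500) & [250,750)
})

test_that("zscore_transform standardises with the population sd", {
  z <- zscore_transform(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  withr::with_seed(2, {
    x <- rnorm(10000)
    zz <- zscore_transform(x)
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(suvrkit:::pop_sd(zz), 1, tolerance = 1e-9)
  })
  expect_error(zscore_transform(c(5, 5)), "variance")
  x <- c(1, NA, 3)
  expect_true(is.na(zscore_transform(x)[2]))
})

test_that("centring before z-transform changes nothing (shift invariance)", {
  withr::with_seed(9, {
    x <- rnorm(500, mean = 3)
    expect_equal(zscore_transform(center_scale(x)), zscore_transform(x),
      tolerance = 1e-9
    )
  })
})

test_that("merge_regions obeys the gap rule and is idempotent", {
  x <- tibble::tibble(
    chrom = "c1", start = c(0L, 2100L), end = c(100L, 2200L)
  )
  m <- merge_regions(x, gap = 2500)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0L, 2200L))

  y <- tibble::tibble(
    chrom = "c1", start = c(0L, 5000L), end = c(100L, 5100L)
  )
  expect_equal(nrow(merge_regions(y, gap = 2500)), 2)

  expect_error(
    merge_regions(tibble::tibble(chrom = "c1", start = c(10L, 0L),
      end = c(20L, 5L)
    ), 10),
    "sorted"
  )

  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(1:20, 1)
      s <- sort(sample(0:10000, n))
      iv <- tibble::tibble(chrom = "c1", start = s, end = s + sample(1:500, n,
        replace = TRUE
      ))
      g <- sample(0:1000, 1)
      once <- merge_regions(iv, g)
      expect_identical(merge_regions(once, g), once)
      expect_true(all(once$end > once$start))
      expect_true(all(diff(once$start) > 0))
    }
  })
})

test_that("region caller merges flagged clusters by the 2.5 kb rule", {
  # flagged-run gaps (first flagged bin start minus previous flagged bin
  # end): patch1->patch2 is 2,250 <= 2,500 so they merge; patch2->patch3 is
  # 2,850 > 2,500 so the third stays separate
  patches <- tibble::tibble(
    chrom = "chr1",
    start = c(10000L, 14400L, 19400L),
    end = c(12000L, 16400L, 21400L)
  )
  tracks <- planted_bin_tracks(patches, size = 200000, sd = 0.05,
    effect = -3, seed = 3
  )
  regions <- call_decreased_regions(tracks$mutant, tracks$wildtype,
    z_cut = -3, merge_gap = 2500
  )
  expect_equal(nrow(regions), 2)
  expect_lt(abs(regions$start[1] - 10000), 501)
  expect_lt(abs(regions$end[1] - 16400), 501)
  expect_lt(abs(regions$start[2] - 19400), 501)
  expect_true(all(regions$mean_z < -3))
  expect_true(all(regions$n_bins >= 1))
})

test_that("identical tracks are rejected as degenerate", {
  bins <- tile_genome(c(c1 = 10000))
  bins$score <- 1
  expect_error(call_decreased_regions(bins, bins), "variance|degenerate")
  other <- tile_genome(c(c1 = 12000))
  expect_error(call_decreased_regions(bins, other), "tiling")
})

test_that("noise-only tracks flag about the Gaussian tail fraction", {
  withr::with_seed(30, {
    n_flagged <- 0
    n_bins <- 0
    n_regions <- 0
    for (s in 1:10) {
      tracks <- planted_bin_tracks(spaced_patches(0), size = 500000,
        sd = 0.2, seed = 100 + s
      )
      d <- tracks$mutant$score - tracks$wildtype$score
      z <- zscore_transform(d)
      n_flagged <- n_flagged + sum(z < -3)
      n_bins <- n_bins + length(z)
      reg <- call_decreased_regions(tracks$mutant, tracks$wildtype)
      n_regions <- n_regions + nrow(reg)
    }
    expected <- pnorm(-3)
    ci <- qbinom(c(0.005, 0.995), n_bins, expected)
    expect_gte(n_flagged, ci[1])
    expect_lte(n_flagged, ci[2])
    # merged-region count stays small on pure noise
    expect_lte(n_regions / 10, 5)
  })
})

test_that("metaprofile respects orientation, layout and shift invariance", {
  bins <- tile_genome(c(c1 = 20000), bin = 100, step = 100)
  const <- dplyr::mutate(bins, score = 1)
  feats <- tibble::tibble(
    chrom = "c1", start = c(5000L, 9000L), end = c(7000L, 11000L),
    strand = c("+", "-")
  )
  prof <- metaprofile(const, feats, flank = 2000, body_bins = 10,
    flank_bins = 5
  )
  expect_true(all(abs(prof$mean - 1) < 1e-9))
  expect_equal(nrow(prof), 20)

  # step signal: 1 inside features, 0 outside
  step_track <- dplyr::mutate(
    bins,
    score = as.numeric((start >= 5000 & start < 7000) |
      (start >= 9000 & start < 11000))
  )
  sp <- metaprofile(step_track, feats, flank = 2000, body_bins = 10,
    flank_bins = 5
  )
  expect_true(all(sp$mean[sp$part == "body"] > 0.99))
  expect_lt(sp$mean[1], 0.01)
  expect_lt(sp$mean[20], 0.01)

  # ascending signal over a minus-strand feature reads descending
  asc <- dplyr::mutate(bins, score = start)
  minus <- tibble::tibble(chrom = "c1", start = 9000L, end = 11000L,
    strand = "-"
  )
  mp <- metaprofile(asc, minus, flank = 0, body_bins = 10, flank_bins = 0)
  expect_true(all(diff(mp$mean) < 0))

  # invariance to feature order
  prof2 <- metaprofile(const, feats[2:1, ], flank = 2000, body_bins = 10,
    flank_bins = 5
  )
  expect_equal(prof$mean, prof2$mean)
})

test_that("geneset signal summary sees a planted genotype shift", {
  bins <- tile_genome(c(c1 = 50000), bin = 500, step = 500)
  a <- dplyr::mutate(bins, score = 2)
  b <- dplyr::mutate(bins, score = 1)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), chrom = "c1",
    start = seq(2000L, 42000L, by = 10000L),
    end = seq(4000L, 44000L, by = 10000L), strand = "+"
  )
  out <- geneset_signal_summary(list(wt = a, mut = b), genes)
  expect_equal(out$summary$median, c(2, 1))
  expect_true(all(out$per_gene$score[out$per_gene$genotype == "wt"] == 2))
  expect_equal(out$n_excluded, 0)
})
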