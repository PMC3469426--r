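small_genome <- function(seed = 2) {
  make_genome(seed = seed, n_chrom = 2, chrom_length = 60000,
    n_genes = 12, n_tes = 10
  )
}

test_that("make_genome is byte-deterministic and respects its layout", {
  g1 <- small_genome()
  g2 <- small_genome()
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  gff1 <- withr::local_tempfile(fileext = ".gff3")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_fasta(g1$chromosomes, fa1)
  write_fasta(g2$chromosomes, fa2)
  write_genome_gff3(g1, gff1)
  write_genome_gff3(g2, gff2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gff1), readLines(gff2))

  # sequences over ACGT only; intervals inside chromosomes; genes stranded
  expect_false(any(grepl("[^ACGT]", g1$chromosomes)))
  sizes <- nchar(g1$chromosomes)
  feats <- dplyr::bind_rows(
    g1$genes[c("chrom", "start", "end")],
    g1$tes[c("chrom", "start", "end")]
  )
  expect_true(all(feats$start >= 0 & feats$end <= sizes[feats$chrom]))
  expect_true(all(feats$end > feats$start))
  expect_true(all(g1$genes$strand %in% c("+", "-")))
})

test_that("observed GC fraction sits inside a 99% binomial interval", {
  g <- make_genome(seed = 8, n_chrom = 1, chrom_length = 100000, gc = 0.5,
    n_genes = 0, n_tes = 0
  )
  n <- 100000
  gc_obs <- sum(strsplit(g$chromosomes[[1]], "")[[1]] %in% c("G", "C"))
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(gc_obs, ci[1])
  expect_lte(gc_obs, ci[2])
})

test_that("pericentromere_fraction = 0 leaves no TE in a pericentromere", {
  g <- make_genome(seed = 4, n_chrom = 1, chrom_length = 60000,
    n_genes = 5, n_tes = 8, pericentromere_fraction = 0
  )
  expect_equal(nrow(g$pericentromeres), 0)
  # genes outside pericentromeres holds vacuously; TEs place anywhere
  expect_equal(nrow(g$tes), 8)
})

test_that("infeasible feature placement fails loudly", {
  expect_error(
    make_genome(seed = 1, n_chrom = 1, chrom_length = 10000,
      n_genes = 20, n_tes = 0, max_tries = 50
    ),
    "could not place"
  )
})

test_that("plant_motif_sites writes retrievable palindromic copies", {
  g <- small_genome()
  none <- plant_motif_sites(g, gene_fraction = 0, seed = 3)
  expect_identical(none$genome$chromosomes, g$chromosomes)
  expect_equal(nrow(none$truth), 0)

  all_in <- plant_motif_sites(g, gene_fraction = 1, seed = 3)
  n_expected <- nrow(g$genes) - attr(all_in$truth, "skipped")
  expect_equal(nrow(all_in$truth), n_expected)
  for (i in seq_len(nrow(all_in$truth))) {
    r <- all_in$truth[i, ]
    site <- substr(all_in$genome$chromosomes[[r$chrom]], r$pos + 1, r$pos + 8)
    expect_identical(site, "TACTAGTA")
    # palindrome: the minus strand reads the same site at the same start
    expect_identical(reverse_complement(site), site)
  }

  # conservation: truth count equals exhaustive search count (the toy
  # genome is too small for chance octamer collisions to be likely, and
  # background occurrences only add)
  found <- sum(vapply(
    all_in$genome$chromosomes,
    function(s) length(gregexpr("TACTAGTA", s, fixed = TRUE)[[1]]),
    numeric(1)
  ))
  expect_gte(found, nrow(all_in$truth))
})

test_that("SELEX selection is flat when affinity-blind, enriching when not", {
  pwm <- build_pwm(rep("TACTAGTA", 50), pseudocount = 1)
  pool <- selex_random_pool(600, read_length = 50, core = 15, seed = 12)
  blind <- simulate_selex(pool, pwm, cycles = 5, reads_per_cycle = 600,
    stringency = 0, seed = 7
  )
  f <- blind$summary$motif_fraction
  expect_lt(diff(range(f)), 0.05) # statistically flat

  keen <- simulate_selex(pool, pwm, cycles = 9, reads_per_cycle = 600,
    stringency = 2, seed = 7
  )
  expect_true(all(diff(keen$summary$motif_fraction) >= -0.02))
  expect_gt(
    keen$summary$motif_fraction[10],
    keen$summary$motif_fraction[2]
  )

  rerun <- simulate_selex(pool, pwm, cycles = 9, reads_per_cycle = 600,
    stringency = 2, seed = 7
  )
  expect_identical(keen$pools, rerun$pools)
})

test_that("ChIP array simulation is seeded and plants genotype-specific patches", {
  g <- small_genome()
  no_noise <- simulate_chip_arrays(g, c("wildtype", "suvr5"),
    noise_sd = 0, seed = 5
  )
  expect_equal(no_noise$probes$wildtype$ip, no_noise$probes$suvr5$ip)

  spec <- tibble::tibble(
    chrom = "chr1", start = 1000L, end = 4000L,
    genotypes = "suvr5", effect = -2
  )
  sim <- simulate_chip_arrays(g, c("wildtype", "suvr5", "kyp"),
    effect_spec = spec, noise_sd = 0, seed = 5
  )
  expect_true("suvr5" %in% unlist(strsplit(sim$truth$genotypes, ",")))
  expect_false("kyp" %in% unlist(strsplit(sim$truth$genotypes, ",")))
  lr <- function(p) log2(p$ip / p$input)
  d_suvr5 <- lr(sim$probes$suvr5) - lr(sim$probes$wildtype)
  d_kyp <- lr(sim$probes$kyp) - lr(sim$probes$wildtype)
  mid <- (sim$probes$suvr5$start + sim$probes$suvr5$end) / 2
  inside <- sim$probes$suvr5$chrom == "chr1" & mid >= 1000 & mid < 4000
  expect_true(all(abs(d_suvr5[inside] + 2) < 1e-9))
  expect_true(all(abs(d_kyp) < 1e-9))

  rerun <- simulate_chip_arrays(g, c("wildtype", "suvr5", "kyp"),
    effect_spec = spec, noise_sd = 0.3, seed = 5
  )
  rerun2 <- simulate_chip_arrays(g, c("wildtype", "suvr5", "kyp"),
    effect_spec = spec, noise_sd = 0.3, seed = 5
  )
  expect_identical(rerun$probes, rerun2$probes)
  expect_error(
    simulate_chip_arrays(g, "wildtype", noise_sd = -1),
    "noise_sd"
  )
})

test_that("methylome simulation hits its compartment levels", {
  g <- small_genome()
  zero <- simulate_methylome(
    g,
    context_levels = list(
      heterochromatin = c(CG = 0, CHG = 0, CHH = 0),
      euchromatin = c(CG = 0, CHG = 0, CHH = 0),
      patch = c(CG = 0, CHG = 0, CHH = 0)
    ),
    depth = 10, seed = 3
  )
  expect_true(all(zero$methylome$meth_count == 0))
  expect_true(all(zero$methylome$total_count == 10))

  m1 <- simulate_methylome(g, depth = 20, seed = 6)
  m2 <- simulate_methylome(g, depth = 20, seed = 6)
  expect_identical(m1$methylome, m2$methylome)

  # recovered weighted level inside a 99% binomial CI (n sites >= 1000)
  het_cg <- dplyr::filter(
    m1$truth, compartment == "heterochromatin", context == "CG"
  )
  calls <- dplyr::semi_join(m1$methylome, het_cg,
    by = c("chrom", "pos", "strand")
  )
  n_reads <- sum(calls$total_count)
  ci <- qbinom(c(0.005, 0.995), n_reads, 0.9) / n_reads
  lev <- weighted_level(calls, "CG")
  expect_gte(lev, ci[1])
  expect_lte(lev, ci[2])
})

test_that("RNA-seq counts respect the null, the fold and the seed", {
  genes <- synthetic_gene_table(200, seed = 2)
  null <- simulate_rnaseq_counts(genes, c("a", "b"), seed = 4)
  expect_equal(nrow(null$truth), 0)
  expect_equal(dim(null$counts), c(200, 4))

  poisson_like <- simulate_rnaseq_counts(genes, c("a", "b"),
    dispersion = 0, library_size = 1e7, seed = 5
  )
  ratio <- sum(poisson_like$counts$a) / sum(poisson_like$counts$b)
  expect_equal(ratio, 1, tolerance = 0.01)

  r1 <- simulate_rnaseq_counts(genes, c("a", "b"), seed = 9)
  r2 <- simulate_rnaseq_counts(genes, c("a", "b"), seed = 9)
  expect_identical(r1$counts, r2$counts)

  expect_error(
    simulate_rnaseq_counts(genes[0, ], c("a", "b")),
    "empty gene list"
  )
  expect_error(
    simulate_rnaseq_counts(genes, "a",
      de_spec = tibble::tibble(gene_id = "g0001", genotypes = "a", fold = -1)
    ),
    "fold"
  )
})
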