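#' Starting pools for SELEX simulation
#'
#' `selex_random_pool()` emulates a synthetic oligo library: fixed flanking
#' sequence around a random core (15 bp by default). `selex_genome_pool()`
#' emulates fragmented genomic DNA (~100 bp fragments drawn uniformly from
#' the genome, random strand).
#'
#' @param n Number of reads.
#' @param read_length Total read length (random pool).
#' @param core Length of the randomised core.
#' @param seed Integer seed.
#' @return Character vector of reads.
#' @export
selex_random_pool <- function(n, read_length = 50, core = 15, seed = 1) {
  if (core > read_length) abort("core longer than read")
  with_seed(seed, {
    flank_len <- read_length - core
    left_len <- flank_len %/% 2
    right_len <- flank_len - left_len
    left <- paste(sample(DNA_BASES, left_len, replace = TRUE), collapse = "")
    right <- paste(sample(DNA_BASES, right_len, replace = TRUE), collapse = "")
    vapply(
      seq_len(n),
      function(i) {
        paste0(
          left,
          paste(sample(DNA_BASES, core, replace = TRUE), collapse = ""),
          right
        )
      },
      character(1)
    )
  })
}

#' @rdname selex_random_pool
#' @param genome A [make_genome()] object.
#' @param fragment_length Fragment size in bp.
#' @export
selex_genome_pool <- function(genome, n, fragment_length = 100, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  with_seed(seed, {
    sizes <- chrom_sizes(genome)
    chroms <- sample(names(sizes), n, replace = TRUE,
      prob = sizes / sum(sizes)
    )
    vapply(
      chroms,
      function(nm) {
        start <- sample(0:(sizes[[nm]] - fragment_length), 1)
        frag <- substr(genome$chromosomes[[nm]], start + 1,
          start + fragment_length
        )
        if (runif(1) < 0.5) frag else reverse_complement(frag)
      },
      character(1),
      USE.NAMES = FALSE
    )
  })
}

best_window_score <- function(pwm, reads) {
  vapply(
    reads,
    function(r) {
      if (nchar(r) < pwm$width) {
        return(-Inf)
      }
      max(
        window_scores(pwm, r, "+"),
        window_scores(pwm, r, "-"),
        na.rm = TRUE
      )
    },
    numeric(1),
    USE.NAMES = FALSE
  )
}

#' Simulate iterative SELEX enrichment
#'
#' Each cycle resamples the pool with replacement, retaining reads with
#' probability `plogis(stringency * (best_score - threshold))` where
#' `best_score` is the read's best PWM log-odds window on either strand.
#' With `stringency = 0` selection is affinity-blind. Per cycle the
#' fraction of reads carrying a site above the scan threshold is recorded.
#'
#' @param pool Character vector of starting reads (see
#'   [selex_random_pool()] / [selex_genome_pool()]).
#' @param pwm The binding model driving selection.
#' @param cycles Number of selection cycles (>= 1).
#' @param reads_per_cycle Pool size resampled at each cycle.
#' @param stringency Slope of the logistic retention curve (0 = none).
#' @param seed Integer seed.
#' @param alpha Scan p-value used both as the default logistic midpoint and
#'   to score the per-cycle motif-containing fraction.
#' @param threshold Logistic midpoint in bits; defaults to
#'   `pvalue_threshold_score(pwm, alpha)`.
#' @return List of class `selex_run`: `pools` (list of per-cycle read
#'   vectors, cycle 0 = input), `summary` tibble
#'   (`cycle`, `motif_fraction`), `threshold`.
#' @export
simulate_selex <- function(pool, pwm, cycles = 9, reads_per_cycle = 2000,
                           stringency = 1, seed = 1, alpha = 0.001,
                           threshold = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (cycles < 1) abort("cycles must be >= 1")
  if (length(pool) == 0) abort("empty starting pool")
  threshold <- threshold %||% pvalue_threshold_score(pwm, alpha)
  with_seed(seed, {
    pools <- vector("list", cycles + 1)
    pools[[1]] <- pool
    frac <- numeric(cycles + 1)
    scores <- best_window_score(pwm, pool)
    frac[1] <- mean(scores >= threshold)
    current <- pool
    for (cy in seq_len(cycles)) {
      retain <- plogis(stringency * (scores - threshold))
      if (all(retain == 0)) abort("degenerate selection: all retention probabilities zero")
      keep <- sample(length(current), reads_per_cycle, replace = TRUE,
        prob = retain
      )
      current <- current[keep]
      scores <- scores[keep]
      pools[[cy + 1]] <- current
      frac[cy + 1] <- mean(scores >= threshold)
    }
    structure(
      list(
        pools = pools,
        summary = tibble(cycle = 0:cycles, motif_fraction = frac),
        threshold = threshold
      ),
      class = "selex_run"
    )
  })
}

#' Simulate H3K9me2 tiling-array probe data
#'
#' Lays probes along each chromosome and draws, per genotype, a per-probe
#' log2(IP/input) equal to a latent H3K9me2 level plus Gaussian noise. The
#' latent level is high over pericentromeres and TEs and low elsewhere;
#' `effect_spec` plants genotype-specific depletion patches (additive
#' shifts, typically negative) that become the ground truth for the region
#' caller.
#'
#' @param genome A [make_genome()] object.
#' @param genotypes Character vector of genotype labels; the first is
#'   conventionally the wild type (patches simply name the genotypes they
#'   affect).
#' @param probe_spacing,probe_width Array design in bp.
#' @param effect_spec Tibble `chrom`, `start`, `end`, `genotypes`
#'   (comma-separated labels), `effect` (log2 shift). NULL for no patches.
#' @param noise_sd Gaussian noise SD on the log2 ratio (must be >= 0).
#' @param base_levels Named vector: latent level in `heterochromatin`
#'   (pericentromere or TE) and `euchromatin`.
#' @param input_intensity Input-channel intensity used to back out IP.
#' @param seed Integer seed.
#' @return List: `probes` (named list of per-genotype tibbles
#'   `chrom start end ip input`), `truth` (the effect_spec).
#' @export
simulate_chip_arrays <- function(genome, genotypes, probe_spacing = 100,
                                 probe_width = 50, effect_spec = NULL,
                                 noise_sd = 0.2,
                                 base_levels = c(heterochromatin = 1.5,
                                   euchromatin = 0.2
                                 ),
                                 input_intensity = 1000, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (probe_spacing <= 0) abort("probe_spacing must be > 0")
  effect_spec <- effect_spec %||% tibble(
    chrom = character(), start = integer(), end = integer(),
    genotypes = character(), effect = double()
  )
  probes <- purrr::imap_dfr(as.list(chrom_sizes(genome)), function(L, nm) {
    starts <- seq(0, L - probe_width, by = probe_spacing)
    tibble(chrom = nm, start = as.integer(starts),
      end = as.integer(starts + probe_width)
    )
  })
  mid <- (probes$start + probes$end) %/% 2
  het <- bind_rows(
    genome$pericentromeres |> select("chrom", "start", "end"),
    genome$tes |> select("chrom", "start", "end")
  )
  in_het <- overlaps_point(probes$chrom, mid, het)
  latent0 <- ifelse(in_het, base_levels[["heterochromatin"]],
    base_levels[["euchromatin"]]
  )
  with_seed(seed, {
    out <- lapply(setNames(genotypes, genotypes), function(g) {
      latent <- latent0
      spec_g <- effect_spec |>
        filter(purrr::map_lgl(
          strsplit(.data$genotypes, ","),
          function(gs) g %in% trimws(gs)
        ))
      if (nrow(spec_g) > 0) {
        for (i in seq_len(nrow(spec_g))) {
          hit <- probes$chrom == spec_g$chrom[i] &
            mid >= spec_g$start[i] & mid < spec_g$end[i]
          latent[hit] <- latent[hit] + spec_g$effect[i]
        }
      }
      lr <- latent + rnorm(nrow(probes), sd = noise_sd)
      probes |>
        mutate(input = input_intensity, ip = input_intensity * 2^lr)
    })
    list(probes = out, truth = effect_spec)
  })
}

overlaps_point <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end)
  )
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Simulate a per-cytosine bisulfite methylome
#'
#' Classifies every cytosine of the genome into CG/CHG/CHH context, assigns
#' each a compartment (pericentromeric heterochromatin, chromosome arm, or
#' a planted low-methylation patch) and draws methylated counts
#' `Binomial(depth, level[compartment, context])`. Patch levels are applied
#' identically in every genotype simulated from the same patches, which is
#' the methylation-independence design used as a negative control.
#'
#' @param genome A [make_genome()] object.
#' @param context_levels Named list of per-compartment level vectors, e.g.
#'   `list(heterochromatin = c(CG = .9, CHG = .7, CHH = .3), euchromatin =
#'   c(CG = .25, CHG = .1, CHH = .04), patch = c(CG = .02, CHG = .01,
#'   CHH = .01))`.
#' @param depth Read depth per cytosine (>= 1).
#' @param patches Tibble `chrom`, `start`, `end` of low-methylation
#'   patches, or NULL.
#' @param seed Integer seed.
#' @return List: `methylome` tibble (`chrom pos strand context meth_count
#'   total_count`, 0-based `pos`), `truth` (compartment per cytosine).
#' @export
simulate_methylome <- function(genome, context_levels = NULL, depth = 20,
                               patches = NULL, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (depth < 1) abort("depth must be >= 1")
  context_levels <- context_levels %||% list(
    heterochromatin = c(CG = 0.9, CHG = 0.7, CHH = 0.3),
    euchromatin = c(CG = 0.25, CHG = 0.1, CHH = 0.04),
    patch = c(CG = 0.02, CHG = 0.01, CHH = 0.01)
  )
  for (lv in context_levels) {
    if (any(lv < 0 | lv > 1)) abort("all levels must be in [0, 1]")
  }
  calls <- classify_contexts(genome) |>
    filter(.data$context != "incomplete")
  het <- genome$pericentromeres |> select("chrom", "start", "end")
  compartment <- rep("euchromatin", nrow(calls))
  compartment[overlaps_point(calls$chrom, calls$pos, het)] <- "heterochromatin"
  if (!is.null(patches) && nrow(patches) > 0) {
    compartment[overlaps_point(calls$chrom, calls$pos, patches)] <- "patch"
  }
  level <- vapply(
    seq_len(nrow(calls)),
    function(i) context_levels[[compartment[i]]][[calls$context[i]]],
    numeric(1)
  )
  with_seed(seed, {
    meth <- rbinom(nrow(calls), size = depth, prob = level)
    methylome <- calls |>
      mutate(meth_count = meth, total_count = depth)
    list(
      methylome = methylome,
      truth = calls |> mutate(compartment = compartment, level = level)
    )
  })
}

#' Simulate an RNA-seq counts matrix with planted differential genes
#'
#' Counts are negative-binomial around `baseline x fold`, rescaled so each
#' sample's expected total equals `library_size` (Poisson when
#' `dispersion = 0`; variance `m + dispersion * m^2` otherwise). Genes in
#' `de_spec` get the same fold change in every genotype that lists them, so
#' shared planted sets model epistasis.
#'
#' @param genes Gene tibble from [make_genome()] (`gene_id`, `start`,
#'   `end`, `baseline_expression`).
#' @param genotypes Character vector of sample labels; the first is
#'   conventionally the wild type.
#' @param de_spec Tibble `gene_id`, `genotypes` (comma-separated),
#'   `fold` (> 0), or NULL for a fully null design.
#' @param library_size Expected total reads per sample.
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param seed Integer seed.
#' @return List: `counts` (tibble `gene_id`, `length`, one column per
#'   genotype), `truth` (expanded de_spec).
#' @export
simulate_rnaseq_counts <- function(genes, genotypes, de_spec = NULL,
                                   library_size = 1e6, dispersion = 0.05,
                                   seed = 1) {
  if (nrow(genes) == 0) abort("empty gene list")
  if (dispersion < 0) abort("dispersion must be >= 0")
  de_spec <- de_spec %||% tibble(
    gene_id = character(), genotypes = character(), fold = double()
  )
  if (any(de_spec$fold <= 0)) abort("fold changes must be > 0")
  with_seed(seed, {
    base <- genes$baseline_expression
    counts <- lapply(setNames(genotypes, genotypes), function(g) {
      fold <- rep(1, nrow(genes))
      if (nrow(de_spec) > 0) {
        affects <- purrr::map_lgl(
          strsplit(de_spec$genotypes, ","),
          function(gs) g %in% trimws(gs)
        )
        for (i in which(affects)) {
          fold[genes$gene_id == de_spec$gene_id[i]] <- de_spec$fold[i]
        }
      }
      mu <- base * fold
      mu <- mu / sum(mu) * library_size
      if (dispersion == 0) {
        rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      }
    })
    counts_tbl <- tibble(
      gene_id = genes$gene_id,
      length = as.integer(genes$end - genes$start)
    ) |>
      bind_cols(as_tibble(counts))
    list(counts = counts_tbl, truth = de_spec)
  })
}
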