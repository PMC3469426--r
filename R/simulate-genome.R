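#' Generate a small annotated genome with known organisation
#'
#' Builds a multi-chromosome toy genome laid out like a plant chromosome: a
#' central pericentromeric block per chromosome (TE-rich, the high-H3K9me2
#' compartment) with gene-bearing arms. Transposable elements are placed
#' preferentially inside pericentromeres; genes only in the arms. All
#' coordinates are 0-based half-open.
#'
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param gc G+C fraction of the random sequence.
#' @param n_genes,n_tes Feature counts across the genome.
#' @param pericentromere_fraction Fraction of each chromosome occupied by
#'   the central pericentromeric block (0 disables it).
#' @param te_pericentromere_enrichment Probability that a TE is placed
#'   inside a pericentromere (when one exists).
#' @param gene_length,te_length Length ranges (bp) sampled uniformly.
#' @param max_tries Placement attempts per feature before a
#'   placement-failure error naming the feature.
#' @return An object of class `synthetic_genome`: list with `chromosomes`
#'   (named character vector), `pericentromeres`, `genes`, `tes` (tibbles)
#'   and `seed`.
#' @export
make_genome <- function(seed = 1, n_chrom = 2, chrom_length = 200000,
                        gc = 0.4, n_genes = 100, n_tes = 60,
                        pericentromere_fraction = 0.25,
                        te_pericentromere_enrichment = 0.8,
                        gene_length = c(1000, 3000),
                        te_length = c(300, 2000),
                        max_tries = 2000) {
  if (gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  if (pericentromere_fraction < 0 || pericentromere_fraction >= 1) {
    abort("pericentromere_fraction must be in [0, 1)")
  }
  with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(n_chrom))
    probs <- c(
      A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2
    )
    chromosomes <- setNames(
      vapply(
        chrom_names,
        function(nm) {
          paste(sample(DNA_BASES, chrom_length, replace = TRUE, prob = probs),
            collapse = ""
          )
        },
        character(1)
      ),
      chrom_names
    )
    peri <- if (pericentromere_fraction > 0) {
      half <- round(chrom_length * pericentromere_fraction / 2)
      mid <- chrom_length %/% 2
      tibble(
        chrom = chrom_names,
        start = as.integer(mid - half), end = as.integer(mid + half)
      )
    } else {
      tibble(chrom = character(), start = integer(), end = integer())
    }

    occupied <- lapply(setNames(chrom_names, chrom_names), function(nm) {
      tibble(start = integer(), end = integer())
    })
    in_peri <- function(chrom, start, end) {
      p <- peri[peri$chrom == chrom, ]
      nrow(p) > 0 && any(start < p$end & end > p$start)
    }
    overlaps_occupied <- function(chrom, start, end) {
      o <- occupied[[chrom]]
      nrow(o) > 0 && any(start < o$end & end > o$start)
    }
    place <- function(label, len, want_peri) {
      for (try in seq_len(max_tries)) {
        chrom <- sample(chrom_names, 1)
        p <- peri[peri$chrom == chrom, ]
        if (want_peri && nrow(p) > 0) {
          start <- sample(p$start[1]:(p$end[1] - len), 1)
        } else {
          start <- sample(0:(nchar(chromosomes[[chrom]]) - len), 1)
        }
        end <- start + len
        hits_peri <- in_peri(chrom, start, end)
        if (!want_peri && hits_peri) next
        if (want_peri && nrow(p) > 0 && !hits_peri) next
        if (overlaps_occupied(chrom, start, end)) next
        occupied[[chrom]] <<- bind_rows(
          occupied[[chrom]], tibble(start = start, end = end)
        )
        return(tibble(chrom = chrom, start = as.integer(start),
          end = as.integer(end)
        ))
      }
      abort(sprintf("could not place feature '%s' after %d tries", label,
        max_tries
      ))
    }

    empty_genes <- tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), baseline_expression = double()
    )
    empty_tes <- tibble(
      te_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character()
    )
    genes <- purrr::map_dfr(seq_len(n_genes), function(i) {
      len <- sample(gene_length[1]:gene_length[2], 1)
      place(paste0("gene_", i), len, want_peri = FALSE) |>
        mutate(
          gene_id = sprintf("gene_%03d", i),
          strand = sample(c("+", "-"), 1),
          baseline_expression = rlnorm(1, meanlog = log(50), sdlog = 1)
        )
    })
    tes <- purrr::map_dfr(seq_len(n_tes), function(i) {
      len <- sample(te_length[1]:te_length[2], 1)
      want_peri <- pericentromere_fraction > 0 &&
        runif(1) < te_pericentromere_enrichment
      place(paste0("te_", i), len, want_peri = want_peri) |>
        mutate(te_id = sprintf("te_%03d", i), strand = sample(c("+", "-"), 1))
    })
    if (nrow(genes) == 0) genes <- empty_genes
    if (nrow(tes) == 0) tes <- empty_tes
    structure(
      list(
        chromosomes = chromosomes, pericentromeres = peri,
        genes = select(genes, "gene_id", "chrom", "start", "end", "strand",
          "baseline_expression"
        ),
        tes = select(tes, "te_id", "chrom", "start", "end", "strand"),
        seed = seed
      ),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d chromosome(s), %s bp total, %d genes, %d TEs, seed %d\n",
    length(x$chromosomes), format(sum(nchar(x$chromosomes)), big.mark = ","),
    nrow(x$genes), nrow(x$tes), x$seed
  ))
  invisible(x)
}

chrom_sizes <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  nchar(genome$chromosomes)
}

# TSS of a gene: start on "+", end - 1 points at the first transcribed base
# on "-" but the half-open convention keeps TSS = end for window arithmetic.
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Plant motif copies upstream of genes
#'
#' Writes one copy of `motif` into the strand-aware upstream window of a
#' random subset of genes (`round(gene_fraction * n_genes)` of them),
#' emulating promoter-proximal binding sites. For minus-strand genes the
#' reverse complement is written into the plus-strand reference so the gene
#' strand reads the motif. Sites whose window would run off the chromosome
#' are skipped (and logged in the returned truth table's attributes).
#'
#' @param genome A [make_genome()] object.
#' @param motif DNA string to plant (default the palindrome `TACTAGTA`).
#' @param gene_fraction Fraction of genes that receive a site.
#' @param upstream_window Window upstream of the TSS within which the site
#'   is placed uniformly.
#' @param seed Integer seed.
#' @return List with `genome` (modified) and `truth`: tibble
#'   `chrom`, `pos` (0-based plus-strand start), `strand`, `gene_id`.
#' @export
plant_motif_sites <- function(genome, motif = "TACTAGTA", gene_fraction,
                              upstream_window = 1000, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  check_dna(motif, allow_n = FALSE)
  if (nchar(motif) > upstream_window) {
    abort("motif longer than upstream window")
  }
  if (gene_fraction < 0 || gene_fraction > 1) {
    abort("gene_fraction must be in [0, 1]")
  }
  w <- nchar(motif)
  empty_truth <- tibble(
    chrom = character(), pos = integer(), strand = character(),
    gene_id = character()
  )
  n_pick <- round(gene_fraction * nrow(genome$genes))
  if (n_pick == 0) {
    return(list(genome = genome, truth = empty_truth))
  }
  with_seed(seed, {
    picked <- genome$genes[sample(nrow(genome$genes), n_pick), ]
    skipped <- 0L
    truth <- purrr::pmap_dfr(picked, function(gene_id, chrom, start, end,
                                              strand, ...) {
      L <- nchar(genome$chromosomes[[chrom]])
      if (strand == "+") {
        win_lo <- start - upstream_window
        win_hi <- start - w
      } else {
        win_lo <- end
        win_hi <- end + upstream_window - w
      }
      if (win_lo < 0 || win_hi + w > L || win_hi < win_lo) {
        skipped <<- skipped + 1L
        return(empty_truth)
      }
      pos <- sample(win_lo:win_hi, 1)
      insert <- if (strand == "+") motif else reverse_complement(motif)
      substr(genome$chromosomes[[chrom]], pos + 1, pos + w) <<- insert
      tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
        gene_id = gene_id
      )
    })
    attr(truth, "skipped") <- skipped
    list(genome = genome, truth = arrange(truth, .data$chrom, .data$pos))
  })
}
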