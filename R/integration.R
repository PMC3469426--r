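#' Strand-aware promoter windows
#'
#' The `upstream` bp ending at the TSS: `[TSS - upstream, TSS)` for plus
#' genes, `[TES, TES + upstream)` reading back from the minus-strand TSS
#' (= the half-open `end`). Windows are clipped at chromosome bounds when
#' sizes are available.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param upstream Window size in bp (> 0).
#' @param sizes Optional named chromosome lengths for right-clipping.
#' @return Tibble: `chrom`, `start`, `end`, `gene_id`, `strand`.
#' @export
promoter_intervals <- function(genes, upstream, sizes = NULL) {
  if (upstream <= 0) abort("upstream must be > 0")
  out <- genes |>
    mutate(
      p_start = ifelse(.data$strand == "+",
        pmax(.data$start - upstream, 0L), .data$end
      ),
      p_end = ifelse(.data$strand == "+", .data$start, .data$end + upstream)
    )
  if (!is.null(sizes)) {
    out <- mutate(out, p_end = pmin(.data$p_end, sizes[.data$chrom]))
  }
  out |>
    transmute(
      .data$chrom, start = as.integer(.data$p_start),
      end = as.integer(.data$p_end), .data$gene_id, .data$strand
    ) |>
    filter(.data$end > .data$start)
}

#' Map reads to a genome by exact match
#'
#' Exact substring search on both strands; only reads with exactly one
#' genomic occurrence become intervals. Multi-mappers and unmapped reads
#' are discarded, with counts recorded in attributes (`n_multi`,
#' `n_unmapped`).
#'
#' @param reads Character vector of reads.
#' @param genome A `synthetic_genome` or named character vector.
#' @return Tibble of unique-hit intervals: `chrom`, `start`, `end`,
#'   `strand`.
#' @export
map_reads_exact <- function(reads, genome) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$chromosomes else genome
  subject <- Biostrings::DNAStringSet(seqs)
  n_multi <- 0L
  n_unmapped <- 0L
  uniq <- unique(reads)
  mapped <- purrr::map_dfr(uniq, function(r) {
    fwd <- Biostrings::vmatchPattern(r, subject)
    rev <- Biostrings::vmatchPattern(reverse_complement(r), subject)
    hits <- bind_rows(
      tibble(chrom = character(), start = integer(), end = integer(),
        strand = character()
      ),
      purrr::imap_dfr(as.list(fwd), function(m, nm) {
        if (length(m) == 0) {
          return(NULL)
        }
        tibble(chrom = nm, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = "+"
        )
      }),
      purrr::imap_dfr(as.list(rev), function(m, nm) {
        if (length(m) == 0) {
          return(NULL)
        }
        tibble(chrom = nm, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = "-"
        )
      })
    )
    # a palindromic read matches both strands at one locus: one location
    loci <- distinct(hits, .data$chrom, .data$start, .data$end)
    n_copies <- sum(reads == r)
    if (nrow(loci) == 0) {
      n_unmapped <<- n_unmapped + n_copies
      return(NULL)
    }
    if (nrow(loci) > 1) {
      n_multi <<- n_multi + n_copies
      return(NULL)
    }
    hits[rep(1, n_copies), ]
  })
  if (nrow(mapped) == 0) {
    mapped <- tibble(chrom = character(), start = integer(),
      end = integer(), strand = character()
    )
  }
  mapped <- arrange(mapped, .data$chrom, .data$start)
  attr(mapped, "n_multi") <- n_multi
  attr(mapped, "n_unmapped") <- n_unmapped
  mapped
}

merge_interval_set <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  x |>
    select("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start) |>
    merge_regions(gap = 0)
}

#' Venn overlap of two interval sets
#'
#' Both sets are merged internally first. A region of A is "shared" iff it
#' overlaps at least `min_overlap` bp with any region of B; the count is
#' asymmetric between perspectives (merged-region counts differ between
#' sets), so both are reported. `A_only + shared_A = |merged A|`.
#'
#' @param setA,setB Interval tibbles (`chrom`, `start`, `end`).
#' @param min_overlap Minimum shared bp (default 1).
#' @return List: `counts` tibble
#'   (`A_only`, `B_only`, `shared_A`, `shared_B`), `A`, `B` merged sets
#'   with a `shared` flag.
#' @export
interval_overlap_venn <- function(setA, setB, min_overlap = 1) {
  A <- merge_interval_set(setA)
  B <- merge_interval_set(setB)
  flag_shared <- function(x, y) {
    if (nrow(x) == 0 || nrow(y) == 0) {
      return(mutate(x, shared = logical(nrow(x))))
    }
    qx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
    qy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1L, y$end))
    ov <- GenomicRanges::findOverlaps(qx, qy, minoverlap = min_overlap)
    mutate(x, shared = seq_len(nrow(x)) %in% S4Vectors::queryHits(ov))
  }
  A <- flag_shared(A, B)
  B <- flag_shared(B, A)
  list(
    counts = tibble(
      A_only = sum(!A$shared), B_only = sum(!B$shared),
      shared_A = sum(A$shared), shared_B = sum(B$shared)
    ),
    A = A, B = B
  )
}

#' Fraction of features carrying a motif hit nearby
#'
#' A feature is flagged iff at least one hit start falls within
#' `[start - flank, end + flank)`.
#'
#' @param features Interval tibble (`chrom`, `start`, `end`).
#' @param hits Motif-hit tibble from [scan_sequence()] / [scan_genome()]
#'   (`chrom`, `start`).
#' @param flank Symmetric flank in bp.
#' @return List: `fraction`, `flags` (features with `has_motif`).
#' @export
fraction_features_with_motif <- function(features, hits, flank = 0) {
  if (nrow(features) == 0) abort("features must be nonempty")
  if (nrow(hits) == 0) {
    flags <- mutate(features, has_motif = FALSE)
    return(list(fraction = 0, flags = flags))
  }
  q <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(pmax(features$start - flank, 0) + 1L,
      features$end + flank
    )
  )
  s <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$start + 1L, width = 1L))
  has <- GenomicRanges::countOverlaps(q, s) > 0
  list(
    fraction = mean(has),
    flags = mutate(features, has_motif = has)
  )
}

#' Genes with signal in their upstream window
#'
#' A gene is included iff its [promoter_intervals()] window overlaps at
#' least one signal interval.
#'
#' @param genes Gene tibble.
#' @param signal Interval tibble (e.g. uniquely mapped gSELEX reads or
#'   called regions).
#' @param upstream Window size in bp.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param sizes Optional chromosome lengths for clipping.
#' @return Character vector of gene ids.
#' @export
genes_with_upstream_signal <- function(genes, signal, upstream = 3000,
                                       min_overlap = 1, sizes = NULL) {
  prom <- promoter_intervals(genes, upstream, sizes = sizes)
  if (nrow(signal) == 0 || nrow(prom) == 0) {
    return(character())
  }
  q <- GenomicRanges::GRanges(prom$chrom, IRanges::IRanges(prom$start + 1L, prom$end))
  s <- GenomicRanges::GRanges(
    signal$chrom, IRanges::IRanges(signal$start + 1L, signal$end)
  )
  ov <- GenomicRanges::findOverlaps(q, s, minoverlap = min_overlap)
  sort(unique(prom$gene_id[S4Vectors::queryHits(ov)]))
}
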