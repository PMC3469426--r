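#' Classify every cytosine of a genome into CG/CHG/CHH context
#'
#' Scans both strands: each C on the plus strand and each G on the plus
#' strand (a C on the minus strand) is classified by its strand-aware
#' downstream bases — next base G gives CG, else next-next base G gives
#' CHG, else CHH (H = A, C or T). Cytosines too close to a chromosome end
#' for the needed lookahead are labelled `incomplete` and excluded from all
#' summaries. Minus-strand cytosines are reported at their own coordinate
#' (the G position on the plus reference).
#'
#' @param genome A `synthetic_genome` or named character vector of
#'   chromosome sequences.
#' @return Tibble: `chrom`, `pos` (0-based), `strand`, `context`.
#' @export
classify_contexts <- function(genome) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$chromosomes else genome
  purrr::imap_dfr(as.list(seqs), function(s, nm) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(b)
    classify_one <- function(pos, nxt, nxt2) {
      ifelse(is.na(nxt), "incomplete",
        ifelse(nxt == "G", "CG",
          ifelse(is.na(nxt2), "incomplete",
            ifelse(nxt2 == "G", "CHG", "CHH")
          )
        )
      )
    }
    # plus strand: C at i, lookahead i+1, i+2
    cp <- which(b == "C")
    plus <- tibble(
      chrom = nm, pos = cp - 1L, strand = "+",
      context = as.character(classify_one(
        cp,
        ifelse(cp + 1 <= L, b[pmin(cp + 1, L)], NA),
        ifelse(cp + 2 <= L, b[pmin(cp + 2, L)], NA)
      ))
    )
    # minus strand: G at i on plus is a C on minus; its downstream bases are
    # plus positions i-1, i-2 complemented, so "G downstream" means plus "C"
    gp <- which(b == "G")
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    minus <- tibble(
      chrom = nm, pos = gp - 1L, strand = "-",
      context = as.character(classify_one(
        gp,
        ifelse(gp - 1 >= 1, comp[b[pmax(gp - 1, 1)]], NA),
        ifelse(gp - 2 >= 1, comp[b[pmax(gp - 2, 1)]], NA)
      ))
    )
    bind_rows(plus, minus) |> arrange(.data$pos, .data$strand)
  })
}

#' Weighted methylation level
#'
#' The count-weighted level `sum(meth) / sum(total)` over the calls of one
#' context, optionally restricted to an interval. Robust to depth variation
#' (deep sites weigh more), unlike the mean of per-site fractions.
#'
#' @param methylome Cytosine-call tibble (`chrom`, `pos`, `strand`,
#'   `context`, `meth_count`, `total_count`).
#' @param context One of "CG", "CHG", "CHH".
#' @param interval Optional list/tibble row with `chrom`, `start`, `end`
#'   (0-based half-open); NULL = whole methylome.
#' @return Fraction in `[0, 1]`, or `NA` when no calls fall in scope
#'   (missing, never 0).
#' @export
weighted_level <- function(methylome, context, interval = NULL) {
  d <- filter(methylome, .data$context == !!context)
  if (!is.null(interval)) {
    d <- filter(
      d,
      .data$chrom == interval$chrom,
      .data$pos >= interval$start, .data$pos < interval$end
    )
  }
  if (nrow(d) == 0 || sum(d$total_count) == 0) {
    return(NA_real_)
  }
  sum(d$meth_count) / sum(d$total_count)
}

#' Sliding-window methylation track
#'
#' Weighted levels per context in sliding windows along each chromosome,
#' for chromosome-scale views of the methylation landscape.
#'
#' @inheritParams weighted_level
#' @param window,step Window width and spacing in bp (defaults 50 kb /
#'   10 kb).
#' @param sizes Named chromosome lengths; inferred from the data when NULL.
#' @return Tibble: `chrom`, `start`, `end`, `context`, `level`, `n_sites`;
#'   windows without calls carry `NA` level.
#' @export
windowed_track <- function(methylome, window = 50000, step = 10000,
                           sizes = NULL) {
  if (window < step) abort("window must be >= step")
  if (is.null(sizes)) {
    sizes <- methylome |>
      group_by(.data$chrom) |>
      summarise(L = max(.data$pos) + 1L, .groups = "drop")
    sizes <- setNames(sizes$L, sizes$chrom)
  }
  wins <- tile_genome(sizes, bin = window, step = step) |>
    select("chrom", "start", "end")
  q <- GenomicRanges::GRanges(
    methylome$chrom, IRanges::IRanges(methylome$pos + 1L, width = 1L)
  )
  s <- GenomicRanges::GRanges(wins$chrom, IRanges::IRanges(wins$start + 1L, wins$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  hits <- tibble(
    win = S4Vectors::subjectHits(ov),
    context = methylome$context[S4Vectors::queryHits(ov)],
    meth = methylome$meth_count[S4Vectors::queryHits(ov)],
    total = methylome$total_count[S4Vectors::queryHits(ov)]
  ) |>
    group_by(.data$win, .data$context) |>
    summarise(
      level = sum(.data$meth) / sum(.data$total), n_sites = n(),
      .groups = "drop"
    )
  tidyr::crossing(
    win = seq_len(nrow(wins)), context = c("CG", "CHG", "CHH")
  ) |>
    left_join(hits, by = c("win", "context")) |>
    mutate(
      chrom = wins$chrom[.data$win], start = wins$start[.data$win],
      end = wins$end[.data$win],
      n_sites = tidyr::replace_na(.data$n_sites, 0L)
    ) |>
    select("chrom", "start", "end", "context", "level", "n_sites") |>
    arrange(.data$chrom, .data$start, .data$context)
}

#' Per-context methylation metaprofile over features
#'
#' Uses the same upstream/scaled-body/downstream layout as [metaprofile()],
#' but pools methylated and total counts within each sub-bin before
#' dividing (a weighted level per bin), once per context.
#'
#' @inheritParams weighted_level
#' @param features Stranded interval tibble.
#' @param flank,body_bins,flank_bins Layout (see [metaprofile()]).
#' @return Tibble: `context`, `bin_index`, `part`, `level`, `n`
#'   (features contributing calls to the bin).
#' @export
meth_metaprofile <- function(methylome, features, flank = 2000,
                             body_bins = 40, flank_bins = 20) {
  if (nrow(features) == 0) abort("features must be nonempty")
  short <- features$end - features$start < body_bins
  if (any(short)) {
    warn(sprintf("%d feature(s) shorter than body_bins skipped", sum(short)))
    features <- features[!short, ]
    if (nrow(features) == 0) abort("no usable features")
  }
  layout <- metaprofile_layout(features, flank, body_bins, flank_bins) |>
    mutate(s = pmax(.data$s, 0)) |>
    filter(.data$e > .data$s) |>
    mutate(sub = row_number())
  q <- GenomicRanges::GRanges(
    methylome$chrom, IRanges::IRanges(methylome$pos + 1L, width = 1L)
  )
  s <- GenomicRanges::GRanges(layout$chrom, IRanges::IRanges(layout$s + 1L, layout$e))
  ov <- GenomicRanges::findOverlaps(q, s)
  pooled <- tibble(
    sub = S4Vectors::subjectHits(ov),
    context = methylome$context[S4Vectors::queryHits(ov)],
    meth = methylome$meth_count[S4Vectors::queryHits(ov)],
    total = methylome$total_count[S4Vectors::queryHits(ov)]
  ) |>
    left_join(
      layout |> select("sub", "bin_index", "part", "feature"),
      by = "sub"
    ) |>
    group_by(.data$context, .data$bin_index) |>
    summarise(
      part = .data$part[1],
      level = sum(.data$meth) / sum(.data$total),
      n = dplyr::n_distinct(.data$feature),
      .groups = "drop"
    )
  tidyr::crossing(
    context = c("CG", "CHG", "CHH"),
    bin_index = sort(unique(layout$bin_index))
  ) |>
    left_join(pooled, by = c("context", "bin_index")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(.data$context, .data$bin_index)
}

#' Percent methylation from bisulfite clone sequencing
#'
#' Compares pre-aligned clone sequences against an unconverted reference:
#' at every reference cytosine site (plus-strand C for plus clones,
#' plus-strand G for minus clones), a clone base equal to the reference is
#' unconverted (methylated) and the conversion product (C to T on plus, G
#' to A on minus) is converted. Any other base flags the clone at that site
#' and excludes it there.
#'
#' @param reference DNA string (plus strand).
#' @param clones Character vector of converted clone sequences, same
#'   length as `reference`.
#' @param clone_strands "+" or "-" per clone (recycled); minus clones read
#'   the reverse-strand cytosines (reference G positions).
#' @return Tibble: `pos` (0-based), `strand`, `context`, `unconverted`,
#'   `total`, `percent`; plus an attribute `n_mismatch` counting flagged
#'   clone-site observations.
#' @export
clone_percent_methylation <- function(reference, clones,
                                      clone_strands = "+") {
  check_dna(reference, allow_n = FALSE)
  if (any(nchar(clones) != nchar(reference))) {
    abort("clones must be pre-aligned to the reference (equal length)")
  }
  clone_strands <- rep(clone_strands, length.out = length(clones))
  ctx <- classify_contexts(setNames(reference, "ref"))
  rb <- strsplit(reference, "", fixed = TRUE)[[1]]
  n_mismatch <- 0L
  site_rows <- ctx |> filter(.data$context != "incomplete")
  out <- purrr::pmap_dfr(
    site_rows,
    function(chrom, pos, strand, context) {
      ref_base <- rb[pos + 1]
      converted_base <- if (strand == "+") "T" else "A"
      use <- which(clone_strands == strand)
      if (length(use) == 0) {
        return(NULL)
      }
      obs <- substr(clones[use], pos + 1, pos + 1)
      unconverted <- sum(obs == ref_base)
      converted <- sum(obs == converted_base)
      n_mismatch <<- n_mismatch + sum(obs != ref_base & obs != converted_base)
      total <- unconverted + converted
      tibble(
        pos = pos, strand = strand, context = context,
        unconverted = unconverted, total = total,
        percent = if (total > 0) 100 * unconverted / total else NA_real_
      )
    }
  )
  attr(out, "n_mismatch") <- n_mismatch
  out
}
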