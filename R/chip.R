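#' Per-probe log2 IP/input ratio
#'
#' @param probes Probe tibble: `chrom`, `start`, `end`, `ip`, `input`.
#' @return The same tibble with a `log_ratio` column.
#' @export
probe_log_ratio <- function(probes) {
  bad <- which(probes$ip <= 0 | probes$input <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "nonpositive intensity at probe %s:%d-%d",
      probes$chrom[bad[1]], probes$start[bad[1]], probes$end[bad[1]]
    ))
  }
  mutate(probes, log_ratio = log2(.data$ip / .data$input))
}

#' Centre scores so the array mean is zero
#'
#' @param x Numeric vector of per-probe scores, or a probe tibble with a
#'   `log_ratio` column (centred in place).
#' @return Same shape as the input, mean-centred.
#' @export
center_scale <- function(x) {
  if (is.data.frame(x)) {
    if (!"log_ratio" %in% names(x)) abort("probe table lacks log_ratio")
    x$log_ratio <- center_scale(x$log_ratio)
    return(x)
  }
  if (length(x) < 2) abort("need at least 2 probes")
  x - mean(x, na.rm = TRUE)
}

#' Tile chromosomes into overlapping bins
#'
#' Bins start at multiples of `step` and have width `bin`; the final bin is
#' truncated at the chromosome end, and a chromosome shorter than one bin
#' yields a single truncated bin.
#'
#' @param sizes Named vector of chromosome lengths, or a
#'   `synthetic_genome`.
#' @param bin,step Bin width and start spacing in bp (defaults 500 / 250,
#'   i.e. half-overlapping tiles).
#' @return An empty bin track: tibble `chrom`, `start`, `end`, `score`
#'   (NA), `n_probes` (0).
#' @export
tile_genome <- function(sizes, bin = 500, step = 250) {
  if (inherits(sizes, "synthetic_genome")) sizes <- chrom_sizes(sizes)
  if (step <= 0 || step > bin) abort("need 0 < step <= bin")
  purrr::imap_dfr(as.list(sizes), function(L, nm) {
    # a chromosome no longer than one bin is a single truncated bin;
    # otherwise bins start at every multiple of step below L
    starts <- if (L <= bin) 0 else seq(0, max(L - 1, 0), by = step)
    starts <- starts[starts < L]
    tibble(
      chrom = nm, start = as.integer(starts),
      end = as.integer(pmin(starts + bin, L)),
      score = NA_real_, n_probes = 0L
    )
  })
}

#' Aggregate probe scores into bins
#'
#' A probe contributes to every bin containing its midpoint (half-open
#' membership); bin score is the mean probe `log_ratio`, and bins without
#' probes stay missing (never silently zero).
#'
#' @param probes Probe tibble with `log_ratio` (see [probe_log_ratio()]).
#' @param bins Bin track from [tile_genome()].
#' @return The bin track with `score` and `n_probes` filled in.
#' @export
aggregate_bins <- function(probes, bins) {
  if (!"log_ratio" %in% names(probes)) abort("probes lack log_ratio")
  mid <- (probes$start + probes$end) %/% 2
  q <- GenomicRanges::GRanges(probes$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  s <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  agg <- tibble(
    bin = S4Vectors::subjectHits(ov),
    score = probes$log_ratio[S4Vectors::queryHits(ov)]
  ) |>
    group_by(.data$bin) |>
    summarise(score = mean(.data$score), n = n(), .groups = "drop")
  bins$score <- NA_real_
  bins$n_probes <- 0L
  bins$score[agg$bin] <- agg$score
  bins$n_probes[agg$bin] <- agg$n
  bins
}

#' Z-score transform
#'
#' Centres and scales to population standard deviation 1 over the
#' non-missing values; missing values propagate.
#'
#' @param values Numeric vector (>= 2 non-missing, nonzero variance).
#' @return Z scores, same length.
#' @export
zscore_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("need at least 2 non-missing values")
  s <- pop_sd(values)
  if (s == 0) abort("zero variance: degenerate input")
  (values - mean(values[ok])) / s
}

#' Merge nearby intervals
#'
#' Consecutive intervals on the same chromosome whose gap
#' (`next start - current end`) is at most `gap` are unioned. Idempotent.
#'
#' @param intervals Tibble `chrom`, `start`, `end`, sorted within
#'   chromosome.
#' @param gap Maximum bridged gap in bp.
#' @return Merged tibble.
#' @export
merge_regions <- function(intervals, gap = 0) {
  if (nrow(intervals) == 0) {
    return(intervals[, c("chrom", "start", "end")])
  }
  srt <- intervals |> group_by(.data$chrom)
  if (any((srt |> mutate(bad = .data$start < lag(.data$start, default = -1L)))$bad)) {
    abort("intervals must be sorted by start within chromosome")
  }
  intervals |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      out_start <- d$start[1]
      out_end <- d$end[1]
      res <- list()
      if (nrow(d) > 1) {
        for (i in 2:nrow(d)) {
          if (d$start[i] - out_end <= gap) {
            out_end <- max(out_end, d$end[i])
          } else {
            res[[length(res) + 1]] <- c(out_start, out_end)
            out_start <- d$start[i]
            out_end <- d$end[i]
          }
        }
      }
      res[[length(res) + 1]] <- c(out_start, out_end)
      m <- do.call(rbind, res)
      tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
    }) |>
    ungroup()
}

#' Call H3K9me2-decreased regions between genotypes
#'
#' Implements the tile/Z/merge procedure: the per-bin difference score is
#' `mutant - wildtype` (both already log2 quantities), Z-transformed over
#' all non-missing bins genome-wide; bins below `z_cut` are flagged and
#' flagged bins within `merge_gap` bp of each other are merged into
#' regions. A missing bin does not extend a flagged run, but the merge gap
#' can bridge it.
#'
#' @param mutant,wildtype Bin tracks on identical tilings
#'   (see [aggregate_bins()]).
#' @param z_cut Z cutoff; bins with `Z < z_cut` are flagged (default -3).
#' @param merge_gap Maximum gap merged, bp (default 2500).
#' @param per_chromosome Z-transform per chromosome instead of genome-wide.
#' @return Tibble of regions: `chrom`, `start`, `end`, `mean_z`, `n_bins`.
#' @export
call_decreased_regions <- function(mutant, wildtype, z_cut = -3,
                                   merge_gap = 2500,
                                   per_chromosome = FALSE) {
  if (!identical(mutant[c("chrom", "start", "end")],
    wildtype[c("chrom", "start", "end")]
  )) {
    abort("mutant and wildtype tracks must share an identical tiling")
  }
  d <- mutant$score - wildtype$score
  z <- if (per_chromosome) {
    stats::ave(d, mutant$chrom, FUN = function(v) zscore_transform(v))
  } else {
    zscore_transform(d)
  }
  flagged <- which(!is.na(z) & z < z_cut)
  if (length(flagged) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      mean_z = double(), n_bins = integer()
    ))
  }
  fl <- tibble(
    chrom = mutant$chrom[flagged], start = mutant$start[flagged],
    end = mutant$end[flagged], z = z[flagged]
  ) |>
    arrange(.data$chrom, .data$start)
  merged <- merge_regions(fl, gap = merge_gap)
  # annotate each region with its constituent flagged bins
  q <- GenomicRanges::GRanges(fl$chrom, IRanges::IRanges(fl$start + 1L, fl$end))
  s <- GenomicRanges::GRanges(
    merged$chrom, IRanges::IRanges(merged$start + 1L, merged$end)
  )
  ov <- GenomicRanges::findOverlaps(q, s)
  ann <- tibble(
    region = S4Vectors::subjectHits(ov),
    z = fl$z[S4Vectors::queryHits(ov)]
  ) |>
    group_by(.data$region) |>
    summarise(mean_z = mean(.data$z), n_bins = n(), .groups = "drop")
  merged |>
    mutate(mean_z = ann$mean_z, n_bins = ann$n_bins) |>
    arrange(.data$chrom, .data$start)
}

# Layout of metaprofile sub-bins for one stranded feature: upstream flank,
# scaled body, downstream flank; bin_index 1 is always 5'-most.
metaprofile_layout <- function(features, flank, body_bins, flank_bins) {
  purrr::pmap_dfr(
    list(
      features$chrom, features$start, features$end,
      if ("strand" %in% names(features)) {
        features$strand
      } else {
        rep("+", nrow(features))
      },
      seq_len(nrow(features))
    ),
    function(chrom, start, end, strand, fid) {
      len <- end - start
      body_edges <- round(seq(start, end, length.out = body_bins + 1))
      up <- if (flank_bins > 0 && flank > 0) {
        e <- round(seq(start - flank, start, length.out = flank_bins + 1))
        tibble(s = e[-length(e)], e = e[-1], part = "upstream")
      } else {
        NULL
      }
      dn <- if (flank_bins > 0 && flank > 0) {
        e <- round(seq(end, end + flank, length.out = flank_bins + 1))
        tibble(s = e[-length(e)], e = e[-1], part = "downstream")
      } else {
        NULL
      }
      body <- tibble(
        s = body_edges[-length(body_edges)], e = body_edges[-1],
        part = "body"
      )
      d <- bind_rows(up, body, dn)
      if (strand == "-") {
        d <- d[rev(seq_len(nrow(d))), ]
        d$part <- c(
          upstream = "downstream", body = "body", downstream = "upstream"
        )[d$part]
      }
      d |>
        mutate(
          chrom = chrom, feature = fid, bin_index = row_number()
        )
    }
  )
}

#' Average signal profile over a set of stranded features
#'
#' Each feature's body is linearly rescaled to `body_bins` sub-bins and its
#' flanks cut into `flank_bins` fixed-width sub-bins; minus-strand features
#' are reversed so bin 1 is always 5'-most. The profile is the per-bin mean
#' over features of the overlap-weighted mean track score (missing-aware).
#'
#' @param signal A bin track (`chrom`, `start`, `end`, `score`); per-base
#'   tracks are just width-1 bins.
#' @param features Tibble of stranded intervals (`chrom`, `start`, `end`,
#'   optional `strand`).
#' @param flank Flank size in bp on each side.
#' @param body_bins,flank_bins Sub-bin counts.
#' @return A `meta_profile` tibble: `bin_index`, `part`, `mean`, `n`.
#' @export
metaprofile <- function(signal, features, flank = 2000, body_bins = 40,
                        flank_bins = 20) {
  if (nrow(features) == 0) abort("features must be nonempty")
  if (flank < 0) abort("flank must be >= 0")
  short <- features$end - features$start < body_bins
  if (any(short)) {
    warn(sprintf("%d feature(s) shorter than body_bins skipped", sum(short)))
    features <- features[!short, ]
    if (nrow(features) == 0) abort("no usable features")
  }
  layout <- metaprofile_layout(features, flank, body_bins, flank_bins)
  layout <- layout |>
    mutate(s = pmax(.data$s, 0)) |>
    filter(.data$e > .data$s)
  sig <- filter(signal, !is.na(.data$score))
  q <- GenomicRanges::GRanges(
    layout$chrom, IRanges::IRanges(layout$s + 1L, layout$e)
  )
  s <- GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$start + 1L, sig$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  w <- GenomicRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(ov)], s[S4Vectors::subjectHits(ov)]
  ))
  per_sub <- tibble(
    i = S4Vectors::queryHits(ov),
    score = sig$score[S4Vectors::subjectHits(ov)], w = w
  ) |>
    group_by(.data$i) |>
    summarise(score = sum(.data$score * .data$w) / sum(.data$w), .groups = "drop")
  layout$value <- NA_real_
  layout$value[per_sub$i] <- per_sub$score
  prof <- layout |>
    group_by(.data$bin_index) |>
    summarise(
      part = .data$part[1],
      mean = mean(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    mutate(mean = ifelse(.data$n == 0, NA_real_, .data$mean))
  structure(
    prof,
    class = c("meta_profile", class(prof)),
    layout = list(flank = flank, body_bins = body_bins, flank_bins = flank_bins)
  )
}

#' Per-gene signal summary and genotype comparison
#'
#' Scores each gene as the mean of the non-missing track bins overlapping
#' its window (gene body, optionally extended upstream of the TSS), per
#' genotype; reports quartiles per genotype and a rank-sum (Wilcoxon)
#' p-value between the first two genotypes as a descriptive comparison.
#'
#' @param tracks Named list of bin tracks, one per genotype.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param upstream Extra strand-aware upstream extension in bp (0 = body
#'   only).
#' @return List: `per_gene` (tibble `genotype`, `gene_id`, `score`),
#'   `summary` (per-genotype quartiles), `comparison` (Wilcoxon p, or NA
#'   with < 2 genotypes), `n_excluded` genes without covered bins.
#' @export
geneset_signal_summary <- function(tracks, genes, upstream = 0) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  win <- genes |>
    mutate(
      start = ifelse(.data$strand == "+",
        pmax(.data$start - upstream, 0), .data$start
      ),
      end = ifelse(.data$strand == "+", .data$end, .data$end + upstream)
    )
  per_gene <- purrr::imap_dfr(tracks, function(track, g) {
    sig <- filter(track, !is.na(.data$score))
    q <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start + 1L, win$end))
    s <- GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$start + 1L, sig$end))
    ov <- GenomicRanges::findOverlaps(q, s)
    tibble(
      gene = S4Vectors::queryHits(ov),
      score = sig$score[S4Vectors::subjectHits(ov)]
    ) |>
      group_by(.data$gene) |>
      summarise(score = mean(.data$score), .groups = "drop") |>
      transmute(genotype = g, gene_id = win$gene_id[.data$gene], .data$score)
  })
  n_excluded <- nrow(genes) * length(tracks) - nrow(per_gene)
  summ <- per_gene |>
    mutate(genotype = factor(.data$genotype, levels = names(tracks))) |>
    group_by(.data$genotype) |>
    summarise(
      q1 = quantile(.data$score, 0.25), median = median(.data$score),
      q3 = quantile(.data$score, 0.75), n = n(), .groups = "drop"
    ) |>
    mutate(genotype = as.character(.data$genotype))
  comparison <- NA_real_
  if (length(tracks) >= 2) {
    a <- filter(per_gene, .data$genotype == names(tracks)[1])$score
    b <- filter(per_gene, .data$genotype == names(tracks)[2])$score
    if (length(a) > 0 && length(b) > 0) {
      comparison <- wilcox.test(a, b)$p.value
    }
  }
  list(
    per_gene = per_gene, summary = summ, comparison = comparison,
    n_excluded = n_excluded
  )
}
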