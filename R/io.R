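#' Write a PWM in minimal MEME text format
#'
#' Emits the version header, alphabet, background frequencies and the
#' letter-probability matrix, which is sufficient for downstream MEME-suite
#' tools.
#'
#' @param pwm A `pwm` object.
#' @param path Output file.
#' @param name Motif identifier written in the MOTIF line.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif1") {
  stopifnot(inherits(pwm, "pwm"))
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(
      sprintf("%s %.5f", DNA_BASES, pwm$background),
      collapse = " "
    ), "",
    sprintf("MOTIF %s", name),
    sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      pwm$width, ifelse(is.na(pwm$n_sites), 20L, pwm$n_sites)
    ),
    apply(pwm$freq, 1, function(row) {
      paste(sprintf("%.6f", row), collapse = " ")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from minimal MEME text format
#'
#' @param path A MEME-format motif file (first motif is read).
#' @return A `pwm` object.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  mat_at <- grep("^letter-probability matrix", lines)
  if (length(mat_at) == 0) abort("no letter-probability matrix found")
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[mat_at[1]]))
  rows <- lines[(mat_at[1] + 1):(mat_at[1] + w)]
  freq <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }))
  freq <- freq / rowSums(freq) # renormalise printed rounding
  new_pwm(freq, background = bg)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is the representation the simulators and scanners use.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write genome annotations as GFF3
#'
#' Genes, transposable elements and pericentromeres are written as distinct
#' feature types (`gene`, `transposable_element`, `pericentromere`).
#' Internal coordinates are 0-based half-open; GFF3 is written 1-based
#' inclusive.
#'
#' @param genome A [make_genome()] object.
#' @param path Output GFF3 file.
#' @export
write_genome_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "synthetic_genome"))
  feat <- bind_rows(
    genome$genes |>
      transmute(.data$chrom, .data$start, .data$end, .data$strand,
        type = "gene", ID = .data$gene_id
      ),
    genome$tes |>
      transmute(.data$chrom, .data$start, .data$end,
        strand = .data$strand %||% "+",
        type = "transposable_element", ID = .data$te_id
      ),
    genome$pericentromeres |>
      mutate(n = row_number()) |>
      transmute(.data$chrom, .data$start, .data$end, strand = "+",
        type = "pericentromere", ID = paste0("pericen_", .data$n)
      )
  )
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand,
    type = feat$type, ID = feat$ID
  )
  GenomeInfoDb::seqlengths(gr) <-
    nchar(genome$chromosomes)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read genome annotations from GFF3
#'
#' @param path GFF3 file produced by [write_genome_gff3()].
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `type`, `ID`.
#' @export
read_genome_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = gr$ID
  )
}

#' Read / write the tab-separated interchange tables
#'
#' Probe tables (`chrom start end ip input`), per-cytosine reports
#' (`chrom pos strand context meth_count total_count`; positions 1-based in
#' the file, 0-based in memory) and gene count matrices
#' (`gene_id length <sample...>`).
#'
#' @param path TSV file.
#' @return A tibble in the package's internal representation.
#' @export
read_probe_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), ip = readr::col_double(),
      input = readr::col_double()
    )
  )
}

#' @rdname read_probe_tsv
#' @param probes Probe tibble.
#' @export
write_probe_tsv <- function(probes, path) {
  readr::write_tsv(select(probes, "chrom", "start", "end", "ip", "input"), path)
  invisible(path)
}

#' @rdname read_probe_tsv
#' @export
read_cytosine_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      strand = readr::col_character(), context = readr::col_character(),
      meth_count = readr::col_integer(), total_count = readr::col_integer()
    )
  ) |>
    mutate(pos = .data$pos - 1L)
}

#' @rdname read_probe_tsv
#' @param methylome Cytosine-call tibble (0-based `pos`).
#' @export
write_cytosine_tsv <- function(methylome, path) {
  methylome |>
    mutate(pos = .data$pos + 1L) |>
    select("chrom", "pos", "strand", "context", "meth_count", "total_count") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname read_probe_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), length = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' @rdname read_probe_tsv
#' @param counts Counts tibble (`gene_id`, `length`, sample columns).
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open, matching the package's internal convention.
#' Scores are written as `round(1000 * score)` per BED custom; exact values
#' belong in a sidecar TSV.
#'
#' @param path BED file.
#' @return Tibble `chrom`, `start`, `end` plus `name`, `score`, `strand`
#'   when present.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  names(x) <- cols[seq_len(ncol(x))]
  x
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score` (numeric, scaled by 1000 on write), `strand`.
#' @export
write_bed <- function(intervals, path) {
  col <- function(nm, default) {
    if (nm %in% names(intervals)) intervals[[nm]] else default
  }
  out <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = col("name", paste0("region_", seq_len(nrow(intervals)))),
    score = round(1000 * col("score", rep(0, nrow(intervals)))),
    strand = col("strand", rep(".", nrow(intervals)))
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
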