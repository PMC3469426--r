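#' Default pipeline configuration
#'
#' All numeric defaults are the analysis defaults used throughout the
#' package: 500/250 bp tiling, Z < -3 with 2.5 kb merging, scan p <= 0.001,
#' DE alpha 0.01 with log2 ratio > 2 ("over 4-fold"), 3 kb / 1 kb upstream
#' windows and 2 kb motif flanks. One global seed fans out to per-stage
#' seeds by fixed offsets, so stages are independently reproducible.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("suvrkit_run_")) {
  structure(
    list(
      seed = seed, out_dir = out_dir, simulate = TRUE,
      genome = list(
        n_chrom = 2, chrom_length = 250000, gc = 0.4,
        n_genes = 100, n_tes = 60, pericentromere_fraction = 0.25
      ),
      motif = list(
        motif = "TACTAGTA", gene_fraction = 0.3, upstream_window = 1000,
        alpha_scan = 0.001, discover_width = 8, restarts = 2,
        discover_reads = 150
      ),
      selex = list(cycles = 9, reads_per_cycle = 1000, stringency = 1,
        pool_size = 1000, fragment_length = 100
      ),
      chip = list(
        bin = 500, step = 250, z_cut = -3, merge_gap = 2500,
        noise_sd = 0.2, probe_spacing = 100, patch_effect = -2,
        n_patches_shared = 4, n_patches_suvr5 = 2, n_patches_kyp = 2,
        patch_length = 3000
      ),
      methylation = list(depth = 20, window = 50000, step = 10000),
      expression = list(
        library_size = 1e6, dispersion = 0.05, min_log2_fold = 2,
        alpha = 0.01, n_de = 10, de_fold = 16
      ),
      integration = list(upstream = 3000, promoter_upstream = 1000,
        flank = 2000
      )
    ),
    class = "pipeline_config"
  )
}

#' Validate and complete a pipeline configuration
#'
#' Fills unset keys from [default_config()], rejects unknown keys and
#' checks every parameter against its operation's preconditions.
#'
#' @param config Partial configuration list.
#' @return The merged, validated configuration.
#' @export
validate_pipeline_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sec in names(config)) {
    if (is.list(defaults[[sec]]) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad) > 0) {
        abort(sprintf("unknown key(s) in '%s': %s", sec,
          paste(bad, collapse = ", ")
        ))
      }
    }
  }
  merged <- defaults
  for (sec in names(config)) {
    if (is.list(defaults[[sec]]) && is.list(config[[sec]])) {
      for (k in names(config[[sec]])) merged[[sec]][[k]] <- config[[sec]][[k]]
    } else {
      merged[[sec]] <- config[[sec]]
    }
  }
  with(merged, {
    if (chip$z_cut >= 0) {
      abort("chip$z_cut must be negative: the caller detects decreases")
    }
    if (chip$step <= 0 || chip$step > chip$bin) abort("need 0 < step <= bin")
    if (motif$alpha_scan <= 0 || motif$alpha_scan > 1) {
      abort("motif$alpha_scan must be in (0, 1]")
    }
    if (expression$alpha <= 0 || expression$alpha > 1) {
      abort("expression$alpha must be in (0, 1]")
    }
    if (expression$min_log2_fold < 0) abort("min_log2_fold must be >= 0")
    if (methylation$window < methylation$step) {
      abort("methylation window must be >= step")
    }
  })
  merged
}

place_patches <- function(genome, n, patch_length, seed, exclude = NULL) {
  with_seed(seed, {
    sizes <- chrom_sizes(genome)
    peri <- genome$pericentromeres
    taken <- exclude %||% tibble(chrom = character(), start = integer(),
      end = integer()
    )
    out <- list()
    tries <- 0
    while (length(out) < n && tries < 5000) {
      tries <- tries + 1
      nm <- sample(names(sizes), 1)
      start <- sample(0:(sizes[[nm]] - patch_length), 1)
      end <- start + patch_length
      p <- peri[peri$chrom == nm, ]
      if (nrow(p) > 0 && any(start < p$end & end > p$start)) next
      if (nrow(taken) > 0 &&
        any(taken$chrom == nm & start < taken$end + 5000 &
          end > taken$start - 5000)) {
        next
      }
      row <- tibble(chrom = nm, start = as.integer(start), end = as.integer(end))
      taken <- bind_rows(taken, row)
      out[[length(out) + 1]] <- row
    }
    if (length(out) < n) abort("could not place depletion patches")
    bind_rows(out)
  })
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate - motif - chip - methylation - expression -
#' integration in dependency order on a synthetic genome with planted
#' ground truth, writes every layer to `out_dir` with a provenance record,
#' and returns the collected results. Rerunning with the same config is
#' byte-identical.
#'
#' @param config A `pipeline_config` (see [default_config()]), a partial
#'   list of overrides, or the path of a YAML file with the same
#'   structure.
#' @param write Write output files (default TRUE); FALSE returns results
#'   only.
#' @return A list of class `pipeline_result` with one element per stage
#'   plus `summary` (the headline statistics) and `config`.
#' @export
run_pipeline <- function(config = default_config(), write = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  genome <- make_genome(
    seed = seed + 1, n_chrom = config$genome$n_chrom,
    chrom_length = config$genome$chrom_length, gc = config$genome$gc,
    n_genes = config$genome$n_genes, n_tes = config$genome$n_tes,
    pericentromere_fraction = config$genome$pericentromere_fraction
  )
  planted <- plant_motif_sites(
    genome,
    motif = config$motif$motif,
    gene_fraction = config$motif$gene_fraction,
    upstream_window = config$motif$upstream_window, seed = seed + 2
  )
  genome <- planted$genome

  motif_pwm <- build_pwm(rep(config$motif$motif, 50), pseudocount = 1)
  pool <- selex_genome_pool(
    genome, config$selex$pool_size,
    fragment_length = config$selex$fragment_length, seed = seed + 3
  )
  selex <- simulate_selex(
    pool, motif_pwm,
    cycles = config$selex$cycles,
    reads_per_cycle = config$selex$reads_per_cycle,
    stringency = config$selex$stringency, seed = seed + 4,
    alpha = config$motif$alpha_scan
  )

  shared <- place_patches(genome, config$chip$n_patches_shared,
    config$chip$patch_length, seed + 5
  )
  suvr5_only <- place_patches(genome, config$chip$n_patches_suvr5,
    config$chip$patch_length, seed + 6, exclude = shared
  )
  kyp_only <- place_patches(genome, config$chip$n_patches_kyp,
    config$chip$patch_length, seed + 7, exclude = bind_rows(shared, suvr5_only)
  )
  effect_spec <- bind_rows(
    mutate(shared, genotypes = "suvr5,kyp", set = "shared"),
    mutate(suvr5_only, genotypes = "suvr5", set = "suvr5_only"),
    mutate(kyp_only, genotypes = "kyp", set = "kyp_only")
  ) |>
    mutate(effect = config$chip$patch_effect)
  chip_sim <- simulate_chip_arrays(
    genome, c("wildtype", "suvr5", "kyp"),
    probe_spacing = config$chip$probe_spacing,
    effect_spec = effect_spec, noise_sd = config$chip$noise_sd,
    seed = seed + 8
  )

  meth_sim <- simulate_methylome(
    genome,
    depth = config$methylation$depth,
    patches = suvr5_only, seed = seed + 9
  )

  de_genes <- with_seed(
    seed + 10,
    sample(genome$genes$gene_id, config$expression$n_de)
  )
  de_spec <- tibble(
    gene_id = de_genes, genotypes = "suvr5,ldl",
    fold = config$expression$de_fold
  )
  rna_sim <- simulate_rnaseq_counts(
    genome$genes, c("wildtype", "suvr5", "ldl", "suvr5_ldl"),
    de_spec = bind_rows(
      de_spec,
      tibble(gene_id = de_genes, genotypes = "suvr5_ldl",
        fold = config$expression$de_fold
      )
    ),
    library_size = config$expression$library_size,
    dispersion = config$expression$dispersion, seed = seed + 11
  )

  # --- motif ----------------------------------------------------------
  final_pool <- selex$pools[[length(selex$pools)]]
  discover_reads <- with_seed(
    seed + 12,
    sample(final_pool, min(config$motif$discover_reads, length(final_pool)))
  )
  fit <- discover_motif(discover_reads,
    width = config$motif$discover_width,
    restarts = config$motif$restarts, seed = seed + 13
  )
  hits <- scan_genome(fit$pwm, genome, alpha = config$motif$alpha_scan)

  # --- chip -----------------------------------------------------------
  bins <- tile_genome(genome, bin = config$chip$bin, step = config$chip$step)
  tracks <- lapply(chip_sim$probes, function(p) {
    p |>
      probe_log_ratio() |>
      center_scale() |>
      aggregate_bins(bins)
  })
  regions <- list(
    suvr5 = call_decreased_regions(tracks$suvr5, tracks$wildtype,
      z_cut = config$chip$z_cut, merge_gap = config$chip$merge_gap
    ),
    kyp = call_decreased_regions(tracks$kyp, tracks$wildtype,
      z_cut = config$chip$z_cut, merge_gap = config$chip$merge_gap
    )
  )
  te_profile <- metaprofile(tracks$suvr5, genome$tes,
    flank = config$integration$flank
  )

  # --- methylation ----------------------------------------------------
  meth_track <- windowed_track(meth_sim$methylome,
    window = config$methylation$window, step = config$methylation$step,
    sizes = chrom_sizes(genome)
  )
  meth_profile <- if (nrow(suvr5_only) > 0) {
    meth_metaprofile(meth_sim$methylome, suvr5_only,
      flank = config$integration$flank
    )
  } else {
    NULL
  }

  # --- expression -----------------------------------------------------
  de <- list(
    suvr5 = call_differential_genes(rna_sim$counts, "suvr5", "wildtype",
      min_log2_fold = config$expression$min_log2_fold,
      alpha = config$expression$alpha
    ),
    ldl = call_differential_genes(rna_sim$counts, "ldl", "wildtype",
      min_log2_fold = config$expression$min_log2_fold,
      alpha = config$expression$alpha
    ),
    suvr5_ldl = call_differential_genes(rna_sim$counts, "suvr5_ldl",
      "wildtype",
      min_log2_fold = config$expression$min_log2_fold,
      alpha = config$expression$alpha
    )
  )
  shared_up <- intersect(
    filter(de$suvr5, .data$called)$gene_id,
    filter(de$ldl, .data$called)$gene_id
  )
  epi <- if (length(shared_up) > 0) {
    geneset_rpkm_summary(de, shared_up,
      epistasis_pair = c("suvr5", "suvr5_ldl")
    )
  } else {
    list(summary = NULL, epistasis = NA_real_, missing_genes = character())
  }

  # --- integration ----------------------------------------------------
  mapped <- map_reads_exact(unique(final_pool), genome)
  venn <- interval_overlap_venn(regions$suvr5, regions$kyp)
  promoter_genes <- genes_with_upstream_signal(genome$genes, mapped,
    upstream = config$integration$promoter_upstream,
    sizes = chrom_sizes(genome)
  )
  # near-consensus occurrences only: at alpha_scan the +/- flank windows of
  # every TE would saturate with weak hits, so "contains the motif" is
  # judged on hits at the strictest attainable p-values (consensus-grade)
  strict_hits <- filter(hits, .data$pvalue <= 4^-7)
  te_motif <- fraction_features_with_motif(genome$tes, strict_hits,
    flank = config$integration$flank
  )

  summary <- list(
    consensus = consensus(fit$pwm, quiet = TRUE),
    selex_motif_fraction_first = selex$summary$motif_fraction[2],
    selex_motif_fraction_last =
      selex$summary$motif_fraction[nrow(selex$summary)],
    n_regions_suvr5 = nrow(regions$suvr5),
    n_regions_kyp = nrow(regions$kyp),
    venn = as.list(venn$counts),
    pct_suvr5_specific = if (nrow(regions$suvr5) > 0) {
      100 * venn$counts$A_only / (venn$counts$A_only + venn$counts$shared_A)
    } else {
      NA_real_
    },
    pct_genes_promoter_signal =
      100 * length(promoter_genes) / nrow(genome$genes),
    pct_tes_with_motif = 100 * te_motif$fraction,
    n_de_suvr5 = sum(de$suvr5$called),
    n_de_ldl = sum(de$ldl$called),
    n_shared_up = length(shared_up),
    epistasis = epi$epistasis
  )

  result <- structure(
    list(
      config = config, genome = genome, planted = planted$truth,
      selex = selex, motif_fit = fit, hits = hits, tracks = tracks,
      regions = regions, te_profile = te_profile,
      chip_truth = chip_sim$truth, methylome = meth_sim$methylome,
      meth_track = meth_track, meth_profile = meth_profile,
      counts = rna_sim$counts, de = de, de_truth = rna_sim$truth,
      mapped = mapped, venn = venn, promoter_genes = promoter_genes,
      te_motif = te_motif, summary = summary
    ),
    class = "pipeline_result"
  )
  if (write) write_reports(result, config$out_dir)
  result
}

#' Write the pipeline report bundle
#'
#' Writes every layer in its interchange format (FASTA, GFF3, TSV, BED,
#' MEME) plus `summary.json` with the headline statistics and
#' `provenance.json` recording the configuration, seed and per-file MD5
#' digests.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(result$genome$chromosomes, p("genome.fa"))
  write_genome_gff3(result$genome, p("annotations.gff3"))
  readr::write_tsv(result$planted, p("planted_motif_sites.tsv"))
  write_meme(result$motif_fit$pwm, p("motif.meme"))
  readr::write_tsv(result$hits, p("motif_hits.tsv"))
  write_bed(
    result$hits |>
      mutate(
        name = "motif", score = .data$score,
        end = .data$start + result$motif_fit$pwm$width
      ),
    p("motif_hits.bed")
  )
  readr::write_tsv(result$selex$summary, p("selex_summary.tsv"))
  for (g in names(result$regions)) {
    rg <- result$regions[[g]]
    readr::write_tsv(rg, p(sprintf("regions_%s.tsv", g)))
    if (nrow(rg) > 0) {
      write_bed(mutate(rg, score = .data$mean_z), p(sprintf("regions_%s.bed", g)))
    }
  }
  write_cytosine_tsv(result$methylome, p("methylome.tsv"))
  readr::write_tsv(result$meth_track, p("methylation_track.tsv"))
  if (!is.null(result$meth_profile)) {
    readr::write_tsv(result$meth_profile, p("methylation_metaprofile.tsv"))
  }
  readr::write_tsv(as_tibble(result$te_profile), p("te_metaprofile.tsv"))
  write_counts_tsv(result$counts, p("counts.tsv"))
  for (g in names(result$de)) {
    readr::write_tsv(as_tibble(result$de[[g]]), p(sprintf("de_%s.tsv", g)))
  }
  readr::write_tsv(result$chip_truth, p("truth_chip_patches.tsv"))
  readr::write_tsv(result$de_truth, p("truth_de_genes.tsv"))
  writeLines(result$promoter_genes, p("genes_with_promoter_signal.txt"))
  summary <- result$summary
  summary$no_de_calls <- summary$n_de_suvr5 == 0
  jsonlite::write_json(summary, p("summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- setdiff(list.files(out_dir), c("provenance.json"))
  prov <- list(
    config = unclass(result$config),
    seed = result$config$seed,
    files = lapply(
      setNames(files, files),
      function(f) list(md5 = unname(tools::md5sum(p(f))))
    )
  )
  jsonlite::write_json(prov, p("provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<pipeline_result> consensus %s | regions suvr5 %d / kyp %d ",
      "(%.0f%% suvr5-specific) | DE suvr5 %d, shared %d | epistasis %.2f\n"
    ),
    s$consensus, s$n_regions_suvr5, s$n_regions_kyp,
    s$pct_suvr5_specific, s$n_de_suvr5, s$n_shared_up, s$epistasis
  ))
  invisible(x)
}
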