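#' Reads per kilobase per million mapped reads
#'
#' `1e9 * count / (library_size * length)` — the classic length- and
#' depth-normalised expression unit. Vectorised.
#'
#' @param count Read count(s).
#' @param length Feature length(s) in bp (> 0).
#' @param library_size Total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length, library_size) {
  if (any(length <= 0)) abort("length must be > 0")
  if (any(library_size <= 0)) abort("library_size must be > 0")
  1e9 * count / (library_size * length)
}

#' Two-sided Fisher exact test
#'
#' Exact p-value for a 2x2 table `(a, b; c, d)` under the standard
#' two-sided rule: the sum of hypergeometric probabilities of all tables
#' with the same margins whose probability does not exceed the observed
#' table's. Wraps the exact test in `stats::fisher.test()`; never a
#' chi-square approximation.
#'
#' @param a,b,c,d Non-negative integer cells (row-wise).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cells must be non-negative")
  if (a + b + c + d == 0) abort("all-zero table")
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  # keep p in (0, 1]: sums can land a hair above 1, and extreme tables
  # underflow to 0
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q(i) = min over j >= rank(i) of m * p(j) / j`,
#' capped at 1 (via `stats::p.adjust`).
#'
#' @param pvals p-values in (0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must be in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes between two samples
#'
#' The no-replicate design: per gene, a 2x2 Fisher exact table of the
#' gene's reads against the rest of each library
#' (`count_mut, lib_mut - count_mut; count_wt, lib_wt - count_wt`),
#' BH adjustment over all tested genes, and a fold criterion on the RPKM
#' ratio (with a pseudo-RPKM added to both sides so zero-count genes stay
#' finite). A gene is called up-regulated when
#' `log2_ratio > min_log2_fold` and its (adjusted by default) p-value is
#' below `alpha`.
#'
#' `min_log2_fold = 2` means "over 4-fold"; set it to 4 for the stricter
#' 16-fold reading of the same rule. `use_adjusted = FALSE` compares the
#' raw p instead of q.
#'
#' @param counts Counts tibble: `gene_id`, `length`, one column per
#'   sample. Library sizes are recomputed as column sums (a
#'   `library_sizes` attribute, if present, is checked and a mismatch
#'   warned about).
#' @param mutant,wildtype Sample column names.
#' @param min_log2_fold Fold-change criterion on the log2 RPKM ratio.
#' @param alpha Significance cutoff.
#' @param pseudo Pseudo-RPKM added before the log ratio (0 reproduces the
#'   strict behaviour with infinite ratios for zero-count wild type).
#' @param use_adjusted Compare BH-adjusted q (default) or raw p to
#'   `alpha`.
#' @return A `de_result` tibble: `gene_id`, `rpkm_wt`, `rpkm_mut`,
#'   `log2_ratio`, `p`, `q`, `called`.
#' @export
call_differential_genes <- function(counts, mutant, wildtype,
                                    min_log2_fold = 2, alpha = 0.01,
                                    pseudo = 0.5, use_adjusted = TRUE) {
  if (min_log2_fold < 0) abort("min_log2_fold must be >= 0")
  for (s in c(mutant, wildtype)) {
    if (!s %in% names(counts)) abort(sprintf("sample '%s' absent", s))
  }
  cm <- counts[[mutant]]
  cw <- counts[[wildtype]]
  if (anyNA(cm) || anyNA(cw)) {
    warn("missing counts treated as 0")
    cm[is.na(cm)] <- 0
    cw[is.na(cw)] <- 0
  }
  lib_m <- sum(cm)
  lib_w <- sum(cw)
  declared <- attr(counts, "library_sizes")
  if (!is.null(declared) &&
    (declared[[mutant]] != lib_m || declared[[wildtype]] != lib_w)) {
    warn("declared library sizes differ from column sums; sums used")
  }
  p <- vapply(
    seq_along(cm),
    function(i) {
      fisher_exact_two_sided(cm[i], lib_m - cm[i], cw[i], lib_w - cw[i])
    },
    numeric(1)
  )
  q <- bh_adjust(p)
  rpkm_mut <- rpkm(cm, counts$length, lib_m)
  rpkm_wt <- rpkm(cw, counts$length, lib_w)
  log2_ratio <- log2((rpkm_mut + pseudo) / (rpkm_wt + pseudo))
  crit_p <- if (use_adjusted) q else p
  res <- tibble(
    gene_id = counts$gene_id,
    rpkm_wt = rpkm_wt, rpkm_mut = rpkm_mut,
    log2_ratio = log2_ratio, p = p, q = q,
    called = log2_ratio > min_log2_fold & crit_p < alpha
  )
  structure(
    res,
    class = c("de_result", class(res)),
    params = list(
      mutant = mutant, wildtype = wildtype,
      min_log2_fold = min_log2_fold, alpha = alpha, pseudo = pseudo,
      use_adjusted = use_adjusted,
      library_sizes = setNames(c(lib_m, lib_w), c(mutant, wildtype))
    )
  )
}

#' RPKM distribution of a gene set across genotypes
#'
#' Quartile summary of a gene set's expression per genotype, plus an
#' epistasis descriptor: the ratio of the combined mutant's median shift
#' from wild type to the single mutant's. A value near 1 means the
#' combined mutant adds nothing beyond the single - the expression-level
#' signature of genes acting in one pathway.
#'
#' @param results Named list of `de_result` tables (one per mutant
#'   genotype, each vs the same wild type).
#' @param gene_set Character vector of gene ids.
#' @param epistasis_pair Length-2 character vector naming the single and
#'   the combined genotype in `results` (defaults to the first and last).
#' @return List: `summary` (per-genotype quartiles of mutant RPKM over the
#'   set, plus the wild type), `epistasis` (scalar descriptor, NA when
#'   undefined), `missing_genes`.
#' @export
geneset_rpkm_summary <- function(results, gene_set,
                                 epistasis_pair = NULL) {
  if (length(gene_set) == 0) abort("gene_set must be nonempty")
  stopifnot(is.list(results), !is.null(names(results)))
  missing_genes <- unique(unlist(lapply(
    results, function(r) setdiff(gene_set, r$gene_id)
  )))
  use <- setdiff(gene_set, missing_genes)
  if (length(missing_genes) > 0) {
    warn(sprintf("%d gene id(s) missing from results; excluded",
      length(missing_genes)
    ))
  }
  if (length(use) == 0) abort("no gene ids present in results")
  per <- purrr::imap_dfr(results, function(r, g) {
    d <- filter(r, .data$gene_id %in% use)
    tibble(
      genotype = g,
      q1 = quantile(d$rpkm_mut, 0.25), median = median(d$rpkm_mut),
      q3 = quantile(d$rpkm_mut, 0.75), n = nrow(d)
    )
  })
  wt <- filter(results[[1]], .data$gene_id %in% use)
  wt_row <- tibble(
    genotype = "wildtype",
    q1 = quantile(wt$rpkm_wt, 0.25), median = median(wt$rpkm_wt),
    q3 = quantile(wt$rpkm_wt, 0.75), n = nrow(wt)
  )
  summ <- bind_rows(wt_row, per)
  epistasis <- NA_real_
  if (length(results) >= 2) {
    epistasis_pair <- epistasis_pair %||%
      c(names(results)[1], names(results)[length(results)])
    single <- filter(summ, .data$genotype == epistasis_pair[1])$median
    combined <- filter(summ, .data$genotype == epistasis_pair[2])$median
    wt_med <- wt_row$median
    if (abs(single - wt_med) > .Machine$double.eps) {
      epistasis <- (combined - wt_med) / (single - wt_med)
    }
  } else {
    warn("epistasis descriptor undefined with fewer than 2 genotypes")
  }
  list(summary = summ, epistasis = epistasis, missing_genes = missing_genes)
}
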