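---
title: "Methods and design of suvrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of suvrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

suvrkit reimplements, as one coherent and fully tested toolkit, the
computational analysis surrounding a sequence-specific H3K9
dimethyltransferase: a zinc-finger protein that binds the palindromic DNA
octamer TACTAGTA in promoters and silences its targets by depositing
H3K9me2 without requiring DNA methylation. The analysis spans five data
layers — SELEX binding-site selection, tiling-array H3K9me2 profiles,
bisulfite methylomes, RNA-seq counts, and their interval-level integration
— and the package adds a sixth: a synthetic-data generator that plants
ground truth into every layer so that each method is validated by
*recovery*, not by inspection.

This vignette explains each model, its assumptions and tunable parameters,
the numerical choices, and the design decisions taken where the procedure
was genuinely open.

## Motif model and exact p-values

A motif of width $w$ is a position weight matrix: per-position base
frequencies $f_{i,b}$ with pseudocount smoothing
$f_{i,b} = (n_{i,b} + c)/(n + 4c)$. A window $x_{1..w}$ scores

$$S(x) = \sum_{i=1}^{w} \log_2 \frac{f_{i,x_i}}{b_{x_i}}$$

in bits against a background $b$ (uniform 0.25 by default, the standard
scanner convention).
`build_pwm()` accepts `pseudocount = 0`, in which case frequencies may be
exactly 0 and the matrix can be summarised (`consensus()`, information
content with the $0\log 0 = 0$ convention) but not scored; scoring demands
strictly positive frequencies.

**Exact p-values.** `score_pvalue()` computes $P(S \ge s)$ for a random
background $w$-mer by dynamic programming: per-position scores are rounded
to a grid of $10^{-3}$ bits and convolved position by position, giving the
full discrete score distribution in $O(w \cdot R \cdot 4)$ where $R$ is the
integer score range. The tests verify the DP against brute-force
enumeration of all $4^w$ words (widths 4–8): agreement is exact on the
identically discretised score distribution, and the accumulated rounding of
a query score is bounded by $w$ grid steps. Conventions at the boundary: a
score above the maximum achievable returns the mass of the top score bin
(so $p > 0$ always; $p \ge 4^{-w}$ for a uniform background), and
`pvalue_threshold_score()` inverts the tail exactly, erroring when `alpha`
is below the smallest attainable tail.

**Scanning.** `scan_sequence()` reports every window with $p \le \alpha$
(default 0.001, the conventional scanning cutoff). Minus-strand windows are
scored as the reverse complement at the same start; a palindromic motif
therefore yields both-strand hits at identical positions, and both are
reported, matching FIMO's behaviour. Windows containing `N` are skipped by
default (`n_policy = "background"` scores them as background instead).

## ZOOPS EM motif discovery

`discover_motif()` assumes each read carries **z**ero **o**r **o**ne motif
**s**ite (ZOOPS), uniformly positioned. With site prevalence $\gamma$ and
read likelihoods factorised over background positions, the E-step computes
per-position site posteriors from the current PWM's odds ratios and the
M-step re-estimates frequencies (with pseudocount $c = 0.5$) and $\gamma$.
EM is an ascent algorithm on the *smoothed* objective — the data
log-likelihood plus the Dirichlet prior the pseudocount encodes — and the
implementation asserts that objective never decreases at every iteration
(the raw likelihood alone is not guaranteed monotone under a smoothed
M-step, which is why the assertion tracks the MAP objective).

Starts matter for EM, so runs are seeded from the top three
strand-collapsed enriched k-mers (`kmer_enrichment()` against a per-read
shuffled control, which preserves base composition) plus random read
windows; the highest-likelihood fit wins. Given the seed, the whole
procedure is deterministic.

Two decisions were open:

- **Width selection.** When `width` is a range, the fit maximising the
  per-column-penalised log-likelihood ratio against the background-only
  model is chosen; the penalty defaults to $\log n$ per column (BIC-flavoured:
  each extra column costs three free frequencies). It is exposed as
  `width_penalty`.
- **No-motif floor.** Motif-free reads still yield a fitted PWM; measured
  on simulated uniform reads, ZOOPS EM overfits to 0.3–0.45 bits/column of
  mean information content, while genuine planted motifs fit near 1.9 of
  the 2-bit maximum. The flagging floor `ic_floor` defaults to 1
  bit/column — half the maximum, several-fold above the overfitting noise —
  and results below it carry `no_motif = TRUE`.

## SELEX simulation

The generator emulates iterative in-vitro selection: per cycle, reads are
resampled with replacement with retention probability
$\mathrm{logit}^{-1}(\kappa\,(S_{\max} - \tau))$, where $S_{\max}$ is the
read's best window log-odds on either strand, $\tau$ defaults to the
$\alpha = 0.001$ threshold score, and the stringency $\kappa$ is a free
slope. No mechanistic washing/amplification model is imposed: the logistic form
is the package's own choice, selected because it is the simplest monotone
sharpness-controlled acceptance curve; $\kappa$ is exposed so users can bracket it. Two pool
types are provided: fixed flanks around a 15 bp random core (oligo SELEX)
and ~100 bp uniform genomic fragments (gSELEX). With $\kappa = 0$ the
motif-containing fraction stays flat across cycles; with $\kappa > 0$ it is
non-decreasing up to resampling noise, and mapped late-cycle gSELEX reads
concentrate upstream of TSSs when promoter sites have been planted — both
properties are asserted in the tests.

## ChIP-chip region calling

The caller follows the tile/Z/merge recipe with these fixed conventions:

- probe normalisation `log2(IP/input)`, then per-array mean-centring;
- tiling of 500 bp bins every 250 bp (a chromosome not longer than one bin
  is a single truncated bin; otherwise bins start at every multiple of the
  step below the chromosome end, the tail truncated);
- probes assigned to every bin containing their **midpoint** (the simplest
  unbiased rule for half-overlapping tiles); bins without probes are
  missing, never silently zero;
- per-bin difference score = mutant − wild type. Both inputs are already
  log2 quantities, so this difference *is* the log2 ratio of the intensity
  quotients; the alternative reading (a second log of the scores) is not
  meaningful for signed scores and was rejected;
- Z-transform over all non-missing bins **genome-wide** (per-chromosome
  available via `per_chromosome = TRUE`), using the population standard
  deviation — at genome bin counts the sample/population distinction is
  far below any threshold effect;
- bins with $Z < -3$ flagged; flagged bins whose end-to-start gap is at
  most 2.5 kb merged into regions (a missing bin does not extend a flagged
  run, but the merge gap can bridge it). Per-region `mean_z` and `n_bins`
  are reported.

Two consequences of the scale-free Z-transform are worth stating plainly.
First, on pure-noise tracks the flagged fraction is the Gaussian tail
$\Phi(-3) \approx 0.135\%$ of bins, so any track with more than a few
hundred bins will almost surely produce a handful of (mostly single-bin)
regions; the caller's false calls scale with genome size and are *not*
zero. Second, planted depletions are only detectable when they occupy a
small fraction of the genome — large planted fractions inflate the Z
denominator and push real patches above the cutoff. The simulated study
conditions (20 patches of 5 kb shifted by −2.0 on noise-SD 0.2 tracks)
recover at 100% sensitivity with boundaries within one bin.

Metagene profiles (`metaprofile()`) use a scaled-body layout: fixed-width
flank bins plus a body linearly rescaled to a fixed bin count,
minus-strand features reversed so bin 1 is 5′-most, overlap-weighted and
missing-aware averaging. Scaled bodies (rather than edge anchoring) were
chosen because the profiled features (TEs, called regions) vary in length
by an order of magnitude; both layouts can be composed from the exposed
parameters (`flank_bins = 0` or `body_bins` small).

## Bisulfite methylation

Cytosine context is classified on both strands from the reference: the
strand-aware next base G gives CG, else next-next G gives CHG, else CHH
(H = A, C or T); minus-strand cytosines are reported at their own
coordinate (the plus-strand G position), the common cytosine-report
convention. Cytosines within two bases of a chromosome end whose lookahead
is incomplete are labelled `incomplete` and excluded from all summaries.

Methylation levels are always **count-weighted**:
$\sum m_i / \sum t_i$, not the mean of per-site fractions — robust to
depth variation, and additive over disjoint intervals (a tested
invariant). Chromosome tracks use 50 kb windows every 10 kb by default
(these values give smooth chromosome-scale views at Arabidopsis-like
cytosine density and are exposed).
Windows or profile bins without calls are missing, never 0.
`meth_metaprofile()` pools methylated and total counts within each layout
sub-bin *before* dividing. Clone analysis counts, per reference cytosine,
clones still carrying the reference base (unconverted = methylated) versus
the conversion product (C→T on plus, G→A on minus clones); any other base
flags the clone at that site and excludes that observation.

The simulator draws per-cytosine counts $\mathrm{Bin}(d, p)$ with $p$ set
by compartment (pericentromeric heterochromatin, arm, planted patch) and
context; planted patches receive the same low level in every genotype —
the methylation-independence negative control: genotypes simulated from
the same patches produce identical metaprofiles.

## Differential expression without replicates

The quantification unit is RPKM, $10^9 c /(N L)$. Per gene, significance
comes from a two-sided Fisher exact test of the 2×2 table
(gene count, rest of library) × (mutant, wild type) — the standard
construction for single-library designs — followed by Benjamini–Hochberg adjustment over
all tested genes. The log2 ratio is computed on RPKM with a pseudo-RPKM of
0.5 added to both sides so zero-count genes stay finite (`pseudo = 0`
restores strict ratios).

Two ambiguities are deliberately kept visible rather than reconciled:

- Both a 4-fold (log2 > 2) and a 16-fold (log2 > 4) reading of the
  calling threshold are in circulation for this rule. The default is
  `min_log2_fold = 2`; the 16-fold variant is the same argument set to 4.
- The significance cutoff is applied to the BH-adjusted q by default;
  `use_adjusted = FALSE` applies it to the raw p instead.

Library sizes are recomputed as column sums (a declared attribute is
checked and mismatches warned). On fully null simulations the combined
fold + q rule calls well under 1% of genes (the acceptance quantity
`t2`); with 5,000 genes at library $10^6$ and dispersion 0.05 the measured
rate is of order $10^{-4}$. Note the Fisher test assumes Poisson sampling,
so with overdispersed counts the q-values alone are anticonservative —
it is the fold criterion that keeps the null rate controlled.

`geneset_rpkm_summary()` reports per-genotype quartiles of a gene set's
RPKM and an epistasis descriptor: (combined-mutant median − wild-type
median)/(single-mutant median − wild-type median), ≈ 1 when the combined
mutant adds nothing beyond the single — the expression signature of one
pathway.

## Integration layer

Coordinates are 0-based half-open internally everywhere; GFF3 is written
1-based inclusive and BED 0-based half-open. Promoter windows are
strand-aware upstream-of-TSS intervals, clipped at chromosome bounds.
`map_reads_exact()` does exact substring search on both strands and keeps
only reads with exactly one genomic locus (a palindromic read matching
both strands at one locus counts once); multi-mappers and unmapped reads
are counted and discarded — this stands in for read alignment on toy
genomes and is not an aligner. Venn overlaps merge each set first and
report both perspectives separately, since merged-region counts differ
between sets; "signal in the promoter" means at least one interval
overlapping the window (threshold exposed). In the demo pipeline the
"fraction of TEs containing the motif" is judged on consensus-grade hits
(p ≤ 4⁻⁷) rather than all α = 0.001 hits, because at α = 0.001 the ±2 kb
flank of every TE contains weak hits by construction (~10 expected windows
per feature at that α) and the fraction saturates at 1.

## Synthetic data: what it does and does not emulate

The generator builds 2 × 250 kb chromosomes (100 genes, 60 TEs) by
default — large enough for metaplots and region statistics, small enough
for seconds-scale tests; test problem sizes range from 60 kb toys to a
2.4 Mb single chromosome for region-caller statistics, and the acceptance
computation uses 5,000-gene count matrices. Pericentromeres are central
blocks occupying 25% of each chromosome; TEs fall inside them with
probability 0.8, genes only in the arms, placements non-overlapping by
rejection sampling (a placement that cannot be satisfied errors, naming
the feature). Gene baselines are log-normal (median 50, log-SD 1);
RNA-seq counts are negative-binomial with variance $m + d m^2$
(dispersion 0.05 by default, Poisson at $d = 0$), scaled to library size
$10^6$. ChIP noise is Gaussian on the log2 ratio (SD 0.2); methylome
compartment levels default to CG/CHG/CHH = 0.9/0.7/0.3 in
heterochromatin, 0.25/0.1/0.04 in arms and ~0 in planted patches —
ballpark plant methylome values.

Deliberately *not* emulated: sequencing errors and quality, alignment
ambiguity, bisulfite conversion failure, array spatial artefacts and dye
bias, replicate structure. Passing recovery tests therefore demonstrates
the correctness of the algorithms under their stated noise models, not
robustness to real-data artefacts upstream of these inputs.

Every simulator is byte-reproducible for a fixed seed and restores the
caller's RNG state. The pipeline (`run_pipeline()`) fans one global seed
out to per-stage seeds by fixed offsets so stages can be rerun in
isolation; the full run is byte-identical across reruns and writes a
provenance record (parameters, seed, per-file MD5) beside its outputs. The
functions themselves are the orchestration interface; a YAML configuration
is accepted for scripted runs.

## Known limitations

- The exact-p-value DP rounds scores to $10^{-3}$ bits; accumulated
  rounding can shift a query by up to $w$ grid steps (~0.008 bits at
  $w = 8$), far below any practical threshold but visible in
  equality-level comparisons.
- ZOOPS EM is single-strand; SELEX reads are assumed already oriented (a
  palindromic motif makes the distinction moot, which is the case this
  package centres on).
- The region caller's false-call count grows linearly with genome size by
  construction (Gaussian tail × bins); consumers who need a fixed
  genome-wide error budget should tighten `z_cut` accordingly.
- `map_reads_exact()` requires exact matches and is unsuitable for reads
  with errors; it exists to close the loop on simulated data.
- The Fisher single-library design ignores biological variance; it is
  implemented as the method this pipeline characterises, not as a
  recommendation for replicated designs.
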