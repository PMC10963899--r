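---
title: "Methods: gene-wise selection and differentiation scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-wise selection and differentiation scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Targeted-enrichment (capture) sequencing of a candidate-gene panel in
individually sequenced case/control specimens — e.g. insecticide-resistant
versus susceptible mosquitoes — produces a multi-sample VCF over a few
hundred genes. The scientific questions are gene-level: which genes are
unusually differentiated between the phenotype classes, which show
signatures of recent selection, and which nonsynonymous variants drive the
differentiation. `popgenescan` implements that scan as a reusable, seeded,
tested pipeline, with a coalescent generator standing in for the sequencing
experiment so every inferential step can be calibrated and power-checked.

## Data model and filtering

A *site tibble* holds one row per biallelic SNP candidate (chrom, 1-based
pos, ref, alt, Phred QUAL, coding effect) plus a `gt` list-column with the
two alleles of every diploid sample in sample-sheet order. Filtering keeps
sites with QUAL ≥ 20 (inclusive — the conventional Phred cutoff), exactly
one single-nucleotide ALT (multiallelic sites are dropped, not split), and
zero missing genotypes *within the analysis cohort*. Missingness is
deliberately evaluated per cohort: filtering each country/colony cohort
separately retains the maximum number of sites per contrast, so different
contrasts legitimately see different site sets.

Gene intervals are 1-based inclusive internally (BED input is shifted +1).
Two lengths are exposed: `length_bp = end − start + 1` (the true inclusive
span) and `reported_length = end − start`, the convention used in printed
gene-panel tables, kept so package output is directly comparable with such
tables. Sites are assigned to genes with both boundaries inclusive, and a
site inside two overlapping genes is counted in both.

Haplotypes are extracted two-per-diploid by reading each genotype's alleles
in written order. Variant callers on capture data typically emit unphased
genotypes; the package does not phase or guess — the output carries a
`phasing = "as-written"` attribute flagging the caveat. Per-gene haplotype
cardinality is therefore always exactly 2N (160 for the 80-specimen
design), including length-zero haplotypes for monomorphic genes.

Genes with mean capture depth below 100× are excluded (inclusive at 100)
before any statistics, mirroring standard practice for capture panels where
off-target genes have unreliable genotypes.

## Effect annotation and πN/πS

SNP effects are classified codon-aware from a CDS model (exon intervals +
spliced sequence; minus-strand genes are handled by reverse complement). A
REF allele that disagrees with the CDS base is a hard error — it catches
coordinate bugs rather than silently mislabelling. Stop-gained and
stop-lost changes are counted with the nonsynonymous class throughout
(site counting and πN), the common πN/πS convention. Site denominators use
the unweighted Nei–Gojobori method: each codon position contributes f/3
synonymous sites, f the fraction of its three possible changes that
preserve the amino acid; synonymous + nonsynonymous sites sum to exactly 3
per codon. Only the standard genetic code is supported. πN/πS is left
*undefined and flagged* (not coerced to 0 or ∞) when πS = 0; a ratio below
1 indicates purifying selection on the protein.

Note this is the individual-genotype estimator of πN/πS; pooled-sequencing
estimators that work from read counts differ in their variance properties,
so absolute values are comparable only in direction.

## Neutrality and differentiation statistics

All estimators are implemented from the primary literature and verified in
the test suite against independent transcriptions and brute-force
enumeration:

- Tajima's D with the 1989 constants, undefined at S = 0 or n < 4; its sign
  equals sign(π − θ̂_W) by construction.
- Fu & Li's D* and F* in the outgroup-free starred form (with the
  widely-adopted corrected constants), using minor-allele-count-1 sites as
  singletons. No outgroup is required anywhere in the pipeline.
- Weir & Cockerham (1984) two-population variance components per SNP, with
  heterozygote terms from the observed genotypes. The gene-wise estimate is
  the ratio of summed components Σa/Σ(a+b+c) — the standard multi-locus
  aggregate, which weights informative sites properly — not the mean of
  per-site ratios. Negative estimates are reported unclamped so bootstrap
  nulls are unbiased.
- pFst is a counts-based likelihood-ratio test (shared vs cohort-specific
  binomial allele frequency, χ²₁). Genotype-likelihood weighting is
  deliberately omitted: the counts-based core is exactly reproducible and
  its type-I error is verified at 5% in the tests.
- FDR control uses Storey q-values by default (π₀ estimated on the
  λ = 0.05…0.95 grid with a df-3 smoothing spline, falling back to the
  λ = 0.5 estimate for small inputs) or plain Benjamini–Hochberg.
- The CLR compares a gene's (folded) SFS to the pooled background SFS of
  all scanned genes as a multinomial composite-likelihood ratio (the
  G-statistic); zero-probability background classes get a 0.5 pseudocount,
  reported via a message. This is intentionally the simplified
  background-SFS form — a full sweep-model parameterisation is an extension
  hook, not the default.

## Significance calls

**Gene FST.** The observed gene-wise FST values are resampled with
replacement (B = 1000 replicates of the full gene set), all draws pooled
into one empirical null per scope, and each gene's p-value is the pooled
exceedance probability with the (k+1)/(N+1) correction (no p = 0
artifacts). The test is one-sided — only high differentiation is of
interest — and the scope defaults to the chromosome, because the
significance rule itself is per-chromosome: a gene is flagged iff its FST
reaches the chromosome's empirical 0.95 quantile (type-7, linear
interpolation; the quantile value is emitted in the report) *and* p < 0.05.
Chromosomes with fewer than 5 genes are skipped with a warning.

**Tajima's D.** A neutral null is simulated at the cohort's haplotype count
with per-locus θ defaulting to the median Watterson estimate of the scanned
genes; the empirical 0.05 and 0.95 quantiles of the simulated D values are
the two-sided cutoffs (both boundaries inclusive). Monomorphic simulated
loci are redrawn up to a cap, then excluded and reported. The calibration
object (draws, cutoffs, config hash, seed) serialises to JSON and can be
reused across runs; reusing it reproduces identical flags.

## The synthetic-data generator

The generator is a Hudson coalescent without intralocus recombination —
capture-panel genes are short (kilobases), so intragenic recombination is a
second-order effect; this is a documented limitation, not an option. Time
is in units of 4N generations and θ = 4Nμ per locus, so the classical
expectations E[S] = θ·a₁(n) and E[π] = θ apply verbatim and are asserted in
the tests to within 3 Monte-Carlo SE at n = 10, θ = 5 and n = 20, θ = 10.

Demographies: constant size; exponential growth (rate g, backwards-time
shrinkage, implemented by exact inversion of the cumulative coalescence
intensity), which skews Tajima's D negative across loci — the shape seen in
expanding field populations; and a simple bottleneck (ancestral size
rescaling beyond a time point). Defaults for the emitted dataset follow the
targeted-capture study design at reduced scale: 2 cohorts × 40 diploids (80
samples, 160 haplotypes per gene), 100 genes across chromosomes "2", "3",
"X", per-locus θ = 10 (of the order of the Watterson estimates seen in
kilobase-scale insect genes), gene length 1500 bp, one sweep gene and one
differentiated gene, ~3% of sites below QUAL 20 and ~5% of genes below
100× coverage so the filters are exercised end to end.

**Sweep emulation.** A fraction f of lineages is forced through a common
ancestor at a recent time (default 0.01 × 4N) before neutral coalescence of
the rest — a partial star genealogy. This is an *emulation*, chosen over a
structured-coalescent selection trajectory because it is orders of
magnitude simpler and produces exactly the property the scan uses:
diversity collapses faster than S, driving Tajima's D strongly negative at
the swept gene (f = 0.9 gives D ≈ −2 to −2.5 at n = 80–160). f = 0 is
exactly the neutral path; f = 1 collapses the whole sample so only pendant
stub mutations (sample singletons) remain.

**Focal differentiation.** One designated site is overwritten so the ALT
frequency is p ± δ/2 in the two cohorts (clipped, with p adjusted and the
realised, rounding-aware δ recorded in the truth table), and the site is
guaranteed nonsynonymous in the paired CDS.

**Coding labels by construction.** CDS sequences are built from
fourfold-degenerate codon families; synonymous mutations are placed at
third codon positions, nonsynonymous at first/second positions, with ALT
bases verified against the genetic code at generation time. The
nonsynonymous:synonymous per-site rate ratio is configurable; the default
0.25 emulates purifying constraint and yields mean πN/πS ≈ 0.25 < 1
through the full pipeline. What the generator does *not* emulate:
sequencing error, mapping artefacts, pooled sequencing, recombination, and
migration structure — so passing tests demonstrate the statistics and
calls, not robustness to those real-data effects.

## Numerical and design choices

- Tajima/Fu–Li statistics are undefined (NA, never 0) at S = 0 or n < 4;
  monomorphic sites have undefined FST components and are excluded from
  gene aggregates.
- Quantiles are type-7 throughout (R's default linear interpolation);
  flag boundaries are inclusive on both sides.
- The bootstrap pools all replicate draws into a single exceedance
  distribution; with all-equal inputs every p is exactly 1.
- Seeds: every stochastic step takes an explicit seed; the pipeline derives
  stage seeds from the run seed with a fixed 32-bit linear map, so a rerun
  is byte-identical and stages can be reproduced in isolation.
- The Tajima's D calibration in the acceptance checks uses 2000–5000
  simulated loci, and the power analyses use 50 replicates of 200
  background genes — sizes chosen so two-stage Monte-Carlo standard errors
  are small relative to the assertion bands.

**Haplotype networks.** Deduplicated haplotypes become frequency-weighted
nodes with per-population counts (the usual pie-chart data). The connection
limit is a statistical-parsimony bound: the per-site mutation intensity is
estimated from the observed divergence j/(L+1) under a Poisson single-hit
model, the probability that one observed difference is a single hit is
r = μe^{−μ}/(1−e^{−μ}), and the limit is the largest j with r^j ≥ 0.95. An
explicit limit can be supplied instead. The network itself connects node
pairs in increasing distance order (ties: higher combined frequency, then
lexicographic order — a total order, so construction is deterministic),
linking only currently disconnected components; a d-step edge inserts d−1
inferred intermediates, and pairs beyond the limit remain in separate
components. This is a minimum-spanning-network-style construction under the
parsimony limit, not a full cladogram estimation with ancestral outgroup
weights: for descriptive clustering of capture-panel haplotypes the two
agree on the structures of interest (predominant shared nodes, single-step
chains, disconnected clusters), but intermediate placement and tie
resolution are implementation-defined. SNP-matrix haplotypes are already
positionally aligned, so no alignment step is needed.

## Known limitations

- Two cohorts only for FST (the case/control design); no multi-population
  hierarchy.
- Unphased genotypes are treated as phased-as-written for haplotypes — a
  flagged caveat, inherited from the scan design, not a claim about true
  phase.
- The CLR is the simplified background-SFS form; the πN/πS estimator is the
  individual-genotype analogue of pooled-read estimators.
- No recombination, migration, or sequencing-error models in the
  generator; calibration nulls inherit these simplifications.

## Scan output

One row per gene (`gene_scan` tibble): n, S, singletons, π (pooled and per
cohort), θ̂_W, Tajima's D (all/syn/nonsyn), D*, F*, CLR, πN, πS, πN/πS,
gene FST, bootstrap p, per-chromosome quantile, and the three flags
(`fst_significant`, `tajima_low`, `tajima_high`). One row per SNP: effect,
per-site Weir–Cockerham FST, pFst Λ and p, q-value, and optional
protein-domain context (containing domain, or "between X and Y" for gaps
between annotated domains). `tidy()`, `glance()` and `autoplot()` methods
cover the scan, the calibration, networks and simulated datasets; reports
are written as TSV plus a Markdown summary, with the config hash and seed
in the run log.
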