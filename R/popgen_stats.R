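# Per-site and gene-wise diversity, neutrality and differentiation
# statistics. These estimators are the analytical core of the package and
# are implemented from the primary literature: Watterson (1975), Tajima
# (1989), Fu & Li (1993) with the usual outgroup-free starred corrections,
# Weir & Cockerham (1984), Nielsen et al.-style composite likelihood
# against a background SFS (simplified), Storey & Tibshirani (2003).

nonsyn_effects <- c("nonsynonymous", "stop_gained", "stop_lost")

partition_rows <- function(sites, partition) {
  switch(partition,
    all = seq_len(nrow(sites)),
    synonymous = which(sites$effect == "synonymous"),
    nonsynonymous = which(sites$effect %in% nonsyn_effects),
    abort("partition must be one of all, synonymous, nonsynonymous")
  )
}

#' Per-cohort allele counts at each site
#'
#' @param sites Site tibble (no missing genotypes in the requested cohorts).
#' @param sample_sheet Sample sheet.
#' @param cohorts Named list of cohort specs (sample ids or
#'   population/phenotype labels).
#' @return A tibble with one row per site x cohort: chrom, pos, cohort,
#'   n_alleles, ref_count, alt_count, p_hat.
#' @export
allele_counts <- function(sites, sample_sheet, cohorts) {
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  out <- imap(cohorts, function(spec, nm) {
    ids <- resolve_cohort(sample_sheet, spec)
    m <- allele_matrix(sites)[, hap_columns(samples, ids), drop = FALSE]
    if (anyNA(m)) abort(paste0("missing genotypes in cohort '", nm, "'"))
    ac <- as.integer(rowSums(m))
    tibble(chrom = sites$chrom, pos = sites$pos, cohort = nm,
           n_alleles = ncol(m), ref_count = ncol(m) - ac, alt_count = ac,
           p_hat = ac / ncol(m))
  })
  list_rbind(out)
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference at one site:
#' `pi = ref_count * alt_count / choose(n, 2)` with `n` the total allele
#' count. Vectorised.
#'
#' @param ref_count,alt_count Integer allele counts.
#' @return Numeric vector of per-site pi values.
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  if (any(n < 2)) abort("site_pi needs at least 2 alleles")
  ref_count * alt_count / choose(n, 2)
}

#' Gene-wise diversity summary
#'
#' Counts segregating sites S, singletons eta_s (minor allele count 1),
#' summed per-site diversity pi and the Watterson estimator
#' `theta_w = S / a1(n)` over one gene's sites within a cohort, optionally
#' restricted to the synonymous or nonsynonymous partition.
#'
#' @param sites Site tibble for one gene (effects annotated when using a
#'   partition other than `"all"`).
#' @param sample_sheet,cohort Analysis cohort (default: all samples).
#' @param partition `"all"`, `"synonymous"` or `"nonsynonymous"`
#'   (nonsynonymous includes stop-affecting SNPs).
#' @return One-row tibble: partition, n (haplotypes), S, eta_s, pi, theta_w.
#' @export
gene_diversity <- function(sites, sample_sheet = NULL, cohort = NULL,
                           partition = "all") {
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  ids <- if (is.null(sample_sheet)) samples else resolve_cohort(sample_sheet, cohort)
  cols <- hap_columns(samples, ids)
  rows <- partition_rows(sites, partition)
  n <- length(cols)
  if (!length(rows)) {
    return(tibble(partition = partition, n = n, S = 0L, eta_s = 0L,
                  pi = 0, theta_w = 0))
  }
  m <- allele_matrix(sites[rows, , drop = FALSE])[, cols, drop = FALSE]
  if (anyNA(m)) abort("missing genotypes; filter the cohort first")
  ac <- rowSums(m)
  poly <- ac > 0 & ac < n
  S <- sum(poly)
  pi <- if (S) sum(site_pi(n - ac[poly], ac[poly])) else 0
  minor <- pmin(ac, n - ac)
  eta_s <- sum(poly & minor == 1)
  tibble(partition = partition, n = n, S = as.integer(S),
         eta_s = as.integer(eta_s), pi = pi,
         theta_w = if (S) S / a1_n(n) else 0)
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the Tajima (1989)
#' constants; undefined (NA) when S = 0 or n < 4. The sign of D equals the
#' sign of `pi - theta_w`.
#'
#' @param div Diversity tibble from [gene_diversity()] (any number of rows).
#' @return `div` with a `tajima_d` column appended.
#' @export
tajimas_d <- function(div) {
  div$tajima_d <- vapply(seq_len(nrow(div)), function(i) {
    n <- div$n[i]; S <- div$S[i]; pi <- div$pi[i]
    if (S == 0 || n < 4) return(NA_real_)
    k <- tajima_constants(n)
    (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }, numeric(1))
  div
}

# Fu & Li (1993) outgroup-free constants, with the starred corrections as
# implemented across the field (Simonsen et al. 1995 erratum)
fu_li_constants <- function(n) {
  a <- a1_n(n)
  b <- a2_n(n)
  an1 <- a + 1 / n  # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn - 2 * (n * a * (a + 1)) / (n - 1)^2) /
    (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- ((n / (n - 1)) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1)) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vF
  list(a = a, b = b, an1 = an1, cn = cn, dn = dn,
       uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu & Li's D* and F* (outgroup-free)
#'
#' Contrast the total singleton count eta_s with S (for D*) and with pi
#' (for F*), per Fu & Li (1993). No outgroup is required: singletons are
#' sites whose minor allele occurs in exactly one sequence. Undefined (NA)
#' when S = 0 or n < 4.
#'
#' @param div Diversity tibble from [gene_diversity()].
#' @return `div` with `fu_li_dstar`, `fu_li_fstar` columns appended.
#' @export
fu_li_star <- function(div) {
  res <- vapply(seq_len(nrow(div)), function(i) {
    n <- div$n[i]; S <- div$S[i]; pi <- div$pi[i]; eta <- div$eta_s[i]
    if (S == 0 || n < 4) return(c(NA_real_, NA_real_))
    k <- fu_li_constants(n)
    dstar <- ((n / (n - 1)) * S - k$a * eta) / sqrt(k$uD * S + k$vD * S^2)
    fstar <- (pi - ((n - 1) / n) * eta) / sqrt(k$uF * S + k$vF * S^2)
    c(dstar, fstar)
  }, numeric(2))
  div$fu_li_dstar <- res[1, ]
  div$fu_li_fstar <- res[2, ]
  div
}

#' Weir-Cockerham per-SNP FST components for two cohorts
#'
#' Variance components a (among populations), b (among individuals within
#' populations) and c (within individuals) from Weir & Cockerham (1984),
#' computed from cohort sample sizes, allele frequencies and observed
#' heterozygote proportions. `fst_site = a / (a + b + c)`; negative
#' estimates are reported unclamped. Sites monomorphic across both cohorts
#' are undefined (NA components) and excluded from gene aggregates.
#'
#' @param sites Site tibble.
#' @param sample_sheet Sample sheet.
#' @param cohorts List of exactly two cohort specs, each with >= 2 diploids.
#' @return Tibble: chrom, pos, a, b, c, fst_site.
#' @export
wc_fst_site <- function(sites, sample_sheet, cohorts) {
  if (length(cohorts) != 2) abort("wc_fst_site needs exactly two cohorts")
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  ids <- lapply(cohorts, resolve_cohort, sample_sheet = sample_sheet)
  if (any(lengths(ids) < 2)) abort("each cohort needs at least 2 diploid samples")
  M <- allele_matrix(sites)
  if (anyNA(M)) abort("missing genotypes; filter the cohorts first")
  comp <- function(idv) {
    cols <- hap_columns(samples, idv)
    m <- M[, cols, drop = FALSE]
    a1c <- m[, seq(1, ncol(m), 2), drop = FALSE]
    a2c <- m[, seq(2, ncol(m), 2), drop = FALSE]
    list(n = length(idv), p = rowMeans(m), h = rowMeans(a1c != a2c))
  }
  c1 <- comp(ids[[1]]); c2 <- comp(ids[[2]])
  r <- 2
  n1 <- c1$n; n2 <- c2$n
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * c1$p + n2 * c2$p) / (r * n_bar)
  s2 <- (n1 * (c1$p - p_bar)^2 + n2 * (c2$p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * c1$h + n2 * c2$h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  mono <- (p_bar == 0 | p_bar == 1) & h_bar == 0
  a[mono] <- NA_real_; b[mono] <- NA_real_; cc[mono] <- NA_real_
  denom <- a + b + cc
  tibble(chrom = sites$chrom, pos = sites$pos, a = a, b = b, c = cc,
         fst_site = ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_))
}

#' Gene-wise multi-locus Weir-Cockerham FST
#'
#' Ratio-of-sums aggregate `sum(a) / sum(a + b + c)` over the gene's
#' polymorphic sites -- the standard multi-locus W&C estimator (not the
#' mean of per-site ratios). NA when the gene has no usable site.
#'
#' @inheritParams wc_fst_site
#' @return A single numeric FST (possibly negative; never clamped).
#' @export
gene_fst <- function(sites, sample_sheet, cohorts) {
  comp <- wc_fst_site(sites, sample_sheet, cohorts)
  use <- !is.na(comp$a)
  if (!any(use)) return(NA_real_)
  denom <- sum(comp$a[use] + comp$b[use] + comp$c[use])
  if (denom == 0) return(NA_real_)
  sum(comp$a[use]) / denom
}

#' Per-SNP allele-frequency likelihood-ratio test (pFst)
#'
#' Tests H0 (one shared binomial allele frequency across two cohorts)
#' against H1 (cohort-specific frequencies): `Lambda = 2 (l1 - l0)`,
#' referred to the upper tail of chi-square with 1 df. Symmetric in cohort
#' order; identical counts give p = 1.
#'
#' @param n1,alt1,n2,alt2 Allele totals and ALT counts per cohort
#'   (vectorised).
#' @return Tibble: lambda, p_value.
#' @export
pfst_test <- function(n1, alt1, n2, alt2) {
  if (any(n1 < 2) || any(n2 < 2)) abort("each cohort needs at least 2 alleles")
  ll <- function(x, n, p) {
    t1 <- ifelse(x == 0, 0, x * log(p))
    t2 <- ifelse(n - x == 0, 0, (n - x) * log(1 - p))
    t1 + t2
  }
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  p0 <- (alt1 + alt2) / (n1 + n2)
  l1 <- ll(alt1, n1, p1) + ll(alt2, n2, p2)
  l0 <- ll(alt1, n1, p0) + ll(alt2, n2, p0)
  lambda <- pmax(0, 2 * (l1 - l0))
  tibble(lambda = lambda, p_value = pchisq(lambda, df = 1, lower.tail = FALSE))
}

#' pFst over a site table
#'
#' Convenience wrapper running [pfst_test()] on every site for a cohort
#' pair, returning per-site results suitable for joining with effects and
#' [wc_fst_site()].
#'
#' @inheritParams wc_fst_site
#' @return Tibble: chrom, pos, lambda, p_value.
#' @export
pfst_sites <- function(sites, sample_sheet, cohorts) {
  ac <- allele_counts(sites, sample_sheet, cohorts)
  wide <- split(ac, ac$cohort)
  a <- wide[[1]]; b <- wide[[2]]
  bind_cols(tibble(chrom = a$chrom, pos = a$pos),
            pfst_test(a$n_alleles, a$alt_count, b$n_alleles, b$alt_count))
}

#' False-discovery-rate q-values
#'
#' `method = "storey"` (default) estimates the null proportion pi0 on a
#' fixed lambda grid with a smoothing spline (Storey & Tibshirani 2003) and
#' scales the step-up adjustment by pi0; `method = "bh"` is plain
#' Benjamini-Hochberg. Storey q-values are <= BH q-values whenever
#' `pi0 < 1`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @param lambda Grid for pi0 estimation.
#' @return Numeric vector of q-values, monotone nondecreasing in p.
#' @export
fdr_qvalues <- function(p, method = c("storey", "bh"),
                        lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  if (method == "bh") return(p.adjust(p, method = "BH"))
  m <- length(p)
  pi0 <- if (m >= 100) {
    pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pl, df = 3)
    predict(fit, x = max(lambda))$y
  } else {
    mean(p > 0.5) / 0.5
  }
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  q[order(o)]
}

#' Site frequency spectrum
#'
#' Histogram of allele-frequency classes over the polymorphic sites of a
#' site set within a cohort: minor-allele counts 1..floor(n/2) when folded
#' (default), ALT-allele counts 1..n-1 when unfolded. Class totals sum
#' to S.
#'
#' @param sites Site tibble (no missingness in the cohort).
#' @param sample_sheet,cohort Analysis cohort.
#' @param folded Fold the spectrum on the minor allele?
#' @return A tibble (`class`, `n_sites`) with attributes `n` and `folded`.
#' @export
sfs <- function(sites, sample_sheet = NULL, cohort = NULL, folded = TRUE) {
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  ids <- if (is.null(sample_sheet)) samples else resolve_cohort(sample_sheet, cohort)
  m <- allele_matrix(sites)
  if (nrow(sites)) m <- m[, hap_columns(samples, ids), drop = FALSE]
  n <- 2L * length(ids)
  if (nrow(sites) && anyNA(m)) abort("missing genotypes; filter the cohort first")
  ac <- if (nrow(sites)) rowSums(m) else integer()
  ac <- ac[ac > 0 & ac < n]
  classes <- if (folded) seq_len(n %/% 2L) else seq_len(n - 1L)
  counts <- if (folded) pmin(ac, n - ac) else ac
  out <- tibble(class = classes,
                n_sites = as.integer(tabulate(counts, nbins = max(classes))[classes]))
  attr(out, "n") <- n
  attr(out, "folded") <- folded
  out
}

as_sfs_vector <- function(x) {
  if (is.data.frame(x)) {
    v <- as.numeric(x$n_sites)
    attr(v, "n") <- attr(x, "n")
    attr(v, "folded") <- attr(x, "folded")
    v
  } else {
    as.numeric(x)
  }
}

#' Composite likelihood ratio against a background SFS
#'
#' Composite log-likelihood of the gene's site-frequency counts under the
#' normalised background spectrum (l0) versus under the gene's own
#' multinomial MLE (l1): `CLR = 2 (l1 - l0) >= 0` (the multinomial
#' G-statistic). Background classes with probability 0 that are observed in
#' the gene receive a pseudocount, reported via a message. This is the
#' simplified background-SFS composite likelihood; it is not the full
#' sweep-model parameterisation.
#'
#' @param gene_sfs,background_sfs SFS tibbles from [sfs()] (same n and
#'   folding) or plain count vectors of equal length.
#' @param pseudocount Pseudocount added to all background classes when a
#'   zero-probability class is observed (default 0.5).
#' @return A single non-negative CLR value.
#' @export
clr_test <- function(gene_sfs, background_sfs, pseudocount = 0.5) {
  g <- as_sfs_vector(gene_sfs)
  bg <- as_sfs_vector(background_sfs)
  if (length(g) != length(bg)) abort("gene and background SFS must share classes")
  if (!is.null(attr(g, "folded")) && !is.null(attr(bg, "folded")) &&
      !identical(attr(g, "folded"), attr(bg, "folded"))) {
    abort("gene and background SFS must share folding")
  }
  if (sum(g) == 0) return(0)
  if (any(bg == 0 & g > 0)) {
    inform("background SFS class with zero probability observed in gene; pseudocount applied")
    bg <- bg + pseudocount
  }
  p0 <- bg / sum(bg)
  p1 <- g / sum(g)
  l0 <- sum(ifelse(g > 0, g * log(p0), 0))
  l1 <- sum(ifelse(g > 0, g * log(p1), 0))
  max(0, 2 * (l1 - l0))
}
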