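# Fixture builders: all test data is generated in code.

# sample sheet for n diploids split into two phenotype cohorts
make_sheet <- function(n, pops = NULL) {
  half <- n %/% 2
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = pops %||% rep(c("popA", "popB"), c(half, n - half)),
    phenotype = rep(c("resistant", "susceptible"), c(half, n - half))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# site tibble from a haplotype matrix (rows = haplotypes, cols = sites);
# haplotypes 2j-1, 2j belong to diploid sample j
sites_from_hap <- function(hm, chrom = "1", pos = NULL, ref = NULL,
                           alt = NULL, qual = 100, samples = NULL) {
  S <- ncol(hm)
  n_samp <- nrow(hm) %/% 2L
  samples <- samples %||% sprintf("S%03d", seq_len(n_samp))
  sites <- tibble::tibble(
    chrom = chrom,
    pos = pos %||% seq_len(S),
    ref = ref %||% rep("A", S),
    alt = alt %||% rep("T", S),
    qual = rep_len(qual, S),
    effect = "unannotated",
    gt = lapply(seq_len(S), function(j) as.integer(hm[, j]))
  )
  attr(sites, "samples") <- samples
  sites
}

# haplotype matrix from allele strings like c("AAT", "ATT")
hap_matrix <- function(strings, ref = "A") {
  m <- do.call(rbind, strsplit(strings, ""))
  matrix(as.integer(m != ref), nrow = nrow(m))
}

random_hap_matrix <- function(n, S, p = NULL) {
  p <- p %||% runif(S, 0.05, 0.95)
  m <- matrix(0L, n, S)
  for (j in seq_len(S)) m[, j] <- rbinom(n, 1, p[j])
  m
}
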