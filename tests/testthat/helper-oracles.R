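# Independent oracles: brute-force or closed-form computations that share
# no code with the implementation under test.

# Tajima's D by explicit pairwise sequence comparison and inline constants
oracle_tajima_d <- function(hm) {
  n <- nrow(hm)
  poly <- apply(hm, 2, function(x) length(unique(x)) > 1)
  S <- sum(poly)
  if (S == 0 || n < 4) return(NA_real_)
  # pi as the average over all C(n,2) sequence pairs of their differences
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(ij) sum(hm[ij[1], ] != hm[ij[2], ]))
  pi <- mean(diffs) * 1  # mean pairwise differences summed over sites
  a1 <- sum(1 / 1:(n - 1))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li's starred statistics, transcribed separately from the published
# corrected formulas (singletons = minor-allele-count-1 sites)
oracle_fu_li <- function(hm) {
  n <- nrow(hm)
  ac <- colSums(hm)
  poly <- ac > 0 & ac < n
  S <- sum(poly)
  if (S == 0 || n < 4) return(c(dstar = NA_real_, fstar = NA_real_))
  eta <- sum(pmin(ac[poly], n - ac[poly]) == 1)
  pairs <- utils::combn(n, 2)
  pi <- mean(apply(pairs, 2, function(ij) sum(hm[ij[1], ] != hm[ij[2], ])))
  a <- sum(1 / 1:(n - 1))
  b <- sum(1 / (1:(n - 1))^2)
  an1 <- sum(1 / 1:n)
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  nn1 <- n / (n - 1)
  vD <- (nn1^2 * b + a^2 * dn - 2 * n * a * (a + 1) / (n - 1)^2) / (a^2 + b)
  uD <- nn1 * (a - nn1) - vD
  dstar <- (nn1 * S - a * eta) / sqrt(uD * S + vD * S^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (nn1 + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vF
  fstar <- (pi - ((n - 1) / n) * eta) / sqrt(uF * S + vF * S^2)
  c(dstar = dstar, fstar = fstar)
}

# Weir & Cockerham (1984) variance components from explicit genotype lists:
# g1, g2 are integer matrices (individuals x 2 alleles)
oracle_wc <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2); r <- 2
  p1 <- mean(g1); p2 <- mean(g2)
  h1 <- mean(g1[, 1] != g1[, 2]); h2 <- mean(g2[, 1] != g2[, 2])
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# pFst log-likelihood ratio via dbinom (binomial coefficients cancel)
oracle_pfst_p <- function(n1, a1, n2, a2) {
  l1 <- dbinom(a1, n1, a1 / n1, log = TRUE) + dbinom(a2, n2, a2 / n2, log = TRUE)
  p0 <- (a1 + a2) / (n1 + n2)
  l0 <- dbinom(a1, n1, p0, log = TRUE) + dbinom(a2, n2, p0, log = TRUE)
  pchisq(max(0, 2 * (l1 - l0)), df = 1, lower.tail = FALSE)
}

# SNP effect by rebuilding the full mutant CDS and diffing the proteins
oracle_effect <- function(cds_seq, cds_index, alt_base) {
  translate <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(Biostrings::GENETIC_CODE[cods], collapse = "")
  }
  mut <- cds_seq
  substr(mut, cds_index, cds_index) <- alt_base
  p0 <- translate(cds_seq)
  p1 <- translate(mut)
  if (p0 == p1) return("synonymous")
  i <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  a0 <- substr(p0, i, i); a1 <- substr(p1, i, i)
  if (a1 == "*") "stop_gained" else if (a0 == "*") "stop_lost" else "nonsynonymous"
}

# Nei-Gojobori synonymous-site fraction of one codon by enumerating all 9
# single-base mutants
oracle_ng_syn <- function(codon) {
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (Biostrings::GENETIC_CODE[[mut]] == aa0) syn <- syn + 1 / 3
    }
  }
  syn
}

# O(n*m) interval-assignment scan
brute_assign <- function(sites, genes) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      if (sites$chrom[i] == genes$chrom[j] &&
          sites$pos[i] >= genes$start[j] && sites$pos[i] <= genes$end[j]) {
        out[[length(out) + 1]] <- c(i = i, gene = genes$gene_id[j])
      }
    }
  }
  out
}

# per-character Hamming scan
brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# multinomial G statistic by direct summation
oracle_g_stat <- function(obs, bg) {
  p0 <- bg / sum(bg)
  tot <- sum(obs)
  2 * sum(ifelse(obs > 0, obs * log(obs / (tot * p0)), 0))
}

# statistical-parsimony limit: independent transcription of the Poisson
# single-hit model (P_j = r^j, mu = -log(1 - j/(L+1)))
oracle_tcs_limit <- function(L, alpha) {
  j <- 0
  repeat {
    jj <- j + 1
    if (jj > L) break
    q <- jj / (L + 1)
    mu <- -log(1 - q)
    r <- mu / (exp(mu) - 1)
    if (r^jj < alpha) break
    j <- jj
  }
  max(j, 1)
}
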