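test_that("allele counts match a direct genotype tally", {
  sheet <- make_sheet(10)
  # 5 samples all 0/1 in cohort A -> alt 5 of 10
  hm <- rbind(matrix(rep(c(0L, 1L), 5), nrow = 10, byrow = TRUE),
              matrix(1L, 10, 1))
  sites <- sites_from_hap(hm)
  ac <- allele_counts(sites, sheet, list(A = "resistant", B = "susceptible"))
  expect_equal(ac$alt_count[ac$cohort == "A"], 5L)
  expect_equal(ac$n_alleles[ac$cohort == "A"], 10L)
  expect_equal(ac$alt_count[ac$cohort == "B"], 10L)  # all 1/1
  # random fixtures vs brute tally
  set.seed(5)
  hm2 <- random_hap_matrix(20, 15)
  s2 <- sites_from_hap(hm2)
  ac2 <- allele_counts(s2, sheet, list(all = NULL))
  expect_equal(ac2$alt_count, colSums(hm2))
})

test_that("per-site pi equals the pairwise enumeration", {
  expect_equal(site_pi(4L, 0L), 0)          # monomorphic
  expect_equal(site_pi(1L, 1L), 1)          # the single pair differs
  expect_equal(site_pi(3L, 1L), 0.5)        # n=4, alt=1: 3 of 6 pairs differ
  expect_error(site_pi(1L, 0L), "at least 2")
})

test_that("gene diversity: Watterson estimator and partition conservation", {
  set.seed(9)
  sheet <- make_sheet(5)  # n = 10 haplotypes
  hm <- random_hap_matrix(10, 5, p = rep(0.4, 5))
  hm[1, ] <- 1L - hm[2, ]  # guarantee polymorphism at all 5 sites
  sites <- sites_from_hap(hm)
  div <- gene_diversity(sites, sheet)
  expect_equal(div$S, 5L)
  expect_equal(div$theta_w, 5 / sum(1 / 1:9), tolerance = 1e-12)
  expect_equal(div$theta_w, 1.7674, tolerance = 1e-4)
  # S = 0 gives zero diversity
  mono <- sites_from_hap(matrix(0L, 10, 3))
  expect_equal(gene_diversity(mono, sheet)$pi, 0)
  expect_equal(gene_diversity(mono, sheet)$theta_w, 0)
  # partitions: S_syn + S_nonsyn + S_other = S_all
  sites$effect <- c("synonymous", "nonsynonymous", "intronic",
                    "synonymous", "stop_gained")
  s_all <- gene_diversity(sites, sheet, partition = "all")$S
  s_syn <- gene_diversity(sites, sheet, partition = "synonymous")$S
  s_non <- gene_diversity(sites, sheet, partition = "nonsynonymous")$S
  expect_equal(s_syn + s_non + 1L, s_all)
})

test_that("Tajima's D reproduces the 4-haplotype worked example and the sign rule", {
  haps <- c("AAA", "AAT", "ATT", "TTT")
  sites <- sites_from_hap(hap_matrix(haps))
  div <- tajimas_d(gene_diversity(sites, make_sheet(2)))
  expect_equal(div$pi, 5 / 3, tolerance = 1e-12)
  expect_lt(abs(div$tajima_d - 0.168), 1e-3)
  # matches the independent pairwise-difference oracle
  expect_equal(div$tajima_d, oracle_tajima_d(hap_matrix(haps)), tolerance = 1e-9)
  # sign(D) = sign(pi - theta_w) on random fixtures; D undefined when S = 0
  set.seed(31)
  for (i in 1:50) {
    hm <- random_hap_matrix(12, sample(2:10, 1))
    s <- sites_from_hap(hm)
    d <- tajimas_d(gene_diversity(s, make_sheet(6)))
    if (d$S == 0) {
      expect_true(is.na(d$tajima_d))
    } else {
      expect_equal(sign(d$tajima_d), sign(d$pi - d$theta_w))
      expect_equal(d$tajima_d, oracle_tajima_d(hm), tolerance = 1e-9)
    }
  }
  # excess singletons with low pi force D < 0
  single <- matrix(0L, 20, 6)
  for (j in 1:6) single[j, j] <- 1L
  d_neg <- tajimas_d(gene_diversity(sites_from_hap(single), make_sheet(10)))
  expect_lt(d_neg$tajima_d, 0)
})

test_that("Fu & Li D*/F* match an independent transcription and basic properties", {
  set.seed(17)
  sheet <- make_sheet(8)
  for (i in 1:100) {
    hm <- random_hap_matrix(16, sample(3:12, 1))
    div <- fu_li_star(tajimas_d(gene_diversity(sites_from_hap(hm), sheet)))
    want <- oracle_fu_li(hm)
    if (div$S == 0) {
      expect_true(is.na(div$fu_li_dstar))
    } else {
      expect_equal(div$fu_li_dstar, unname(want["dstar"]), tolerance = 1e-9)
      expect_equal(div$fu_li_fstar, unname(want["fstar"]), tolerance = 1e-9)
    }
  }
  # zero singletons with S > 0 gives D* > 0
  hm0 <- random_hap_matrix(16, 6, p = rep(0.5, 6))
  ac <- colSums(hm0)
  hm0 <- hm0[, ac >= 3 & ac <= 13, drop = FALSE]
  div0 <- fu_li_star(gene_diversity(sites_from_hap(hm0), sheet))
  expect_gt(div0$fu_li_dstar, 0)
  # permuting haplotype order leaves D*, F* unchanged
  perm <- hm0[sample(nrow(hm0)), , drop = FALSE]
  divp <- fu_li_star(gene_diversity(sites_from_hap(perm), sheet))
  expect_equal(divp$fu_li_dstar, div0$fu_li_dstar, tolerance = 1e-12)
  expect_equal(divp$fu_li_fstar, div0$fu_li_fstar, tolerance = 1e-12)
})

test_that("Weir-Cockerham per-site FST: fixed difference, identical cohorts, dual oracle", {
  sheet <- make_sheet(10)
  # pop1 all 0/0, pop2 all 1/1 -> fst 1
  fixed <- sites_from_hap(matrix(rep(c(0L, 1L), each = 10), ncol = 1))
  wc <- wc_fst_site(fixed, sheet, list("resistant", "susceptible"))
  expect_equal(wc$fst_site, 1)
  # identical genotype composition in both cohorts -> fst <= 0
  half <- rbind(matrix(c(0L, 1L), 5, 2, byrow = TRUE),
                matrix(c(1L, 1L), 5, 2, byrow = TRUE))  # 10 individuals
  hm_same <- matrix(c(t(half), t(half)), ncol = 1)      # 20 ind, both pops alike
  same <- sites_from_hap(hm_same)
  wc0 <- wc_fst_site(same, make_sheet(20), list("resistant", "susceptible"))
  expect_lte(wc0$fst_site, 0)
  # worked fixture pop1 (4xAA, 1xAa), pop2 (1xAA, 2xAa, 2xaa) vs oracle
  g1 <- rbind(matrix(0L, 4, 2), c(0L, 1L))
  g2 <- rbind(matrix(0L, 1, 2), matrix(c(0L, 1L), 2, 2, byrow = TRUE),
              matrix(1L, 2, 2))
  hm <- matrix(c(t(g1), t(g2)), ncol = 1)
  sites <- sites_from_hap(hm)
  wc1 <- wc_fst_site(sites, make_sheet(10), list("resistant", "susceptible"))
  want <- oracle_wc(g1, g2)
  expect_equal(wc1$a, unname(want["a"]), tolerance = 1e-9)
  expect_equal(wc1$fst_site, unname(want["fst"]), tolerance = 1e-9)
  # monomorphic overall -> undefined
  mono <- sites_from_hap(matrix(0L, 20, 1))
  expect_true(is.na(wc_fst_site(mono, sheet, list("resistant", "susceptible"))$fst_site))
})

test_that("gene-wise FST is the ratio of summed components", {
  set.seed(41)
  sheet <- make_sheet(12)
  # single-SNP gene reduces to the per-site value
  hm1 <- random_hap_matrix(24, 1, p = 0.4)
  hm1[1, 1] <- 1L - hm1[2, 1]
  s1 <- sites_from_hap(hm1)
  expect_equal(gene_fst(s1, sheet, list("resistant", "susceptible")),
               wc_fst_site(s1, sheet, list("resistant", "susceptible"))$fst_site)
  # all fixed differences -> 1
  fixed <- sites_from_hap(matrix(rep(c(0L, 1L), each = 12), nrow = 24,
                                 ncol = 4))
  expect_equal(gene_fst(fixed, sheet, list("resistant", "susceptible")), 1)
  # 20-SNP random fixture equals the summation oracle
  hm <- random_hap_matrix(24, 20)
  s <- sites_from_hap(hm)
  comp <- wc_fst_site(s, sheet, list("resistant", "susceptible"))
  ok <- !is.na(comp$a)
  expect_equal(gene_fst(s, sheet, list("resistant", "susceptible")),
               sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok]),
               tolerance = 1e-12)
})

test_that("pooled identical cohorts give near-zero gene FST", {
  set.seed(73)
  vals <- replicate(300, {
    hm <- random_hap_matrix(40, 10)
    gene_fst(sites_from_hap(hm), make_sheet(20),
             list("resistant", "susceptible"))
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.02)
})

test_that("pFst LRT: null identity, symmetry, chi-square oracle", {
  res <- pfst_test(20, 5, 20, 5)
  expect_equal(res$lambda, 0)
  expect_equal(res$p_value, 1)
  # worked case 18/20 vs 2/20 against the dbinom oracle
  res2 <- pfst_test(20, 18, 20, 2)
  expect_equal(res2$p_value, oracle_pfst_p(20, 18, 20, 2), tolerance = 1e-12)
  expect_lt(res2$p_value, 1e-5)
  # symmetry in cohort order, including boundary counts
  for (cnt in list(c(20, 0, 20, 7), c(40, 40, 40, 12), c(10, 3, 30, 29))) {
    a <- pfst_test(cnt[1], cnt[2], cnt[3], cnt[4])$p_value
    b <- pfst_test(cnt[3], cnt[4], cnt[1], cnt[2])$p_value
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(a, oracle_pfst_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
  }
})

test_that("FDR q-values: BH step-up hand case and Storey scaling", {
  expect_equal(fdr_qvalues(rep(1, 10), method = "bh"), rep(1, 10))
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh"),
               rep(0.04, 4))
  set.seed(1)
  p <- c(runif(300)^3, runif(700))  # enriched near 0 -> pi0 < 1
  qs <- fdr_qvalues(p, method = "storey")
  qb <- fdr_qvalues(p, method = "bh")
  expect_true(all(qs <= qb + 1e-12))
  # monotone nondecreasing in p
  o <- order(p)
  expect_true(all(diff(qs[o]) >= -1e-12))
  expect_error(fdr_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site frequency spectrum folds correctly and conserves S", {
  sheet <- make_sheet(5)  # n = 10
  single <- matrix(0L, 10, 3)
  single[1, 1] <- 1L; single[2, 2] <- 1L; single[9, 3] <- 1L
  sp <- sfs(sites_from_hap(single), sheet, folded = TRUE)
  expect_equal(sp$n_sites[sp$class == 1], 3L)
  set.seed(2)
  hm <- random_hap_matrix(10, 30)
  s <- sites_from_hap(hm)
  d <- gene_diversity(s, sheet)
  expect_equal(sum(sfs(s, sheet, folded = TRUE)$n_sites), d$S)
  expect_equal(sum(sfs(s, sheet, folded = FALSE)$n_sites), d$S)
})

test_that("CLR equals the multinomial G statistic and is nonnegative", {
  bg <- c(40, 20, 10, 5, 5)
  # proportional gene SFS -> 0
  expect_equal(clr_test(2 * bg, bg), 0, tolerance = 1e-12)
  obs <- c(10, 1, 0, 3, 6)
  expect_equal(clr_test(obs, bg), oracle_g_stat(obs, bg), tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    o <- rpois(5, 4)
    expect_gte(clr_test(o, bg), 0)
  }
  # zero-probability background class triggers the pseudocount path
  expect_message(v <- clr_test(c(5, 1), c(10, 0)), "pseudocount")
  expect_gte(v, 0)
})
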