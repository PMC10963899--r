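test_that("VCF round trip preserves CHROM/POS/REF/ALT/GT byte-identically", {
  set.seed(42)
  sheet <- make_sheet(4)
  hm <- random_hap_matrix(8, 5)
  hm[1, 3] <- NA  # one missing allele
  sites <- sites_from_hap(hm, chrom = "2", pos = c(10L, 25L, 30L, 47L, 90L),
                          ref = c("A", "C", "G", "T", "A"),
                          alt = c("G", "T", "A", "C", "T"),
                          qual = c(55.5, 90, 20, 31.2, 1000))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sites, sheet, path, provenance = c(seed = 1))
  back <- read_vcf(path, sheet)
  expect_equal(nrow(back), 3 + 2)
  expect_identical(back$chrom, sites$chrom)
  expect_identical(back$pos, sites$pos)
  expect_identical(back$ref, sites$ref)
  expect_identical(back$alt, sites$alt)
  expect_identical(back$gt, sites$gt)
  # and the serialized lines themselves survive a second write
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, sheet, path2, provenance = c(seed = 1))
  expect_identical(readLines(path), readLines(path2))
})

test_that("genotype encodings follow the VCF conventions", {
  sheet <- make_sheet(2)
  sites <- sites_from_hap(matrix(c(0L, 1L, 1L, 1L), nrow = 4), pos = 5L)
  sites$gt[[1]][3:4] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sites, sheet, path)
  row <- strsplit(readLines(path)[5], "\t")[[1]]
  expect_identical(row[10], "0/1")
  expect_identical(row[11], "./.")
  back <- read_vcf(path, sheet)
  expect_identical(back$gt[[1]], c(0L, 1L, NA_integer_, NA_integer_))
})

test_that("empty site list writes a header-only VCF", {
  sheet <- make_sheet(2)
  sites <- sites_from_hap(matrix(integer(), nrow = 4, ncol = 0))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sites, sheet, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(nrow(read_vcf(path, sheet)), 0)
})

test_that("unsorted sites and sample mismatches are rejected", {
  sheet <- make_sheet(2)
  sites <- sites_from_hap(random_hap_matrix(4, 2), pos = c(20L, 10L))
  expect_error(write_vcf(sites, sheet, tempfile()), "sorted")
  ok <- sites_from_hap(random_hap_matrix(4, 2), pos = c(10L, 20L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(ok, sheet, path)
  bad_sheet <- make_sheet(3)
  expect_error(read_vcf(path, bad_sheet), "absent from VCF")
})

test_that("quality threshold is inclusive at 20 and indels/multiallelics drop", {
  sheet <- make_sheet(3)
  hm <- random_hap_matrix(6, 5, p = rep(0.5, 5))
  sites <- sites_from_hap(hm, pos = 1:5 * 10L,
                          qual = c(19.9, 20.0, 500, 500, 500))
  sites$alt[3] <- "T,G"          # multiallelic
  sites$ref[4] <- "AT"           # indel
  kept <- filter_sites(sites, sheet)
  expect_identical(kept$pos, c(20L, 50L))
  # idempotence
  expect_identical(filter_sites(kept, sheet)$pos, kept$pos)
  expect_error(filter_sites(sites, sheet, qual_min = -1), "non-negative")
})

test_that("missingness is evaluated per cohort", {
  sheet <- make_sheet(4)  # S001-2 resistant, S003-4 susceptible
  hm <- random_hap_matrix(8, 2, p = rep(0.5, 2))
  sites <- sites_from_hap(hm, pos = c(10L, 20L))
  sites$gt[[2]][7] <- NA_integer_  # missing only in sample S004 (cohort B)
  kept_a <- filter_sites(sites, sheet, cohort = "resistant")
  kept_b <- filter_sites(sites, sheet, cohort = "susceptible")
  expect_identical(kept_a$pos, c(10L, 20L))
  expect_identical(kept_b$pos, 10L)
  # empty output is permitted, with a warning
  sites$gt[[1]][1] <- NA_integer_
  sites$gt[[2]][1] <- NA_integer_
  expect_warning(filter_sites(sites, sheet, cohort = "resistant"),
                 "no sites retained")
})

test_that("gene intervals load from TSV (1-based) and BED (+1 start)", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               "UGT301A3\t2\t82046643\t82050536\t+"), tsv)
  g <- load_gene_intervals(tsv)
  expect_equal(g$reported_length, 3893)
  expect_equal(g$length_bp, 3894)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tgeneX\t0\t-", bed)
  gb <- load_gene_intervals(bed)
  expect_equal(gb$start, 100L)
  expect_equal(gb$end, 200L)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               "gA\t1\t1\t10\t+", "gA\t1\t20\t30\t+"), dup)
  expect_error(load_gene_intervals(dup), "gA")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand", "gB\t1\t50\t10\t+"), bad)
  expect_error(load_gene_intervals(bad), "end <= start")
})

test_that("site-to-gene assignment is boundary-inclusive and matches a brute-force scan", {
  set.seed(7)
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = c("1", "1", "2"),
    start = c(100L, 150L, 100L), end = c(200L, 260L, 300L),
    strand = "+", cds_id = NA_character_
  )
  sites <- sites_from_hap(random_hap_matrix(4, 6),
                          chrom = c("1", "1", "1", "1", "2", "3"),
                          pos = c(100L, 200L, 180L, 99L, 250L, 10L))
  out <- assign_sites_to_genes(sites, genes)
  # start boundary inclusive (g1 alone), end boundary inclusive (g1 and g2)
  expect_setequal(out$gene_id[out$pos == 100 & out$chrom == "1"], "g1")
  expect_setequal(out$gene_id[out$pos == 200 & out$chrom == "1"], c("g1", "g2"))
  # overlap zone appears under both genes
  expect_setequal(out$gene_id[out$pos == 180], c("g1", "g2"))
  expect_true(is.na(out$gene_id[out$pos == 99]))
  expect_identical(out$effect[out$pos == 10], "intergenic")
  # random fixture vs O(n*m) scan
  rs <- sites_from_hap(random_hap_matrix(4, 40),
                       chrom = sample(c("1", "2"), 40, replace = TRUE),
                       pos = sample.int(400, 40))
  rg <- tibble::tibble(
    gene_id = paste0("g", 1:8), chrom = rep(c("1", "2"), 4),
    start = as.integer(sample.int(300, 8)), strand = "+", cds_id = NA_character_
  )
  rg$end <- rg$start + as.integer(sample.int(80, 8))
  got <- assign_sites_to_genes(rs, rg)
  got_pairs <- sort(paste(got$chrom, got$pos, got$gene_id)[!is.na(got$gene_id)])
  want <- brute_assign(rs, rg)
  want_pairs <- sort(vapply(want, function(w) {
    i <- as.integer(w["i"])
    paste(rs$chrom[i], rs$pos[i], w["gene"])
  }, character(1)))
  expect_identical(got_pairs, want_pairs)
})

test_that("coverage filter keeps genes at exactly 100x and warns on absences", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "1",
                          start = c(1L, 100L, 200L), end = c(50L, 150L, 250L),
                          strand = "+", cds_id = NA_character_)
  cov <- tibble::tibble(gene_id = c("g1", "g2"), mean_depth = c(99.9, 100.0))
  expect_warning(kept <- coverage_filter(genes, cov), "absent")
  expect_identical(kept$gene_id, "g2")
  all_cov <- tibble::tibble(gene_id = genes$gene_id, mean_depth = 500)
  expect_identical(coverage_filter(genes, all_cov)$gene_id, genes$gene_id)
  empty <- tibble::tibble(gene_id = character(), mean_depth = numeric())
  expect_warning(none <- coverage_filter(genes, empty), "absent")
  expect_equal(nrow(none), 0)
  bad <- tibble::tibble(gene_id = "g1", mean_depth = "high")
  expect_error(coverage_filter(genes, bad), "non-numeric")
})

test_that("haplotype extraction yields 2N haplotypes with provenance", {
  set.seed(3)
  sheet <- make_sheet(80)
  sites <- sites_from_hap(random_hap_matrix(160, 7), pos = 1:7 * 3L)
  h <- extract_haplotypes(sites, sheet, gene = "gX")
  expect_equal(nrow(h), 160)
  expect_equal(unique(nchar(h$haplotype)), 7)
  expect_equal(sum(h$population == "popA"), 80)
  # homozygous sample gives two identical haplotypes
  one <- make_sheet(1)
  hom <- sites_from_hap(matrix(c(1L, 1L, 0L, 0L), nrow = 2), pos = c(1L, 2L))
  h1 <- extract_haplotypes(hom, one)
  expect_identical(h1$haplotype[1], h1$haplotype[2])
  # zero polymorphic sites: empty strings, count still 2N
  h0 <- extract_haplotypes(sites_from_hap(matrix(integer(), 4, 0)), make_sheet(2))
  expect_equal(nrow(h0), 4)
  expect_identical(unique(h0$haplotype), "")
  # missing genotypes direct the user to filter first
  miss <- sites_from_hap(matrix(c(NA_integer_, 0L, 1L, 0L), nrow = 4, ncol = 1))
  expect_error(extract_haplotypes(miss, make_sheet(2)), "filter")
})
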