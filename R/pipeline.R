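# End-to-end orchestration: filter -> annotate -> per-gene statistics ->
# gene FST + bootstrap + quantile flags -> per-SNP wcFst/pFst/q-values ->
# Tajima calibration + flags, with TSV/JSON/Markdown reports.

#' Per-gene statistics scan
#'
#' Computes, for every gene with assigned sites, the full per-gene bundle:
#' segregating sites, pi (per cohort and pooled), Watterson's theta,
#' Tajima's D on all/synonymous/nonsynonymous partitions, Fu & Li's D* and
#' F*, the CLR against the pooled background SFS, piN/piS (when CDS models
#' are supplied), and the gene-wise Weir-Cockerham FST between the two
#' cohorts.
#'
#' @param sites Filtered, gene-assigned (and ideally effect-annotated)
#'   site tibble.
#' @param genes Gene interval tibble (defines the gene universe; genes
#'   without sites get S = 0 rows).
#' @param sample_sheet Sample sheet.
#' @param cohorts List/vector of two cohort specs (ids or labels); the
#'   pooled union is the diversity cohort, the pair is the FST contrast.
#' @param cds_models Optional named list of [cds_model()] objects for
#'   piN/piS denominators.
#' @return A `gene_scan` tibble, one row per gene.
#' @export
scan_genes <- function(sites, genes, sample_sheet, cohorts,
                       cds_models = NULL) {
  stopifnot(length(cohorts) == 2)
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  ids_a <- resolve_cohort(sample_sheet, cohorts[[1]])
  ids_b <- resolve_cohort(sample_sheet, cohorts[[2]])
  pooled <- union(ids_a, ids_b)

  site_groups <- split(seq_len(nrow(sites)), sites$gene_id)
  background <- sfs(sites[!is.na(sites$gene_id), , drop = FALSE],
                    sample_sheet, pooled, folded = TRUE)

  rows <- lapply(seq_len(nrow(genes)), function(gi) {
    g <- genes$gene_id[gi]
    gs <- sites[site_groups[[g]] %||% integer(), , drop = FALSE]
    attr(gs, "samples") <- samples
    div_all <- gene_diversity(gs, sample_sheet, pooled, "all") %>%
      tajimas_d() %>% fu_li_star()
    div_syn <- tajimas_d(gene_diversity(gs, sample_sheet, pooled, "synonymous"))
    div_non <- tajimas_d(gene_diversity(gs, sample_sheet, pooled, "nonsynonymous"))
    pi_a <- gene_diversity(gs, sample_sheet, ids_a, "all")$pi
    pi_b <- gene_diversity(gs, sample_sheet, ids_b, "all")$pi
    fst <- if (nrow(gs)) gene_fst(gs, sample_sheet, list(ids_a, ids_b)) else NA_real_
    clr <- if (div_all$S > 0) {
      clr_test(sfs(gs, sample_sheet, pooled, folded = TRUE), background)
    } else {
      NA_real_
    }
    pn_ps <- if (!is.null(cds_models[[g]]) && nrow(gs)) {
      pi_n_pi_s(gs, ng_site_counts(cds_models[[g]]), sample_sheet, pooled)
    } else {
      tibble(pi_n = NA_real_, pi_s = NA_real_, pi_ratio = NA_real_,
             ratio_defined = NA)
    }
    tibble(
      gene_id = g, chrom = genes$chrom[gi],
      n = div_all$n, S = div_all$S, eta_s = div_all$eta_s,
      pi = div_all$pi, theta_w = div_all$theta_w,
      pi_cohort1 = pi_a, pi_cohort2 = pi_b,
      tajima_d = div_all$tajima_d,
      tajima_d_syn = div_syn$tajima_d,
      tajima_d_nonsyn = div_non$tajima_d,
      fu_li_dstar = div_all$fu_li_dstar, fu_li_fstar = div_all$fu_li_fstar,
      clr = clr,
      pi_n = pn_ps$pi_n, pi_s = pn_ps$pi_s, pi_ratio = pn_ps$pi_ratio,
      fst_gene = fst
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("gene_scan", class(out))
  out
}

#' Per-SNP differentiation report
#'
#' Per-site Weir-Cockerham FST, pFst likelihood-ratio p-values with FDR
#' q-values, coding effect, and optional protein-domain context labels.
#'
#' @inheritParams scan_genes
#' @param fdr_method `"storey"` (default) or `"bh"`.
#' @param domains Optional named list (by gene id) of domain tibbles
#'   (`domain`, `aa_start`, `aa_end`) for [snp_domain_context()] labels.
#' @return Tibble: chrom, pos, gene_id, effect, fst_site, lambda, p_value,
#'   q_value, domain_context.
#' @export
scan_snps <- function(sites, sample_sheet, cohorts, fdr_method = "storey",
                      domains = NULL, cds_models = NULL) {
  stopifnot(length(cohorts) == 2)
  ids <- list(resolve_cohort(sample_sheet, cohorts[[1]]),
              resolve_cohort(sample_sheet, cohorts[[2]]))
  wc <- wc_fst_site(sites, sample_sheet, ids)
  pf <- pfst_sites(sites, sample_sheet, ids)
  out <- tibble(
    chrom = sites$chrom, pos = sites$pos,
    gene_id = sites$gene_id %||% NA_character_,
    effect = sites$effect,
    fst_site = wc$fst_site, lambda = pf$lambda, p_value = pf$p_value
  )
  out$q_value <- fdr_qvalues(out$p_value, method = fdr_method)
  out$domain_context <- "none"
  if (!is.null(domains) && !is.null(cds_models)) {
    for (g in intersect(names(domains), names(cds_models))) {
      rows <- which(out$gene_id == g)
      if (!length(rows)) next
      idx <- cds_index_of(cds_models[[g]], out$pos[rows])
      codons <- (idx - 1L) %/% 3L + 1L
      plen <- cds_models[[g]]$length %/% 3L
      out$domain_context[rows] <- vapply(codons, function(ci) {
        if (is.na(ci)) "none" else snp_domain_context(ci, domains[[g]], plen)
      }, character(1))
    }
  }
  out
}

# single-exon CDS models from gene intervals + a CDS FASTA, where the CDS
# spans the full gene interval (the synthetic-dataset layout); genes whose
# CDS length does not match their span are skipped
cds_models_from_fasta <- function(genes, cds_fasta) {
  seqs <- Biostrings::readDNAStringSet(cds_fasta)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cid <- genes$cds_id[i]
    if (is.na(cid) || !cid %in% names(seqs)) next
    s <- as.character(seqs[[cid]])
    span <- genes$end[i] - genes$start[i] + 1L
    if (nchar(s) != span || nchar(s) %% 3L != 0L) next
    out[[genes$gene_id[i]]] <- cds_model(
      cid, genes$gene_id[i],
      tibble(start = genes$start[i], end = genes$end[i]),
      genes$strand[i], s
    )
  }
  out
}

#' Run the full gene-wise scan pipeline
#'
#' Executes, for one cohort pair: quality/biallelic/missingness filtering,
#' coverage filtering of genes, gene assignment, codon-aware effect
#' annotation, the per-gene statistics scan, gene-wise FST bootstrap
#' p-values and per-chromosome quantile flags, Tajima's D calibration (a
#' neutral coalescent null matched to the cohort size, with theta set to
#' the median Watterson estimate unless supplied) and flags, and the
#' per-SNP differentiation report. Deterministic under a fixed seed.
#'
#' @param data A `sim_dataset` from [simulate_dataset()], or a named list
#'   of paths with elements `vcf`, `gff3` (or `genes`), `cds_fasta`,
#'   `samples`, `coverage`.
#' @param cohorts Two cohort specs (default the `resistant` /
#'   `susceptible` phenotype classes).
#' @param qual_min,min_cov,B,quantile,alpha Pipeline thresholds (defaults
#'   20, 100, 1000, 0.95, 0.05).
#' @param n_loci_null Loci in the Tajima's D calibration (default 2000).
#' @param theta_null Per-locus theta of the calibration; default the
#'   median Watterson estimate over scanned genes.
#' @param calibration Optional precomputed [calibrate_tajima_null()]
#'   object (or path to its JSON); skips recalibration.
#' @param seed Seed driving bootstrap and calibration.
#' @param out_dir Optional directory: writes `gene_report.tsv`,
#'   `snp_report.tsv`, `calibration.json`, `summary.md` and `run_log.tsv`.
#' @return A `scan_result` list: `gene_report` (a `gene_scan` tibble with
#'   flags), `snp_report`, `calibration`, `log`, `config_hash`.
#' @export
run_scan <- function(data, cohorts = c("resistant", "susceptible"),
                     qual_min = 20, min_cov = 100, B = 1000,
                     quantile = 0.95, alpha = 0.05, n_loci_null = 2000,
                     theta_null = NULL, calibration = NULL, seed = 1L,
                     out_dir = NULL) {
  paths <- if (inherits(data, "sim_dataset")) data$paths else data
  t0 <- Sys.time()
  log <- list()
  stage <- function(name, n) {
    log[[length(log) + 1]] <<- tibble(
      stage = name, records = n,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    )
  }

  sheet <- read_sample_sheet(paths$samples)
  cohort_ids <- lapply(cohorts, resolve_cohort, sample_sheet = sheet)
  pooled <- union(cohort_ids[[1]], cohort_ids[[2]])

  sites <- read_vcf(paths$vcf, sheet)
  stage("read_vcf", nrow(sites))
  sites <- filter_sites(sites, sheet, qual_min = qual_min, cohort = pooled)
  stage("filter_sites", nrow(sites))

  genes <- load_gene_intervals(paths$gff3 %||% paths$genes)
  genes <- coverage_filter(genes, paths$coverage, min_cov = min_cov)
  stage("coverage_filter", nrow(genes))

  sites <- assign_sites_to_genes(sites, genes)
  cds_models <- if (!is.null(paths$cds_fasta)) {
    cds_models_from_fasta(genes, paths$cds_fasta)
  }
  if (!is.null(cds_models)) sites <- annotate_effects(sites, cds_models, genes)
  stage("annotate", nrow(sites))

  gene_sites <- sites[!is.na(sites$gene_id), , drop = FALSE]
  attr(gene_sites, "samples") <- attr(sites, "samples")
  scan <- scan_genes(gene_sites, genes, sheet, cohort_ids, cds_models)
  stage("gene_stats", nrow(scan))

  scan <- bootstrap_fst_pvalues(scan, B = B, seed = derive_seed(seed, 1),
                                scope = "chrom")
  scan <- quantile_flags(scan, q = quantile, p_max = alpha)
  stage("fst_significance", sum(scan$fst_significant, na.rm = TRUE))

  if (is.character(calibration)) calibration <- read_calibration(calibration)
  if (is.null(calibration)) {
    theta_null <- theta_null %||%
      stats::median(scan$theta_w[scan$S > 0], na.rm = TRUE)
    calibration <- calibrate_tajima_null(
      n = 2L * length(pooled), theta = theta_null, n_loci = n_loci_null,
      seed = derive_seed(seed, 2)
    )
  }
  scan <- flag_tajima(scan, calibration)
  stage("tajima_flags", sum(scan$tajima_low | scan$tajima_high, na.rm = TRUE))

  snp_report <- scan_snps(gene_sites, sheet, cohort_ids,
                          cds_models = cds_models)
  stage("snp_stats", nrow(snp_report))

  cfg <- list(cohorts = cohorts, qual_min = qual_min, min_cov = min_cov,
              B = B, quantile = quantile, alpha = alpha,
              n_loci_null = n_loci_null, seed = seed,
              calibration = calibration$config_hash)
  result <- structure(
    list(gene_report = scan, snp_report = snp_report,
         calibration = calibration, log = list_rbind(log),
         config_hash = hash(cfg), seed = seed),
    class = "scan_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(result, file.path(out_dir, "gene_report.tsv"), "tsv")
    readr::write_tsv(snp_report, file.path(out_dir, "snp_report.tsv"))
    write_calibration(calibration, file.path(out_dir, "calibration.json"))
    write_report(result, file.path(out_dir, "summary.md"), "markdown")
    readr::write_tsv(mutate(result$log, config_hash = result$config_hash),
                     file.path(out_dir, "run_log.tsv"))
  }
  result
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Gene-wise population-genetics scan\n")
  cat("  genes:", nrow(x$gene_report),
      "  SNPs:", nrow(x$snp_report), "\n")
  cat("  fst_significant:", sum(x$gene_report$fst_significant, na.rm = TRUE),
      "  tajima_low:", sum(x$gene_report$tajima_low, na.rm = TRUE),
      "  tajima_high:", sum(x$gene_report$tajima_high, na.rm = TRUE), "\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}

#' Write a scan report
#'
#' `"tsv"` writes the machine-readable gene table; `"markdown"` writes a
#' human summary listing significant genes per category (empty sections
#' are valid).
#'
#' @param result A `scan_result` (or bare `gene_scan` tibble for TSV).
#' @param path Output path.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  scan <- if (inherits(result, "scan_result")) result$gene_report else result
  if (format == "tsv") {
    readr::write_tsv(scan, path)
    return(invisible(path))
  }
  sig_fst <- filter(scan, fst_significant %in% TRUE)
  low <- filter(scan, .data$tajima_low %in% TRUE)
  high <- filter(scan, .data$tajima_high %in% TRUE)
  fmt_genes <- function(df) {
    if (!nrow(df)) return("(none)")
    paste0("- ", df$gene_id, " (chr", df$chrom, ", FST = ",
           signif(df$fst_gene, 4), ", Tajima's D = ",
           signif(df$tajima_d, 4), ")", collapse = "\n")
  }
  lines <- c(
    "# Gene-wise scan summary",
    "",
    paste0("Genes scanned: ", nrow(scan), "."),
    "",
    paste0("## Significant gene-wise FST differentiation (", nrow(sig_fst), ")"),
    "", fmt_genes(sig_fst), "",
    paste0("## Tajima's D below the simulated 0.05 quantile (", nrow(low), ")"),
    "", fmt_genes(low), "",
    paste0("## Tajima's D above the simulated 0.95 quantile (", nrow(high), ")"),
    "", fmt_genes(high), ""
  )
  writeLines(lines, path)
  invisible(path)
}
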