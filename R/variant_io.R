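# Variant, gene-model, sample-sheet and coverage I/O.
#
# The central container is the "site tibble": one row per SNP with columns
#   chrom, pos (1-based), ref, alt, qual, effect, gt
# where `gt` is a list-column holding, per site, an integer vector of length
# 2N over {0, 1, NA} -- the two alleles of every diploid sample in sample-
# sheet order (sample1 allele1, sample1 allele2, sample2 allele1, ...).

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `population`, `phenotype`
#' (phenotype typically `resistant`/`susceptible` in a case/control design).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "population", "phenotype")
  if (!all(need %in% names(sheet))) {
    abort(paste0("sample sheet must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  as_tibble(sheet[need])
}

#' Read biallelic-candidate SNPs from a VCF
#'
#' Parses a VCF v4.x with GT fields into a site tibble. Alleles and genotype
#' strings are preserved verbatim (no filtering happens here; see
#' [filter_sites()]). Positions are 1-based as in the VCF.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_sheet Optional sample sheet tibble; when given, the VCF must
#'   contain every sheet sample and genotypes are ordered to match the sheet.
#' @return A site tibble with attribute `samples` (ordered sample ids).
#' @export
read_vcf <- function(path, sample_sheet = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) {  # single-row VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    sites <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), qual = double(), effect = character(),
                    gt = list())
    attr(sites, "samples") <- sample_sheet$sample_id %||% character()
    return(sites)
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF rows without a GT entry in FORMAT")
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad)) {
    abort(paste0("malformed VCF data row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  vcf_samples <- colnames(v@gt)[-1]
  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample_id, vcf_samples)
    if (length(missing)) {
      abort(paste0("sample sheet samples absent from VCF: ",
                   paste(missing, collapse = ", ")))
    }
    vcf_samples <- sample_sheet$sample_id
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_chr))) {
    gt_chr <- matrix(gt_chr, nrow = 1, dimnames = list(NULL, names(gt_chr)))
  }
  gt_chr <- gt_chr[, vcf_samples, drop = FALSE]

  parse_gt_row <- function(x) {
    parts <- strsplit(x, "[/|]")
    out <- integer(2L * length(x))
    for (j in seq_along(parts)) {
      p <- parts[[j]]
      if (length(p) != 2L || is.na(x[j])) {
        out[c(2L * j - 1L, 2L * j)] <- NA_integer_
      } else {
        a <- suppressWarnings(as.integer(p))
        out[c(2L * j - 1L, 2L * j)] <- a  # "." parses to NA = missing
      }
    }
    out
  }
  gt <- lapply(seq_len(nrow(gt_chr)), function(i) parse_gt_row(gt_chr[i, ]))

  sites <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = pos,
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.double(fix[, "QUAL"])),
    effect = "unannotated",
    gt = gt
  )
  attr(sites, "samples") <- vcf_samples
  sites
}

#' Write a site tibble as VCF v4.2
#'
#' GT-only FORMAT; the header records the tool and optional provenance
#' (seed, filter description). Round-trips through [read_vcf()] with
#' CHROM/POS/REF/ALT/GT preserved byte-identically.
#'
#' @param sites Site tibble sorted by (chrom, pos).
#' @param sample_sheet Sample sheet matching the `gt` ordering.
#' @param path Output path.
#' @param provenance Optional named character vector written as
#'   `##popgenescan_<name>=<value>` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, sample_sheet, path, provenance = NULL) {
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    abort("sites must be sorted by (chrom, pos) before writing")
  }
  samples <- sample_sheet$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=popgenescan-", as.character(utils::packageVersion("popgenescan"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(provenance)) {
    header <- c(header, paste0("##popgenescan_", names(provenance), "=", provenance))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  body <- character(0)
  if (nrow(sites) > 0) {
    gt_str <- vapply(sites$gt, function(g) {
      if (length(g) != 2L * length(samples)) {
        abort("genotype vector length does not match sample sheet")
      }
      a1 <- g[seq(1L, length(g), by = 2L)]
      a2 <- g[seq(2L, length(g), by = 2L)]
      paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2),
            sep = "/", collapse = "\t")
    }, character(1))
    qual_str <- ifelse(is.na(sites$qual), ".",
                       formatC(sites$qual, format = "fg", digits = 15))
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                  qual_str, ".", ".", "GT", gt_str, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Quality / biallelic / missingness site filter
#'
#' Retains sites with `qual >= qual_min` (default 20), exactly one
#' single-nucleotide ALT allele against a single-nucleotide REF, and zero
#' missing genotypes within the analysis cohort. Missingness is evaluated
#' per cohort, so different cohorts may retain different site sets --
#' filter once per cohort rather than globally.
#'
#' @param sites Site tibble.
#' @param sample_sheet Sample sheet (needed to resolve `cohort` labels); if
#'   `NULL`, `cohort` must be sample ids matching the table's `samples`
#'   attribute.
#' @param qual_min Minimum Phred site quality (inclusive); default 20.
#' @param cohort Sample ids, or population/phenotype labels, over which
#'   missingness is checked. Default: all samples.
#' @param subset If `TRUE`, genotypes of samples outside the cohort are
#'   dropped from the output (a per-cohort VCF view).
#' @return Filtered site tibble (idempotent under refiltering).
#' @export
filter_sites <- function(sites, sample_sheet = NULL, qual_min = 20,
                         cohort = NULL, subset = FALSE) {
  if (qual_min < 0) abort("qual_min must be non-negative")
  samples <- attr(sites, "samples")
  if (is.null(samples) && !is.null(sample_sheet)) samples <- sample_sheet$sample_id
  cohort_ids <- if (is.null(sample_sheet)) {
    cohort %||% samples
  } else {
    resolve_cohort(sample_sheet, cohort)
  }
  keep <- !is.na(sites$qual) & sites$qual >= qual_min &
    nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    !grepl(",", sites$alt, fixed = TRUE) & sites$ref != sites$alt
  cols <- hap_columns(samples, cohort_ids)
  if (nrow(sites) > 0) {
    no_missing <- vapply(sites$gt, function(g) !anyNA(g[cols]), logical(1))
    keep <- keep & no_missing
  }
  out <- sites[keep, , drop = FALSE]
  if (subset && !identical(cohort_ids, samples)) {
    out$gt <- lapply(out$gt, function(g) g[cols])
    samples <- cohort_ids
  }
  if (nrow(out) == 0) warn("no sites retained after filtering")
  attr(out, "samples") <- samples
  out
}

#' Load gene intervals from TSV, BED or GFF3
#'
#' TSV and GFF3 coordinates are 1-based inclusive; BED starts are converted
#' by +1. `reported_length` is defined as `end - start` (the printed-table
#' convention of targeted-capture gene panels); the inclusive span
#' `length_bp = end - start + 1` is also exposed.
#'
#' @param path Input path.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"bed"`, `"gff3"`.
#' @return A tibble: gene_id, chrom, start, end, strand, cds_id,
#'   reported_length, length_bp.
#' @export
load_gene_intervals <- function(path, format = c("auto", "tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3",
      "tsv"
    )
  }
  genes <- switch(format,
    tsv = {
      first <- readLines(path, n = 1)
      has_header <- grepl("gene_id", first, fixed = TRUE)
      cn <- c("gene_id", "chrom", "start", "end", "strand")
      df <- readr::read_tsv(path, col_names = if (has_header) TRUE else cn,
                            show_col_types = FALSE)
      if (!all(cn %in% names(df))) {
        abort("gene TSV must have columns gene_id, chrom, start, end, strand")
      }
      tibble(gene_id = as.character(df$gene_id), chrom = as.character(df$chrom),
             start = as.integer(df$start), end = as.integer(df$end),
             strand = as.character(df$strand),
             cds_id = if ("cds_id" %in% names(df)) as.character(df$cds_id) else NA_character_)
    },
    bed = {
      df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
      if (ncol(df) < 4) abort("BED gene file needs at least 4 columns")
      tibble(gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
             start = as.integer(df[[2]]) + 1L, end = as.integer(df[[3]]),
             strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+",
             cds_id = NA_character_)
    },
    gff3 = {
      if (!requireNamespace("rtracklayer", quietly = TRUE)) {
        abort("reading GFF3 requires the rtracklayer package")
      }
      gr <- rtracklayer::import(path, format = "gff3")
      g <- gr[tolower(as.character(gr$type)) == "gene"]
      ids <- as.character(g$ID %||% g$Name)
      cds <- gr[tolower(as.character(gr$type)) == "cds"]
      cds_parent <- if (length(cds)) {
        vapply(cds$Parent, function(p) sub("^mRNA:", "", p[1]), character(1))
      } else {
        character()
      }
      cds_map <- setNames(as.character(cds$ID), cds_parent)
      tibble(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             cds_id = unname(cds_map[ids]))
    }
  )
  if (any(genes$end <= genes$start)) {
    abort(paste0("gene end <= start for: ",
                 paste(genes$gene_id[genes$end <= genes$start], collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) {
    abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  genes %>%
    mutate(reported_length = end - start, length_bp = end - start + 1L)
}

#' Assign SNPs to gene intervals
#'
#' A site belongs to gene g iff chromosomes match and
#' `start <= pos <= end` (both boundaries inclusive). Sites inside several
#' overlapping genes are duplicated, once per gene; unassigned sites keep
#' `gene_id = NA` and are flagged `intergenic` in `effect` (unless already
#' annotated).
#'
#' @param sites Site tibble.
#' @param genes Gene interval tibble from [load_gene_intervals()].
#' @return Site tibble with a `gene_id` column (possibly more rows than the
#'   input where genes overlap).
#' @export
assign_sites_to_genes <- function(sites, genes) {
  samples <- attr(sites, "samples")
  if (nrow(sites) == 0) {
    out <- mutate(sites, gene_id = character(0))
    attr(out, "samples") <- samples
    return(out)
  }
  s_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  g_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(s_gr, g_gr, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  assigned <- sites[si, , drop = FALSE]
  assigned$gene_id <- genes$gene_id[gi]
  orphan <- sites[setdiff(seq_len(nrow(sites)), unique(si)), , drop = FALSE]
  if (nrow(orphan)) {
    orphan$gene_id <- NA_character_
    orphan$effect <- ifelse(orphan$effect == "unannotated", "intergenic", orphan$effect)
  }
  out <- bind_rows(assigned, orphan) %>% arrange(chrom, pos)
  attr(out, "samples") <- samples
  out
}

#' Drop genes with insufficient mean coverage
#'
#' Genes with mean targeted-capture depth below `min_cov` (default 100x) are
#' removed; genes absent from the coverage table are dropped with a warning.
#'
#' @param genes Gene interval tibble.
#' @param coverage A tibble/data frame with columns `gene_id`, `mean_depth`,
#'   or a path to such a TSV.
#' @param min_cov Minimum mean depth (inclusive).
#' @return Filtered gene tibble with a `mean_depth` column.
#' @export
coverage_filter <- function(genes, coverage, min_cov = 100) {
  if (is.character(coverage)) {
    coverage <- readr::read_tsv(coverage, show_col_types = FALSE)
  }
  if (!all(c("gene_id", "mean_depth") %in% names(coverage))) {
    abort("coverage table must have columns gene_id, mean_depth")
  }
  if (!is.numeric(coverage$mean_depth)) {
    abort("non-numeric mean_depth in coverage table")
  }
  merged <- left_join(genes, as_tibble(coverage[c("gene_id", "mean_depth")]),
                      by = "gene_id")
  absent <- merged$gene_id[is.na(merged$mean_depth)]
  if (length(absent)) {
    warn(paste0(length(absent), " gene(s) absent from coverage table dropped: ",
                paste(head(absent, 5), collapse = ", ")))
  }
  filter(merged, !is.na(mean_depth), mean_depth >= min_cov)
}

#' Extract per-gene haplotypes from filtered genotypes
#'
#' Each diploid sample contributes two haplotypes, taken as the first and
#' second allele of every genotype in VCF written order. Unphased genotypes
#' are therefore treated as phased-as-written; the output carries a
#' `phasing` attribute recording this caveat.
#'
#' @param sites Site tibble restricted to one gene, fully filtered (no
#'   missing genotypes among the chosen samples).
#' @param sample_sheet Sample sheet; haplotypes are emitted for every sheet
#'   sample, with population provenance.
#' @param gene Optional gene id stored as an attribute.
#' @return A `haplotype_set` tibble: sample_id, population, phase,
#'   haplotype (allele string over the gene's sites, ascending position).
#' @export
extract_haplotypes <- function(sites, sample_sheet, gene = NULL) {
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  sites <- arrange(sites, pos)
  cols <- hap_columns(samples, sample_sheet$sample_id)
  n_hap <- 2L * nrow(sample_sheet)
  if (nrow(sites) == 0) {
    haps <- rep("", n_hap)
    positions <- integer()
  } else {
    m <- allele_matrix(sites)[, cols, drop = FALSE]
    if (anyNA(m)) {
      abort("missing genotypes present; run filter_sites() on this cohort first")
    }
    ch <- ifelse(m == 0L, sites$ref, sites$alt)  # recycles down rows (sites)
    haps <- apply(ch, 2, paste0, collapse = "")
    positions <- sites$pos
  }
  out <- tibble(
    sample_id = rep(sample_sheet$sample_id, each = 2L),
    population = rep(sample_sheet$population, each = 2L),
    phase = rep(c(1L, 2L), nrow(sample_sheet)),
    haplotype = haps
  )
  class(out) <- c("haplotype_set", class(out))
  attr(out, "gene_id") <- gene
  attr(out, "positions") <- positions
  attr(out, "phasing") <- "as-written (unphased input treated as phased)"
  out
}
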