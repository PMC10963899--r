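# Codon-aware SNP effect classification and Nei-Gojobori site counting.
# Feeds the synonymous/nonsynonymous partitions of the gene scan and the
# piN/piS denominators. Standard genetic code only.

GENCODE <- Biostrings::GENETIC_CODE

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Build a CDS model
#'
#' A coding-sequence model linking a spliced CDS to its genomic exon
#' intervals. The spliced sequence is given 5'->3' in coding orientation;
#' for minus-strand genes it is the reverse complement of the concatenated
#' genomic exon sequence.
#'
#' @param cds_id,gene_id Identifiers.
#' @param exons Data frame with 1-based inclusive genomic `start`, `end`
#'   columns, ascending, non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param seq Spliced CDS sequence (character, ACGT), length divisible by 3.
#' @param validate If `TRUE`, additionally require an ATG start, a terminal
#'   stop codon, and no internal stops.
#' @return An object of class `cds_model`.
#' @export
cds_model <- function(cds_id, gene_id, exons, strand, seq, validate = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_tibble(exons[c("start", "end")])
  exons <- arrange(exons, start)
  if (any(exons$end < exons$start)) abort("exon end < start")
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) abort("CDS contains non-ACGT characters")
  width <- sum(exons$end - exons$start + 1L)
  if (nchar(seq) != width) {
    abort(paste0("spliced CDS length (", nchar(seq),
                 ") does not match exon widths (", width, ")"))
  }
  if (nchar(seq) %% 3L != 0L) abort("CDS length not divisible by 3")
  aa <- translate_cds(seq)
  if (validate) {
    if (substr(seq, 1, 3) != "ATG") abort("CDS does not start with ATG")
    if (substr(aa, nchar(aa), nchar(aa)) != "*") abort("CDS lacks terminal stop")
    if (grepl("\\*", substr(aa, 1, nchar(aa) - 1))) abort("internal stop codon in CDS")
  }
  structure(
    list(cds_id = cds_id, gene_id = gene_id, exons = exons, strand = strand,
         seq = seq, length = nchar(seq)),
    class = "cds_model"
  )
}

translate_cds <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(unname(GENCODE[codons]), collapse = "")
}

# genomic position -> index into the spliced CDS (NA when not exonic)
cds_index_of <- function(cds, pos) {
  offs <- cumsum(c(0L, cds$exons$end - cds$exons$start + 1L))
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(cds$exons))) {
    inx <- pos >= cds$exons$start[i] & pos <= cds$exons$end[i]
    idx[inx] <- offs[i] + (pos[inx] - cds$exons$start[i] + 1L)
  }
  if (cds$strand == "-") idx <- ifelse(is.na(idx), NA_integer_, cds$length - idx + 1L)
  idx
}

#' Classify the coding effect of a SNP
#'
#' Maps the genomic ALT allele onto the spliced CDS (reverse complementing
#' on minus-strand genes), translates the affected codon, and returns one of
#' `synonymous`, `nonsynonymous`, `stop_gained`, `stop_lost`, `intronic`
#' (inside the gene span but outside exons) or `intergenic`.
#'
#' A REF allele that disagrees with the CDS base at the mapped position is
#' an error: it indicates a coordinate or reference mismatch.
#'
#' @param cds A [cds_model()].
#' @param pos,ref,alt Genomic 1-based position and REF/ALT nucleotides
#'   (vectors of equal length).
#' @param gene_span Optional `c(start, end)` of the gene used to distinguish
#'   intronic from intergenic; defaults to the exon span.
#' @return Character vector of effects.
#' @export
classify_snp_effect <- function(cds, pos, ref, alt, gene_span = NULL) {
  span <- gene_span %||% c(min(cds$exons$start), max(cds$exons$end))
  idx <- cds_index_of(cds, pos)
  out <- character(length(pos))
  for (k in seq_along(pos)) {
    if (is.na(idx[k])) {
      out[k] <- if (pos[k] >= span[1] && pos[k] <= span[2]) "intronic" else "intergenic"
      next
    }
    cref <- ref[k]
    calt <- alt[k]
    if (cds$strand == "-") {
      cref <- complement_base(cref)
      calt <- complement_base(calt)
    }
    i <- idx[k]
    if (substr(cds$seq, i, i) != cref) {
      abort(paste0("REF allele disagrees with CDS base at genomic position ",
                   pos[k], " (CDS index ", i, "): coordinate or reference mismatch"))
    }
    cod_i <- (i - 1L) %/% 3L
    cod <- substr(cds$seq, 3L * cod_i + 1L, 3L * cod_i + 3L)
    in_cod <- (i - 1L) %% 3L + 1L
    mut <- cod
    substr(mut, in_cod, in_cod) <- calt
    aa0 <- unname(GENCODE[cod])
    aa1 <- unname(GENCODE[mut])
    out[k] <- if (aa0 == aa1) {
      "synonymous"
    } else if (aa1 == "*") {
      "stop_gained"
    } else if (aa0 == "*") {
      "stop_lost"
    } else {
      "nonsynonymous"
    }
  }
  out
}

#' Annotate site effects against a set of CDS models
#'
#' Fills the `effect` column of a gene-assigned site tibble using
#' [classify_snp_effect()] per gene. Sites without a gene or without a CDS
#' model keep their current annotation (`intergenic` / `unannotated`).
#'
#' @param sites Site tibble with a `gene_id` column
#'   (see [assign_sites_to_genes()]).
#' @param cds_models Named list of [cds_model()] objects keyed by gene id.
#' @param genes Optional gene tibble supplying gene spans for the
#'   intronic/intergenic distinction.
#' @return The site tibble with `effect` filled in.
#' @export
annotate_effects <- function(sites, cds_models, genes = NULL) {
  samples <- attr(sites, "samples")
  for (g in unique(sites$gene_id)) {
    if (is.na(g) || is.null(cds_models[[g]])) next
    rows <- which(sites$gene_id == g)
    span <- NULL
    if (!is.null(genes)) {
      gi <- match(g, genes$gene_id)
      if (!is.na(gi)) span <- c(genes$start[gi], genes$end[gi])
    }
    sites$effect[rows] <- classify_snp_effect(
      cds_models[[g]], sites$pos[rows], sites$ref[rows], sites$alt[rows],
      gene_span = span
    )
  }
  attr(sites, "samples") <- samples
  sites
}

#' Nei-Gojobori synonymous/nonsynonymous site counts
#'
#' For every codon, each of the three positions contributes `f/3`
#' synonymous sites, where `f` is the fraction of the three possible
#' single-nucleotide changes at that position that preserve the amino acid
#' (unweighted Nei & Gojobori 1986). Changes creating or destroying stop
#' codons count as nonsynonymous. Per codon, synonymous + nonsynonymous
#' sites always sum to 3.
#'
#' @param cds A [cds_model()] or a plain CDS sequence string.
#' @return A list with `syn_sites`, `nonsyn_sites` (gene totals) and
#'   `codons`, a tibble of per-codon fractional counts.
#' @export
ng_site_counts <- function(cds) {
  seq <- if (inherits(cds, "cds_model")) cds$seq else toupper(cds)
  if (grepl("[^ACGT]", seq)) abort("ambiguity codes in CDS are not supported")
  if (nchar(seq) %% 3L != 0L) abort("CDS length not divisible by 3")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  bases <- c("A", "C", "G", "T")
  per_codon <- vapply(codons, function(cod) {
    aa0 <- unname(GENCODE[cod])
    syn <- 0
    for (p in 1:3) {
      alt <- setdiff(bases, substr(cod, p, p))
      mut <- vapply(alt, function(b) {
        m <- cod
        substr(m, p, p) <- b
        unname(GENCODE[m])
      }, character(1))
      syn <- syn + sum(mut == aa0) / 3
    }
    syn
  }, numeric(1))
  tibble_codons <- tibble(
    codon_index = seq_along(codons),
    codon = codons,
    syn = unname(per_codon),
    nonsyn = 3 - unname(per_codon)
  )
  list(
    syn_sites = sum(tibble_codons$syn),
    nonsyn_sites = sum(tibble_codons$nonsyn),
    codons = tibble_codons
  )
}

#' Gene-wise piN/piS
#'
#' Nucleotide diversity of nonsynonymous polymorphism over nonsynonymous
#' sites, divided by the synonymous analogue: `piN = sum(site pi at
#' nonsynonymous SNPs) / nonsyn_sites`, `piS` likewise over synonymous SNPs
#' and sites. Stop-affecting SNPs count as nonsynonymous. A ratio below 1
#' indicates purifying selection on the protein sequence. When `piS = 0`
#' the ratio is undefined and flagged, not coerced to a number.
#'
#' @param sites Effect-annotated site tibble for one gene.
#' @param counts Site-class denominators from [ng_site_counts()].
#' @param sample_sheet,cohort Cohort over which per-site diversity is
#'   computed (default: all samples).
#' @return One-row tibble: pi_n, pi_s, pi_ratio, ratio_defined.
#' @export
pi_n_pi_s <- function(sites, counts, sample_sheet = NULL, cohort = NULL) {
  samples <- attr(sites, "samples") %||% sample_sheet$sample_id
  ids <- if (is.null(sample_sheet)) samples else resolve_cohort(sample_sheet, cohort)
  cols <- hap_columns(samples, ids)
  pi_of <- function(rows) {
    if (!length(rows)) return(0)
    m <- allele_matrix(sites[rows, ])[, cols, drop = FALSE]
    n <- ncol(m)
    ac <- rowSums(m)
    sum(site_pi(n - ac, ac))
  }
  nonsyn_rows <- which(sites$effect %in% c("nonsynonymous", "stop_gained", "stop_lost"))
  syn_rows <- which(sites$effect == "synonymous")
  pi_n <- pi_of(nonsyn_rows) / counts$nonsyn_sites
  pi_s <- pi_of(syn_rows) / counts$syn_sites
  defined <- pi_s > 0
  tibble(
    pi_n = pi_n, pi_s = pi_s,
    pi_ratio = if (defined) pi_n / pi_s else NA_real_,
    ratio_defined = defined
  )
}

#' Protein-domain context of a coding SNP
#'
#' Reports which annotated protein domain (signal peptide, N-terminal
#' domain, sugar-donor binding regions, conserved motif, transmembrane
#' domain, cytoplasmic tail, ...) contains the amino-acid position of a SNP,
#' or a "between X and Y" label when it falls in the gap separating two
#' annotated domains, or `"none"`.
#'
#' @param codon_index Amino-acid (codon) position of the SNP.
#' @param domains Optional tibble with columns `domain`, `aa_start`,
#'   `aa_end` (amino-acid coordinates).
#' @param protein_length Optional protein length used to validate domains.
#' @return A single character label.
#' @export
snp_domain_context <- function(codon_index, domains = NULL, protein_length = NULL) {
  if (is.null(domains) || nrow(domains) == 0) return("none")
  if (!is.null(protein_length) && any(domains$aa_end > protein_length)) {
    abort("domain interval extends beyond protein length")
  }
  domains <- arrange(domains, aa_start)
  inside <- which(codon_index >= domains$aa_start & codon_index <= domains$aa_end)
  if (length(inside)) return(domains$domain[inside[1]])
  before <- which(domains$aa_end < codon_index)
  after <- which(domains$aa_start > codon_index)
  if (length(before) && length(after)) {
    return(paste0("between ", domains$domain[max(before)],
                  " and ", domains$domain[min(after)]))
  }
  "none"
}
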