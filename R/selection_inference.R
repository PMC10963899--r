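# Significance calls on gene-wise statistics: bootstrap p-values for
# gene FST, per-chromosome quantile thresholds, and coalescent-calibrated
# Tajima's D flags.

#' Bootstrap p-values for gene-wise FST
#'
#' Resamples the observed gene-wise FST values with replacement (`B`
#' replicates, each of the same size as the gene set), pools all replicate
#' draws into one empirical null, and reports
#' `p = (k + 1) / (N + 1)` per gene, where `k` is the number of pooled null
#' draws at or above the gene's observed FST. The `+1` correction avoids
#' p = 0 artifacts. One-sided: only high differentiation is tested. Scope
#' defaults to per-chromosome, matching the per-chromosome significance
#' rule.
#'
#' @param scan Tibble with columns `gene_id`, `chrom`, `fst_gene`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Seed; fixed seed gives identical p-values across runs.
#' @param scope `"chrom"` (resample within chromosomes) or `"global"`.
#' @return `scan` with a `p_boot` column.
#' @export
bootstrap_fst_pvalues <- function(scan, B = 1000, seed = NULL,
                                  scope = c("chrom", "global")) {
  scope <- match.arg(scope)
  if (B < 1) abort("B must be at least 1")
  groups <- if (scope == "chrom") scan$chrom else rep("all", nrow(scan))
  p <- rep(NA_real_, nrow(scan))
  with_seed(seed, {
    for (g in unique(groups)) {
      rows <- which(groups == g & !is.na(scan$fst_gene))
      if (length(rows) < 2) {
        if (length(rows)) {
          warn(paste0("scope '", g, "' has fewer than 2 genes with defined FST; ",
                      "bootstrap p left NA"))
        }
        next
      }
      v <- scan$fst_gene[rows]
      draws <- sample(v, B * length(v), replace = TRUE)
      sorted <- sort(draws)
      N <- length(sorted)
      # k = number of pooled draws >= observed value
      k <- N - findInterval(v, sorted, left.open = TRUE)
      p[rows] <- (k + 1) / (N + 1)
    }
  })
  scan$p_boot <- p
  scan
}

#' Per-chromosome quantile significance flags for gene FST
#'
#' A gene is `fst_significant` iff its gene-wise FST reaches the empirical
#' `q` quantile (type-7, linear interpolation) of genes on its chromosome
#' AND its bootstrap p-value is below `p_max`. The per-chromosome quantile
#' value is emitted in the `fst_quantile` column. Chromosomes with fewer
#' than `min_genes` genes are skipped with a warning.
#'
#' @param scan Tibble with `chrom`, `fst_gene`, `p_boot`.
#' @param q Quantile level (default 0.95).
#' @param p_max Bootstrap p-value threshold (default 0.05).
#' @param min_genes Minimum genes per chromosome (default 5).
#' @return `scan` with `fst_quantile` and `fst_significant` columns.
#' @export
quantile_flags <- function(scan, q = 0.95, p_max = 0.05, min_genes = 5) {
  scan$fst_quantile <- NA_real_
  scan$fst_significant <- NA
  for (ch in unique(scan$chrom)) {
    rows <- which(scan$chrom == ch)
    vals <- scan$fst_gene[rows]
    if (sum(!is.na(vals)) < min_genes) {
      warn(paste0("chromosome '", ch, "' has fewer than ", min_genes,
                  " genes with defined FST; significance flag skipped"))
      next
    }
    thr <- unname(quantile(vals, q, na.rm = TRUE, type = 7))
    scan$fst_quantile[rows] <- thr
    scan$fst_significant[rows] <- !is.na(vals) & vals >= thr &
      !is.na(scan$p_boot[rows]) & scan$p_boot[rows] < p_max
  }
  scan
}

# Tajima's D straight from a 0/1 haplotype matrix (used on simulated loci)
tajima_d_matrix <- function(mat, consts = NULL) {
  n <- nrow(mat)
  S <- ncol(mat)
  if (S == 0 || n < 4) return(NA_real_)
  k <- consts %||% tajima_constants(n)
  ac <- colSums(mat)
  pi <- sum(ac * (n - ac)) / choose(n, 2)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Calibrate the neutral null of gene-wise Tajima's D
#'
#' Simulates `n_loci` neutral coalescent loci at the cohort's sample size
#' and per-locus theta, computes Tajima's D per locus, and stores the draws
#' with their empirical 0.05 and 0.95 quantiles as the (lower, upper)
#' significance cutoffs -- the two extremities of the simulated density.
#' Loci with S = 0 are redrawn up to `retry_cap` times, then counted as
#' undefined and excluded (reported in the returned object).
#'
#' @param n Haplotype sample size matching the cohort under test.
#' @param theta Per-locus 4N*mu (e.g. the median Watterson estimate of the
#'   observed data).
#' @param n_loci Number of simulated loci (default 2000).
#' @param demography A [demog_constant()]-family object.
#' @param seed Seed; same seed gives identical cutoffs.
#' @param retry_cap Redraw attempts for S = 0 loci.
#' @return A `tajima_calibration` object: draws, `lower`, `upper`, the
#'   configuration and its hash.
#' @export
calibrate_tajima_null <- function(n, theta, n_loci = 2000,
                                  demography = demog_constant(), seed = NULL,
                                  retry_cap = 20) {
  consts <- tajima_constants(n)
  draws <- rep(NA_real_, n_loci)
  n_undefined <- 0L
  with_seed(seed, {
    for (i in seq_len(n_loci)) {
      d <- NA_real_
      for (try in seq_len(retry_cap)) {
        mat <- simulate_locus(n, theta, demography,
                              locus_length_bp = max(1000L, ceiling(theta * 50)))
        d <- tajima_d_matrix(mat, consts)
        if (!is.na(d)) break
      }
      if (is.na(d)) n_undefined <- n_undefined + 1L
      draws[i] <- d
    }
  })
  if (n_undefined > 0) {
    inform(paste0(n_undefined, " locus/loci remained monomorphic after ",
                  retry_cap, " redraws and were excluded"))
  }
  ok <- draws[!is.na(draws)]
  cfg <- list(n = n, theta = theta, n_loci = n_loci,
              demography = unclass(demography), seed = seed)
  structure(
    list(draws = ok,
         lower = unname(quantile(ok, 0.05, type = 7)),
         upper = unname(quantile(ok, 0.95, type = 7)),
         n_undefined = n_undefined, config = cfg,
         config_hash = hash(cfg)),
    class = "tajima_calibration"
  )
}

#' Flag genes against a Tajima's D calibration
#'
#' `tajima_low` iff D <= lower cutoff; `tajima_high` iff D >= upper cutoff
#' (both boundaries inclusive; two-sided by design). Undefined D values are
#' never flagged.
#'
#' @param scan Tibble with a `tajima_d` column.
#' @param calib A [calibrate_tajima_null()] object.
#' @return `scan` with logical `tajima_low`, `tajima_high` columns.
#' @export
flag_tajima <- function(scan, calib) {
  stopifnot(inherits(calib, "tajima_calibration"))
  d <- scan$tajima_d
  scan$tajima_low <- !is.na(d) & d <= calib$lower
  scan$tajima_high <- !is.na(d) & d >= calib$upper
  scan
}

#' Save / load a Tajima's D calibration as JSON
#'
#' The JSON artifact stores the draws, cutoffs, configuration and its hash
#' so a calibration can be reused across runs.
#'
#' @param calib A `tajima_calibration` object.
#' @param path Output / input path.
#' @return `path` invisibly; `read_calibration()` returns the object.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config <- as.list(x$config)
  structure(x, class = "tajima_calibration")
}
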