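#' Harmonic and squared-harmonic sums used by neutrality statistics
#'
#' `a1_n(n)` is \eqn{\sum_{i=1}^{n-1} 1/i} and `a2_n(n)` is
#' \eqn{\sum_{i=1}^{n-1} 1/i^2}, where `n` is the number of sampled
#' haplotypes. These are the normalising constants of the Watterson
#' estimator and of the variance terms of Tajima's D and Fu & Li's tests.
#'
#' @param n Haplotype sample size (integer, >= 2).
#' @return A numeric scalar.
#' @export
a1_n <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

#' @rdname a1_n
#' @export
a2_n <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1)^2)
}

#' Tajima (1989) constants for sample size n
#'
#' Returns the full set of constants (a1, a2, b1, b2, c1, c2, e1, e2)
#' entering the variance of Tajima's D for `n` sampled haplotypes.
#'
#' @param n Haplotype sample size (>= 4 for a defined variance).
#' @return A named list of numeric scalars.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- a1_n(n)
  a2 <- a2_n(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# run expr with a local RNG state seeded by `seed`; restores the caller's
# .Random.seed so library code never perturbs user RNG streams
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# derive a reproducible child seed below 2^31 from a parent seed and an index
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647L)
}

#' Genotype/allele matrix of a site table
#'
#' Converts the `gt` list-column of a site tibble (one integer vector of
#' length 2N per site, alleles ordered sample-by-sample) into an
#' S x 2N integer matrix (rows = sites, columns = haploid allele slots).
#'
#' @param sites A site tibble as returned by [read_vcf()].
#' @return An integer matrix with one row per site.
#' @export
allele_matrix <- function(sites) {
  stopifnot(is.data.frame(sites), "gt" %in% names(sites))
  if (nrow(sites) == 0) {
    return(matrix(integer(), nrow = 0, ncol = 0))
  }
  do.call(rbind, sites$gt)
}

# columns of the allele matrix belonging to the given sample ids,
# given the ordered sample vector the matrix was built over
hap_columns <- function(samples, ids) {
  idx <- match(ids, samples)
  if (anyNA(idx)) {
    abort(paste0(
      "samples not present in site table: ",
      paste(ids[is.na(idx)], collapse = ", ")
    ))
  }
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

# resolve a cohort spec (sample ids, or population/phenotype labels from the
# sample sheet) to a character vector of sample ids
resolve_cohort <- function(sample_sheet, cohort) {
  if (is.null(cohort)) {
    return(sample_sheet$sample_id)
  }
  if (all(cohort %in% sample_sheet$sample_id)) {
    return(cohort)
  }
  hit <- sample_sheet$population %in% cohort |
    sample_sheet$phenotype %in% cohort
  if (!any(hit)) {
    abort(paste0(
      "cohort spec matches no sample ids, populations or phenotypes: ",
      paste(cohort, collapse = ", ")
    ))
  }
  sample_sheet$sample_id[hit]
}
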