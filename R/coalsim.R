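# Hudson coalescent simulator (no intralocus recombination) with simple
# demographies, partial-sweep emulation and case/control focal-SNP
# injection. Time is measured in units of 4N generations and theta = 4N*mu
# per locus (the ms convention), so published neutral expectations apply:
# E[S] = theta * a1(n), E[pi] = theta.

#' Demography specifications
#'
#' `demog_constant()` is the equilibrium coalescent. `demog_growth(rate)`
#' is exponential growth at `rate` (backwards in time the population
#' shrinks as `exp(-rate * t)`, inflating the coalescence intensity and
#' skewing Tajima's D negative). `demog_bottleneck(time, strength)` scales
#' the population to `strength * N` for times older than `time`.
#'
#' @param rate Exponential growth rate per 4N generations (> 0).
#' @param time Bottleneck onset, in 4N generations before sampling.
#' @param strength Relative size of the ancestral (pre-`time`) population.
#' @return A `demography` object.
#' @export
demog_constant <- function() {
  structure(list(type = "constant"), class = "demography")
}

#' @rdname demog_constant
#' @export
demog_growth <- function(rate) {
  if (rate < 0) abort("growth rate must be non-negative")
  structure(list(type = "growth", rate = rate), class = "demography")
}

#' @rdname demog_constant
#' @export
demog_bottleneck <- function(time, strength) {
  if (time < 0 || strength <= 0) abort("invalid bottleneck parameters")
  structure(list(type = "bottleneck", time = time, strength = strength),
            class = "demography")
}

# waiting time to the next coalescence for k lineages at current time t,
# by inversion of the cumulative coalescence intensity
coal_wait <- function(k, t, demog) {
  rate0 <- k * (k - 1)  # per unit of 4N generations
  w <- rexp(1)
  switch(demog$type,
    constant = w / rate0,
    growth = {
      g <- demog$rate
      if (g == 0) return(w / rate0)
      log(exp(g * t) + g * w / rate0) / g - t
    },
    bottleneck = {
      tb <- demog$time
      s <- demog$strength
      if (t >= tb) return(w * s / rate0)
      cap <- (tb - t) * rate0
      if (w <= cap) w / rate0 else (tb - t) + (w - cap) * s / rate0
    },
    abort("unknown demography type")
  )
}

# simulate the genealogy of n lineages; returns per-branch leaf sets and
# branch lengths. sweep_f > 0 forces that fraction of lineages through a
# common ancestor at sweep_time (partial star genealogy).
simulate_genealogy <- function(n, demog, sweep_f = 0, sweep_time = 0.01) {
  active <- as.list(seq_len(n))
  birth <- rep(0, n)
  branch_leaves <- vector("list", 2 * n)
  branch_len <- numeric(2 * n)
  nb <- 0L
  t <- 0
  if (sweep_f > 0) {
    m <- round(sweep_f * n)
    if (m >= 2) {
      swept <- sample.int(n, m)
      t <- sweep_time
      for (i in swept) {
        nb <- nb + 1L
        branch_leaves[[nb]] <- active[[i]]
        branch_len[nb] <- t - birth[i]
      }
      keep <- setdiff(seq_along(active), swept)
      active <- c(active[keep], list(sort(unlist(active[swept]))))
      birth <- c(birth[keep], t)
    }
  }
  while (length(active) > 1) {
    k <- length(active)
    t <- t + coal_wait(k, t, demog)
    pair <- sample.int(k, 2)
    for (i in pair) {
      nb <- nb + 1L
      branch_leaves[[nb]] <- active[[i]]
      branch_len[nb] <- t - birth[i]
    }
    merged <- sort(c(active[[pair[1]]], active[[pair[2]]]))
    active <- c(active[-pair], list(merged))
    birth <- c(birth[-pair], t)
  }
  list(n = n, branch_leaves = branch_leaves[seq_len(nb)],
       branch_len = branch_len[seq_len(nb)])
}

#' Simulate one locus under the coalescent
#'
#' Hudson coalescent without intralocus recombination: exponential
#' coalescence times (time-changed under growth/bottleneck), infinite-sites
#' mutations dropped as Poisson(`theta` x branch length) uniformly on
#' branches and mapped to unique positions within `locus_length_bp`.
#' Optionally a fraction `sweep_f` of lineages is forced through a recent
#' common ancestor at `sweep_time` before neutral coalescence of the rest,
#' emulating a partial selective sweep: diversity drops faster than S and
#' Tajima's D is driven negative. `sweep_f = 0` is exact neutrality.
#'
#' @param n Number of sampled haplotypes (>= 2).
#' @param theta Population mutation rate 4N*mu per locus (> 0).
#' @param demography A [demog_constant()]-family object.
#' @param locus_length_bp Locus length in base pairs (mutation positions).
#' @param sweep_f Fraction of lineages in the star component, in `[0, 1]`.
#' @param sweep_time Age of the forced ancestor, in 4N generations.
#' @param s_fixed If non-NULL, condition on exactly this many segregating
#'   sites instead of drawing Poisson.
#' @param seed Optional seed; the same seed yields an identical matrix.
#' @return An `n x S` binary matrix (rows = haplotypes) with attribute
#'   `positions` (ascending site positions in bp).
#' @export
simulate_locus <- function(n, theta, demography = demog_constant(),
                           locus_length_bp = 1000, sweep_f = 0,
                           sweep_time = 0.01, s_fixed = NULL, seed = NULL) {
  if (n < 2) abort("need at least 2 haplotypes")
  if (theta <= 0 && is.null(s_fixed)) abort("theta must be positive")
  if (sweep_f < 0 || sweep_f > 1) abort("sweep_f must lie in [0, 1]")
  with_seed(seed, {
    gen <- simulate_genealogy(n, demography, sweep_f, sweep_time)
    L <- sum(gen$branch_len)
    S <- if (!is.null(s_fixed)) as.integer(s_fixed) else rpois(1, theta * L)
    if (S > locus_length_bp) {
      abort("more mutations than available positions; increase locus_length_bp")
    }
    mat <- matrix(0L, nrow = n, ncol = S)
    if (S > 0 && L > 0) {
      br <- sample.int(length(gen$branch_len), S, replace = TRUE,
                       prob = gen$branch_len)
      for (j in seq_len(S)) {
        mat[gen$branch_leaves[[br[j]]], j] <- 1L
      }
      posn <- sort(sample.int(locus_length_bp, S))
      attr(mat, "positions") <- posn
    } else {
      attr(mat, "positions") <- integer()
    }
    mat
  })
}

#' Inject a focal allele-frequency difference between two cohorts
#'
#' Overwrites one site of a haplotype matrix so the ALT frequency becomes
#' `p + delta/2` in cohort 1 (the first `n1` haplotypes) and `p - delta/2`
#' in cohort 2, clipped to `[0, 1]` with `p` adjusted (and reported) when
#' clipping is needed. Realised counts are rounded; the realised frequency
#' difference is returned for the truth table.
#'
#' @param mat Haplotype matrix from [simulate_locus()].
#' @param n1 Number of haplotypes in cohort 1 (rows `1:n1`).
#' @param delta Target ALT frequency difference, in `[0, 1]`.
#' @param site Column to overwrite; `NULL` appends a new column.
#' @param p Centre frequency (default 0.5).
#' @param seed Optional seed for carrier assignment.
#' @return List: `mat`, `site`, `realized_delta`, `p1`, `p2`.
#' @export
inject_focal_differentiation <- function(mat, n1, delta, site = NULL, p = 0.5,
                                         seed = NULL) {
  if (delta < 0 || delta > 1) abort("delta must lie in [0, 1]")
  n <- nrow(mat)
  n2 <- n - n1
  if (delta == 0 && is.null(site)) {
    return(list(mat = mat, site = NA_integer_, realized_delta = 0,
                p1 = p, p2 = p))
  }
  p_adj <- min(max(p, delta / 2), 1 - delta / 2)
  if (p_adj != p) {
    inform(paste0("centre frequency adjusted from ", p, " to ", p_adj,
                  " to accommodate delta = ", delta))
  }
  p1 <- p_adj + delta / 2
  p2 <- p_adj - delta / 2
  with_seed(seed, {
    col <- integer(n)
    c1 <- round(p1 * n1)
    c2 <- round(p2 * n2)
    col[sample.int(n1, c1)] <- 1L
    col[n1 + sample.int(n2, c2)] <- 1L
    if (is.null(site)) {
      posn <- attr(mat, "positions")
      mat <- cbind(mat, col)
      attr(mat, "positions") <- posn  # caller assigns the new position
      site <- ncol(mat)
    } else {
      mat[, site] <- col
    }
    list(mat = mat, site = site, realized_delta = c1 / n1 - c2 / n2,
         p1 = p1, p2 = p2)
  })
}

#' Configuration for a synthetic targeted-capture dataset
#'
#' Defaults mirror a reduced-scale targeted-enrichment case/control design:
#' two cohorts of 40 diploids (80 samples, 160 haplotypes per gene), 100
#' genes laid out on chromosomes 2, 3 and X, one gene under a partial sweep
#' and one gene carrying a nonsynonymous focal SNP with a prescribed
#' allele-frequency difference between phenotype classes.
#'
#' @param n_diploid Diploids per cohort, length-2 integer
#'   (cohort 1 = resistant, cohort 2 = susceptible).
#' @param n_genes Number of genes.
#' @param theta Per-locus 4N*mu.
#' @param locus_length_bp Gene (= CDS) length, divisible by 3.
#' @param chroms Chromosome names over which genes are distributed.
#' @param demography Shared [demog_constant()]-family object.
#' @param sweep_gene,sweep_f Index of the swept gene and its star fraction.
#' @param focal_gene,focal_delta Index of the differentiated gene and the
#'   target ALT-frequency difference between cohorts at its focal SNP.
#' @param nonsyn_syn_ratio Per-site nonsynonymous:synonymous mutation-rate
#'   ratio used to label mutations (0.25 emulates purifying constraint).
#' @param qual_low_frac Fraction of sites given QUAL below 20 (exercises
#'   the quality filter).
#' @param low_cov_frac Fraction of genes given mean coverage below 100x
#'   (exercises the coverage filter).
#' @param seed Default seed for [simulate_dataset()].
#' @return A `coalescent_config` list.
#' @export
sim_config <- function(n_diploid = c(40L, 40L), n_genes = 100L, theta = 10,
                       locus_length_bp = 1500L, chroms = c("2", "3", "X"),
                       demography = demog_constant(),
                       sweep_gene = 1L, sweep_f = 0.9,
                       focal_gene = 2L, focal_delta = 0.5,
                       nonsyn_syn_ratio = 0.25,
                       qual_low_frac = 0.03, low_cov_frac = 0.05,
                       seed = 1L) {
  if (locus_length_bp %% 3L != 0L) abort("locus_length_bp must be divisible by 3")
  if (sweep_f < 0 || sweep_f > 1 || focal_delta < 0 || focal_delta > 1) {
    abort("sweep_f and focal_delta must lie in [0, 1]")
  }
  if (theta <= 0) abort("theta must be positive")
  structure(
    list(n_diploid = as.integer(n_diploid), n_genes = as.integer(n_genes),
         theta = theta, locus_length_bp = as.integer(locus_length_bp),
         chroms = chroms, demography = demography,
         sweep_gene = sweep_gene, sweep_f = sweep_f,
         focal_gene = focal_gene, focal_delta = focal_delta,
         nonsyn_syn_ratio = nonsyn_syn_ratio,
         qual_low_frac = qual_low_frac, low_cov_frac = low_cov_frac,
         seed = as.integer(seed)),
    class = "coalescent_config"
  )
}

# fourfold-degenerate codon prefixes: any third-position change is
# synonymous; used to build synthetic CDS where mutation effects are
# controlled by construction
fourfold_prefixes <- c("GC", "GG", "CC", "AC", "GT")

random_cds <- function(n_codons) {
  pref <- sample(fourfold_prefixes, n_codons, replace = TRUE)
  third <- sample(c("A", "C", "G", "T"), n_codons, replace = TRUE)
  paste0(pref, third, collapse = "")
}

# choose an ALT base at cds position i realising the requested effect class
pick_alt <- function(seq, i, want_syn) {
  refb <- substr(seq, i, i)
  cod_i <- (i - 1L) %/% 3L
  cod <- substr(seq, 3L * cod_i + 1L, 3L * cod_i + 3L)
  in_cod <- (i - 1L) %% 3L + 1L
  cands <- setdiff(c("A", "C", "G", "T"), refb)
  ok <- vapply(cands, function(b) {
    mut <- cod
    substr(mut, in_cod, in_cod) <- b
    same <- unname(GENCODE[mut]) == unname(GENCODE[cod])
    if (want_syn) same else !same
  }, logical(1))
  if (!any(ok)) return(NA_character_)
  sample(cands[ok], 1)
}

#' Emit a complete synthetic targeted-capture dataset
#'
#' Simulates every gene as one coalescent locus over the pooled cohorts,
#' maps mutations onto codon positions of a synthetic CDS (so
#' synonymous/nonsynonymous labels hold by construction), applies the
#' configured sweep and focal-SNP differentiation, and writes the standard
#' file set: VCF v4.2, GFF3 gene models, CDS FASTA, sample sheet TSV,
#' per-gene coverage TSV and a truth table.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Seed; defaults to `config$seed`.
#' @return A `sim_dataset` object: `$paths` (named file paths), `$truth`
#'   (per-gene truth tibble), `$genes`, `$config`, `$dir`.
#' @export
simulate_dataset <- function(config, dir = tempfile("simdata"), seed = NULL) {
  seed <- seed %||% config$seed
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n1 <- 2L * config$n_diploid[1]
  n2 <- 2L * config$n_diploid[2]
  n_hap <- n1 + n2
  n_samp <- sum(config$n_diploid)
  L <- config$locus_length_bp

  samples <- sprintf("S%03d", seq_len(n_samp))
  sheet <- tibble(
    sample_id = samples,
    population = rep(c("simR", "simS"), config$n_diploid),
    phenotype = rep(c("resistant", "susceptible"), config$n_diploid)
  )

  chrom_of <- rep(config$chroms, length.out = config$n_genes)
  chrom_of <- sort(factor(chrom_of, levels = config$chroms))
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  idx_on_chrom <- stats::ave(seq_along(chrom_of), chrom_of, FUN = seq_along)
  gene_start <- 1000000L + (idx_on_chrom - 1L) * (L + 10000L)
  genes <- tibble(
    gene_id = gene_ids, chrom = as.character(chrom_of),
    start = gene_start, end = gene_start + L - 1L, strand = "+",
    cds_id = paste0("cds_", gene_ids)
  )

  syn_prob <- 1 / (1 + 2 * config$nonsyn_syn_ratio)

  with_seed(seed, {
    cds_seqs <- vapply(seq_len(config$n_genes), function(i) random_cds(L %/% 3L),
                       character(1))
    all_sites <- vector("list", config$n_genes)
    truth <- vector("list", config$n_genes)

    for (g in seq_len(config$n_genes)) {
      is_sweep <- g == config$sweep_gene && config$sweep_f > 0
      is_focal <- g == config$focal_gene && config$focal_delta > 0
      mat <- simulate_locus(
        n_hap, config$theta, config$demography, locus_length_bp = L,
        sweep_f = if (is_sweep) config$sweep_f else 0
      )
      realized_delta <- 0
      focal_col <- NA_integer_
      if (is_focal) {
        inj <- inject_focal_differentiation(mat, n1, config$focal_delta)
        mat <- inj$mat
        focal_col <- inj$site
        realized_delta <- inj$realized_delta
      }
      S <- ncol(mat)
      seqg <- cds_seqs[g]
      if (S > 0) {
        want_syn <- runif(S) < syn_prob
        if (!is.na(focal_col)) want_syn[focal_col] <- FALSE  # focal SNP nonsynonymous
        syn_pool <- seq(3L, L, by = 3L)
        nonsyn_pool <- setdiff(seq_len(L), syn_pool)
        if (sum(want_syn) > length(syn_pool) || sum(!want_syn) > length(nonsyn_pool)) {
          abort("locus too short for the requested number of mutations")
        }
        cdspos <- integer(S)
        cdspos[want_syn] <- sample(syn_pool, sum(want_syn))
        cdspos[!want_syn] <- sample(nonsyn_pool, sum(!want_syn))
        alt <- vapply(seq_len(S), function(j) pick_alt(seqg, cdspos[j], want_syn[j]),
                      character(1))
        refb <- substring(seqg, cdspos, cdspos)
        o <- order(cdspos)
        qual <- round(runif(S, 30, 3000), 1)
        low <- runif(S) < config$qual_low_frac
        qual[low] <- round(runif(sum(low), 5, 19.9), 1)
        gt_list <- lapply(o, function(j) as.integer(mat[, j]))
        all_sites[[g]] <- tibble(
          chrom = genes$chrom[g], pos = genes$start[g] + cdspos[o] - 1L,
          ref = refb[o], alt = alt[o], qual = qual[o],
          effect = "unannotated", gt = gt_list
        )
      } else {
        all_sites[g] <- list(NULL)
      }
      truth[[g]] <- tibble(
        gene_id = genes$gene_id[g],
        class = if (is_sweep) "sweep" else if (is_focal) "differentiated" else "neutral",
        true_f = if (is_sweep) config$sweep_f else 0,
        true_delta = if (is_focal) config$focal_delta else 0,
        realized_delta = realized_delta,
        n_sites = S
      )
    }

    sites <- bind_rows(all_sites) %>% arrange(chrom, pos)
    attr(sites, "samples") <- samples
    truth <- bind_rows(truth)

    depth <- round(runif(config$n_genes, 150, 500), 1)
    low <- runif(config$n_genes) < config$low_cov_frac
    depth[low] <- round(runif(sum(low), 40, 99), 1)
    coverage <- tibble(gene_id = genes$gene_id, mean_depth = depth)

    paths <- list(
      vcf = file.path(dir, "variants.vcf"),
      gff3 = file.path(dir, "genes.gff3"),
      cds_fasta = file.path(dir, "cds.fasta"),
      samples = file.path(dir, "samples.tsv"),
      coverage = file.path(dir, "coverage.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_vcf(sites, sheet, paths$vcf,
              provenance = c(seed = seed, generator = "coalescent-synthetic"))
    gff <- c("##gff-version 3",
             paste(genes$chrom, "popgenescan", "gene", genes$start, genes$end,
                   ".", genes$strand, ".", paste0("ID=", genes$gene_id),
                   sep = "\t"),
             paste(genes$chrom, "popgenescan", "CDS", genes$start, genes$end,
                   ".", genes$strand, "0",
                   paste0("ID=", genes$cds_id, ";Parent=", genes$gene_id),
                   sep = "\t"))
    writeLines(gff, paths$gff3)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(cds_seqs, genes$cds_id)),
      paths$cds_fasta
    )
    readr::write_tsv(sheet, paths$samples)
    readr::write_tsv(coverage, paths$coverage)
    readr::write_tsv(truth, paths$truth)

    structure(
      list(paths = paths, truth = truth, genes = genes, config = config,
           dir = dir, cds_seqs = setNames(cds_seqs, genes$gene_id)),
      class = "sim_dataset"
    )
  })
}

#' CDS models of a simulated dataset
#'
#' Rebuilds the [cds_model()] list (keyed by gene id) for a dataset emitted
#' by [simulate_dataset()], for use with [annotate_effects()].
#'
#' @param dataset A `sim_dataset`.
#' @return Named list of `cds_model` objects.
#' @export
sim_cds_models <- function(dataset) {
  g <- dataset$genes
  out <- lapply(seq_len(nrow(g)), function(i) {
    cds_model(g$cds_id[i], g$gene_id[i],
              tibble(start = g$start[i], end = g$end[i]),
              g$strand[i], dataset$cds_seqs[[g$gene_id[i]]])
  })
  setNames(out, g$gene_id)
}
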