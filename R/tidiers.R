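# broom-style tidiers and ggplot2 autoplot methods for the package's
# result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_segment
#'   geom_histogram geom_vline facet_wrap labs theme_minimal scale_size_area
#' @export
ggplot2::autoplot

#' Tidiers for gene scans
#'
#' `tidy()` returns the per-gene table as a plain tibble; `glance()`
#' returns a one-row summary (gene counts, flag counts, median statistics).
#'
#' @param x A `gene_scan` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gene_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gene_scan")
  as_tibble(out)
}

#' @rdname tidy.gene_scan
#' @export
glance.gene_scan <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_polymorphic = sum(x$S > 0),
    median_fst = stats::median(x$fst_gene, na.rm = TRUE),
    median_tajima_d = stats::median(x$tajima_d, na.rm = TRUE),
    n_fst_significant = sum(x$fst_significant %in% TRUE),
    n_tajima_low = sum(x$tajima_low %in% TRUE),
    n_tajima_high = sum(x$tajima_high %in% TRUE)
  )
}

#' @rdname tidy.gene_scan
#' @export
tidy.scan_result <- function(x, ...) tidy(x$gene_report)

#' @rdname tidy.gene_scan
#' @export
glance.scan_result <- function(x, ...) glance(x$gene_report)

#' Gene-wise FST scan plot
#'
#' One point per gene along each chromosome with the per-chromosome
#' quantile threshold as a dashed line; significant genes are highlighted.
#'
#' @param object A `gene_scan` tibble (with flags).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_scan <- function(object, ...) {
  df <- tidy(object) %>%
    group_by(chrom) %>%
    mutate(x = seq_len(dplyr::n())) %>%
    ungroup()
  p <- ggplot(df, aes(x = x, y = fst_gene)) +
    geom_point(aes(colour = fst_significant %in% TRUE), size = 1.5) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "gene index on chromosome", y = "gene-wise FST",
         colour = "significant") +
    theme_minimal()
  if ("fst_quantile" %in% names(df) && any(!is.na(df$fst_quantile))) {
    p <- p + geom_hline(aes(yintercept = fst_quantile), linetype = "dashed",
                        na.rm = TRUE)
  }
  p
}

#' @rdname autoplot.gene_scan
#' @export
autoplot.scan_result <- function(object, ...) autoplot(object$gene_report)

#' Tidiers for Tajima's D calibrations
#'
#' `tidy()` returns the simulated draws; `glance()` the cutoffs and
#' configuration summary.
#'
#' @param x A `tajima_calibration`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tajima_calibration <- function(x, ...) {
  tibble(tajima_d = x$draws)
}

#' @rdname tidy.tajima_calibration
#' @export
glance.tajima_calibration <- function(x, ...) {
  tibble(n_loci = length(x$draws), lower = x$lower, upper = x$upper,
         n = x$config$n, theta = x$config$theta,
         n_undefined = x$n_undefined, config_hash = x$config_hash)
}

#' Simulated Tajima's D null density with cutoffs
#'
#' @param object A `tajima_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tajima_calibration <- function(object, ...) {
  ggplot(tidy(object), aes(x = tajima_d)) +
    geom_histogram(bins = 60, fill = "grey70") +
    geom_vline(xintercept = c(object$lower, object$upper),
               linetype = "dashed", colour = "red") +
    labs(x = "simulated Tajima's D", y = "loci") +
    theme_minimal()
}

#' Tidiers for haplotype networks
#'
#' `tidy()` returns the node table (haplotype, frequency, per-population
#' counts); `glance()` a one-row network summary.
#'
#' @param x A `haplo_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.haplo_network <- function(x, ...) x$nodes

#' @rdname tidy.haplo_network
#' @export
glance.haplo_network <- function(x, ...) {
  tibble(n_observed = sum(x$nodes$observed),
         n_intermediate = sum(!x$nodes$observed),
         total_frequency = sum(x$nodes$freq),
         n_edges = nrow(x$edges), n_components = x$components,
         limit = x$limit)
}

#' Haplotype network plot
#'
#' Fruchterman-Reingold layout with node area proportional to haplotype
#' frequency; inferred intermediates are drawn as small open points.
#'
#' @param object A `haplo_network`.
#' @param seed Layout seed (layout is stochastic).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplo_network <- function(object, seed = 1L, ...) {
  lay <- with_seed(seed, igraph::layout_with_fr(object$graph))
  nodes <- object$nodes %>%
    mutate(x = lay[, 1], y = lay[, 2])
  eidx <- cbind(match(object$edges$from, nodes$node),
                match(object$edges$to, nodes$node))
  edges <- tibble(x = nodes$x[eidx[, 1]], y = nodes$y[eidx[, 1]],
                  xend = nodes$x[eidx[, 2]], yend = nodes$y[eidx[, 2]])
  ggplot() +
    geom_segment(data = edges, aes(x = x, y = y, xend = xend, yend = yend),
                 colour = "grey50") +
    geom_point(data = filter(nodes, observed),
               aes(x = x, y = y, size = freq), colour = "steelblue") +
    geom_point(data = filter(nodes, !observed),
               aes(x = x, y = y), shape = 21, size = 1.5, colour = "grey40") +
    scale_size_area(max_size = 12) +
    labs(size = "haplotypes") +
    ggplot2::theme_void()
}

#' Tidiers for simulated datasets
#'
#' `tidy()` returns the per-gene truth table; `glance()` the design
#' summary.
#'
#' @param x A `sim_dataset`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sim_dataset <- function(x, ...) x$truth

#' @rdname tidy.sim_dataset
#' @export
glance.sim_dataset <- function(x, ...) {
  tibble(n_genes = nrow(x$truth),
         n_samples = sum(x$config$n_diploid),
         n_haplotypes = 2L * sum(x$config$n_diploid),
         theta = x$config$theta,
         n_sweep = sum(x$truth$class == "sweep"),
         n_differentiated = sum(x$truth$class == "differentiated"))
}
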