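# Statistical-parsimony haplotype networks: pairwise Hamming distances, a
# 95%-parsimony connection limit, and a deterministic minimum-spanning
# network under that limit, with inferred intermediate nodes on multi-step
# edges. Node metadata records per-population haplotype counts (the
# pie-chart data of the usual network figures).

#' Pairwise Hamming distances between haplotypes
#'
#' @param haps A `haplotype_set` tibble (see [extract_haplotypes()]) or a
#'   character vector of equal-length allele strings.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
pairwise_hamming <- function(haps) {
  h <- if (is.data.frame(haps)) haps$haplotype else haps
  if (length(unique(nchar(h))) > 1) abort("haplotypes must have equal length")
  n <- length(h)
  if (n == 0) abort("empty haplotype set")
  L <- nchar(h[1])
  if (L == 0) {
    return(matrix(0L, n, n, dimnames = list(h, h)))
  }
  m <- do.call(rbind, strsplit(h, ""))
  d <- matrix(0L, n, n, dimnames = list(h, h))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` such that the probability that
#' two haplotypes separated by `j` observed differences are connected
#' parsimoniously (every difference a single hit) is at least `alpha`.
#' The per-site mutation intensity is estimated from the observed
#' divergence `j / (L + 1)` via a Poisson single-hit model:
#' `mu = -log(1 - j/(L+1))`, the single-hit probability of one observed
#' difference is `r = mu * exp(-mu) / (1 - exp(-mu))`, and the parsimony
#' probability is `P_j = r^j`. As `alpha` approaches 0 every pair becomes
#' connectable (`limit = seq_length`); the limit is nondecreasing in `L`
#' at fixed `alpha`.
#'
#' @param seq_length Number of compared sites (>= 1).
#' @param alpha Parsimony confidence level in (0, 1); default 0.95.
#' @return Integer connection limit (>= 1).
#' @export
parsimony_limit <- function(seq_length, alpha = 0.95) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (seq_length < 1) abort("seq_length must be at least 1")
  limit <- 0L
  for (j in seq_len(seq_length)) {
    mu <- -log(1 - j / (seq_length + 1))
    r <- mu * exp(-mu) / (1 - exp(-mu))
    if (r^j >= alpha) limit <- j else break
  }
  max(limit, 1L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Deduplicates haplotypes into frequency-weighted nodes, then connects
#' node pairs in order of increasing Hamming distance (ties broken by
#' higher combined frequency, then lexicographic haplotype order), adding
#' an edge only between currently disconnected components. A d-step
#' connection (d <= limit) inserts d - 1 inferred intermediate nodes of
#' frequency 0; pairs beyond the limit stay in separate components. Node
#' metadata records per-population haplotype counts.
#'
#' @param haps A `haplotype_set` tibble, or a character vector (then
#'   `populations` may label each haplotype).
#' @param limit Connection limit in mutational steps; default computed by
#'   [parsimony_limit()] at `alpha`.
#' @param alpha Parsimony level used when `limit` is `NULL`.
#' @param populations Optional population label per haplotype (character
#'   vector input only).
#' @return A `haplo_network`: list with `nodes` (tibble: node, haplotype,
#'   freq, observed, one `count_<population>` column per population),
#'   `edges` (tibble: from, to), `graph` (igraph), `limit`, `components`.
#' @export
build_network <- function(haps, limit = NULL, alpha = 0.95, populations = NULL) {
  if (is.data.frame(haps)) {
    h <- haps$haplotype
    pops <- haps$population
  } else {
    h <- haps
    pops <- populations %||% rep("all", length(h))
  }
  if (length(h) == 0) abort("empty haplotype set")
  if (length(unique(nchar(h))) > 1) abort("haplotypes must have equal length")
  L <- nchar(h[1])
  limit <- limit %||% if (L >= 1) parsimony_limit(L, alpha) else 1L

  uh <- sort(unique(h))
  nodes <- tibble(
    node = paste0("H", seq_along(uh)),
    haplotype = uh,
    freq = as.integer(table(factor(h, levels = uh))),
    observed = TRUE
  )
  for (p in sort(unique(pops))) {
    nodes[[paste0("count_", p)]] <-
      as.integer(table(factor(h[pops == p], levels = uh)))
  }

  d <- pairwise_hamming(uh)
  k <- nrow(nodes)
  pairs <- NULL
  if (k > 1) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    pairs <- tibble(i = idx[, 1], j = idx[, 2], d = d[idx]) %>%
      filter(d <= limit) %>%
      mutate(fsum = nodes$freq[i] + nodes$freq[j],
             lex1 = pmin(uh[i], uh[j]), lex2 = pmax(uh[i], uh[j])) %>%
      arrange(d, desc(fsum), lex1, lex2)
  }

  # union-find over observed nodes
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  edges <- list()
  extra_nodes <- list()
  n_int <- 0L
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]; dd <- pairs$d[r]
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      parent[ri] <- rj
      if (dd == 1) {
        edges[[length(edges) + 1]] <- c(nodes$node[i], nodes$node[j])
      } else {
        chain <- nodes$node[i]
        for (s in seq_len(dd - 1)) {
          n_int <- n_int + 1L
          im <- paste0("I", n_int)
          extra_nodes[[n_int]] <- im
          edges[[length(edges) + 1]] <- c(chain, im)
          chain <- im
        }
        edges[[length(edges) + 1]] <- c(chain, nodes$node[j])
      }
    }
  }
  if (n_int > 0) {
    inter <- tibble(node = unlist(extra_nodes), haplotype = NA_character_,
                    freq = 0L, observed = FALSE)
    for (cn in setdiff(names(nodes), names(inter))) inter[[cn]] <- 0L
    nodes <- bind_rows(nodes, inter)
  }
  edge_tbl <- if (length(edges)) {
    tibble(from = vapply(edges, `[`, character(1), 1),
           to = vapply(edges, `[`, character(1), 2))
  } else {
    tibble(from = character(), to = character())
  }
  g <- igraph::graph_from_data_frame(edge_tbl, directed = FALSE,
                                     vertices = nodes)
  structure(
    list(nodes = nodes, edges = edge_tbl, graph = g, limit = limit,
         components = igraph::components(g)$no),
    class = "haplo_network"
  )
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Statistical-parsimony haplotype network\n")
  cat("  observed haplotypes:", sum(x$nodes$observed),
      " (total frequency ", sum(x$nodes$freq), ")\n", sep = "")
  cat("  inferred intermediates:", sum(!x$nodes$observed), "\n")
  cat("  edges:", nrow(x$edges), "  components:", x$components,
      "  connection limit:", x$limit, "steps\n")
  invisible(x)
}

#' Export a haplotype network
#'
#' `write_graphml()` writes the igraph representation as GraphML;
#' `write_nexus_network()` writes a Nexus file with a `Network` block
#' (vertices with frequencies, single-step edges); `network_node_table()`
#' writes the node table (haplotype, frequency, per-population counts) as
#' TSV.
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_nexus_network <- function(net, path) {
  n <- nrow(net$nodes)
  vlines <- sprintf("  %s [freq=%d]%s;", net$nodes$node, net$nodes$freq,
                    ifelse(net$nodes$observed,
                           paste0(" [hap=", net$nodes$haplotype, "]"), ""))
  elines <- sprintf("  %s -- %s;", net$edges$from, net$edges$to)
  writeLines(c(
    "#NEXUS",
    "BEGIN NETWORK;",
    sprintf("DIMENSIONS NVERTICES=%d NEDGES=%d;", n, nrow(net$edges)),
    "VERTICES", vlines,
    "EDGES", elines,
    "END;"
  ), path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
network_node_table <- function(net, path) {
  readr::write_tsv(net$nodes, path)
  invisible(path)
}
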