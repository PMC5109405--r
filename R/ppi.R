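#' Protein-protein interaction graph handling
#'
#' The PPI container is an undirected simple igraph graph: duplicate edges
#' (including reversed duplicates) and self-loops are removed on
#' construction, so link statistics are invariant to edge orientation in
#' the input file.
#'
#' @param edges data.frame or 2-column matrix of node-name pairs, or an
#'   igraph object (simplified and made undirected).
#' @param vertices optional extra node names to include even if isolated
#'   (genes known to the network but without interactions).
#' @return an undirected simple `igraph` graph.
#' @export
ppi_graph <- function(edges, vertices = NULL) {
  if (inherits(edges, "igraph")) {
    g <- igraph::as_undirected(edges, mode = "collapse")
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("need two columns of node names", call. = FALSE)
    nodes <- unique(c(as.character(edges[[1L]]), as.character(edges[[2L]]),
                      as.character(vertices)))
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                       vertices = nodes)
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' @rdname ppi_graph
#' @param path two-column TSV edge list (lines starting with `#` ignored).
#' @export
read_ppi_edgelist <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  ppi_graph(df)
}

#' @rdname ppi_graph
#' @param graph an igraph graph.
#' @export
write_ppi_edgelist <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(el[, c("from", "to")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map a gene set onto the network
#'
#' @param genes character vector.
#' @param graph igraph graph.
#' @return the genes present among the graph's nodes.
#' @export
map_to_network <- function(genes, graph) {
  intersect(unique(as.character(genes)), igraph::V(graph)$name)
}

#' Direct interaction links from a query set to a target set
#'
#' For every mapped query gene, counts its direct (distance-1) neighbors in
#' the target set; genes belonging to both sets are kept in the query and
#' counted like any other (a gene is never its own neighbor) unless
#' `exclude_overlap = TRUE`. The per-gene average is over all mapped query
#' genes, including those with zero links.
#'
#' @param query,target character gene sets.
#' @param graph igraph graph (see [ppi_graph()]).
#' @param exclude_overlap drop query genes that are also targets.
#' @return An object of class `ppi_link_stats`: `mapped_query`, `counts`
#'   (named per-gene link counts), `total_links`, `average`, `undefined`
#'   (`TRUE` when no query gene maps).
#' @examples
#' g <- ppi_graph(data.frame(from = c("a", "a", "b"), to = c("c", "d", "e")))
#' direct_link_stats(c("a", "b"), c("c", "d"), g)$average  # (2 + 0) / 2
#' @export
direct_link_stats <- function(query, target, graph, exclude_overlap = FALSE) {
  mapped <- map_to_network(query, graph)
  if (exclude_overlap) mapped <- setdiff(mapped, target)
  target <- unique(as.character(target))
  if (!length(mapped)) {
    return(structure(list(mapped_query = character(), counts = numeric(),
                          total_links = 0L, average = NA_real_,
                          undefined = TRUE), class = "ppi_link_stats"))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  counts <- stats::setNames(numeric(length(mapped)), mapped)
  hit1 <- el$from %in% mapped & el$to %in% target
  hit2 <- el$to %in% mapped & el$from %in% target
  t1 <- table(el$from[hit1])
  t2 <- table(el$to[hit2])
  counts[names(t1)] <- counts[names(t1)] + as.numeric(t1)
  counts[names(t2)] <- counts[names(t2)] + as.numeric(t2)
  structure(list(mapped_query = mapped, counts = counts,
                 total_links = as.integer(sum(counts)),
                 average = sum(counts) / length(mapped),
                 undefined = FALSE), class = "ppi_link_stats")
}

#' @export
print.ppi_link_stats <- function(x, ...) {
  if (x$undefined) {
    cat("ppi_link_stats: no query genes mapped (average undefined)\n")
  } else {
    cat(sprintf("ppi_link_stats: %d mapped query genes, %d direct links to target (average %.2f)\n",
                length(x$mapped_query), x$total_links, x$average))
  }
  invisible(x)
}

#' Export the query-target induced link subgraph
#'
#' Writes the edges with one end in the (mapped) query set and the other in
#' the target set as a plain two-column edge list, for external
#' visualisation.
#'
#' @inheritParams direct_link_stats
#' @param path output TSV path.
#' @export
export_link_subgraph <- function(query, target, graph, path) {
  mapped <- map_to_network(query, graph)
  target <- unique(as.character(target))
  el <- igraph::as_data_frame(graph, what = "edges")
  keep <- (el$from %in% mapped & el$to %in% target) |
    (el$to %in% mapped & el$from %in% target)
  utils::write.table(el[keep, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Two-sided Wilcoxon rank-sum comparison of two link-count samples
#'
#' Exact for small samples via a tie-aware count distribution of the
#' rank-sum statistic (dynamic programming over all
#' `choose(n + m, n)` group assignments; the two-sided p is the total
#' probability of rank sums at least as far from their null mean as the
#' observed one). For larger samples a tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param counts_a,counts_b non-empty numeric vectors (per-gene link
#'   counts).
#' @param exact force (or forbid) the exact route; default: exact when
#'   `length(a) * length(b) <= 400`.
#' @return two-sided p-value.
#' @examples
#' compare_link_distributions(c(3, 3, 3), c(0, 0, 0))  # 2 / choose(6, 3)
#' @export
compare_link_distributions <- function(counts_a, counts_b, exact = NULL) {
  if (!length(counts_a) || !length(counts_b)) {
    stop("both count vectors must be non-empty", call. = FALSE)
  }
  exact <- exact %||% (length(counts_a) * length(counts_b) <= 400)
  if (exact) .ranksum_exact(counts_a, counts_b)
  else .ranksum_normal(counts_a, counts_b)
}

.ranksum_exact <- function(x, y) {
  if (length(y) < length(x)) { tmp <- x; x <- y; y <- tmp }  # DP over smaller group
  n <- length(x)
  N <- n + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))  # doubled average ranks: integers
  w_obs <- sum(r2[seq_len(n)])
  e_w <- n * (N + 1)                           # null mean of the doubled sum
  maxw <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  # f[j + 1, w + 1] = number of j-subsets of the ranks with doubled sum w
  f <- matrix(0, n + 1L, maxw + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    jmax <- min(n, N)  # standard 0/1 counting: update j downwards
    for (j in seq(jmax, 1L)) {
      src <- seq_len(maxw + 1L - r)
      f[j + 1L, src + r] <- f[j + 1L, src + r] + f[j, src]
    }
  }
  probs <- f[n + 1L, ] / choose(N, n)
  w <- seq_len(maxw + 1L) - 1L
  sum(probs[abs(w - e_w) >= abs(w_obs - e_w) - 1e-9])
}

.ranksum_normal <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}
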