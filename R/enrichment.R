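#' Read and write gene-set collections in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors, with set
#'   descriptions in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions per-set description strings (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation test
#'
#' For each set of the collection, the probability of observing at least
#' the seen overlap between the query and the set under random draws from
#' the universe — the hypergeometric upper tail, identical to a one-tailed
#' Fisher exact test — with BH adjustment across sets. The universe
#' defaults to the genes covered by the collection; pass the measured gene
#' universe to get the standard conservative restriction (measured genes
#' intersected with collection coverage). Query and sets are restricted to
#' the universe before testing.
#'
#' @param query character vector of genes of interest.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe background gene universe; default: union of the
#'   collection's sets.
#' @param fdr_threshold reporting threshold for the `significant` flag
#'   (a loose 0.2 by default, the usual choice when the query is small).
#' @return data.frame of class `enrichment_result`, one row per set, sorted
#'   by p: `set_name`, `overlap` (k), `query_size` (n), `set_size` (K),
#'   `universe_size` (N), `p`, `fdr`, `significant`.
#' @examples
#' coll <- list(s1 = c("a", "b", "c"), s2 = c("d", "e"))
#' hypergeometric_enrichment(c("a", "b"), coll, universe = letters[1:10])
#' @export
hypergeometric_enrichment <- function(query, collection, universe = NULL,
                                      fdr_threshold = 0.2) {
  if (is.null(universe)) universe <- unique(unlist(collection))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  sets <- lapply(collection, intersect, y = universe)
  query <- intersect(unique(as.character(query)), universe)
  if (!length(query)) {
    warning("query is empty after restriction to the universe")
  }
  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  # P(overlap >= k): hypergeometric upper tail
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_name = names(collection), overlap = k,
                    query_size = n, set_size = unname(K), universe_size = N,
                    p = unname(p), stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_name), ]
  out$significant <- out$fdr <= fdr_threshold
  rownames(out) <- NULL
  structure(out, fdr_threshold = fdr_threshold,
            class = c("enrichment_result", "data.frame"))
}
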