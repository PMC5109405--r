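#' Upper-tail cumulative binomial probability, safe in log space
#'
#' Computes `P(X >= s)` for `X ~ Binomial(k, p_e)`. This is the null model
#' used throughout the package for concordance scores: of `k` shared items
#' (gene pairs or directed DE genes), `s` agree in direction, and under the
#' null each agrees independently with probability `p_e` (0.5 unless stated
#' otherwise). For the pair counts met in cross-platform ordering
#' comparisons (`k` in the tens of millions) the probability underflows
#' double precision, so the log10 tail is computed directly in log space;
#' `log10 = TRUE` returns it. A Hoeffding certificate for bound claims is
#' available via [hoeffding_log10_bound()].
#'
#' @param s observed number of successes, `0 <= s <= k` (vectorised).
#' @param k number of trials.
#' @param p_e null success probability in (0, 1).
#' @param log10 return log10 of the tail probability instead.
#' @return numeric vector of upper-tail probabilities (or their log10).
#' @examples
#' binomial_upper_tail(8, 10, 0.5)          # 0.0546875
#' binomial_upper_tail(35e6, 37811288, 0.5, log10 = TRUE)
#' @export
binomial_upper_tail <- function(s, k, p_e, log10 = FALSE) {
  if (any(!is.finite(s)) || any(!is.finite(k)) ||
      any(s < 0) || any(k < 0) || any(s > k) ||
      any(s != floor(s)) || any(k != floor(k))) {
    stop("require integer counts with 0 <= s <= k", call. = FALSE)
  }
  if (any(p_e <= 0) || any(p_e >= 1)) {
    stop("`p_e` must lie strictly inside (0, 1)", call. = FALSE)
  }
  lp <- stats::pbinom(s - 1, size = k, prob = p_e,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' @rdname binomial_upper_tail
#' @details `hoeffding_log10_bound` returns log10 of the Hoeffding bound
#'   `exp(-2 k (s/k - p_e)^2)` for `s > k * p_e` (0 otherwise), an upper
#'   bound on the exact tail that cannot underflow; use it to certify
#'   "p <= bound" claims when the exact tail is far below double range.
#' @export
hoeffding_log10_bound <- function(s, k, p_e) {
  eps <- pmax(s / k - p_e, 0)
  -2 * k * eps^2 / log(10)
}

#' Mine gene pairs with stable relative orderings across normal samples
#'
#' A gene pair `(hi, lo)` is stable when `expression(hi) > expression(lo)`
#' holds strictly in at least `support_threshold` of the pooled normal
#' samples — at the default threshold of 1, in every sample. Ties support
#' neither orientation, so a pair with any tied sample fails the 100%
#' criterion. Matrices from different platforms are first restricted to
#' their common gene core; because only within-sample orderings are
#' compared, per-platform monotone distortions are irrelevant and pooling
#' across platforms is legitimate.
#'
#' Pair mining is O(genes^2 x samples) in time and O(genes^2) in memory
#' (a genes-by-genes support-count matrix); `max_genes` guards against
#' accidental genome-scale calls, which need ~800 MB at the 10,000 default.
#'
#' @param matrices a matrix/[expr_matrix()] or list of them (normal samples
#'   only), genes in rows.
#' @param support_threshold required support fraction in (0, 1].
#' @param max_genes refuse larger gene cores (memory contract).
#' @return An object of class `stable_reo_set`: list with `genes`
#'   (the common gene core), `pairs` (integer matrix, columns `hi`, `lo`,
#'   indices into `genes`), `support_threshold`, `n_samples`.
#' @examples
#' m <- matrix(c(5, 3, 1), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
#' find_stable_pairs(m)$pairs   # all 3 orderings of a single sample
#' @export
find_stable_pairs <- function(matrices, support_threshold = 1,
                              max_genes = 10000L) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!length(matrices)) stop("no matrices supplied", call. = FALSE)
  if (!is.numeric(support_threshold) || support_threshold <= 0 ||
      support_threshold > 1) {
    stop("`support_threshold` must lie in (0, 1]", call. = FALSE)
  }
  mats <- lapply(matrices, .as_values)
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!length(genes)) stop("empty gene intersection across matrices", call. = FALSE)
  if (length(genes) > max_genes) {
    stop(sprintf("gene core has %d genes, exceeding max_genes = %d",
                 length(genes), max_genes), call. = FALSE)
  }
  genes <- sort(genes)
  pooled <- do.call(cbind, lapply(mats, function(m) m[genes, , drop = FALSE]))
  n_samples <- ncol(pooled)
  if (n_samples < 1L) stop("at least one sample is required", call. = FALSE)
  g <- length(genes)
  support <- matrix(0L, g, g)
  for (j in seq_len(n_samples)) {
    v <- pooled[, j]
    support <- support + (outer(v, v, ">") * 1L)  # strict; ties add nothing
  }
  need <- support_threshold * n_samples - 1e-9
  hit <- which(support >= need, arr.ind = TRUE, useNames = FALSE)
  hit <- hit[hit[, 1L] != hit[, 2L], , drop = FALSE]
  # at thresholds <= 0.5 both orientations could pass; keep the majority one
  if (nrow(hit)) {
    keep <- support[hit] > support[hit[, c(2L, 1L), drop = FALSE]] |
      support[hit[, c(2L, 1L), drop = FALSE]] < need
    hit <- hit[keep, , drop = FALSE]
  }
  pairs <- hit
  colnames(pairs) <- c("hi", "lo")
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  structure(list(genes = genes, pairs = pairs,
                 support_threshold = support_threshold,
                 n_samples = n_samples),
            class = "stable_reo_set")
}

#' @export
print.stable_reo_set <- function(x, ...) {
  cat(sprintf(
    "stable_reo_set: %d ordered pairs over %d genes (support >= %g in %d samples)\n",
    nrow(x$pairs), length(x$genes), x$support_threshold, x$n_samples))
  invisible(x)
}

#' @rdname find_stable_pairs
#' @param x a `stable_reo_set`.
#' @export
stable_pairs_df <- function(x) {
  data.frame(hi_gene = x$genes[x$pairs[, "hi"]],
             lo_gene = x$genes[x$pairs[, "lo"]],
             stringsAsFactors = FALSE)
}

#' @rdname find_stable_pairs
#' @param path output path; written gzip-compressed when it ends in `.gz`.
#' @export
write_stable_pairs <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(stable_pairs_df(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Concordance of two stable-ordering pair sets
#'
#' Of the unordered gene pairs present (in either orientation) in both
#' sets, counts how many carry the same orientation, and evaluates the
#' score `s/k` against the cumulative binomial null with same-direction
#' probability `p_e = 0.5`. Used to check that orderings mined from
#' different platforms describe the same normal-tissue landscape.
#'
#' @param set_a,set_b `stable_reo_set` objects.
#' @return An object of class `concordance`: `k`, `s`, `score`, `p_value`,
#'   `log10_p`, `log10_hoeffding`, `p_e`, and `undefined` (`TRUE` when no
#'   pair is shared, in which case `p_value = 1`).
#' @examples
#' m <- matrix(c(5, 3, 1, 6, 4, 2), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' s <- find_stable_pairs(m)
#' cross_set_concordance(s, s)$score  # identical sets: 1
#' @export
cross_set_concordance <- function(set_a, set_b) {
  key_a <- .pair_keys(set_a)
  key_b <- .pair_keys(set_b)
  shared <- intersect(key_a$key, key_b$key)
  k <- length(shared)
  if (k == 0L) {
    return(structure(list(k = 0L, s = 0L, score = NA_real_, p_value = 1,
                          log10_p = 0, log10_hoeffding = 0, p_e = 0.5,
                          undefined = TRUE), class = "concordance"))
  }
  ia <- match(shared, key_a$key)
  ib <- match(shared, key_b$key)
  s <- sum(key_a$orient[ia] == key_b$orient[ib])
  .concordance_result(s, k, p_e = 0.5)
}

# canonical unordered key + orientation flag for each stored ordered pair
.pair_keys <- function(set) {
  hi <- set$genes[set$pairs[, "hi"]]
  lo <- set$genes[set$pairs[, "lo"]]
  first <- pmin(hi, lo)
  second <- pmax(hi, lo)
  list(key = paste(first, second, sep = "\r"), orient = hi == first)
}

.concordance_result <- function(s, k, p_e = 0.5) {
  structure(list(
    k = as.integer(k), s = as.integer(s), score = s / k,
    p_value = binomial_upper_tail(s, k, p_e),
    log10_p = binomial_upper_tail(s, k, p_e, log10 = TRUE),
    log10_hoeffding = hoeffding_log10_bound(s, k, p_e),
    p_e = p_e, undefined = FALSE), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  if (x$undefined) {
    cat("concordance: no shared items (score undefined, p = 1)\n")
  } else {
    cat(sprintf(
      "concordance: s/k = %d/%d = %.4f; binomial upper-tail p = %.3g (log10 p = %.4g)\n",
      x$s, x$k, x$score, x$p_value, x$log10_p))
  }
  invisible(x)
}
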