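#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration with fixed
#' margins: the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance for floating-point ties) are summed. This is the
#' statistic on the per-gene, per-sample hot path of the reversal-pair
#' caller, so it is implemented directly on `dhyper` rather than through
#' `fisher.test`.
#'
#' @param a,b,c,d non-negative integer cell counts of the table
#'   `rbind(c(a, b), c(c, d))`; vectorised.
#' @return numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2 / choose(10, 5)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("all cells must be non-negative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    .fisher2x2_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

.fisher2x2_one <- function(a, b, c, d) {
  m <- a + b      # row-1 margin
  n2 <- c + d     # row-2 margin
  k <- a + c      # column-1 margin
  if (m + n2 == 0L || k == 0L || k == m + n2) return(1)
  x <- max(0L, k - n2):min(k, m)
  dens <- stats::dhyper(x, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}
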