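# Independent brute-force oracles used to validate the package's optimized
# routines. These are deliberately naive (double loops, full enumeration)
# and share no code with the implementation.

# all ordered pairs (hi, lo) whose strict ordering holds in >= thr of samples
oracle_stable_pairs <- function(mat, thr = 1) {
  genes <- rownames(mat)
  out <- NULL
  n <- ncol(mat)
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      wins <- 0L
      for (s in seq_len(n)) if (mat[i, s] > mat[j, s]) wins <- wins + 1L
      if (wins >= thr * n - 1e-9 && wins > n - wins) {
        out <- rbind(out, c(genes[i], genes[j]))
      } else if (wins >= thr * n - 1e-9 && n - wins >= thr * n - 1e-9) {
        # both directions pass (thr <= 0.5) and tie: neither kept
      }
    }
  }
  if (is.null(out)) out <- matrix(character(), 0, 2)
  colnames(out) <- c("hi", "lo")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# exact two-sided Fisher p by enumeration of all tables with the observed
# margins, probabilities from products of binomial coefficients
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  if (k == 0 || k == n || r1 + r2 == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, k - x) / choose(n, k)
  }, numeric(1))
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  e_w <- n * (N + 1) / 2
  combos <- utils::combn(N, n)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# exact rank-product tail: P(product of n_cmp iid uniform{1..g} ranks <= obs)
oracle_rank_product_p <- function(obs_log_rp, g, n_cmp) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(g)), n_cmp)))
  lp <- rowSums(log(grid))
  mean(lp <= n_cmp * obs_log_rp + 1e-9)
}

# bare numeric matrix from an expr_matrix (drop class and annotations)
strip_expr <- function(x) {
  x <- unclass(x)
  attr(x, "group") <- NULL
  attr(x, "dataset") <- NULL
  x
}

# a small random gene-by-sample matrix with gene/sample names
random_expr <- function(g, n, sd = 1, prefix = "g") {
  m <- matrix(rnorm(g * n, sd = sd), g, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(g)),
                              sprintf("s%03d", seq_len(n))))
  m
}

# stable_reo_set built directly from an explicit pair list (hand fixtures)
manual_stable_set <- function(genes, pairs_hi, pairs_lo) {
  pairs <- cbind(hi = match(pairs_hi, genes), lo = match(pairs_lo, genes))
  structure(list(genes = genes, pairs = pairs, support_threshold = 1,
                 n_samples = 1L),
            class = "stable_reo_set")
}
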