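#' Rank-product differential expression between two sample groups
#'
#' For every pairwise comparison of one group-A sample against one group-B
#' sample, genes are ranked by the log2 difference (rank 1 = most
#' up-regulated in A for the up statistic; symmetrically for down; ties get
#' average ranks). The rank product is the geometric mean of a gene's ranks
#' over all comparisons. Significance comes from a permutation null.
#' Under the default `null_scheme = "array"` each permutation round
#' shuffles every sample's values across genes and recomputes all pairwise
#' rank vectors, so the dependence between comparisons sharing a sample is
#' preserved in the null; the permuted rank products of all genes are
#' pooled and `p = (1 + #null <= observed) / (1 + #null)`.
#' `null_scheme = "independent"` shuffles each comparison's rank vector
#' independently instead — cheaper, but markedly anti-conservative when
#' comparisons share samples; it is retained because its null has a closed
#' enumerable form: with `exact = TRUE` the null CDF of a product of
#' independent uniform ranks is computed by convolution (feasible for
#' small gene numbers; the enumeration route used in validation).
#' BH adjustment is applied per tail.
#'
#' When `|A| * |B| > max_comparisons` a seeded random subset of comparisons
#' is used.
#'
#' @param matrix genes-by-samples matrix or [expr_matrix()].
#' @param group_a_samples,group_b_samples disjoint column-name vectors; `A`
#'   is conventionally the non-responder group, so `UP` means higher in A.
#' @param n_permutations permutation rounds for the Monte-Carlo null.
#' @param alpha_fdr FDR threshold recorded for [de_gene_list()].
#' @param seed seed for comparison subsetting and permutations.
#' @param max_comparisons cap on the number of A-vs-B comparisons.
#' @param null_scheme permutation null: `"array"` (within-sample value
#'   permutation, dependence-preserving; default) or `"independent"`
#'   (per-comparison rank shuffles).
#' @param exact use the exact product-of-uniform-ranks null (implies the
#'   independent scheme).
#' @return An object of class `rank_product`: `table` (per gene: `rp_up`,
#'   `rp_down`, `p_up`, `p_down`, `fdr_up`, `fdr_down`), `n_comparisons`,
#'   `n_permutations`, `alpha_fdr`, `seed`.
#' @export
rank_product_de <- function(matrix, group_a_samples, group_b_samples,
                            n_permutations = 100L, alpha_fdr = 0.05,
                            seed = 1L, max_comparisons = 200L,
                            null_scheme = c("array", "independent"),
                            exact = FALSE) {
  null_scheme <- match.arg(null_scheme)
  vals <- .as_values(matrix)
  if (length(intersect(group_a_samples, group_b_samples))) {
    stop("groups overlap", call. = FALSE)
  }
  if (!all(c(group_a_samples, group_b_samples) %in% colnames(vals))) {
    stop("unknown sample ids", call. = FALSE)
  }
  if (length(group_a_samples) < 2L || length(group_b_samples) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  if (!exact) .check_count(n_permutations, "n_permutations")
  seeds <- .derive_seeds(seed, 2L)
  cmp <- expand.grid(a = group_a_samples, b = group_b_samples,
                     stringsAsFactors = FALSE)
  if (nrow(cmp) > max_comparisons) {
    cmp <- cmp[.with_seed(seeds[1L], sample.int(nrow(cmp), max_comparisons)), ]
  }
  g <- nrow(vals)
  n_cmp <- nrow(cmp)
  # per comparison: log rank vectors for both tails
  lr_up <- matrix(0, g, n_cmp)
  lr_down <- matrix(0, g, n_cmp)
  for (i in seq_len(n_cmp)) {
    d <- vals[, cmp$a[i]] - vals[, cmp$b[i]]
    lr_up[, i] <- log(rank(-d, ties.method = "average"))
    lr_down[, i] <- log(rank(d, ties.method = "average"))
  }
  lrp_up <- rowSums(lr_up)      # log of the rank product^n_cmp
  lrp_down <- rowSums(lr_down)
  if (exact) {
    null <- .rank_product_exact_null(g, n_cmp)
    p_up <- .rank_product_exact_p(lrp_up, null)
    p_down <- .rank_product_exact_p(lrp_down, null)
  } else {
    samples <- sort(unique(c(cmp$a, cmp$b)))
    sub <- vals[, samples, drop = FALSE]
    # canonical (label-free) orientation for the null so that swapping the
    # group labels reproduces the identical null sample
    c1 <- pmin(match(cmp$a, samples), match(cmp$b, samples))
    c2 <- pmax(match(cmp$a, samples), match(cmp$b, samples))
    null <- .with_seed(seeds[2L], {
      out <- numeric(g * n_permutations)
      lg <- log(seq_len(g))
      for (b in seq_len(n_permutations)) {
        acc <- numeric(g)
        if (null_scheme == "array") {
          # permute each sample's values across genes, keep comparison
          # dependence by recomputing every pairwise rank vector
          pm <- apply(sub, 2L, function(col) col[sample.int(g)])
          for (i in seq_len(n_cmp)) {
            acc <- acc + log(rank(pm[, c2[i]] - pm[, c1[i]],
                                  ties.method = "average"))
          }
        } else {
          for (i in seq_len(n_cmp)) acc <- acc + lg[sample.int(g)]
        }
        out[(b - 1L) * g + seq_len(g)] <- acc
      }
      sort(out)
    })
    tol <- 1e-9
    p_up <- (1 + findInterval(lrp_up + tol, null)) / (1 + length(null))
    p_down <- (1 + findInterval(lrp_down + tol, null)) / (1 + length(null))
  }
  tab <- data.frame(gene = rownames(vals),
                    rp_up = exp(lrp_up / n_cmp),
                    rp_down = exp(lrp_down / n_cmp),
                    p_up = p_up, p_down = p_down,
                    fdr_up = stats::p.adjust(p_up, method = "BH"),
                    fdr_down = stats::p.adjust(p_down, method = "BH"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_comparisons = n_cmp,
                 n_permutations = if (exact) NA_integer_ else n_permutations,
                 alpha_fdr = alpha_fdr, seed = seed, exact = exact,
                 null_scheme = if (exact) "independent" else null_scheme),
            class = "rank_product")
}

# Exact distribution of the product of n_cmp iid uniform{1..g} ranks,
# as counts over log-product values.
.rank_product_exact_null <- function(g, n_cmp, max_values = 200000L) {
  vals <- as.numeric(seq_len(g))
  cnt <- rep(1, g)
  for (i in seq_len(n_cmp - 1L)) {
    prod <- as.vector(outer(vals, as.numeric(seq_len(g))))
    wt <- as.vector(outer(cnt, rep(1, g)))
    agg <- rowsum(wt, group = prod)
    vals <- as.numeric(rownames(agg))
    cnt <- as.vector(agg)
    if (length(vals) > max_values) {
      stop("exact rank-product null too large; use the permutation null",
           call. = FALSE)
    }
  }
  o <- order(vals)
  list(log_vals = log(vals[o]), cum = cumsum(cnt[o]), total = g^n_cmp)
}

.rank_product_exact_p <- function(log_prod, null) {
  idx <- findInterval(log_prod + 1e-9, null$log_vals)
  ifelse(idx == 0L, 0, null$cum[pmax(idx, 1L)]) / null$total
}

#' @export
print.rank_product <- function(x, ...) {
  n_de <- sum(pmin(x$table$fdr_up, x$table$fdr_down) <= x$alpha_fdr)
  cat(sprintf("rank_product: %d genes, %d comparisons, %s null; %d genes at FDR <= %g\n",
              nrow(x$table), x$n_comparisons,
              if (x$exact) "exact" else sprintf("%d-permutation", x$n_permutations),
              n_de, x$alpha_fdr))
  invisible(x)
}

#' Directed DE gene list from a rank-product fit
#'
#' A gene is called when its better tail reaches `alpha_fdr`; its direction
#' is the tail with the smaller p-value (`UP` = higher in group A). A gene
#' can never appear with both directions.
#'
#' @param x a [rank_product_de()] result.
#' @param alpha_fdr FDR threshold (default: the fit's).
#' @param source_label label recorded on the list.
#' @return data.frame of class `directed_gene_list` with columns `gene`,
#'   `direction`, and attribute `source_label`.
#' @export
de_gene_list <- function(x, alpha_fdr = NULL, source_label = "dataset") {
  stopifnot(inherits(x, "rank_product"))
  alpha_fdr <- alpha_fdr %||% x$alpha_fdr
  tab <- x$table
  up <- tab$fdr_up <= alpha_fdr & tab$p_up < tab$p_down
  down <- tab$fdr_down <= alpha_fdr & tab$p_down < tab$p_up
  directed_gene_list(c(tab$gene[up], tab$gene[down]),
                     c(rep("UP", sum(up)), rep("DOWN", sum(down))),
                     source_label)
}

#' @rdname de_gene_list
#' @param genes,direction character vectors defining the list directly.
#' @export
directed_gene_list <- function(genes, direction, source_label = "list") {
  direction <- as.character(direction)
  if (length(genes) != length(direction) ||
      !all(direction %in% c("UP", "DOWN"))) {
    stop("`direction` must be UP/DOWN, one per gene", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("a gene may appear only once", call. = FALSE)
  structure(data.frame(gene = as.character(genes), direction = direction,
                       stringsAsFactors = FALSE),
            source_label = source_label,
            class = c("directed_gene_list", "data.frame"))
}

#' Concordance of two directed DE gene lists and inconsistency-free merge
#'
#' Of the `k` genes shared by the two lists, `s` carry the same direction;
#' the score `s/k` is tested against the cumulative binomial null with
#' `p_e = 0.5`. The merged list is the union minus the shared genes whose
#' directions disagree (directions of consistent shared genes agree by
#' construction, so either source can supply them). With no shared genes
#' the concordance is flagged undefined and the merge is the plain union.
#'
#' @param list_a,list_b [directed_gene_list()] objects (or data.frames with
#'   `gene` and `direction` columns).
#' @return list with `concordance` (a `concordance` object) and `merged`
#'   (a `directed_gene_list`).
#' @examples
#' a <- directed_gene_list(c("g1", "g2", "g3"), c("UP", "UP", "DOWN"), "A")
#' b <- directed_gene_list(c("g2", "g3", "g4"), c("UP", "UP", "DOWN"), "B")
#' concordance_and_merge(a, b)$merged   # g3 excluded: directions disagree
#' @export
concordance_and_merge <- function(list_a, list_b) {
  la <- directed_gene_list(list_a$gene, list_a$direction,
                           attr(list_a, "source_label") %||% "A")
  lb <- directed_gene_list(list_b$gene, list_b$direction,
                           attr(list_b, "source_label") %||% "B")
  shared <- intersect(la$gene, lb$gene)
  k <- length(shared)
  dir_a <- la$direction[match(shared, la$gene)]
  dir_b <- lb$direction[match(shared, lb$gene)]
  consistent <- shared[dir_a == dir_b]
  s <- length(consistent)
  conc <- if (k == 0L) {
    structure(list(k = 0L, s = 0L, score = NA_real_, p_value = 1,
                   log10_p = 0, log10_hoeffding = 0, p_e = 0.5,
                   undefined = TRUE), class = "concordance")
  } else {
    .concordance_result(s, k, p_e = 0.5)
  }
  drop <- setdiff(shared, consistent)
  merged_genes <- setdiff(union(la$gene, lb$gene), drop)
  dirs <- ifelse(merged_genes %in% la$gene,
                 la$direction[match(merged_genes, la$gene)],
                 lb$direction[match(merged_genes, lb$gene)])
  merged <- directed_gene_list(merged_genes, dirs, source_label = "merged")
  list(concordance = conc, merged = merged)
}
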