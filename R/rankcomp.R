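# Individual-sample differential expression from stable-ordering reversals.
#
# For a focal gene g, the stable landscape fixes two partner sets: genes
# normally below g (pairs (g, x)) and genes normally above g (pairs (y, g)).
# A reversal of a (g, x) pair in a disease sample (g now strictly below x)
# supports DOWN-regulation of g; a reversal of a (y, g) pair supports UP.
# Fisher's exact test asks whether the two reversal frequencies differ.

# Align a sample (named vector or 1-column matrix) to the landscape genes.
.align_sample <- function(sample_values, set) {
  v <- drop(sample_values)
  if (is.null(names(v))) stop("sample values must be named by gene", call. = FALSE)
  if (!all(set$genes %in% names(v))) {
    stop("sample does not cover the stable-set gene universe", call. = FALSE)
  }
  unname(v[set$genes])
}

# Reversal tables for all genes at once. `exclude` is a logical vector over
# set$genes: pairs whose *partner* gene is excluded are dropped from the
# focal gene's table (the coupled-pair filtering step).
.reversal_tables <- function(v, set, exclude = NULL) {
  g <- length(set$genes)
  hi <- set$pairs[, "hi"]
  lo <- set$pairs[, "lo"]
  rev <- v[hi] < v[lo]              # strict: ties are not reversals
  if (is.null(exclude)) {
    keep_hi <- keep_lo <- rep(TRUE, length(hi))
  } else {
    keep_hi <- !exclude[lo]         # focal = hi, partner = lo
    keep_lo <- !exclude[hi]         # focal = lo, partner = hi
  }
  data.frame(
    gene = set$genes,
    n_less = tabulate(hi[keep_hi], g),
    r_down = tabulate(hi[keep_hi & rev], g),
    n_greater = tabulate(lo[keep_lo], g),
    r_up = tabulate(lo[keep_lo & rev], g),
    stringsAsFactors = FALSE)
}

#' Reversal-pair counts for one gene in one sample
#'
#' Counts, over the gene's stable partners, how many orderings are strictly
#' reversed in the sample: reversals of pairs where the gene is normally the
#' higher member support its down-regulation (`r_down` of `n_less`), and
#' reversals where it is normally the lower member support up-regulation
#' (`r_up` of `n_greater`). Ties in the disease sample count as
#' non-reversed.
#'
#' @param sample_values named numeric vector of log2 expression covering the
#'   stable set's gene universe.
#' @param gene focal gene id.
#' @param stable_set a [find_stable_pairs()] result.
#' @return list with `gene`, `n_less`, `r_down`, `n_greater`, `r_up`, and
#'   `untestable` (`TRUE` when the gene has no stable partner).
#' @export
reversal_counts <- function(sample_values, gene, stable_set) {
  i <- match(gene, stable_set$genes)
  if (is.na(i)) stop("gene not in the stable-set universe", call. = FALSE)
  v <- .align_sample(sample_values, stable_set)
  tab <- .reversal_tables(v, stable_set)[i, ]
  list(gene = gene, n_less = tab$n_less, r_down = tab$r_down,
       n_greater = tab$n_greater, r_up = tab$r_up,
       untestable = (tab$n_less + tab$n_greater) == 0L)
}

#' Call differentially expressed genes in a single disease sample
#'
#' For every testable gene the reversal table is assessed with the
#' two-sided Fisher exact test on
#' `rbind(c(r_down, n_less - r_down), c(r_up, n_greater - r_up))`,
#' p-values are Benjamini-Hochberg adjusted across the genes of the sample,
#' and significant genes (FDR <= `alpha`) get a direction from the larger
#' reversal proportion (`UP` when `r_up/n_greater > r_down/n_less`). Genes
#' with fewer than `min_partners` stable partners are reported as `NONE`
#' with missing p.
#'
#' @param sample_values named numeric vector over the stable-set universe
#'   (or a 1-column matrix with rownames).
#' @param stable_set a [find_stable_pairs()] result with at least one pair.
#' @param alpha BH false-discovery-rate threshold for calling a gene.
#' @param min_partners minimum total stable partners for a gene to be
#'   testable (degenerate Fisher tables otherwise).
#' @param sample_id label stored with the call.
#' @return An object of class `sample_de_call`: list with `sample_id`,
#'   `table` (per gene: reversal counts, `p`, `fdr`, `direction`), `alpha`,
#'   `min_partners`, `filter_iterations`, `converged`.
#' @seealso [filter_de_calls()], [run_rankcomp()]
#' @export
call_de_single_sample <- function(sample_values, stable_set, alpha = 0.05,
                                  min_partners = 10L,
                                  sample_id = "sample") {
  if (!nrow(stable_set$pairs)) stop("empty stable set", call. = FALSE)
  .check_fraction(alpha, "alpha", open_min = TRUE)
  v <- .align_sample(sample_values, stable_set)
  tab <- .reversal_tables(v, stable_set)
  tab$testable <- (tab$n_less + tab$n_greater) >= min_partners
  tab$p <- NA_real_
  idx <- which(tab$testable)
  tab$p[idx] <- fisher_exact_2x2(tab$r_down[idx], tab$n_less[idx] - tab$r_down[idx],
                                 tab$r_up[idx], tab$n_greater[idx] - tab$r_up[idx])
  tab$fdr <- NA_real_
  tab$fdr[idx] <- stats::p.adjust(tab$p[idx], method = "BH")
  tab$direction <- .assign_direction(tab, alpha)
  structure(list(sample_id = sample_id, table = tab, alpha = alpha,
                 min_partners = min_partners, filter_iterations = 0L,
                 converged = TRUE),
            class = "sample_de_call")
}

.assign_direction <- function(tab, alpha) {
  prop_down <- tab$r_down / pmax(tab$n_less, 1L)
  prop_up <- tab$r_up / pmax(tab$n_greater, 1L)
  dir <- rep("NONE", nrow(tab))
  sig <- !is.na(tab$fdr) & tab$fdr <= alpha
  dir[sig & prop_up > prop_down] <- "UP"
  dir[sig & prop_down > prop_up] <- "DOWN"
  dir
}

#' Coupled-pair filtering of single-sample DE calls
#'
#' A gene's significance can be driven by reversal pairs whose other member
#' is itself deregulated. Each round, every currently-called gene is
#' re-tested on its reversal table with all pairs against other
#' currently-called partners excluded, and BH is re-applied across the
#' current call set. If any gene fails, only the *weakest* failing gene
#' (largest recomputed p) is removed before the next round — backward
#' elimination, so of two mutually coupled genes the marginal one is
#' removed and the strong one then regains its evidence and is retained.
#' Iteration stops at the fixed point where every retained gene survives
#' exclusion of all its retained-DE partners; the retained set can only
#' shrink. A called gene left with fewer than `min_partners` usable
#' partners counts as failing. Retained genes carry their filtered
#' `p`/`fdr`.
#'
#' @param call a [call_de_single_sample()] result.
#' @param stable_set the same stable set the call was made against.
#' @param sample_values the same sample the call was made on.
#' @param max_iter cap on elimination rounds; non-convergence returns the
#'   last state with `converged = FALSE` and a warning.
#' @return the filtered `sample_de_call`.
#' @export
filter_de_calls <- function(call, stable_set, sample_values, max_iter = 100L) {
  stopifnot(inherits(call, "sample_de_call"))
  v <- .align_sample(sample_values, stable_set)
  tab <- call$table
  de <- tab$direction != "NONE"
  iters <- 0L
  converged <- TRUE
  while (any(de)) {
    if (iters >= max_iter) {
      converged <- FALSE
      warning("coupled-pair filtering did not converge within max_iter")
      break
    }
    iters <- iters + 1L
    ftab <- .reversal_tables(v, stable_set, exclude = de)
    idx <- which(de)
    usable <- (ftab$n_less[idx] + ftab$n_greater[idx]) >= call$min_partners
    p_f <- rep(NA_real_, length(idx))
    p_f[usable] <- fisher_exact_2x2(
      ftab$r_down[idx][usable], ftab$n_less[idx][usable] - ftab$r_down[idx][usable],
      ftab$r_up[idx][usable], ftab$n_greater[idx][usable] - ftab$r_up[idx][usable])
    fdr_f <- stats::p.adjust(p_f, method = "BH")
    fail <- is.na(fdr_f) | fdr_f > call$alpha
    tab$p[idx] <- p_f
    tab$fdr[idx] <- fdr_f
    if (!any(fail)) break
    worst <- idx[which.max(replace(p_f, is.na(p_f), Inf))]
    de[worst] <- FALSE
  }
  tab$direction[tab$direction != "NONE" & !de] <- "NONE"
  call$table <- tab
  call$filter_iterations <- iters
  call$converged <- converged
  call
}

#' @export
print.sample_de_call <- function(x, ...) {
  n_de <- sum(x$table$direction != "NONE")
  cat(sprintf("sample_de_call '%s': %d DE genes of %d testable (FDR <= %g, %d filter iteration(s))\n",
              x$sample_id, n_de, sum(x$table$testable), x$alpha,
              x$filter_iterations))
  invisible(x)
}

#' @rdname call_de_single_sample
#' @param x a `sample_de_call`.
#' @return `de_genes`: data.frame of the called genes with direction, p, fdr.
#' @export
de_genes <- function(x) {
  keep <- x$table$direction != "NONE"
  data.frame(sample_id = rep(x$sample_id, sum(keep)), gene = x$table$gene[keep],
             direction = x$table$direction[keep], p = x$table$p[keep],
             fdr = x$table$fdr[keep], stringsAsFactors = FALSE)
}

#' Run the reversal-pair caller over a cancer cohort
#'
#' Maps [call_de_single_sample()] (and, by default, [filter_de_calls()])
#' over every column of the cancer matrix.
#'
#' @param cancer_matrix matrix or [expr_matrix()] whose rows cover the
#'   stable-set gene universe.
#' @param stable_set a [find_stable_pairs()] result.
#' @inheritParams call_de_single_sample
#' @param filter apply coupled-pair filtering per sample.
#' @return An object of class `rankcomp`: list with `calls` (one
#'   `sample_de_call` per sample), `de_table` (long data.frame: sample_id,
#'   gene, direction, p, fdr), `alpha`, `mean_de_per_sample`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_genes = 50, n_responders = 3,
#'                                         n_nonresponders = 3, seed = 2))
#' land <- find_stable_pairs(cohort$normals)
#' fit <- run_rankcomp(cohort$cancers, land)
#' summary(fit)
#' @export
run_rankcomp <- function(cancer_matrix, stable_set, alpha = 0.05,
                         min_partners = 10L, filter = TRUE) {
  vals <- .as_values(cancer_matrix)
  calls <- lapply(colnames(vals), function(sid) {
    v <- vals[, sid]
    names(v) <- rownames(vals)
    cl <- call_de_single_sample(v, stable_set, alpha = alpha,
                                min_partners = min_partners, sample_id = sid)
    if (filter) cl <- filter_de_calls(cl, stable_set, v)
    cl
  })
  names(calls) <- colnames(vals)
  de_table <- do.call(rbind, lapply(calls, de_genes))
  if (is.null(de_table)) {
    de_table <- data.frame(sample_id = character(), gene = character(),
                           direction = character(), p = numeric(),
                           fdr = numeric(), stringsAsFactors = FALSE)
  }
  rownames(de_table) <- NULL
  structure(list(calls = calls, de_table = de_table, alpha = alpha,
                 mean_de_per_sample = nrow(de_table) / max(length(calls), 1L)),
            class = "rankcomp")
}

#' @export
print.rankcomp <- function(x, ...) {
  cat(sprintf("rankcomp: %d samples, %.1f DE genes/sample on average (FDR <= %g)\n",
              length(x$calls), x$mean_de_per_sample, x$alpha))
  invisible(x)
}

#' @export
summary.rankcomp <- function(object, ...) {
  per_sample <- vapply(object$calls,
                       function(cl) sum(cl$table$direction != "NONE"),
                       integer(1))
  out <- list(n_samples = length(object$calls),
              de_per_sample = per_sample,
              mean_de_per_sample = object$mean_de_per_sample,
              alpha = object$alpha)
  class(out) <- "summary.rankcomp"
  out
}

#' @export
print.summary.rankcomp <- function(x, ...) {
  cat(sprintf("rankcomp over %d samples (FDR <= %g)\n", x$n_samples, x$alpha))
  cat(sprintf("DE genes per sample: mean %.1f, range %d-%d\n",
              x$mean_de_per_sample, min(x$de_per_sample), max(x$de_per_sample)))
  invisible(x)
}
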