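#' Per-gene deregulation counts by responder group
#'
#' Counts, for every gene of the landscape universe, in how many samples of
#' each responder group the gene was called deregulated (any direction by
#' default; per-direction counts are included alongside).
#'
#' @param calls a [run_rankcomp()] result or list of `sample_de_call`s.
#' @param metadata data.frame with `sample_id` and `group`
#'   (`"responder"` / `"nonresponder"`) covering every called sample.
#' @return data.frame of class `dereg_profile`: per gene
#'   `count_nonresp`, `count_resp`, `count_up_nonresp`, `count_up_resp`,
#'   `count_down_nonresp`, `count_down_resp`, with attributes `n_nonresp`,
#'   `n_resp`.
#' @export
build_profile <- function(calls, metadata) {
  if (inherits(calls, "rankcomp")) calls <- calls$calls
  ids <- vapply(calls, `[[`, character(1), "sample_id")
  grp <- metadata$group[match(ids, metadata$sample_id)]
  if (anyNA(grp)) stop("unlabeled sample(s): ",
                       paste(ids[is.na(grp)], collapse = ", "), call. = FALSE)
  if (!all(grp %in% c("responder", "nonresponder"))) {
    stop("groups must be responder/nonresponder", call. = FALSE)
  }
  genes <- calls[[1L]]$table$gene
  count <- function(group, dir) {
    sel <- which(grp == group)
    if (!length(sel)) return(integer(length(genes)))
    rowSums(vapply(calls[sel], function(cl) {
      d <- cl$table$direction
      if (is.null(dir)) d != "NONE" else d == dir
    }, logical(length(genes))))
  }
  out <- data.frame(
    gene = genes,
    count_nonresp = count("nonresponder", NULL),
    count_resp = count("responder", NULL),
    count_up_nonresp = count("nonresponder", "UP"),
    count_up_resp = count("responder", "UP"),
    count_down_nonresp = count("nonresponder", "DOWN"),
    count_down_resp = count("responder", "DOWN"),
    stringsAsFactors = FALSE)
  structure(out, n_nonresp = sum(grp == "nonresponder"),
            n_resp = sum(grp == "responder"),
            class = c("dereg_profile", "data.frame"))
}

#' Genes deregulated in a non-randomly high fraction of cancer samples
#'
#' Pools both responder groups and keeps genes whose deregulation count is
#' in the upper tail of `Binomial(n_total, p0)` at `p < alpha` (no
#' multiplicity adjustment; the null rate `p0` defaults in the pipeline to
#' the per-sample expected false-call rate of the individual-sample
#' caller).
#'
#' @param profile a [build_profile()] result.
#' @param p0 null per-sample deregulation probability, in (0, 1).
#' @param alpha significance level on the raw binomial p.
#' @return character vector of selected genes, with the per-gene p-values
#'   as a `p_values` attribute.
#' @export
cancer_related_background_test <- function(profile, p0, alpha = 0.05) {
  .check_fraction(p0, "p0", open_min = TRUE, open_max = TRUE)
  n_total <- attr(profile, "n_nonresp") + attr(profile, "n_resp")
  cnt <- profile$count_nonresp + profile$count_resp
  p <- binomial_upper_tail(cnt, n_total, p0)
  sel <- profile$gene[p < alpha]
  structure(sel, p_values = stats::setNames(p, profile$gene))
}

#' Contrast per-gene deregulation frequencies between responder groups
#'
#' For each gene, a two-sided Fisher exact test compares the deregulation
#' frequency in non-responders against responders
#' (`rbind(c(count_nonresp, n_nonresp - count_nonresp),
#'         c(count_resp, n_resp - count_resp))`), with BH adjustment across
#' genes. Genes at FDR <= `alpha_fdr` are the cancer-related
#' treatment-response genes. Set `direction = "UP"` or `"DOWN"` to contrast
#' per-direction counts instead of direction-agnostic ones.
#'
#' @param profile a [build_profile()] result with both groups non-empty.
#' @param alpha_fdr BH FDR threshold.
#' @param direction `"any"` (default), `"UP"` or `"DOWN"`.
#' @return data.frame of class `freq_contrast`: per gene the contrasted
#'   counts, `p`, `fdr`, `selected`; attribute `alpha_fdr`.
#' @seealso [selected_genes()]
#' @export
frequency_difference_test <- function(profile, alpha_fdr = 0.05,
                                      direction = c("any", "UP", "DOWN")) {
  direction <- match.arg(direction)
  n_nr <- attr(profile, "n_nonresp")
  n_r <- attr(profile, "n_resp")
  if (!n_nr || !n_r) stop("both groups must be non-empty", call. = FALSE)
  cnt_nr <- switch(direction, any = profile$count_nonresp,
                   UP = profile$count_up_nonresp,
                   DOWN = profile$count_down_nonresp)
  cnt_r <- switch(direction, any = profile$count_resp,
                  UP = profile$count_up_resp,
                  DOWN = profile$count_down_resp)
  p <- fisher_exact_2x2(cnt_nr, n_nr - cnt_nr, cnt_r, n_r - cnt_r)
  fdr <- stats::p.adjust(p, method = "BH")
  structure(data.frame(gene = profile$gene, count_nonresp = cnt_nr,
                       n_nonresp = n_nr, count_resp = cnt_r, n_resp = n_r,
                       p = p, fdr = fdr, selected = fdr <= alpha_fdr,
                       stringsAsFactors = FALSE),
            alpha_fdr = alpha_fdr,
            class = c("freq_contrast", "data.frame"))
}

#' @rdname frequency_difference_test
#' @param x a `freq_contrast` result.
#' @export
selected_genes <- function(x) x$gene[x$selected]

#' Partition group-level DE genes into cancer-related and cancer-unrelated
#'
#' Intersects the cancer-related gene set (from the deregulation-frequency
#' contrast) with the merged group-level DE list; merged DE genes outside
#' the intersection are the cancer-unrelated treatment-response genes.
#'
#' @param cancer_related character vector of cancer-related genes (or a
#'   `freq_contrast` object, whose selected genes are used).
#' @param merged_group_de a [directed_gene_list()] (or data.frame with a
#'   `gene` column).
#' @return list of class `response_gene_classes`: `cancer_related`,
#'   `shared_with_group_de`, `cancer_unrelated`, `sizes`.
#' @export
partition_classes <- function(cancer_related, merged_group_de) {
  if (inherits(cancer_related, "freq_contrast")) {
    cancer_related <- selected_genes(cancer_related)
  }
  cancer_related <- unique(as.character(cancer_related))
  merged <- unique(as.character(merged_group_de$gene))
  shared <- intersect(cancer_related, merged)
  unrelated <- setdiff(merged, shared)
  structure(list(cancer_related = cancer_related,
                 shared_with_group_de = shared,
                 cancer_unrelated = unrelated,
                 sizes = c(cancer_related = length(cancer_related),
                           merged_group_de = length(merged),
                           shared = length(shared),
                           cancer_unrelated = length(unrelated))),
            class = "response_gene_classes")
}

#' @export
print.response_gene_classes <- function(x, ...) {
  cat(sprintf(paste0(
    "response_gene_classes: %d cancer-related; %d merged group-DE genes of which\n",
    "  %d shared (cancer-related) and %d cancer-unrelated\n"),
    x$sizes[["cancer_related"]], x$sizes[["merged_group_de"]],
    x$sizes[["shared"]], x$sizes[["cancer_unrelated"]]))
  invisible(x)
}
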