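#' Curated treatment-response gene categories (synthetic reconstruction)
#'
#' Loads the bundled GMT of the four curated gene categories used in the
#' PPI proximity analysis: drug metabolism/transport (pharmacokinetic, 28
#' genes), purine/pyrimidine metabolism (47), downstream 5-FU effectors
#' (17) and radio-response genes (21). The category *sizes* mirror the
#' published curation; the member lists are a synthetic reconstruction
#' (plausible pathway members, not the original supplementary lists) and
#' the file is editable, so users can substitute their own curation.
#'
#' @return named list of four character vectors (see [read_gmt()]).
#' @examples
#' cats <- pcrt_gene_categories()
#' lengths(cats)
#' length(effective_genes(cats))  # 47 + 17 + 21 = 85
#' @export
pcrt_gene_categories <- function() {
  read_gmt(system.file("extdata", "pcrt_gene_categories_synthetic.gmt",
                       package = "reoresponse", mustWork = TRUE))
}

#' @rdname pcrt_gene_categories
#' @param categories a category list as returned by [pcrt_gene_categories()].
#' @details `effective_genes` pools the purine/pyrimidine-metabolism,
#'   5-FU-effector and radio-response categories — the genes acting on the
#'   DNA-damage axis of chemoradiation — as opposed to the pharmacokinetic
#'   category.
#' @export
effective_genes <- function(categories = pcrt_gene_categories()) {
  unique(c(categories$purine_pyrimidine_metabolism,
           categories$fu_downstream_effectors,
           categories$radio_response))
}
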