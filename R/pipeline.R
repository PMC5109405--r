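#' Configuration for an end-to-end synthetic-cohort pipeline run
#'
#' Assembles the defaults of every stage: simulate a multi-platform cohort,
#' mine the stable normal ordering landscape, call per-sample DE genes,
#' contrast deregulation frequencies, run the two-dataset rank-product
#' comparison with concordance merging, partition the response-gene
#' classes, and compute enrichment and PPI link statistics. Thresholds
#' default to the conventional values used throughout: stable-pair support
#' 1.0, per-sample FDR 0.05, group-DE FDR 0.05, frequency-contrast FDR
#' 0.05, enrichment reporting FDR 0.2.
#'
#' @param out_dir output directory (created if missing).
#' @param cohort a [cohort_config()] or list of its arguments.
#' @param seed master seed; the cohort seed and all stage sub-seeds are
#'   derived from it.
#' @param stages stage subset to run (downstream stages are skipped
#'   automatically when their inputs are missing).
#' @param support_threshold,rankcomp_alpha,group_de_fdr,freq_contrast_fdr,enrichment_fdr
#'   stage thresholds, all in (0, 1].
#' @param background_p0 null rate for [cancer_related_background_test()];
#'   default = `rankcomp_alpha`, the expected per-sample false-call rate.
#' @param n_permutations rank-product permutation rounds.
#' @param ppi_base_prob,ppi_boost_prob synthetic PPI edge probabilities.
#' @param n_gene_sets random gene sets in the synthetic collection.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("reo_run_"),
                            cohort = cohort_config(),
                            seed = 1L,
                            stages = c("simulate", "landscape", "rankcomp",
                                       "groupde", "classes", "enrich", "ppi"),
                            support_threshold = 1,
                            rankcomp_alpha = 0.05,
                            group_de_fdr = 0.05,
                            freq_contrast_fdr = 0.05,
                            enrichment_fdr = 0.2,
                            background_p0 = rankcomp_alpha,
                            n_permutations = 100L,
                            ppi_base_prob = 0.02,
                            ppi_boost_prob = 0.3,
                            n_gene_sets = 15L) {
  for (thr in c(support_threshold = support_threshold,
                rankcomp_alpha = rankcomp_alpha, group_de_fdr = group_de_fdr,
                freq_contrast_fdr = freq_contrast_fdr,
                enrichment_fdr = enrichment_fdr)) {
    if (!is.numeric(thr) || thr <= 0 || thr > 1) {
      stop("thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  stages <- match.arg(stages, several.ok = TRUE)
  if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, cohort)
  structure(list(out_dir = out_dir, cohort = cohort, seed = as.integer(seed),
                 stages = stages, support_threshold = support_threshold,
                 rankcomp_alpha = rankcomp_alpha, group_de_fdr = group_de_fdr,
                 freq_contrast_fdr = freq_contrast_fdr,
                 enrichment_fdr = enrichment_fdr,
                 background_p0 = background_p0,
                 n_permutations = as.integer(n_permutations),
                 ppi_base_prob = ppi_base_prob,
                 ppi_boost_prob = ppi_boost_prob,
                 n_gene_sets = as.integer(n_gene_sets)),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Executes the configured stages in order, writing each stage's tabular
#' output under `config$out_dir` and a JSON run manifest (`manifest.json`)
#' summarising parameters, seeds and the headline sizes of every stage
#' (stable pairs, mean DE genes per sample, per-dataset DE counts,
#' concordance k/s/score, response-gene class sizes, PPI link averages).
#' Outputs are pure functions of (config, seed): rerunning the same config
#' reproduces identical files. A stage failure aborts with the stage name;
#' outputs of completed stages are retained.
#'
#' For the two-dataset group comparison the cancer cohort is split into two
#' pseudo-datasets by alternating samples within each responder group.
#'
#' @param config a [pipeline_config()], a list of its arguments, or the
#'   path of a JSON file holding them.
#' @return the manifest, invisibly.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_config(n_genes = 120, seed = 5),
#'                        n_permutations = 20)
#' manifest <- run_pipeline(cfg)
#' manifest$landscape$n_stable_pairs
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!inherits(config, "pipeline_config")) {
    cohort <- config$cohort
    config$cohort <- NULL
    config <- do.call(pipeline_config,
                      c(config, if (!is.null(cohort)) list(cohort = cohort)))
  }
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .derive_seeds(cfg$seed, 4L)  # cohort, rank-product, gene sets, ppi
  res <- new.env(parent = emptyenv())
  res$manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("cohort", "out_dir"))],
    cohort = unclass(cfg$cohort), seeds = as.list(seeds))
  out <- function(...) file.path(cfg$out_dir, ...)
  stage <- function(name, need, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    if (!all(vapply(need, exists, logical(1), envir = res))) {
      return(invisible(NULL))
    }
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  stage("simulate", character(), function() {
    cc <- cfg$cohort
    cc$seed <- seeds[1L]
    res$cohort <- simulate_cohort(cc)
    for (i in seq_along(res$cohort$normals)) {
      write_expr_tsv(res$cohort$normals[[i]],
                     out(sprintf("normals_platform%d.tsv", i)))
    }
    write_expr_tsv(res$cohort$cancers, out("cancers.tsv"))
    write_sample_metadata(c(res$cohort$normals, list(res$cohort$cancers)),
                          out("sample_metadata.tsv"))
    for (nm in c("cancer_related", "markers", "events")) {
      utils::write.table(res$cohort$truth[[nm]],
                         out(paste0("truth_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$manifest$simulate <- list(
      n_genes = cfg$cohort$n_genes,
      n_normal_samples = sum(vapply(res$cohort$normals, ncol, integer(1))),
      n_cancer_samples = ncol(res$cohort$cancers),
      n_planted_cancer_related = nrow(res$cohort$truth$cancer_related),
      n_planted_markers = nrow(res$cohort$truth$markers),
      n_planted_events = nrow(res$cohort$truth$events))
  })

  stage("landscape", "cohort", function() {
    res$landscape <- find_stable_pairs(res$cohort$normals,
                                       support_threshold = cfg$support_threshold)
    write_stable_pairs(res$landscape, out("stable_pairs.tsv.gz"))
    res$manifest$landscape <- list(
      n_core_genes = length(res$landscape$genes),
      n_stable_pairs = nrow(res$landscape$pairs),
      support_threshold = cfg$support_threshold)
  })

  stage("rankcomp", "landscape", function() {
    res$rankcomp <- run_rankcomp(res$cohort$cancers, res$landscape,
                                 alpha = cfg$rankcomp_alpha)
    utils::write.table(res$rankcomp$de_table, out("rankcomp_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$manifest$rankcomp <- list(
      mean_de_per_sample = res$rankcomp$mean_de_per_sample,
      alpha = cfg$rankcomp_alpha)
  })

  stage("groupde", "cohort", function() {
    groups <- sample_groups(res$cohort$cancers)
    split2 <- function(ids) list(ids[seq_along(ids) %% 2L == 1L],
                                 ids[seq_along(ids) %% 2L == 0L])
    nr <- split2(names(groups)[groups == "nonresponder"])
    rs <- split2(names(groups)[groups == "responder"])
    rp_seeds <- .derive_seeds(seeds[2L], 2L)
    lists <- lapply(1:2, function(d) {
      rp <- rank_product_de(res$cohort$cancers, nr[[d]], rs[[d]],
                            n_permutations = cfg$n_permutations,
                            alpha_fdr = cfg$group_de_fdr, seed = rp_seeds[d])
      utils::write.table(rp$table,
                         out(sprintf("rank_product_dataset%d.tsv", d)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      de_gene_list(rp, source_label = sprintf("dataset%d", d))
    })
    cm <- concordance_and_merge(lists[[1L]], lists[[2L]])
    res$merged <- cm$merged
    utils::write.table(cm$merged, out("merged_group_de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(k = cm$concordance$k, s = cm$concordance$s,
           score = cm$concordance$score, p_value = cm$concordance$p_value),
      out("group_de_concordance.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    res$manifest$groupde <- list(
      n_de_dataset1 = nrow(lists[[1L]]), n_de_dataset2 = nrow(lists[[2L]]),
      k = cm$concordance$k, s = cm$concordance$s,
      score = cm$concordance$score, n_merged = nrow(cm$merged))
  })

  stage("classes", c("rankcomp", "merged"), function() {
    md <- data.frame(sample_id = colnames(res$cohort$cancers),
                     group = unname(sample_groups(res$cohort$cancers)),
                     stringsAsFactors = FALSE)
    profile <- build_profile(res$rankcomp, md)
    contrast <- frequency_difference_test(profile,
                                          alpha_fdr = cfg$freq_contrast_fdr)
    background <- cancer_related_background_test(profile, cfg$background_p0)
    res$classes <- partition_classes(contrast, res$merged)
    utils::write.table(as.data.frame(contrast), out("frequency_contrast.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(background),
               out("background_cancer_related_genes.txt"))
    writeLines(res$classes$cancer_related, out("cancer_related_genes.txt"))
    writeLines(res$classes$cancer_unrelated, out("cancer_unrelated_genes.txt"))
    res$manifest$classes <- c(as.list(res$classes$sizes),
                              list(n_background_selected = length(background)))
  })

  stage("enrich", c("classes", "landscape"), function() {
    universe <- res$landscape$genes
    truth <- res$cohort$truth
    coll <- simulate_gene_sets(
      universe, n_sets = cfg$n_gene_sets, seed = seeds[3L],
      include = list(planted_cancer_related = truth$cancer_related$gene,
                     planted_marker = truth$markers$gene))
    write_gmt(coll, out("gene_sets_synthetic.gmt"),
              descriptions = "synthetic")
    enr <- list(
      cancer_related = hypergeometric_enrichment(
        res$classes$cancer_related, coll, universe = universe,
        fdr_threshold = cfg$enrichment_fdr),
      cancer_unrelated = hypergeometric_enrichment(
        res$classes$cancer_unrelated, coll, universe = universe,
        fdr_threshold = cfg$enrichment_fdr))
    for (nm in names(enr)) {
      utils::write.table(as.data.frame(enr[[nm]]),
                         out(sprintf("enrichment_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$manifest$enrich <- lapply(enr, function(e) {
      list(n_significant = sum(e$significant), top_set = e$set_name[1L])
    })
  })

  stage("ppi", "classes", function() {
    universe <- res$cohort$truth$baseline$gene
    ppi_seeds <- .derive_seeds(seeds[4L], 2L)
    effective <- .with_seed(ppi_seeds[1L], {
      sort(sample(setdiff(universe, res$cohort$truth$markers$gene),
                  min(40L, length(universe))))
    })
    edges <- simulate_ppi(universe,
                          query_set = res$cohort$truth$cancer_related$gene,
                          target_set = effective,
                          base_edge_prob = cfg$ppi_base_prob,
                          boost_edge_prob = cfg$ppi_boost_prob,
                          seed = ppi_seeds[2L])
    utils::write.table(edges, out("ppi_edges.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    graph <- ppi_graph(edges, vertices = universe)
    st_rel <- direct_link_stats(res$classes$cancer_related, effective, graph)
    st_unr <- direct_link_stats(res$classes$cancer_unrelated, effective, graph)
    p_rs <- if (!st_rel$undefined && !st_unr$undefined) {
      compare_link_distributions(st_rel$counts, st_unr$counts)
    } else NA_real_
    stats_list <- list(
      cancer_related = list(n_mapped = length(st_rel$mapped_query),
                            total_links = st_rel$total_links,
                            average = st_rel$average),
      cancer_unrelated = list(n_mapped = length(st_unr$mapped_query),
                              total_links = st_unr$total_links,
                              average = st_unr$average),
      rank_sum_p = p_rs)
    jsonlite::write_json(stats_list, out("ppi_link_stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    export_link_subgraph(res$classes$cancer_related, effective, graph,
                         out("ppi_query_target_links.tsv"))
    res$manifest$ppi <- stats_list
  })

  jsonlite::write_json(res$manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res$manifest)
}
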