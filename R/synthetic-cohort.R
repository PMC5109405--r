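#' Configuration for the synthetic multi-platform cohort generator
#'
#' The generator emulates the data structure the REO pipeline was designed
#' for: several small cohorts of normal tissue profiled on different
#' "platforms" (each platform measures a gene subset and applies its own
#' strictly monotone affine distortion in log2 space, which leaves
#' within-sample orderings untouched), plus a cancer cohort split into
#' responders and non-responders in which cancer-related genes are
#' deregulated per sample with group-specific probability and
#' cancer-unrelated marker genes carry a small systematic shift in every
#' sample of one group (a pharmacokinetic-style difference: visible to a
#' group-level test, largely invisible to per-sample ordering reversals).
#'
#' Gene baselines are assigned by index (`gene_0001` lowest, spaced by
#' `baseline_spread` log2 units), so the true normal ordering is explicit
#' and brute-force checkable.
#'
#' @param n_genes number of genes in the universe.
#' @param n_platforms number of normal-tissue platforms/datasets.
#' @param genes_per_platform genes measured per platform (subset of the
#'   universe; the cross-platform core is their intersection); default 90%
#'   of the universe.
#' @param n_normal_per_platform normal samples per platform; recycled or
#'   truncated to `n_platforms`. Default 21, 7 and 6, the cohort sizes of
#'   the three public normal rectal-tissue datasets the design mirrors.
#' @param n_responders,n_nonresponders cancer cohort sizes (defaults 34 and
#'   38, the pooled sizes of the two public chemoradiation cohorts).
#' @param baseline_spread log2 gap between adjacent gene baselines.
#' @param noise_sd per-measurement Gaussian noise, log2 units.
#' @param frac_cancer_related fraction of genes planted as cancer-related.
#' @param dereg_freq_nonresp,dereg_freq_resp per-sample probability that a
#'   planted cancer-related gene is deregulated in a non-responder /
#'   responder sample.
#' @param dereg_effect log2 magnitude of a planted per-sample deregulation.
#' @param frac_cancer_unrelated_marker fraction of genes planted as
#'   cancer-unrelated group markers.
#' @param marker_effect log2 magnitude of the systematic marker shift;
#'   deliberately small relative to the gaps of stable pairs so markers are
#'   rarely called deregulated against the normal landscape.
#' @param marker_group group whose samples all carry the marker shift.
#' @param seed master seed; per-stage sub-streams are derived from it so
#'   stages can be regenerated independently.
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_genes = 500L,
                          n_platforms = 3L,
                          genes_per_platform = max(2L, round(0.9 * n_genes)),
                          n_normal_per_platform = c(21L, 7L, 6L),
                          n_responders = 34L,
                          n_nonresponders = 38L,
                          baseline_spread = 0.05,
                          noise_sd = 0.2,
                          frac_cancer_related = 0.1,
                          dereg_freq_nonresp = 0.8,
                          dereg_freq_resp = 0.1,
                          dereg_effect = 3.0,
                          frac_cancer_unrelated_marker = 0.05,
                          marker_effect = 0.3,
                          marker_group = "nonresponder",
                          seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  n_platforms <- .check_count(n_platforms, "n_platforms")
  genes_per_platform <- .check_count(genes_per_platform, "genes_per_platform")
  if (genes_per_platform > n_genes) {
    stop("`genes_per_platform` must not exceed `n_genes`", call. = FALSE)
  }
  n_normal_per_platform <- vapply(rep_len(n_normal_per_platform, n_platforms),
                                  .check_count, integer(1),
                                  name = "n_normal_per_platform")
  n_responders <- .check_count(n_responders, "n_responders", positive = FALSE)
  n_nonresponders <- .check_count(n_nonresponders, "n_nonresponders",
                                  positive = FALSE)
  if (baseline_spread <= 0) stop("`baseline_spread` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (dereg_effect <= 0) stop("`dereg_effect` must be positive", call. = FALSE)
  if (marker_effect <= 0) stop("`marker_effect` must be positive", call. = FALSE)
  .check_fraction(frac_cancer_related, "frac_cancer_related")
  .check_fraction(dereg_freq_nonresp, "dereg_freq_nonresp")
  .check_fraction(dereg_freq_resp, "dereg_freq_resp")
  .check_fraction(frac_cancer_unrelated_marker, "frac_cancer_unrelated_marker")
  if (frac_cancer_related + frac_cancer_unrelated_marker > 1) {
    stop("truth classes would overlap: frac_cancer_related + ",
         "frac_cancer_unrelated_marker > 1", call. = FALSE)
  }
  marker_group <- match.arg(marker_group, c("nonresponder", "responder"))
  structure(list(
    n_genes = n_genes, n_platforms = n_platforms,
    genes_per_platform = genes_per_platform,
    n_normal_per_platform = n_normal_per_platform,
    n_responders = n_responders, n_nonresponders = n_nonresponders,
    baseline_spread = baseline_spread, noise_sd = noise_sd,
    frac_cancer_related = frac_cancer_related,
    dereg_freq_nonresp = dereg_freq_nonresp,
    dereg_freq_resp = dereg_freq_resp,
    dereg_effect = dereg_effect,
    frac_cancer_unrelated_marker = frac_cancer_unrelated_marker,
    marker_effect = marker_effect, marker_group = marker_group,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Simulate a multi-platform normal + cancer cohort with planted truth
#'
#' Normal samples of platform `p` are `baseline(g) + N(0, noise_sd)` for the
#' platform's gene subset, passed through a per-platform strictly increasing
#' affine transform (REOs are invariant to it by construction). Cancer
#' samples start from the same normal model over the full gene universe;
#' each planted cancer-related gene is shifted by its planted direction
#' times `dereg_effect` independently per sample with the group-specific
#' frequency, and every sample of `marker_group` additionally carries the
#' small `marker_effect` shift of each cancer-unrelated marker gene.
#' Everything is deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `reo_cohort` with elements
#'   \describe{
#'     \item{normals}{list of [expr_matrix()] objects, one per platform.}
#'     \item{cancers}{[expr_matrix()] of responder + non-responder samples
#'       over the full gene universe.}
#'     \item{truth}{ground truth: `cancer_related` (gene, direction,
#'       planted per-group frequencies), `markers` (gene, direction, group),
#'       `events` (sample_id, gene, direction) per planted per-sample
#'       deregulation, and `baseline` (gene, value).}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_genes = 60, seed = 7))
#' names(cohort$truth)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  baseline <- (seq_len(cfg$n_genes) - 1L) * cfg$baseline_spread + 4
  names(baseline) <- genes
  seeds <- .derive_seeds(cfg$seed, 3L)

  # -- truth assignment ------------------------------------------------------
  n_cr <- round(cfg$frac_cancer_related * cfg$n_genes)
  n_mk <- round(cfg$frac_cancer_unrelated_marker * cfg$n_genes)
  truth <- .with_seed(seeds[1L], {
    picked <- sample(genes, n_cr + n_mk)
    cr <- sort(picked[seq_len(n_cr)])
    mk <- sort(picked[n_cr + seq_len(n_mk)])
    list(
      cancer_related = data.frame(
        gene = cr,
        direction = sample(c("UP", "DOWN"), n_cr, replace = TRUE),
        freq_nonresp = rep(cfg$dereg_freq_nonresp, n_cr),
        freq_resp = rep(cfg$dereg_freq_resp, n_cr),
        stringsAsFactors = FALSE),
      markers = data.frame(
        gene = mk,
        direction = sample(c("UP", "DOWN"), n_mk, replace = TRUE),
        group = rep(cfg$marker_group, n_mk),
        stringsAsFactors = FALSE))
  })

  # -- normal cohorts, one per platform -------------------------------------
  normals <- .with_seed(seeds[2L], {
    lapply(seq_len(cfg$n_platforms), function(p) {
      sub <- sort(sample.int(cfg$n_genes, cfg$genes_per_platform))
      n_s <- cfg$n_normal_per_platform[p]
      vals <- baseline[sub] +
        matrix(stats::rnorm(length(sub) * n_s, sd = cfg$noise_sd),
               length(sub), n_s)
      a <- stats::runif(1, 0.8, 1.25)   # strictly increasing affine map:
      b <- stats::runif(1, -1, 1)       # orderings are preserved exactly
      vals <- a * vals + b
      dimnames(vals) <- list(genes[sub],
                             sprintf("norm_p%d_%02d", p, seq_len(n_s)))
      expr_matrix(vals, group = "normal", dataset = sprintf("platform%d", p))
    })
  })

  # -- cancer cohort over the full universe ---------------------------------
  cancer <- .with_seed(seeds[3L], {
    groups <- c(rep("nonresponder", cfg$n_nonresponders),
                rep("responder", cfg$n_responders))
    ids <- c(sprintf("nonresp_%02d", seq_len(cfg$n_nonresponders)),
             sprintf("resp_%02d", seq_len(cfg$n_responders)))
    n_s <- length(ids)
    vals <- baseline +
      matrix(stats::rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
             cfg$n_genes, n_s)
    dimnames(vals) <- list(genes, ids)
    events <- list()
    tc <- truth$cancer_related
    if (nrow(tc)) {
      freq <- ifelse(groups == "nonresponder",
                     cfg$dereg_freq_nonresp, cfg$dereg_freq_resp)
      for (i in seq_len(nrow(tc))) {
        hit <- stats::runif(n_s) < freq
        sgn <- if (tc$direction[i] == "UP") 1 else -1
        vals[tc$gene[i], hit] <- vals[tc$gene[i], hit] + sgn * cfg$dereg_effect
        if (any(hit)) {
          events[[length(events) + 1L]] <- data.frame(
            sample_id = ids[hit], gene = tc$gene[i],
            direction = tc$direction[i], stringsAsFactors = FALSE)
        }
      }
    }
    tm <- truth$markers
    if (nrow(tm)) {
      in_grp <- groups == cfg$marker_group
      sgn <- ifelse(tm$direction == "UP", 1, -1)
      vals[tm$gene, in_grp] <- vals[tm$gene, in_grp] +
        sgn * cfg$marker_effect
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(sample_id = character(), gene = character(),
                 direction = character(), stringsAsFactors = FALSE)
    list(matrix = expr_matrix(vals, group = groups, dataset = "cancer"),
         events = events)
  })

  truth$events <- cancer$events
  truth$baseline <- data.frame(gene = genes, value = unname(baseline),
                               stringsAsFactors = FALSE)
  structure(list(normals = normals, cancers = cancer$matrix,
                 truth = truth, config = cfg),
            class = "reo_cohort")
}

#' @export
print.reo_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "reo_cohort: %d genes; %d normal platform(s) (%s samples); ",
    "%d cancers (%d nonresponders / %d responders)\n"),
    x$config$n_genes, length(x$normals),
    paste(vapply(x$normals, ncol, integer(1)), collapse = "+"),
    ncol(x$cancers), sum(sample_groups(x$cancers) == "nonresponder"),
    sum(sample_groups(x$cancers) == "responder")))
  cat(sprintf("planted: %d cancer-related, %d marker genes, %d per-sample events\n",
              nrow(x$truth$cancer_related), nrow(x$truth$markers),
              nrow(x$truth$events)))
  invisible(x)
}

#' Simulate a protein-protein interaction edge list with planted link excess
#'
#' Erdos-Renyi background over the gene universe at `base_edge_prob`; any
#' pair with one end in `query_set` and the other in `target_set` is drawn
#' at `boost_edge_prob` instead. No self loops, no duplicate edges;
#' deterministic given `seed`.
#'
#' @param gene_universe character vector of node names.
#' @param query_set,target_set subsets of the universe between which the
#'   edge probability is boosted.
#' @param base_edge_prob,boost_edge_prob edge probabilities in `[0, 1]`,
#'   `boost_edge_prob >= base_edge_prob`.
#' @param seed integer seed.
#' @return data.frame with columns `from`, `to` (one row per edge).
#' @examples
#' simulate_ppi(letters[1:4], "a", "b", 0, 1, seed = 1)
#' @export
simulate_ppi <- function(gene_universe, query_set, target_set,
                         base_edge_prob, boost_edge_prob, seed = 1L) {
  .check_fraction(base_edge_prob, "base_edge_prob")
  .check_fraction(boost_edge_prob, "boost_edge_prob")
  if (boost_edge_prob < base_edge_prob) {
    stop("`boost_edge_prob` must be >= `base_edge_prob`", call. = FALSE)
  }
  gene_universe <- as.character(gene_universe)
  if (anyDuplicated(gene_universe)) stop("duplicate genes in universe", call. = FALSE)
  if (!all(query_set %in% gene_universe) || !all(target_set %in% gene_universe)) {
    stop("query and target sets must be subsets of the universe", call. = FALSE)
  }
  n <- length(gene_universe)
  if (n < 2L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  gi <- gene_universe[idx[, 1L]]
  gj <- gene_universe[idx[, 2L]]
  boosted <- (gi %in% query_set & gj %in% target_set) |
    (gj %in% query_set & gi %in% target_set)
  prob <- ifelse(boosted, boost_edge_prob, base_edge_prob)
  keep <- .with_seed(seed, stats::runif(length(prob)) < prob)
  data.frame(from = gi[keep], to = gj[keep], stringsAsFactors = FALSE)
}

#' Simulate a gene-set collection
#'
#' Draws `n_sets` random gene sets from the universe (sizes uniform in
#' `set_size`), optionally appending caller-supplied sets unchanged (used to
#' plant genuinely enriched categories). Returned in the named-list form
#' that [read_gmt()] produces.
#'
#' @param gene_universe character vector of gene ids.
#' @param n_sets number of random sets.
#' @param set_size length-2 range of set sizes.
#' @param include optional named list of gene vectors appended as-is.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
simulate_gene_sets <- function(gene_universe, n_sets = 20L,
                               set_size = c(10L, 50L), include = NULL,
                               seed = 1L) {
  n_sets <- .check_count(n_sets, "n_sets", positive = FALSE)
  sets <- .with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      k <- sample(seq(set_size[1L], set_size[2L]), 1L)
      sort(sample(gene_universe, min(k, length(gene_universe))))
    })
  })
  names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
  c(include, sets)
}
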