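# minimal hand-built call objects for profile tests
fake_call <- function(sample_id, genes, de = character(), dir = "UP") {
  tab <- data.frame(gene = genes, n_less = 1L, r_down = 0L, n_greater = 1L,
                    r_up = 0L, testable = TRUE, p = 1, fdr = 1,
                    direction = "NONE", stringsAsFactors = FALSE)
  tab$direction[tab$gene %in% de] <- dir
  structure(list(sample_id = sample_id, table = tab, alpha = 0.05,
                 min_partners = 10L, filter_iterations = 0L,
                 converged = TRUE), class = "sample_de_call")
}

test_that("deregulation profiles count exactly, with direction splits", {
  genes <- paste0("g", 1:6)
  calls <- c(
    lapply(1:5, function(i) fake_call(paste0("nr", i), genes,
                                      de = if (i <= 3) "g1" else character())),
    lapply(1:4, function(i) fake_call(paste0("r", i), genes)))
  md <- data.frame(sample_id = c(paste0("nr", 1:5), paste0("r", 1:4)),
                   group = rep(c("nonresponder", "responder"), c(5, 4)),
                   stringsAsFactors = FALSE)
  prof <- build_profile(calls, md)
  expect_equal(attr(prof, "n_nonresp"), 5L)
  expect_equal(attr(prof, "n_resp"), 4L)
  expect_equal(prof$count_nonresp[prof$gene == "g1"], 3)
  expect_equal(prof$count_up_nonresp[prof$gene == "g1"], 3)
  expect_equal(prof$count_down_nonresp[prof$gene == "g1"], 0)
  expect_equal(prof$count_resp[prof$gene == "g1"], 0)
  expect_true(all(prof$count_nonresp[prof$gene != "g1"] == 0))
  expect_error(build_profile(calls, md[-1, ]), "unlabeled")
})

test_that("profiles equal a naive nested-loop recount on simulated calls", {
  co <- simulate_cohort(cohort_config(n_genes = 80, n_responders = 4,
                                      n_nonresponders = 4, seed = 19))
  land <- find_stable_pairs(co$normals)
  fit <- run_rankcomp(co$cancers, land)
  md <- data.frame(sample_id = colnames(co$cancers),
                   group = unname(sample_groups(co$cancers)),
                   stringsAsFactors = FALSE)
  prof <- build_profile(fit, md)
  for (g in sample(prof$gene, 10)) {
    for (grp in c("nonresponder", "responder")) {
      n <- 0L
      for (cl in fit$calls) {
        grp_i <- md$group[md$sample_id == cl$sample_id]
        if (grp_i == grp && cl$table$direction[cl$table$gene == g] != "NONE") {
          n <- n + 1L
        }
      }
      col <- if (grp == "nonresponder") "count_nonresp" else "count_resp"
      expect_equal(prof[[col]][prof$gene == g], n)
    }
  }
})

test_that("background binomial test selects only high-frequency genes", {
  genes <- paste0("g", 1:4)
  calls <- c(
    lapply(1:38, function(i) fake_call(paste0("nr", i), genes,
                                       de = c("g1", if (i <= 10) "g2"))),
    lapply(1:34, function(i) fake_call(paste0("r", i), genes,
                                       de = if (i <= 10) "g2")))
  md <- data.frame(sample_id = c(paste0("nr", 1:38), paste0("r", 1:34)),
                   group = rep(c("nonresponder", "responder"), c(38, 34)),
                   stringsAsFactors = FALSE)
  prof <- build_profile(calls, md)
  sel <- cancer_related_background_test(prof, p0 = 0.05)
  expect_true(all(c("g1", "g2") %in% sel))   # 38/72 and 20/72 at p0 = 0.05
  expect_false("g3" %in% sel)                # never deregulated: p = 1
  pv <- attr(sel, "p_values")
  expect_equal(unname(pv["g3"]), 1)
  # pmf-summation oracle for the 20-of-72 tail at p0 = 0.05
  expect_equal(unname(pv["g2"]), sum(dbinom(20:72, 72, 0.05)),
               tolerance = 1e-12)
  expect_lt(unname(pv["g2"]), 1e-6)
  # saturated null: nothing can be non-randomly frequent
  expect_length(cancer_related_background_test(prof, p0 = 0.999), 0)
  expect_error(cancer_related_background_test(prof, p0 = 0), "fraction")
})

test_that("frequency contrast matches Fisher, is symmetric and monotone", {
  genes <- paste0("g", 1:3)
  # g1: 20/38 vs 2/34; g2: 5/20-style equal frequencies; g3: nothing
  calls <- c(
    lapply(1:38, function(i) fake_call(paste0("nr", i), genes,
                                       de = c(if (i <= 20) "g1",
                                              if (i <= 10) "g2"))),
    lapply(1:34, function(i) fake_call(paste0("r", i), genes,
                                       de = c(if (i <= 2) "g1",
                                              if (i <= 9) "g2"))))
  md <- data.frame(sample_id = c(paste0("nr", 1:38), paste0("r", 1:34)),
                   group = rep(c("nonresponder", "responder"), c(38, 34)),
                   stringsAsFactors = FALSE)
  prof <- build_profile(calls, md)
  fc <- frequency_difference_test(prof)
  expect_equal(fc$p[fc$gene == "g1"],
               stats::fisher.test(rbind(c(20, 18), c(2, 32)))$p.value,
               tolerance = 1e-7)
  expect_true("g1" %in% selected_genes(fc))
  expect_false("g3" %in% selected_genes(fc))
  expect_equal(fc$p[fc$gene == "g3"], 1)
  # swapping the group labels leaves the two-sided p unchanged
  md_swap <- md
  md_swap$group <- c(nonresponder = "responder",
                     responder = "nonresponder")[md$group]
  fc_swap <- frequency_difference_test(build_profile(calls, md_swap))
  expect_equal(fc$p, fc_swap$p)
  # selections shrink as the threshold tightens
  for (alpha in c(0.05, 0.01, 0.001)) {
    s1 <- selected_genes(frequency_difference_test(prof, alpha_fdr = alpha))
    s2 <- selected_genes(frequency_difference_test(prof,
                                                   alpha_fdr = alpha / 5))
    expect_true(all(s2 %in% s1))
  }
})

test_that("equal-frequency profiles are essentially never selected", {
  genes <- paste0("g", 1:40)
  set.seed(29)
  n_sel <- vapply(1:10, function(s) {
    set.seed(s)
    cnt_nr <- rbinom(40, 20, 0.3)
    cnt_r <- rbinom(40, 20, 0.3)
    calls <- c(
      lapply(1:20, function(i) fake_call(paste0("nr", i), genes,
                                         de = genes[cnt_nr >= i])),
      lapply(1:20, function(i) fake_call(paste0("r", i), genes,
                                         de = genes[cnt_r >= i])))
    md <- data.frame(sample_id = c(paste0("nr", 1:20), paste0("r", 1:20)),
                     group = rep(c("nonresponder", "responder"), c(20, 20)),
                     stringsAsFactors = FALSE)
    length(selected_genes(frequency_difference_test(build_profile(calls, md))))
  }, numeric(1))
  expect_lt(mean(n_sel), 0.5)
})

test_that("class partition obeys its set identities", {
  merged <- directed_gene_list(paste0("g", 1:10),
                               rep(c("UP", "DOWN"), 5), "merged")
  pc <- partition_classes(c("g1", "g5", "x9"), merged)
  expect_setequal(pc$shared_with_group_de, c("g1", "g5"))
  expect_setequal(pc$cancer_unrelated, paste0("g", c(2:4, 6:10)))
  expect_equal(unname(pc$sizes["cancer_unrelated"]),
               unname(pc$sizes["merged_group_de"] - pc$sizes["shared"]))
  # disjoint inputs
  pc2 <- partition_classes(c("y1", "y2"), merged)
  expect_length(pc2$shared_with_group_de, 0)
  expect_equal(length(pc2$cancer_unrelated), 10)
  # cancer-related superset of merged
  pc3 <- partition_classes(paste0("g", 1:10), merged)
  expect_length(pc3$cancer_unrelated, 0)
})
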