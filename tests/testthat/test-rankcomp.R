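test_that("fisher_exact_2x2 handles degenerate and textbook tables", {
  expect_equal(fisher_exact_2x2(0, 10, 0, 12), 1.0)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / choose(10, 5))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "non-negative")
})

test_that("fisher_exact_2x2 agrees with enumeration and stats::fisher.test", {
  set.seed(21)
  for (i in 1:40) {
    cells <- rpois(4, 6)
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher2x2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-7)
  }
})

test_that("reversal counts behave at the extremes and match a hand fixture", {
  co <- simulate_cohort(cohort_config(n_genes = 30, genes_per_platform = 30,
                                      noise_sd = 0, n_responders = 2,
                                      n_nonresponders = 2, seed = 3))
  land <- find_stable_pairs(co$normals)
  base <- co$truth$baseline$value
  names(base) <- co$truth$baseline$gene
  rc <- reversal_counts(base, "gene_0015", land)
  expect_equal(rc$r_up, 0)
  expect_equal(rc$r_down, 0)
  expect_equal(rc$n_less, 14)
  expect_equal(rc$n_greater, 15)
  moved <- base
  moved["gene_0015"] <- max(base) + 1  # above every partner
  rc2 <- reversal_counts(moved, "gene_0015", land)
  expect_equal(rc2$r_up, rc2$n_greater)
  expect_equal(rc2$r_down, 0)

  # 6-gene hand-listed stable pairs vs exhaustive per-pair check
  genes <- paste0("g", 1:6)
  hi <- c("g2", "g3", "g4", "g5", "g6", "g6")
  lo <- c("g1", "g1", "g2", "g2", "g3", "g5")
  ss <- manual_stable_set(genes, hi, lo)
  v <- c(g1 = 3.0, g2 = 1.0, g3 = 5.0, g4 = 2.0, g5 = 6.0, g6 = 4.0)
  for (g in genes) {
    got <- reversal_counts(v, g, ss)
    n_less <- sum(hi == g); r_down <- sum(hi == g & v[g] < v[lo[hi == g]])
    n_greater <- sum(lo == g); r_up <- sum(lo == g & v[hi[lo == g]] < v[g])
    expect_equal(got$n_less, n_less)
    expect_equal(got$r_down, unname(r_down))
    expect_equal(got$n_greater, n_greater)
    expect_equal(got$r_up, unname(r_up))
  }
})

test_that("a planted jump among 200 genes is called UP, with filter retention", {
  co <- simulate_cohort(cohort_config(n_genes = 200, genes_per_platform = 200,
                                      frac_cancer_related = 0,
                                      frac_cancer_unrelated_marker = 0,
                                      n_responders = 2, n_nonresponders = 2,
                                      seed = 17))
  land <- find_stable_pairs(co$normals)
  v <- co$cancers[, 1]
  names(v) <- rownames(co$cancers)
  # a low-quartile gene (with stable partners on both sides) jumps to the top
  v["gene_0030"] <- max(v) + 1
  call <- call_de_single_sample(v, land, sample_id = "jump")
  row <- call$table[call$table$gene == "gene_0030", ]
  expect_equal(row$direction, "UP")
  # none of its reversal partners are themselves DE: filtering keeps it
  filt <- filter_de_calls(call, land, v)
  frow <- filt$table[filt$table$gene == "gene_0030", ]
  expect_equal(frow$direction, "UP")
  expect_equal(frow$p, row$p)
})

test_that("per-gene p-value vector equals a naive fisher.test reference", {
  co <- simulate_cohort(cohort_config(n_genes = 50, genes_per_platform = 50,
                                      n_responders = 2, n_nonresponders = 2,
                                      seed = 23))
  land <- find_stable_pairs(co$normals)
  v <- co$cancers[, 3]
  names(v) <- rownames(co$cancers)
  call <- call_de_single_sample(v, land, min_partners = 1)
  # naive loop: per gene, rebuild the table from the raw pair list
  genes <- land$genes
  hi <- land$genes[land$pairs[, "hi"]]
  lo <- land$genes[land$pairs[, "lo"]]
  for (g in genes[seq(1, 50, by = 3)]) {
    below <- lo[hi == g]
    above <- hi[lo == g]
    r_down <- sum(v[g] < v[below])
    r_up <- sum(v[g] > v[above])
    p_ref <- stats::fisher.test(rbind(
      c(r_down, length(below) - r_down),
      c(r_up, length(above) - r_up)))$p.value
    expect_equal(call$table$p[call$table$gene == g], p_ref, tolerance = 1e-7)
  }
})

test_that("coupled-pair filtering removes the dependent gene, keeps the driver", {
  # M's entire evidence is reversals against strong genes S1..S10; each S
  # gene's evidence comes from 30 independent fillers. After filtering,
  # every S stays and M (whose table empties once the S are excluded) drops.
  s_genes <- sprintf("S%02d", 1:10)
  f_genes <- sprintf("F%02d", 1:30)   # normally below every S
  l_genes <- sprintf("L%02d", 1:10)   # normally below M (M's n_less side)
  t_genes <- sprintf("T%02d", 1:5)    # normally above every S
  genes <- c(l_genes, "M", s_genes, f_genes, t_genes)
  hi <- c(rep("M", 10), rep(s_genes, each = 31), rep(t_genes, each = 10))
  lo <- c(l_genes,
          as.vector(vapply(s_genes, function(s) c("M", f_genes),
                           character(31))),
          rep(s_genes, times = 5))
  ss <- manual_stable_set(genes, hi, lo)
  # baseline-ish values: L < M < F < S < T
  v <- c(stats::setNames(seq(1, 2, length.out = 10), l_genes),
         M = 3,
         stats::setNames(seq(6, 7, length.out = 10), s_genes),
         stats::setNames(seq(4, 5, length.out = 30), f_genes),
         stats::setNames(seq(8, 9, length.out = 5), t_genes))
  v[s_genes] <- 0  # every S crashes below everything: strong DOWN
  call <- call_de_single_sample(v, ss, min_partners = 5)
  raw_de <- call$table$gene[call$table$direction != "NONE"]
  expect_true(all(c("M", s_genes) %in% raw_de))
  expect_equal(call$table$direction[call$table$gene == "M"], "UP")
  filt <- filter_de_calls(call, ss, v)
  kept <- filt$table$gene[filt$table$direction != "NONE"]
  expect_setequal(kept, s_genes)       # marginal M removed, drivers kept
  expect_gt(filt$filter_iterations, 0)
  expect_true(filt$converged)
  # manual recomputation of M's reduced table: no usable partners remain
  # on the n_greater side, so its Fisher table is [0,10 | 0,0] with p = 1
  expect_equal(fisher_exact_2x2(0, 10, 0, 0), 1)
})

test_that("filtering is monotone and a no-call sample passes through", {
  co <- simulate_cohort(cohort_config(n_genes = 80, n_responders = 3,
                                      n_nonresponders = 3, seed = 31))
  land <- find_stable_pairs(co$normals)
  for (sid in colnames(co$cancers)[1:3]) {
    v <- co$cancers[, sid]
    names(v) <- rownames(co$cancers)
    raw <- call_de_single_sample(v, land, sample_id = sid)
    filt <- filter_de_calls(raw, land, v)
    raw_de <- raw$table$gene[raw$table$direction != "NONE"]
    filt_de <- filt$table$gene[filt$table$direction != "NONE"]
    expect_true(all(filt_de %in% raw_de))
  }
  # a sample drawn straight from the normal model: expect no calls at all
  base <- co$truth$baseline$value
  names(base) <- co$truth$baseline$gene
  quiet <- call_de_single_sample(base, land)
  expect_equal(sum(quiet$table$direction != "NONE"), 0)
  fq <- filter_de_calls(quiet, land, base)
  expect_equal(fq$filter_iterations, 0)
})

test_that("negating expression swaps call directions with identical p-values", {
  co <- simulate_cohort(cohort_config(n_genes = 60, n_responders = 2,
                                      n_nonresponders = 2, seed = 37))
  land_pos <- find_stable_pairs(co$normals)
  land_neg <- find_stable_pairs(lapply(co$normals, function(m) -strip_expr(m)))
  v <- co$cancers[, 2]
  names(v) <- rownames(co$cancers)
  a <- call_de_single_sample(v, land_pos)
  b <- call_de_single_sample(-v, land_neg)
  expect_equal(a$table$p, b$table$p[match(a$table$gene, b$table$gene)])
  swap <- c(UP = "DOWN", DOWN = "UP", NONE = "NONE")
  expect_identical(unname(swap[a$table$direction]),
                   b$table$direction[match(a$table$gene, b$table$gene)])
})

test_that("run_rankcomp is sample-order equivariant and null on normal copies", {
  co <- simulate_cohort(cohort_config(n_genes = 60, n_responders = 3,
                                      n_nonresponders = 3, seed = 41))
  land <- find_stable_pairs(co$normals)
  fit <- run_rankcomp(co$cancers, land)
  perm <- c(4, 1, 6, 2, 5, 3)
  fit_p <- run_rankcomp(co$cancers[, perm], land)
  for (sid in colnames(co$cancers)) {
    expect_identical(fit$calls[[sid]]$table, fit_p$calls[[sid]]$table)
  }
  # cancer matrix made of copies of one normal-model draw: no planted signal
  base <- co$truth$baseline$value
  set.seed(99)
  one <- base + rnorm(length(base), sd = 0.2)
  copies <- matrix(one, length(base), 4,
                   dimnames = list(co$truth$baseline$gene, paste0("c", 1:4)))
  fit0 <- run_rankcomp(copies, land)
  expect_lt(fit0$mean_de_per_sample, 0.05 * length(land$genes))
})
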