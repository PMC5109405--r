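make_two_group <- function(g = 20, na = 3, nb = 3, seed = 1, shift = NULL) {
  set.seed(seed)
  m <- random_expr(g, na + nb, sd = 0.5)
  if (!is.null(shift)) m[names(shift), seq_len(na)] <-
    m[names(shift), seq_len(na)] + shift
  list(m = m, a = colnames(m)[seq_len(na)], b = colnames(m)[na + seq_len(nb)])
}

test_that("a gene ranked first in every comparison attains the minimal RP", {
  d <- make_two_group(15, 3, 3, seed = 2)
  d$m["g001", d$a] <- d$m["g001", d$a] + 50  # always the most up in A
  rp <- rank_product_de(d$m, d$a, d$b, n_permutations = 30, seed = 4)
  tab <- rp$table
  expect_equal(tab$rp_up[tab$gene == "g001"], 1)
  expect_equal(min(tab$p_up), tab$p_up[tab$gene == "g001"])
})

test_that("exact permutation p equals the full enumeration oracle", {
  d <- make_two_group(5, 2, 2, seed = 3)
  rp <- rank_product_de(d$m, d$a, d$b, exact = TRUE)
  for (i in seq_len(5)) {
    expect_equal(rp$table$p_up[i],
                 oracle_rank_product_p(log(rp$table$rp_up[i]), 5, 4),
                 tolerance = 1e-12)
    expect_equal(rp$table$p_down[i],
                 oracle_rank_product_p(log(rp$table$rp_down[i]), 5, 4),
                 tolerance = 1e-12)
  }
})

test_that("swapping the group labels swaps the up and down statistics", {
  d <- make_two_group(12, 3, 4, seed = 5)
  rp_ab <- rank_product_de(d$m, d$a, d$b, n_permutations = 25, seed = 7)
  rp_ba <- rank_product_de(d$m, d$b, d$a, n_permutations = 25, seed = 7)
  expect_equal(rp_ab$table$rp_up, rp_ba$table$rp_down)
  expect_equal(rp_ab$table$rp_down, rp_ba$table$rp_up)
  expect_equal(rp_ab$table$p_up, rp_ba$table$p_down)
})

test_that("permutation p is monotone in RP and the fit is seed-deterministic", {
  d <- make_two_group(30, 3, 3, seed = 8)
  rp <- rank_product_de(d$m, d$a, d$b, n_permutations = 40, seed = 11)
  o <- order(rp$table$rp_up)
  expect_true(all(diff(rp$table$p_up[o]) >= -1e-15))
  rp2 <- rank_product_de(d$m, d$a, d$b, n_permutations = 40, seed = 11)
  expect_identical(rp$table, rp2$table)
  expect_error(rank_product_de(d$m, d$a, c(d$a[1], d$b[-1]),
                               n_permutations = 5), "overlap")
  expect_error(rank_product_de(d$m, d$a[1], d$b, n_permutations = 5),
               "2 samples")
})

test_that("strong consistent shifts are called with the right direction", {
  shift <- c(g001 = 3, g002 = -3)
  d <- make_two_group(40, 5, 5, seed = 13, shift = shift)
  rp <- rank_product_de(d$m, d$a, d$b, n_permutations = 60, seed = 17)
  de <- de_gene_list(rp, source_label = "sim")
  expect_true("g001" %in% de$gene[de$direction == "UP"])
  expect_true("g002" %in% de$gene[de$direction == "DOWN"])
})

test_that("directed gene lists enforce their invariant", {
  expect_error(directed_gene_list(c("a", "a"), c("UP", "DOWN")), "once")
  expect_error(directed_gene_list("a", "SIDEWAYS"), "UP/DOWN")
})

test_that("concordance-and-merge reproduces the worked examples", {
  a <- directed_gene_list(c("g1", "g2", "g3"), c("UP", "UP", "DOWN"), "A")
  b <- directed_gene_list(c("g2", "g3", "g4"), c("UP", "UP", "DOWN"), "B")
  res <- concordance_and_merge(a, b)
  expect_equal(res$concordance$k, 2L)
  expect_equal(res$concordance$s, 1L)
  expect_equal(res$concordance$score, 0.5)
  got <- res$merged[order(res$merged$gene), ]
  expect_equal(got$gene, c("g1", "g2", "g4"))
  expect_equal(got$direction, c("UP", "UP", "DOWN"))

  # disjoint lists: undefined concordance, merged is the plain union
  da <- directed_gene_list(paste0("a", 1:3), rep("UP", 3))
  db <- directed_gene_list(paste0("b", 1:4), rep("DOWN", 4))
  r2 <- concordance_and_merge(da, db)
  expect_true(r2$concordance$undefined)
  expect_equal(nrow(r2$merged), 7)

  # k = 10, s = 8 reproduces the binomial pmf sum
  ga <- directed_gene_list(paste0("g", 1:10),
                           rep(c("UP", "DOWN"), each = 5))
  gb <- directed_gene_list(paste0("g", 1:10),
                           c(rep("UP", 5), "UP", "UP", rep("DOWN", 3)))
  r3 <- concordance_and_merge(ga, gb)
  expect_equal(r3$concordance$k, 10L)
  expect_equal(r3$concordance$s, 8L)
  expect_equal(r3$concordance$p_value, 56 / 1024)
})

test_that("merge size identity and commutativity hold on random lists", {
  set.seed(19)
  for (i in 1:20) {
    genes <- paste0("g", 1:15)
    a <- directed_gene_list(sample(genes, 8),
                            sample(c("UP", "DOWN"), 8, TRUE))
    b <- directed_gene_list(sample(genes, 6),
                            sample(c("UP", "DOWN"), 6, TRUE))
    r <- concordance_and_merge(a, b)
    k <- r$concordance$k; s <- r$concordance$s
    expect_equal(nrow(r$merged), nrow(a) + nrow(b) - k - (k - s))
    r_rev <- concordance_and_merge(b, a)
    expect_equal(r_rev$concordance$k, k)
    expect_equal(r_rev$concordance$s, s)
    m1 <- r$merged[order(r$merged$gene), ]
    m2 <- r_rev$merged[order(r_rev$merged$gene), ]
    expect_equal(m1$gene, m2$gene)
    expect_equal(m1$direction, m2$direction)
  }
})

test_that("null cohorts give uniform-like p-values and few BH calls", {
  # random splits of exchangeable samples: the dependence-preserving array
  # null should keep p-values centred and the BH call list near-empty
  ps <- NULL; n_calls <- 0
  for (s in 1:6) {
    set.seed(100 + s)
    m <- random_expr(50, 8, sd = 1)
    rp <- rank_product_de(m, colnames(m)[1:4], colnames(m)[5:8],
                          n_permutations = 40, seed = s)
    ps <- c(ps, rp$table$p_up)
    n_calls <- n_calls + nrow(de_gene_list(rp))
  }
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.62)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_lt(n_calls / (6 * 50), 0.02)
})
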