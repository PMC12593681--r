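test_that("perfectly correlated genes give a unit-weight positive edge", {
  set.seed(1)
  base <- rnorm(10)
  v <- mat_with_names(c(base, base, rnorm(10)), c("g1", "g2", "g3"))
  m <- omics_matrix(v, "expr", "quantitative")
  net <- infer_correlation_network(m, "pearson", min_abs_cor = 0.5, max_fdr = 0.05)
  e <- net$edges[net$edges$source == "g1" & net$edges$target == "g2", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 1)
  expect_equal(e$sign, 1L)
})

test_that("constant genes are excluded without crashing", {
  v <- mat_with_names(c(rep(5, 10), rnorm(10), rnorm(10)), c("flat", "g2", "g3"))
  m <- omics_matrix(v, "expr", "quantitative")
  expect_message(net <- infer_correlation_network(m), "constant_profile")
  expect_false("flat" %in% net$nodes)
  expect_equal(net$inference$excluded_genes, "flat")
})

test_that("correlation inference validates its preconditions", {
  m <- omics_matrix(mat_with_names(rnorm(4), c("a", "b")), "x", "quantitative")
  expect_error(infer_correlation_network(m), "at least 3 samples")
  m2 <- omics_matrix(mat_with_names(rnorm(8), c("a", "b")), "x", "quantitative")
  expect_error(infer_correlation_network(m2, min_abs_cor = 1.2), "\\(0, 1\\)")
})

test_that("correlation edge sets match the brute-force all-pairs oracle", {
  for (method in c("pearson", "spearman")) {
    v <- planted_block_matrix(seed = if (method == "pearson") 42 else 43)
    m <- omics_matrix(v, "expr", "quantitative")
    net <- infer_correlation_network(m, method, min_abs_cor = 0.5, max_fdr = 0.05)
    oracle <- oracle_correlation_edges(v, method, 0.5, 0.05)
    expect_gt(nrow(net$edges), 20)  # planted block produces real signal
    expect_equal(edge_key(net$edges), edge_key(oracle))
  }
})

test_that("raising thresholds never adds correlation edges", {
  v <- planted_block_matrix(seed = 99, rho = 0.7)
  m <- omics_matrix(v, "expr", "quantitative")
  loose <- infer_correlation_network(m, min_abs_cor = 0.4, max_fdr = 0.1)
  tight_cor <- infer_correlation_network(m, min_abs_cor = 0.6, max_fdr = 0.1)
  tight_fdr <- infer_correlation_network(m, min_abs_cor = 0.4, max_fdr = 0.01)
  expect_true(all(edge_key(tight_cor$edges) %in% edge_key(loose$edges)))
  expect_true(all(edge_key(tight_fdr$edges) %in% edge_key(loose$edges)))
})

test_that("methylation binarization uses the >= threshold convention", {
  v <- mat_with_names(c(0.30, 0.29, 0, 1), c("a", "b"))
  m <- omics_matrix(v, "meth", "beta")
  b <- binarize_methylation(m, 0.30)
  expect_equal(b$modality, "binary")
  expect_equal(unname(b$values[, 1]), c(1, 0))  # 0.30 -> 1, 0.29 -> 0
  z <- binarize_methylation(omics_matrix(mat_with_names(rep(0, 4), c("a", "b")),
                                         "meth", "beta"), 0.3)
  expect_true(all(z$values == 0))
  expect_error(binarize_methylation(m, 1), "\\(0, 1\\)")
})

test_that("CNV splits into disjoint amplification/deletion event matrices", {
  v <- mat_with_names(c(2, 0,   -1, 1,   0, -2), c("a", "b", "c"))
  m <- omics_matrix(v, "cnv", "cnv")
  halves <- split_cnv(m)
  expect_equal(unname(halves$amplification$values[, 1]), c(1, 0, 0))
  expect_equal(unname(halves$deletion$values[, 1]), c(0, 1, 0))
  expect_equal(unname(halves$amplification$values["c", ]), c(0, 0))
  expect_equal(unname(halves$deletion$values["c", ]), c(0, 1))
  # the two binarizations never overlap
  expect_true(all(halves$amplification$values * halves$deletion$values == 0))
})

test_that("Fisher 2x2 p-values match the independent stats::fisher.test", {
  expect_equal(round(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 4),
               0.4857)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
  set.seed(5)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("identical binary profiles yield a co-occurrence edge", {
  x <- rep(c(1, 0), each = 12)
  v <- mat_with_names(c(x, x), c("a", "b"), sprintf("s%d", 1:24))
  m <- omics_matrix(v, "meth", "binary")
  net <- infer_cooccurrence_network(m, 0.05, 0.05)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$sign, 1L)
  # weight equals the joint-presence cell GOF statistic from chisq.test
  o11 <- 12; e11 <- 0.25
  ref <- unname(chisq.test(c(o11, 12), p = c(e11, 0.75), correct = FALSE)$statistic)
  expect_equal(net$edges$weight, ref)
})

test_that("degenerate binary genes are skipped and reported", {
  v <- mat_with_names(c(rep(0, 10), rep(c(1, 0), 5), rep(c(0, 1), 5)),
                      c("dead", "a", "b"))
  m <- omics_matrix(v, "meth", "binary")
  expect_message(net <- infer_cooccurrence_network(m), "constant_status")
  expect_false("dead" %in% net$nodes)
})

test_that("co-occurrence edge sets match the brute-force cascade oracle", {
  set.seed(11)
  # modules of synchronized genes + independent background, 60 genes
  st <- matrix(rbinom(60 * 40, 1, 0.3), 60, 40,
               dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:40)))
  ev <- rbinom(40, 1, 0.4)
  st[1:8, ] <- matrix(ev, 8, 40, byrow = TRUE)
  ev2 <- rbinom(40, 1, 0.5)
  st[9:14, ] <- matrix(ev2, 6, 40, byrow = TRUE)
  m <- omics_matrix(st, "meth", "binary")
  net <- suppressMessages(infer_cooccurrence_network(m, 0.05, 0.05))
  oracle <- suppressWarnings(oracle_cooccurrence_edges(
    st[rownames(st) %in% net$nodes, ], 0.05, 0.05))
  expect_gt(nrow(net$edges), 10)
  expect_equal(edge_key(net$edges), edge_key(oracle))
  # weights agree too
  ord <- order(net$edges$source, net$edges$target)
  ord_o <- order(oracle$source, oracle$target)
  expect_equal(net$edges$weight[ord], oracle$weight[ord_o], tolerance = 1e-10)
})

test_that("independent binary pairs rarely produce a false edge", {
  # Monte-Carlo type-I check: a single independent pair at alpha = 0.05
  false_edges <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    v <- matrix(rbinom(2 * 200, 1, 0.5), 2, 200,
                dimnames = list(c("a", "b"), sprintf("s%d", 1:200)))
    m <- omics_matrix(v, "x", "binary")
    net <- suppressMessages(infer_cooccurrence_network(m, 0.05, 0.05))
    false_edges <- false_edges + nrow(net$edges)
  }
  expect_lte(false_edges, 5L)
})

test_that("inferred networks are invariant to gene order", {
  v <- planted_block_matrix(seed = 3, n_genes = 20, block = 6)
  m <- omics_matrix(v, "expr", "quantitative")
  net1 <- infer_correlation_network(m)
  m2 <- omics_matrix(v[rev(rownames(v)), ], "expr", "quantitative")
  net2 <- infer_correlation_network(m2)
  expect_equal(edge_key(net1$edges), edge_key(net2$edges))
  o1 <- net1$edges[order(net1$edges$source, net1$edges$target), ]
  o2 <- net2$edges[order(net2$edges$source, net2$edges$target), ]
  expect_equal(o1$weight, o2$weight)
  expect_equal(o1$adjusted_p, o2$adjusted_p)
})

test_that("network edge lists round-trip through the TSV writer", {
  v <- planted_block_matrix(seed = 3, n_genes = 20, block = 6)
  net <- infer_correlation_network(omics_matrix(v, "expr", "quantitative"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$source, net$edges$source)
  expect_equal(back$weight, net$edges$weight, tolerance = 1e-12)
  expect_true(all(back$layer == "expr"))
})
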