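test_that("transition columns follow the stated block rules on a manual fixture", {
  # single layer, genes A-B, drug X targeting A, lambda = 0.5
  n1 <- omics_network("L1", nodes = c("A", "B"),
                      edges = data.frame(source = "A", target = "B", weight = 1,
                                         sign = 1L, statistic = 1, adjusted_p = 0))
  mx <- build_multiplex(list(n1))
  db <- drug_gene_bipartite(data.frame(drug = "X", gene = "A"))
  mh <- build_mh_network(mx, filter_bipartite(db, mx$genes))
  H <- as.matrix(build_transition_matrix(mh, delta = 0.5, lambda = 0.5)$H)
  expect_equal(H[, "A@L1"], c("A@L1" = 0, "B@L1" = 0.5, "X" = 0.5))
  expect_equal(H[, "B@L1"], c("A@L1" = 1, "B@L1" = 0, "X" = 0))
  expect_equal(H[, "X"], c("A@L1" = 0.5, "B@L1" = 0, "X" = 0.5))
})

test_that("an intra-isolated projection redirects its mass across layers", {
  n1 <- omics_network("L1", nodes = c("A", "B"))
  n2 <- omics_network("L2", nodes = c("A", "B"))
  mh <- build_mh_network(build_multiplex(list(n1, n2)),
                         filter_bipartite(
                           drug_gene_bipartite(data.frame(drug = "X", gene = "B")),
                           c("A", "B")))
  H <- as.matrix(build_transition_matrix(mh, delta = 0.3, lambda = 0.5)$H)
  expect_equal(H["A@L2", "A@L1"], 1)  # no intra neighbours, no drugs
})

test_that("H stays column-stochastic over the delta/lambda fuzz grid", {
  grid <- expand.grid(delta = c(0, 0.25, 0.5, 0.75, 1),
                      lambda = c(0, 0.25, 0.5, 0.75, 1))
  fixtures <- list(
    suppressMessages(random_mh_network(15, 3, 4, seed = 1)),
    suppressMessages(random_mh_network(10, 2, 0, seed = 2)),   # no drugs
    suppressMessages(random_mh_network(8, 1, 3, seed = 3)),    # single layer
    suppressMessages(random_mh_network(12, 4, 5, edge_prob = 0, seed = 4)), # isolated genes
    suppressMessages(random_mh_network(12, 2, 4,
                                       strategy = "neighborhood_coupling",
                                       seed = 5)))
  for (mh in fixtures) {
    for (i in seq_len(nrow(grid))) {
      for (w in c(FALSE, TRUE)) {
        H <- build_transition_matrix(mh, grid$delta[i], grid$lambda[i],
                                     weighted = w)
        expect_true(all(abs(Matrix::colSums(H$H) - 1) < 1e-12))
        expect_true(all(H$H@x >= 0))
      }
    }
  }
  expect_error(build_transition_matrix(fixtures[[1]], delta = 1.5), "\\[0, 1\\]")
})

test_that("restart walk solves the two-node case in closed form", {
  n1 <- omics_network("L1", nodes = c("A", "B"),
                      edges = data.frame(source = "A", target = "B", weight = 1,
                                         sign = 1L, statistic = 1, adjusted_p = 0))
  mh <- build_mh_network(build_multiplex(list(n1)),
                         filter_bipartite(drug_gene_bipartite(
                           data.frame(drug = character(), gene = character())[0, ]),
                           c("A", "B")) |> suppressWarnings())
  H <- build_transition_matrix(mh)
  p <- rwr_from_seed(H, "A", r = 0.5, tol = 1e-14)
  expect_equal(unname(p$p), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_true(p$converged)
})

test_that("r = 1 returns the restart profile exactly", {
  mh <- suppressMessages(random_mh_network(10, 2, 3, seed = 6))
  H <- build_transition_matrix(mh)
  sp <- seed_profile(H, "g01")
  p <- rwr_from_seed(H, sp, r = 1)
  expect_identical(unname(p$p), unname(sp$p_rs))
})

test_that("seed profiles place tau mass on the right projections", {
  mh <- suppressMessages(random_mh_network(6, 3, 2, seed = 8))
  H <- build_transition_matrix(mh)
  sp <- seed_profile(H, "g02", tau = c(0.6, 0.3, 0.1))
  got <- sp$p_rs[sp$p_rs > 0]
  expect_equal(unname(got), c(0.6, 0.3, 0.1))
  expect_equal(names(got), paste0("g02@layer", 1:3))
  dsp <- seed_profile(H, H$index$drugs[1])
  expect_equal(sum(dsp$p_rs > 0), 1L)
  expect_error(seed_profile(H, "nope"), "unknown seed")
  expect_error(seed_profile(H, "g02", tau = c(1, 1, 1)), "summing to 1")
})

test_that("power iteration matches the direct linear solve on random fixtures", {
  for (seed in 1:8) {
    mh <- suppressMessages(random_mh_network(
      n_genes = sample(5:25, 1), n_layers = sample(1:4, 1),
      n_drugs = sample(0:5, 1), seed = seed))
    H <- build_transition_matrix(mh, delta = runif(1), lambda = runif(1))
    sid <- sample(c(H$index$genes, H$index$drugs), 1)
    sp <- seed_profile(H, sid)
    r <- runif(1, 0.1, 0.9)
    p <- rwr_from_seed(H, sp, r = r, tol = 1e-12)
    ref <- oracle_rwr_solve(H$H, sp$p_rs, r)
    expect_lt(sum(abs(p$p - ref)), 1e-8)
    expect_lt(abs(sum(p$p) - 1), 1e-8)
  }
})

test_that("proximity mass on the seed grows as the restart rate rises", {
  mh <- suppressMessages(random_mh_network(12, 3, 3, seed = 10))
  H <- build_transition_matrix(mh)
  sp <- seed_profile(H, "g03")
  self_mass <- vapply(c(0.2, 0.5, 0.8, 0.95), function(r) {
    agg <- aggregate_proximity(rwr_from_seed(H, sp, r = r, tol = 1e-12),
                               H$index, "sum")
    agg[["g03"]]
  }, numeric(1))
  expect_true(all(diff(self_mass) > 0))
})

test_that("layer aggregation follows the stated formulas", {
  mh <- suppressMessages(random_mh_network(4, 2, 1, seed = 12))
  H <- build_transition_matrix(mh)
  ix <- H$index
  p <- rwr_from_seed(H, "g01", r = 0.5, tol = 1e-12)
  gm <- matrix(p$p[seq_len(ix$G * ix$L)], ix$G, ix$L)
  manual_geo <- apply(gm, 1, function(v) if (any(v == 0)) 0 else exp(mean(log(v))))
  manual_sum <- rowSums(gm)
  drugs <- p$p[ix$G * ix$L + seq_along(ix$drugs)]
  geo <- aggregate_proximity(p, ix, "geometric")
  expect_equal(unname(geo), unname(c(manual_geo, drugs) / sum(c(manual_geo, drugs))))
  agg_sum <- aggregate_proximity(p, ix, "sum")
  expect_equal(unname(agg_sum), unname(c(manual_sum, drugs) / sum(c(manual_sum, drugs))))
  expect_equal(sum(aggregate_proximity(p, ix, "arithmetic")), 1)
  expect_error(aggregate_proximity(p, ix, "harmonic"))
})

test_that("geometric aggregation annihilates on any zero layer", {
  # layer-major layout: (a@1, b@1, a@2, b@2) -> a = (0.1, 0.4), b = (0, 0.5)
  fake <- structure(list(seed_id = "s", p = c(0.1, 0, 0.4, 0.5), iterations = 1L,
                         converged = TRUE), class = "proximity_vector")
  ix <- list(G = 2L, L = 2L, genes = c("a", "b"), drugs = character())
  agg <- aggregate_proximity(fake, ix, "geometric")
  expect_equal(unname(agg[["a"]]), 0.2 / 0.2)  # sqrt(0.1*0.4)=0.2, b -> 0
  expect_equal(unname(agg[["b"]]), 0)
})

test_that("the similarity matrix composes seed-wise runs and is column-stochastic", {
  mh <- suppressMessages(random_mh_network(8, 2, 2, seed = 14))
  cfg <- run_config(r = 0.6, tol = 1e-12)
  S <- build_similarity_matrix(mh, cfg)
  n <- length(mh$multiplex$genes) + length(mh$bipartite$drugs)
  expect_equal(dim(S), c(n, n))
  expect_true(all(abs(colSums(S) - 1) < 1e-8))
  H <- build_transition_matrix(mh, cfg$delta, cfg$lambda)
  ref <- aggregate_proximity(
    rwr_from_seed(H, seed_profile(H, "g03"), r = 0.6, tol = 1e-12),
    H$index, cfg$aggregation)
  expect_equal(S[, "g03"], ref)
  expect_false(is.null(attr(S, "convergence")))
})

test_that("similarity columns shift boundedly under delta/lambda perturbation", {
  mh <- suppressMessages(random_mh_network(10, 3, 3, seed = 15))
  base <- build_similarity_matrix(mh, run_config(delta = 0.5, lambda = 0.5))
  for (cfg in list(run_config(delta = 0.4, lambda = 0.5),
                   run_config(delta = 0.6, lambda = 0.5),
                   run_config(delta = 0.5, lambda = 0.4),
                   run_config(delta = 0.5, lambda = 0.6))) {
    pert <- build_similarity_matrix(mh, cfg)
    l1 <- max(colSums(abs(pert - base)))
    expect_lt(l1, 0.5)  # bounded drift, not a blow-up
  }
})

test_that("layer contributions renormalize the stored projection slice", {
  mh <- suppressMessages(random_mh_network(6, 3, 2, seed = 16))
  H <- build_transition_matrix(mh)
  p <- rwr_from_seed(H, "g01", r = 0.5, tol = 1e-12)
  lc <- layer_contribution(p, H$index, "g04")
  expect_length(lc, 3L)
  expect_equal(sum(lc), 1)
  raw <- p$p[paste0("g04@layer", 1:3)]
  expect_equal(unname(lc), unname(raw / sum(raw)))
  expect_error(layer_contribution(p, H$index, H$index$drugs[1]), "drug")
  # equal layer values give 1/L fractions
  fake <- structure(list(seed_id = "s", p = rep(1 / 6, 6), iterations = 1L,
                         converged = TRUE), class = "proximity_vector")
  ix <- list(G = 2L, L = 3L, genes = c("a", "b"), drugs = character(),
             layer_names = c("x", "y", "z"))
  expect_equal(unname(layer_contribution(fake, ix, "a")), rep(1 / 3, 3))
})

test_that("similarity matrices round-trip through the TSV writer", {
  mh <- suppressMessages(random_mh_network(6, 2, 2, seed = 18))
  S <- build_similarity_matrix(mh, run_config())
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_similarity_matrix(S, prefix)
  back <- as.matrix(read.delim(paste0(prefix, "_similarity.tsv"),
                               row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(unclass(S)[, ]), tolerance = 1e-12)
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"))
  expect_equal(nodes$node, rownames(S))
})
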