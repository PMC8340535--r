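make_events <- function(up, down, sample = "S1", net) {
  suppressMessages(build_sample_events(data.frame(gene = up), NULL, down,
                                       sample, net))
}

test_that("sample scores on the 2-cycle match the hand-derived closed form", {
  net <- two_cycle()
  ops <- diffusion_operators(net, beta = 0.5)
  ev <- make_events("A", "B", net = net)
  sc <- sample_scores(ops$fwd, ops$rev, ev)
  expect_equal(unname(sc$f), c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(unname(sc$b), c(1, 2) / 3, tolerance = 1e-12)
  expect_equal(unname(sc$c), c(2, 2) / 9, tolerance = 1e-12)
})

test_that("score vectors are stochastic means and respect beta = 1", {
  net <- largest_scc(random_scc_network(40, seed = 5))
  ops <- diffusion_operators(net, beta = 0.4)
  all_ev <- make_events(net$nodes, net$nodes, net = net)
  sc <- sample_scores(ops$fwd, ops$rev, all_ev)
  expect_equal(sum(sc$f), 1, tolerance = 1e-9)
  expect_equal(sum(sc$b), 1, tolerance = 1e-9)
  expect_true(all(sc$c > 0))

  ops1 <- diffusion_operators(net, beta = 1)
  up <- net$nodes[1:5]; down <- net$nodes[4:8]
  sc1 <- sample_scores(ops1$fwd, ops1$rev, make_events(up, down, net = net))
  expect_setequal(names(sc1$c)[sc1$c > 0], intersect(up, down))
})

test_that("rank_genes averages ties and matches a sort-based oracle", {
  expect_equal(rank_genes(c(0.5, 0.2, 0.2)), c(1, 2.5, 2.5))
  expect_equal(rank_genes(c(9, 7, 5, 3)), 1:4)
  expect_error(rank_genes(c(1, NaN)), "non-finite|NA")

  set.seed(8)
  x <- sample(round(runif(500), 2))  # plenty of ties
  r <- rank_genes(x)
  # oracle: explicit tie grouping over the descending sort
  ord <- order(-x)
  oracle <- numeric(500)
  i <- 1
  while (i <= 500) {
    j <- i
    while (j < 500 && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    oracle[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  expect_equal(r, oracle)
})

test_that("aggregate_ranks matches a direct median oracle with tie-breaks", {
  set.seed(9)
  n <- 200
  nodes <- sprintf("G%03d", 1:n)
  scores <- lapply(1:12, function(s) {
    cc <- stats::setNames(round(runif(n), 3), nodes)
    list(sample = paste0("S", s), c = cc, r = rank_genes(cc))
  })
  rk <- aggregate_ranks(scores, method = "median")
  rank_mat <- do.call(rbind, lapply(scores, `[[`, "r"))
  med <- apply(rank_mat, 2, median)
  msc <- colMeans(do.call(rbind, lapply(scores, `[[`, "c")))
  ord <- order(med, -msc, nodes)
  expect_equal(rk$table$gene, nodes[ord])
  expect_equal(rk$table$agg_rank, unname(med[ord]))

  # identical rank vectors: aggregated order equals the per-sample order
  same <- aggregate_ranks(scores[c(1, 1, 1)], method = "median")
  expect_equal(same$table$agg_rank, unname(sort(scores[[1]]$r)))

  # 3 samples with ranks 1, 5, 9 -> median 5
  expect_equal(unname(medinet:::aggregate_rank_stat(rbind(1, 5, 9), "median")), 5)
})

test_that("scores are invariant to node relabeling", {
  net <- largest_scc(random_scc_network(30, seed = 11))
  ops <- diffusion_operators(net, beta = 0.4)
  up <- net$nodes[c(2, 5)]; down <- net$nodes[c(9, 12, 20)]
  sc <- sample_scores(ops$fwd, ops$rev, make_events(up, down, net = net))

  # relabel nodes (prefix flips lexicographic order), rebuild, rescore
  relab <- stats::setNames(paste0(rev(LETTERS[1:26])[seq_along(net$nodes) %% 26 + 1],
                                  "_", net$nodes), net$nodes)
  net2 <- network_from_edges(relab[net$nodes[net$edges$from]],
                             relab[net$nodes[net$edges$to]])
  ops2 <- diffusion_operators(net2, beta = 0.4)
  sc2 <- sample_scores(ops2$fwd, ops2$rev,
                       make_events(unname(relab[up]), unname(relab[down]), net = net2))
  expect_equal(unname(sc2$c[relab[names(sc$c)]]), unname(sc$c), tolerance = 1e-12)
})

test_that("adding an upstream event moves f by at most 2/|upstream_new|", {
  net <- largest_scc(random_scc_network(50, seed = 13))
  ops <- diffusion_operators(net, beta = 0.4)
  for (k in c(1, 4, 9)) {
    up <- net$nodes[1:k]
    f_old <- sample_scores(ops$fwd, ops$rev,
                           make_events(up, net$nodes[20], net = net))$f
    f_new <- sample_scores(ops$fwd, ops$rev,
                           make_events(c(up, net$nodes[k + 1]), net$nodes[20],
                                       net = net))$f
    expect_lte(sum(abs(f_new - f_old)), 2 / (k + 1) + 1e-12)
  }
})

test_that("duplicating the whole cohort leaves the aggregated order unchanged", {
  # (duplicating a single sample can flip medians even for odd cohorts, so the
  # exact invariance holds for whole-cohort duplication)
  set.seed(14)
  nodes <- sprintf("G%02d", 1:50)
  scores <- lapply(1:5, function(s) {
    cc <- stats::setNames(runif(50), nodes)
    list(sample = paste0("S", s), c = cc, r = rank_genes(cc))
  })
  a <- aggregate_ranks(scores, method = "median")
  dup <- c(scores, lapply(scores, function(s) { s$sample <- paste0(s$sample, "bis"); s }))
  b <- aggregate_ranks(dup, method = "median")
  expect_equal(a$table$gene, b$table$gene)
})

test_that("select_top_fraction sizes and FDR filtering behave as specified", {
  n <- 2484
  nodes <- sprintf("G%04d", 1:n)
  cc <- stats::setNames(seq(n, 1) / n, nodes)
  rk <- aggregate_ranks(list(list(sample = "S1", c = cc, r = rank_genes(cc))))
  top <- select_top_fraction(rk, fraction = 0.05)
  expect_equal(nrow(top), 125L)  # ceiling(0.05 * 2484)

  q1 <- stats::setNames(rep(1, n), nodes)
  expect_equal(nrow(select_top_fraction(rk, 0.05, q = q1)), 0L)
  q0 <- stats::setNames(rep(0, n), nodes)
  expect_equal(nrow(select_top_fraction(rk, 0.05, q = q0)), 125L)
  expect_error(select_top_fraction(rk, fraction = 0), "fraction")
  expect_error(select_top_fraction(rk, fraction = 1.5), "fraction")
})
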