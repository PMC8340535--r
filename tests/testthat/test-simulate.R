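test_that("simulation_config validates its parameters", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(noise_fraction = 1.2, seed = 1), "noise_fraction")
  expect_error(simulation_config(beta = 0, seed = 1), "beta")
  expect_error(simulation_config(n_mirnas = 5, de_mirna_per_sample = 10, seed = 1),
               "miRNA")
  cfg <- simulation_config(seed = 1)
  expect_s3_class(cfg, "medinet_sim_config")
  expect_equal(cfg$n_samples, 12L)
  expect_equal(cfg$n_planted_mediators, 10L)
  expect_equal(cfg$passengers_per_sample, 13L)
})

test_that("generated networks have a dominant SCC and are reproducible", {
  cfg <- small_cohort_config(31, n_genes = 100L, n_mirnas = 10L, mean_degree = 6)
  net1 <- generate_network(cfg)
  net2 <- generate_network(cfg)
  expect_identical(net1, net2)
  scc <- largest_scc(net1)
  expect_gte(sum(scc$kind == "gene"), 90L)
})

test_that("generated out-degrees follow the configured Poisson distribution", {
  degs <- integer(0)
  for (seed in 1:20) {
    cfg <- small_cohort_config(seed, n_genes = 400L, n_mirnas = 0L,
                               de_mirna_per_sample = 0L, mean_degree = 8)
    net <- generate_network(cfg)
    gene_idx <- which(net$kind == "gene")
    d <- tabulate(net$edges$from, nbins = length(net$nodes))[gene_idx]
    degs <- c(degs, d)
  }
  # chi-square GOF against Poisson(8); duplicate-edge collapsing trims a
  # little mass from the upper tail, so bin coarsely
  brk <- c(-Inf, 4, 6, 8, 10, 12, Inf)
  obs <- table(cut(degs, brk))
  pr <- diff(c(0, ppois(c(4, 6, 8, 10, 12), 8), 1))
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("cohorts regenerate bit-identically and carry coherent truth", {
  c1 <- small_cohort(32)
  c2 <- small_cohort(32)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$layers, c2$layers)
  expect_identical(c1$truth$mediators, c2$truth$mediators)

  cfg <- c1$truth$config
  expect_equal(length(c1$truth$mediators), cfg$n_planted_mediators)
  expect_false(any(c1$truth$mediators %in% c1$truth$drivers))

  # drivers mutated in every sample; passengers strictly private
  mut <- c1$mutations
  for (d in c1$truth$drivers) {
    expect_equal(sort(unique(mut$TUMOR_SAMPLE[mut$GENE == d])),
                 sort(unique(mut$TUMOR_SAMPLE)))
  }
  passengers <- setdiff(mut$GENE, c1$truth$drivers)
  per_gene <- table(mut$TUMOR_SAMPLE[mut$GENE %in% passengers],
                    mut$GENE[mut$GENE %in% passengers])
  expect_true(all(colSums(per_gene > 0) == 1L))
})

test_that("signal events stay within two forward hops of planted structure", {
  cohort <- small_cohort(33, noise_fraction = 0)
  net <- cohort$network
  g <- medinet:::as_igraph(net)
  med <- cohort$truth$mediators
  reach <- unique(c(med, unlist(lapply(
    igraph::ego(g, order = 2L, nodes = med, mode = "out"), names))))
  up2 <- unique(unlist(lapply(
    igraph::ego(g, order = 2L, nodes = med, mode = "in"), names)))
  for (ev in cohort$truth$events) {
    mir_events <- ev$upstream[net$kind[ev$upstream] == "mirna"]
    expect_true(all(ev$downstream %in% reach))
    expect_true(all(mir_events %in% up2))
  }
})

test_that("differential tables encode the intended events", {
  cohort <- small_cohort(34)
  sid <- unique(cohort$layers$mrna$sample)[1]
  lyr <- lapply(cohort$layers, function(t) t[t$sample == sid, ])
  down <- combine_downstream(lyr$mrna, lyr$protein, lyr$phosphosite)
  want <- cohort$truth$events[[sid]]$downstream
  expect_setequal(toupper(as.character(down)), toupper(want))
  # phosphosite tables have 1-5 sites per gene, >= 1 significant
  ph <- lyr$phosphosite
  per_gene <- split(ph$padj, ph$gene)
  expect_true(all(lengths(per_gene) >= 1 & lengths(per_gene) <= 5))
  expect_true(all(vapply(per_gene, function(p) any(p < 0.05), logical(1))))
})

test_that("recovery metrics handle the degenerate cases", {
  cohort <- small_cohort(35)
  run <- score_cohort(cohort$network, cohort$mutations, cohort$layers)
  m <- recovery_metrics(run$ranking, cohort$truth)
  expect_true(m$recall >= 0 && m$recall <= 1)
  expect_true(m$auroc >= 0 && m$auroc <= 1)

  # all planted in the selected set -> recall 1
  fake_sel <- data.frame(gene = cohort$truth$mediators)
  expect_equal(recovery_metrics(run$ranking, cohort$truth, fake_sel)$recall, 1)

  bad_truth <- cohort$truth; bad_truth$mediators <- character(0)
  expect_error(recovery_metrics(run$ranking, bad_truth), "empty planted")
})

test_that("random rankings give AUROC near one half", {
  cohort <- small_cohort(36)
  n <- length(cohort$network$nodes)
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    cc <- stats::setNames(runif(n), cohort$network$nodes)
    rk <- aggregate_ranks(list(list(sample = "S1", c = cc, r = rank_genes(cc))))
    recovery_metrics(rk, cohort$truth)$auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("increasing noise degrades recovery monotonically in trend", {
  med_recall <- vapply(c(0, 0.3, 0.6), function(noise) {
    rec <- vapply(1:5, function(seed) {
      cohort <- small_cohort(40 + seed, noise_fraction = noise)
      run <- score_cohort(cohort$network, cohort$mutations, cohort$layers)
      recovery_metrics(run$ranking, cohort$truth)$recall
    }, numeric(1))
    mean(rec)
  }, numeric(1))
  expect_true(cor(med_recall, c(0, 0.3, 0.6), method = "spearman") <= 0)
})
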