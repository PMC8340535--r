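# shared builders for small deterministic graphs and cohorts

edge_df <- function(src, tgt, directed = 1L, type = "interaction") {
  data.frame(source = src, target = tgt,
             directed = rep(directed, length.out = length(src)),
             type = rep(type, length.out = length(src)),
             stringsAsFactors = FALSE)
}

two_cycle <- function() network_from_edges(c("A", "B"), c("B", "A"))

# random strongly connected digraph: a Hamiltonian cycle plus extra edges
random_scc_network <- function(n, extra = 3L * n, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  from <- c(ids, sample(ids, extra, replace = TRUE))
  to <- c(ids[c(2:n, 1L)], sample(ids, extra, replace = TRUE))
  keep <- from != to
  network_from_edges(from[keep], to[keep])
}

# independent SCC oracle: pairwise reachability via boolean transitive
# closure by repeated squaring
scc_oracle_nodes <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(net$edges$from, net$edges$to)] <- TRUE
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  mutual <- A & t(A)
  comp_id <- apply(mutual, 1L, function(row) paste(which(row), collapse = ","))
  comp <- split(seq_len(n), comp_id)
  sizes <- lengths(comp)
  big <- comp[sizes == max(sizes)]
  firsts <- vapply(big, function(ix) min(net$nodes[ix]), character(1))
  sort(net$nodes[big[[order(firsts)[1L]]]])
}

# independent diffusion oracle: truncated power series with plain matrices
series_oracle <- function(W, beta, k_max = 2000L) {
  Wd <- as.matrix(W)
  n <- nrow(Wd)
  term <- diag(n)
  acc <- matrix(0, n, n)
  for (k in 0:k_max) {
    acc <- acc + beta * (1 - beta)^k * term
    term <- term %*% Wd
    if ((1 - beta)^(k + 1) < 1e-14) break
  }
  dimnames(acc) <- dimnames(W)
  acc
}

small_cohort_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_samples = 6L, n_genes = 250L, n_mirnas = 40L, mean_degree = 10,
         n_planted_mediators = 4L, n_shared_drivers = 2L,
         passengers_per_sample = 5L, de_mirna_per_sample = 8L,
         downstream_per_sample = 80L, noise_fraction = 0.3, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

small_cohort <- function(seed, ...) {
  cfg <- small_cohort_config(seed, ...)
  simulate_cohort(generate_network(cfg), cfg)
}
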