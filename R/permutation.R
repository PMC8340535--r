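#' Permute the event labels of one sample
#'
#' Draws, independently for each event category (mutated genes, differentially
#' expressed miRNAs, downstream genes), a uniform random subset of eligible
#' network nodes of exactly the same size: gene categories permute onto gene
#' nodes, the miRNA category onto miRNA nodes. This is the degree-blind null
#' used by the permutation test.
#'
#' @param events A `medinet_sample_events`.
#' @param net The scoring `medinet_network` (provides node kinds).
#' @return A new `medinet_sample_events` with relabelled events; per-category
#'   sizes are identical to the input by construction.
#' @details Uses the current RNG state; seed via [set.seed()] (or let
#'   [run_permutation_test()] manage seeding).
#' @export
permute_events <- function(events, net) {
  stopifnot(inherits(events, "medinet_sample_events"),
            inherits(net, "medinet_network"))
  genes <- net$nodes[net$kind == "gene"]
  mirnas <- net$nodes[net$kind == "mirna"]
  up_kind <- net$kind[events$upstream]
  n_mut <- sum(up_kind == "gene")
  n_mir <- sum(up_kind == "mirna")
  n_down <- length(events$downstream)
  if (n_mut > length(genes) || n_down > length(genes) || n_mir > length(mirnas)) {
    stop("event category larger than the eligible node pool; cannot permute")
  }
  new_mut <- if (n_mut > 0L) sample(genes, n_mut) else character(0)
  new_mir <- if (n_mir > 0L) sample(mirnas, n_mir) else character(0)
  new_down <- if (n_down > 0L) sample(genes, n_down) else character(0)
  out <- events
  out$upstream <- sort(c(new_mut, new_mir), method = "radix")
  out$downstream <- sort(new_down, method = "radix")
  out$provenance <- c(stats::setNames(rep("mutation", n_mut), new_mut),
                      stats::setNames(rep("mirna", n_mir), new_mir),
                      stats::setNames(rep("downstream", n_down), new_down))
  out
}

#' Empirical p-values from permutation null runs
#'
#' For each gene, counts the null runs in which the aggregated statistic was
#' at least as good as (i.e. a rank at most equal to) the observed one, and
#' applies the add-one estimator `p = (1 + #better-or-equal) / (1 + n_perm)`,
#' which can never return 0.
#'
#' @param observed Named numeric vector of observed aggregated ranks
#'   (smaller = better).
#' @param null_runs List of aggregated-rank vectors from permutation runs,
#'   each over the same (named) node set.
#' @return Named vector of empirical p-values in (0, 1].
#' @export
empirical_pvalues <- function(observed, null_runs) {
  if (length(null_runs) < 1L) stop("at least one null run is required")
  exceed <- rep(0L, length(observed))
  for (nr in null_runs) {
    if (length(nr) != length(observed) ||
        (!is.null(names(nr)) && !identical(names(nr), names(observed)))) {
      stop("null run does not match the observed node set")
    }
    exceed <- exceed + (nr <= observed)
  }
  stats::setNames((1 + exceed) / (1 + length(null_runs)), names(observed))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the
#' sorted p-values. Implemented directly (and cross-checked against
#' `stats::p.adjust` in the test suite).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted q-values, same order and names as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(p)
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  out <- numeric(m)
  out[ord] <- q
  names(out) <- names(p)
  out
}

# ---- fast internal cohort scoring --------------------------------------
# Event sets are encoded as integer index lists into the operator's node
# order; samples are batched into n x S weight matrices so that one BLAS
# product per direction scores the whole cohort.
cohort_stat <- function(Ffwd, Frev, up_idx, down_idx,
                        combine = "product", method = "median") {
  n <- ncol(Ffwd)
  S <- length(up_idx)
  U <- matrix(0, n, S)
  D <- matrix(0, n, S)
  for (s in seq_len(S)) {
    U[up_idx[[s]], s] <- 1 / length(up_idx[[s]])
    D[down_idx[[s]], s] <- 1 / length(down_idx[[s]])
  }
  Fm <- crossprod(Ffwd, U)                       # n x S forward means
  B <- crossprod(Frev, D)                        # n x S backward means
  C <- switch(combine, product = Fm * B, sum = Fm + B, forward_only = Fm)
  R <- matrix(0, n, S)
  for (s in seq_len(S)) R[, s] <- rank(-C[, s], ties.method = "average")
  list(agg = aggregate_rank_stat(t(R), method), scores = C)
}

#' Permutation test for the cohort-level mediator ranking
#'
#' Re-runs the whole scoring pipeline under the event-relabelling null: in
#' each repetition every sample's event categories are redrawn uniformly over
#' the eligible network nodes (sizes preserved exactly), per-sample scores and
#' ranks are recomputed with the *same* precomputed diffusion operators, and
#' the aggregated rank statistic is compared with the observed one. Empirical
#' p-values use the add-one estimator and are BH-adjusted.
#'
#' @param operators List with `fwd` and `rev` diffusion operators (see
#'   [diffusion_operators()]).
#' @param events_list List of scoreable `medinet_sample_events`.
#' @param net The scoring network (for node kinds).
#' @param ranking The observed `medinet_ranking` (from [aggregate_ranks()]).
#' @param n_perm Number of permutations (default 10000; use ~500 for quick
#'   runs).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param combine Score combination, as in [sample_scores()].
#' @param verbose Log progress every 100 repetitions (default `FALSE`).
#' @return A `medinet_permutation` object: list with `p_emp`, `q`,
#'   `exceed_counts` (all named by gene), `n_perm`, and `seed`.
#' @export
run_permutation_test <- function(operators, events_list, net, ranking,
                                 n_perm = 10000L, seed,
                                 combine = c("product", "sum", "forward_only"),
                                 verbose = FALSE) {
  combine <- match.arg(combine)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || is.na(n_perm) || n_perm < 1) {
    stop("n_perm must be a positive integer")
  }
  n_perm <- as.integer(n_perm)
  if (missing(seed)) stop("a seed is required for a reproducible permutation test")
  stopifnot(inherits(ranking, "medinet_ranking"))
  nodes <- rownames(operators$fwd$F)
  gene_idx <- which(net$kind[nodes] == "gene")
  mirna_idx <- which(net$kind[nodes] == "mirna")
  # per-sample category sizes, frozen from the observed events
  sizes <- lapply(events_list, function(ev) {
    k <- net$kind[ev$upstream]
    list(mut = sum(k == "gene"), mir = sum(k == "mirna"),
         down = length(ev$downstream))
  })
  obs <- ranking$table$agg_rank[match(nodes, ranking$table$gene)]
  if (anyNA(obs)) stop("ranking does not cover the operator's node set")
  exceed <- rep(0L, length(nodes))
  set.seed(seed)
  for (rep_i in seq_len(n_perm)) {
    up_idx <- vector("list", length(sizes))
    down_idx <- vector("list", length(sizes))
    for (s in seq_along(sizes)) {
      sz <- sizes[[s]]
      up <- c(if (sz$mut > 0L) sample(gene_idx, sz$mut) else integer(0),
              if (sz$mir > 0L) sample(mirna_idx, sz$mir) else integer(0))
      dn <- if (sz$down > 0L) sample(gene_idx, sz$down) else integer(0)
      # the null must preserve per-sample, per-category event counts exactly
      stopifnot(length(up) == sz$mut + sz$mir, length(dn) == sz$down)
      up_idx[[s]] <- up
      down_idx[[s]] <- dn
    }
    null_agg <- cohort_stat(operators$fwd$F, operators$rev$F, up_idx, down_idx,
                            combine = combine, method = ranking$method)$agg
    exceed <- exceed + (null_agg <= obs)
    if (verbose && rep_i %% 100L == 0L) {
      message(sprintf("permutation %d/%d", rep_i, n_perm))
    }
  }
  p_emp <- stats::setNames((1 + exceed) / (1 + n_perm), nodes)
  structure(list(p_emp = p_emp, q = bh_fdr(p_emp),
                 exceed_counts = stats::setNames(exceed, nodes),
                 n_perm = n_perm, seed = seed),
            class = "medinet_permutation")
}

#' @export
print.medinet_permutation <- function(x, ...) {
  cat(sprintf("medinet_permutation: %d reps (seed %s); %d genes with q <= 0.05\n",
              x$n_perm, format(x$seed), sum(x$q <= 0.05)))
  invisible(x)
}
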