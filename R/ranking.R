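#' Score all network genes for one sample by bidirectional diffusion
#'
#' The forward score vector `f` is the mean of the forward operator's rows
#' indexed by the sample's upstream events (where signal from mutations and
#' dysregulated miRNAs flows to); the backward score vector `b` is the mean of
#' the reverse-network operator's rows indexed by the downstream events (where
#' the observed molecular changes trace back to). The combined score rewards
#' genes that relay upstream causes to downstream consequences.
#'
#' @param op_fwd,op_rev `medinet_diffusion` operators on the network and its
#'   edge-reversed counterpart (see [diffusion_operators()]).
#' @param events A scoreable `medinet_sample_events`.
#' @param combine `"product"` (default; demands both signals), `"sum"`, or
#'   `"forward_only"`.
#' @return A `medinet_sample_score`: list with `sample`, vectors `f`, `b`,
#'   `c` over nodes, and `r` (ranks, 1 = best, ties averaged).
#' @export
sample_scores <- function(op_fwd, op_rev, events,
                          combine = c("product", "sum", "forward_only")) {
  combine <- match.arg(combine)
  stopifnot(inherits(op_fwd, "medinet_diffusion"),
            inherits(op_rev, "medinet_diffusion"),
            inherits(events, "medinet_sample_events"))
  if (!events$scoreable) {
    stop("sample ", events$sample, " is unscoreable (empty event set)")
  }
  nodes <- rownames(op_fwd$F)
  up <- match(events$upstream, nodes)
  dn <- match(events$downstream, nodes)
  if (anyNA(up) || anyNA(dn)) {
    stop("event ids not present in the diffusion operator for sample ", events$sample)
  }
  f <- colMeans(op_fwd$F[up, , drop = FALSE])
  b <- colMeans(op_rev$F[dn, , drop = FALSE])
  cc <- switch(combine, product = f * b, sum = f + b, forward_only = f)
  structure(list(sample = events$sample, f = f, b = b, c = cc,
                 r = rank_genes(cc)),
            class = "medinet_sample_score")
}

#' Rank genes by combined score
#'
#' Descending-score ranks: the best-scoring gene gets rank 1; ties receive the
#' average of the ranks they span.
#'
#' @param scores Numeric vector of non-negative, finite combined scores.
#' @return Numeric rank vector (same names as `scores`).
#' @export
rank_genes <- function(scores) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores contain NA or non-finite values")
  }
  rank(-scores, ties.method = "average")
}

#' Aggregate per-sample ranks into a cohort-level mediator ranking
#'
#' Integrates the per-sample rankings into one cohort ordering: each gene's
#' aggregated statistic is the median (default) of its ranks across scoreable
#' samples. The cohort order is ascending in the aggregated rank; ties are
#' broken by mean combined score (descending), then by node id.
#'
#' @param scores List of `medinet_sample_score` objects (one per scoreable
#'   sample, all over the same node set).
#' @param method `"median"` (default), `"mean"`, or `"sum"`.
#' @return A `medinet_ranking`: data.frame `table` with columns `gene`,
#'   `agg_rank`, `mean_score`, `cohort_rank` (1 = top mediator candidate)
#'   sorted by cohort order, plus the per-sample `rank_matrix`
#'   (samples x genes) and `samples`.
#' @export
aggregate_ranks <- function(scores, method = c("median", "mean", "sum")) {
  method <- match.arg(method)
  if (length(scores) == 0L) stop("no scoreable samples: cannot aggregate ranks")
  nodes <- names(scores[[1L]]$c)
  rank_matrix <- do.call(rbind, lapply(scores, function(s) {
    if (!identical(names(s$c), nodes)) stop("rank vectors span different node sets")
    s$r
  }))
  rownames(rank_matrix) <- vapply(scores, function(s) s$sample, character(1))
  score_matrix <- do.call(rbind, lapply(scores, function(s) s$c))
  agg <- aggregate_rank_stat(rank_matrix, method)
  mean_score <- colMeans(score_matrix)
  ord <- order(agg, -mean_score, nodes, method = "radix")
  tab <- data.frame(gene = nodes[ord], agg_rank = agg[ord],
                    mean_score = mean_score[ord],
                    cohort_rank = seq_along(nodes),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, rank_matrix = rank_matrix,
                 samples = rownames(rank_matrix), method = method),
            class = "medinet_ranking")
}

# aggregated rank statistic per gene (columns of a samples x genes matrix)
aggregate_rank_stat <- function(rank_matrix, method) {
  switch(method,
         median = matrixStats::colMedians(rank_matrix),
         mean = colMeans(rank_matrix),
         sum = colSums(rank_matrix))
}

#' @export
print.medinet_ranking <- function(x, ...) {
  cat(sprintf("medinet_ranking: %d genes aggregated over %d samples (%s rank)\n",
              nrow(x$table), length(x$samples), x$method))
  print(utils::head(x$table, 5L))
  invisible(x)
}

#' Select the top-ranked mediator candidates and apply the FDR cut
#'
#' Takes the first `ceiling(fraction * N)` genes of the cohort order, then
#' drops genes whose permutation-derived FDR-adjusted p exceeds `q_alpha`.
#'
#' @param ranking A `medinet_ranking`.
#' @param fraction Top fraction of the ranked list to consider (default 0.05).
#' @param q Named vector of FDR-adjusted empirical p-values per gene (from
#'   [run_permutation_test()]); `NULL` skips the FDR filter.
#' @param q_alpha FDR threshold (default 0.05).
#' @return Data.frame of selected mediators (subset of `ranking$table` rows,
#'   with `q` column when supplied).
#' @export
select_top_fraction <- function(ranking, fraction = 0.05, q = NULL, q_alpha = 0.05) {
  stopifnot(inherits(ranking, "medinet_ranking"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]")
  }
  n_top <- ceiling(fraction * nrow(ranking$table))
  top <- ranking$table[seq_len(n_top), , drop = FALSE]
  if (!is.null(q)) {
    qv <- q[match(top$gene, names(q))]
    if (anyNA(qv)) stop("q-values missing for some top-ranked genes")
    top$q <- unname(qv)
    top <- top[top$q <= q_alpha, , drop = FALSE]
  }
  rownames(top) <- NULL
  top
}
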