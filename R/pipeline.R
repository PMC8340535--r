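#' Score a multi-omics cohort end to end
#'
#' Runs the full observed-data pipeline: somatic variant filtering, per-sample
#' event assembly (upstream = mutated genes + significant miRNAs, downstream =
#' layer-combined differential genes), bidirectional insulated diffusion, and
#' cohort rank aggregation. Unscoreable samples (no on-network events) are
#' dropped with a warning.
#'
#' @param net The scoring `medinet_network`; reduced to its largest SCC
#'   internally if not already strongly connected.
#' @param mutations Cohort mutation table (data.frame in the mutation-table
#'   layout, or parsed records).
#' @param layers Named list of differential tables with a `sample` column:
#'   `mrna`, `mirna`, `protein`, `phosphosite` (missing layers allowed).
#' @param alpha FDR threshold for differential significance (default 0.05).
#' @param beta Restart probability (default 0.4).
#' @param combine Score combination (`"product"`, `"sum"`, `"forward_only"`).
#' @param agg_method Rank aggregation (`"median"`, `"mean"`, `"sum"`).
#' @return A `medinet_run`: list with `network` (SCC actually scored),
#'   `operators`, `events` (per-sample), `scores`, `ranking`, and
#'   `dropped_samples`.
#' @export
score_cohort <- function(net, mutations, layers, alpha = 0.05, beta = 0.4,
                         combine = c("product", "sum", "forward_only"),
                         agg_method = c("median", "mean", "sum")) {
  combine <- match.arg(combine)
  agg_method <- match.arg(agg_method)
  stopifnot(inherits(net, "medinet_network"))
  scc <- largest_scc(net)
  if (length(scc$nodes) < 2L) stop("scoring network has fewer than 2 strongly connected nodes")

  records <- if (!is.null(mutations$tumor_sample)) mutations else as_mutation_records(mutations)
  records <- filter_somatic_variants(records)
  samples <- sort(unique(c(records$tumor_sample,
                           unlist(lapply(layers, function(l) l$sample)))),
                  method = "radix")
  per_layer <- function(layer, sid) {
    tab <- layers[[layer]]
    if (is.null(tab)) return(NULL)
    tab[tab$sample == sid, , drop = FALSE]
  }
  events <- list()
  dropped <- character(0)
  for (sid in samples) {
    muts <- records[records$tumor_sample == sid, , drop = FALSE]
    rna <- per_layer("mrna", sid)
    prot <- per_layer("protein", sid)
    phos <- per_layer("phosphosite", sid)
    mirna <- per_layer("mirna", sid)
    down <- combine_downstream(
      rna %||% empty_layer(), prot %||% empty_layer(), phos, alpha = alpha)
    ev <- suppressMessages(
      build_sample_events(muts, mirna, down, sid, scc, alpha = alpha))
    if (ev$scoreable) events[[sid]] <- ev else dropped <- c(dropped, sid)
  }
  if (length(events) == 0L) stop("no scoreable samples in the cohort")
  operators <- diffusion_operators(scc, beta = beta)
  scores <- lapply(events, function(ev) sample_scores(operators$fwd, operators$rev,
                                                      ev, combine = combine))
  ranking <- aggregate_ranks(scores, method = agg_method)
  structure(list(network = scc, operators = operators, events = events,
                 scores = scores, ranking = ranking, dropped_samples = dropped,
                 params = list(alpha = alpha, beta = beta, combine = combine,
                               agg_method = agg_method)),
            class = "medinet_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_layer <- function() {
  data.frame(feature = character(0), log2fc = numeric(0), padj = numeric(0),
             detected = logical(0), stringsAsFactors = FALSE)
}

#' @export
print.medinet_run <- function(x, ...) {
  cat(sprintf("medinet_run: %d nodes, %d scoreable samples (%d dropped)\n",
              length(x$network$nodes), length(x$events), length(x$dropped_samples)))
  invisible(x)
}

#' Detect mediators: permutation test and top-fraction selection
#'
#' Completes a scored run with the permutation-based empirical FDR and the
#' top-fraction/FDR mediator selection.
#'
#' @param run A `medinet_run` from [score_cohort()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed (mandatory).
#' @param fraction Top fraction of the cohort ranking to consider (default
#'   0.05).
#' @param q_alpha FDR threshold for the final mediator set (default 0.05).
#' @param verbose Log permutation progress.
#' @return A `medinet_result`: list with `mediators` (selected data.frame),
#'   `ranking`, `permutation`, and a per-gene `table` (gene, agg rank, score,
#'   p_emp, q, and per-sample upstream/downstream event tallies).
#' @export
detect_mediators <- function(run, n_perm = 10000L, seed, fraction = 0.05,
                             q_alpha = 0.05, verbose = FALSE) {
  stopifnot(inherits(run, "medinet_run"))
  perm <- run_permutation_test(run$operators, run$events, run$network,
                               run$ranking, n_perm = n_perm, seed = seed,
                               combine = run$params$combine, verbose = verbose)
  tab <- run$ranking$table
  tab$p_emp <- unname(perm$p_emp[tab$gene])
  tab$q <- unname(perm$q[tab$gene])
  up_count <- table(unlist(lapply(run$events, function(e) unique(e$upstream))))
  down_count <- table(unlist(lapply(run$events, function(e) unique(e$downstream))))
  tab$n_samples_up <- as.integer(up_count[tab$gene]); tab$n_samples_up[is.na(tab$n_samples_up)] <- 0L
  tab$n_samples_down <- as.integer(down_count[tab$gene]); tab$n_samples_down[is.na(tab$n_samples_down)] <- 0L
  mediators <- select_top_fraction(run$ranking, fraction = fraction,
                                   q = perm$q, q_alpha = q_alpha)
  structure(list(mediators = mediators, ranking = run$ranking,
                 permutation = perm, table = tab,
                 params = c(run$params, list(n_perm = perm$n_perm, seed = seed,
                                             fraction = fraction, q_alpha = q_alpha))),
            class = "medinet_result")
}

#' @export
print.medinet_result <- function(x, ...) {
  cat(sprintf("medinet_result: %d mediators (top %.1f%%, q <= %g, %d permutations)\n",
              nrow(x$mediators), 100 * x$params$fraction, x$params$q_alpha,
              x$params$n_perm))
  invisible(x)
}

#' Write pipeline results as deterministic TSV/JSON files
#'
#' Emits `mediators.tsv` (selected mediators: gene, aggregated rank, score,
#' empirical p, q, per-sample event tallies), `results.tsv` (the same columns
#' for every gene), and `summary.json` (parameters and headline counts).
#' Output is formatted with fixed significant digits so identical runs give
#' byte-identical files.
#'
#' @param result A `medinet_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "medinet_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- result$table
  fmt <- data.frame(gene = tab$gene,
                    agg_rank = formatC(tab$agg_rank, format = "g", digits = 10),
                    score = formatC(tab$mean_score, format = "e", digits = 10),
                    p_emp = formatC(tab$p_emp, format = "g", digits = 10),
                    q = formatC(tab$q, format = "g", digits = 10),
                    n_samples_up = tab$n_samples_up,
                    n_samples_down = tab$n_samples_down,
                    stringsAsFactors = FALSE)
  utils::write.table(fmt, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sel <- fmt[tab$gene %in% result$mediators$gene, , drop = FALSE]
  utils::write.table(sel, file.path(dir, "mediators.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_mediators = nrow(result$mediators),
         n_genes = nrow(tab),
         params = result$params),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `network.tsv`, `mutations.tsv` and
#'   per-layer per-sample differential tables.
#' @return List with `network`, `mutations`, `layers` in the shapes accepted
#'   by [score_cohort()].
#' @export
read_cohort_dir <- function(dir) {
  net <- load_network(file.path(dir, "network.tsv"))
  mutations <- read_mutation_table(file.path(dir, "mutations.tsv"))
  layers <- list()
  for (layer in c("mrna", "mirna", "protein", "phosphosite")) {
    files <- sort(list.files(dir, pattern = paste0("^", layer, "_.*\\.tsv$"),
                             full.names = TRUE))
    if (length(files) == 0L) next
    tabs <- lapply(files, function(f) {
      tab <- read_differential_table(f, layer)
      tab$sample <- sub(paste0("^", layer, "_(.*)\\.tsv$"), "\\1", basename(f))
      tab
    })
    layers[[layer]] <- do.call(rbind, tabs)
  }
  list(network = net, mutations = mutations, layers = layers)
}
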