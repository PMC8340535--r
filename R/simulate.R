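#' Configuration for a synthetic multi-omics cohort
#'
#' Builds (and validates) the parameter set of the cohort generator. Defaults
#' emulate a 12-tumor cohort driven by two engineered tumor-suppressor
#' deletions shared by every tumor, ~13 private passenger mutations per tumor,
#' and per-sample differential calls at roughly one quarter of the scale of a
#' full study (so tests run in seconds); the interaction-network density
#' (mean out-degree 13) matches a curated gene/miRNA functional network's
#' strongly connected core.
#'
#' @param n_samples Number of tumor samples (default 12).
#' @param n_genes,n_mirnas Node counts for the generated network (defaults
#'   2000 genes, 150 miRNAs).
#' @param mean_degree Mean out-degree of gene nodes (default 13).
#' @param n_planted_mediators Planted mediator genes (default 10).
#' @param n_shared_drivers Driver genes mutated in every sample (default 2).
#' @param passengers_per_sample Private passenger mutations per sample
#'   (default 13).
#' @param de_mirna_per_sample Differentially expressed miRNAs per sample
#'   (default 27).
#' @param downstream_per_sample Downstream differential genes per sample
#'   after layer combination (default 1000).
#' @param noise_fraction Fraction of miRNA/downstream events placed uniformly
#'   at random rather than around the planted mediators (default 0.3).
#' @param beta Restart probability used by the pipeline (default 0.4).
#' @param seed RNG seed; mandatory.
#' @return A `medinet_sim_config` (validated list).
#' @export
simulation_config <- function(n_samples = 12L, n_genes = 2000L, n_mirnas = 150L,
                              mean_degree = 13, n_planted_mediators = 10L,
                              n_shared_drivers = 2L, passengers_per_sample = 13L,
                              de_mirna_per_sample = 27L,
                              downstream_per_sample = 1000L,
                              noise_fraction = 0.3, beta = 0.4, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single numeric seed is mandatory")
  }
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas), mean_degree = mean_degree,
              n_planted_mediators = as.integer(n_planted_mediators),
              n_shared_drivers = as.integer(n_shared_drivers),
              passengers_per_sample = as.integer(passengers_per_sample),
              de_mirna_per_sample = as.integer(de_mirna_per_sample),
              downstream_per_sample = as.integer(downstream_per_sample),
              noise_fraction = noise_fraction, beta = beta,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_samples", "n_genes", "n_mirnas", "n_planted_mediators",
                         "n_shared_drivers", "passengers_per_sample",
                         "de_mirna_per_sample", "downstream_per_sample")])
  if (any(counts < 0L)) stop("all count parameters must be non-negative")
  if (cfg$n_samples < 1L || cfg$n_genes < 10L) stop("cohort needs >= 1 sample and >= 10 genes")
  if (cfg$noise_fraction < 0 || cfg$noise_fraction > 1) stop("noise_fraction must be in [0, 1]")
  if (cfg$beta <= 0 || cfg$beta > 1) stop("beta must be in (0, 1]")
  if (cfg$de_mirna_per_sample > cfg$n_mirnas) stop("more DE miRNAs requested than miRNA nodes")
  if (cfg$downstream_per_sample > cfg$n_genes) stop("more downstream events requested than genes")
  structure(cfg, class = "medinet_sim_config")
}

#' Generate a random directed gene/miRNA network
#'
#' Gene nodes receive Poisson(`mean_degree`) out-edges to uniformly chosen
#' gene targets; each miRNA node receives out-edges into the gene layer plus
#' two incoming edges from random genes so that miRNAs survive the reduction
#' to the largest strongly connected component. Regenerates (up to 10
#' attempts) until the largest SCC covers at least 90% of the gene nodes.
#'
#' @param cfg A `medinet_sim_config`.
#' @return A `medinet_network` (the full generated graph; reduce with
#'   [largest_scc()] before diffusion).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "medinet_sim_config"))
  genes <- sprintf("Gene%04d", seq_len(cfg$n_genes))
  mirnas <- if (cfg$n_mirnas > 0L) sprintf("mmu-miR-%04d", seq_len(cfg$n_mirnas)) else character(0)
  set.seed(cfg$seed)
  for (attempt in seq_len(10L)) {
    deg <- stats::rpois(cfg$n_genes, cfg$mean_degree)
    from <- rep(genes, deg)
    to <- sample(genes, length(from), replace = TRUE)
    if (length(mirnas) > 0L) {
      mdeg <- pmax(1L, stats::rpois(cfg$n_mirnas, cfg$mean_degree))
      from <- c(from, rep(mirnas, mdeg), sample(genes, 2L * cfg$n_mirnas, replace = TRUE))
      to <- c(to, sample(genes, sum(mdeg), replace = TRUE), rep(mirnas, each = 2L))
    }
    net <- network_from_edges(from, to)
    scc <- largest_scc(net)
    if (sum(scc$kind == "gene") >= 0.9 * cfg$n_genes) return(net)
  }
  stop("failed to generate a network whose largest SCC covers 90% of genes in 10 attempts; ",
       "increase mean_degree")
}

out_neighbourhood <- function(net, nodes, hops = 2L) {
  g <- as_igraph(net)
  reach <- igraph::ego(g, order = hops, nodes = nodes, mode = "out")
  sort(unique(unlist(lapply(reach, names))), method = "radix")
}

#' Simulate a multi-omics tumor cohort with planted mediators
#'
#' Plants `n_planted_mediators` mediator genes inside the 2-hop forward
#' neighbourhood of the shared driver genes, then generates per-sample events
#' that converge on them: upstream events are the drivers (every sample),
#' private passenger mutations (unique to one sample each), and differentially
#' expressed miRNAs drawn from miRNAs lying within 2 forward hops upstream of
#' a mediator; downstream events are genes within 2 forward hops downstream of
#' the mediators. A `noise_fraction` of the miRNA and downstream events is
#' placed uniformly at random instead. Differential tables emit adjusted
#' p-values directly (below `alpha = 0.05` for events, above otherwise);
#' phosphosite-route genes receive 1-5 sites with at least one significant.
#'
#' @param net A `medinet_network` from [generate_network()].
#' @param cfg The `medinet_sim_config` used to generate `net`.
#' @return A `medinet_cohort`: list with `mutations` (cohort mutation table),
#'   `layers` (named list of per-layer differential tables, each with a
#'   `sample` column), `truth` (planted mediators, drivers, per-sample
#'   intended events, config echo), and `network` (the scoring SCC).
#' @export
simulate_cohort <- function(net, cfg) {
  stopifnot(inherits(net, "medinet_network"), inherits(cfg, "medinet_sim_config"))
  scc <- largest_scc(net)
  genes <- scc$nodes[scc$kind == "gene"]
  mirnas <- scc$nodes[scc$kind == "mirna"]
  set.seed(cfg$seed + 1L)

  g <- as_igraph(scc)
  outdeg <- igraph::degree(g, mode = "out")
  # drivers: high out-degree genes, so their forward neighbourhood is rich
  driver_pool <- genes[order(-outdeg[genes])][seq_len(max(cfg$n_shared_drivers * 10L, 20L))]
  drivers <- sample_n(driver_pool, cfg$n_shared_drivers)
  # mediators: direct targets of the drivers (<= 2 forward hops as fallback),
  # restricted to genes with enough out-edges to have a downstream
  # neighbourhood of their own -- convergence must be topologically real
  near1 <- setdiff(intersect(unlist(lapply(
    igraph::ego(g, order = 1L, nodes = drivers, mode = "out"), names)), genes), drivers)
  near1 <- near1[outdeg[near1] >= stats::median(outdeg[genes])]
  cand <- near1
  if (length(cand) < cfg$n_planted_mediators) {
    near2 <- setdiff(intersect(out_neighbourhood(scc, drivers, 2L), genes), drivers)
    cand <- unique(c(cand, near2[outdeg[near2] >= stats::median(outdeg[genes])]))
  }
  if (length(cand) < cfg$n_planted_mediators) {
    stop("driver neighbourhood too small to plant ", cfg$n_planted_mediators,
         " mediators (", length(cand), " candidates)")
  }
  mediators <- sample_n(cand, cfg$n_planted_mediators)

  # per-mediator 1-hop / 2-hop neighbourhoods (excluding the mediator itself):
  # downstream events are drawn per mediator with 1-hop preference, so each
  # mediator is the local ancestor of its share of the evidence
  med_n1 <- lapply(mediators, function(m)
    setdiff(intersect(names(igraph::ego(g, 1L, m, mode = "out")[[1L]]), genes), m))
  med_n2 <- lapply(seq_along(mediators), function(i)
    setdiff(setdiff(intersect(out_neighbourhood(scc, mediators[i], 2L), genes),
                    med_n1[[i]]), mediators[i]))
  down_pool <- unique(c(unlist(med_n1), unlist(med_n2)))
  n_sig_down <- round((1 - cfg$noise_fraction) * cfg$downstream_per_sample)
  if (length(down_pool) < n_sig_down) {
    small <- mediators[which.min(lengths(med_n1))]
    stop("mediator neighbourhoods too small for ", n_sig_down,
         " signal downstream events (pool ", length(down_pool),
         "); smallest neighbourhood at mediator ", small)
  }
  # miRNAs upstream of each mediator within <= 2 forward hops, preferring
  # direct regulators; med_mir[[i]] lists the candidate regulators of mediator i
  med_mir1 <- lapply(mediators, function(m)
    intersect(names(igraph::ego(g, 1L, m, mode = "in")[[1L]]), mirnas))
  med_mir2 <- lapply(seq_along(mediators), function(i)
    setdiff(intersect(names(igraph::ego(g, 2L, mediators[i], mode = "in")[[1L]]),
                      mirnas), med_mir1[[i]]))
  mir_pool <- unique(c(unlist(med_mir1), unlist(med_mir2)))

  # cohort-level dysregulation program: tumors converge on the same mediators,
  # so the signal portion of the miRNA and downstream event sets is shared
  # across samples (with per-sample noise on top), mirroring the commonly
  # dysregulated features seen across tumors of one aetiology
  n_mir_all <- min(cfg$de_mirna_per_sample, length(mirnas))
  n_mir_sig <- min(round((1 - cfg$noise_fraction) * n_mir_all), length(mir_pool))
  mir_core <- allocate_events(med_mir1, med_mir2, n_mir_sig)
  mir_core <- c(mir_core, sample_n(setdiff(mir_pool, mir_core),
                                   n_mir_sig - length(mir_core)))
  # mediators carry their own downstream differential evidence (as the
  # relays of an always-on driver program they are dysregulated themselves),
  # alongside their regulon
  down_core <- unique(c(mediators, allocate_events(med_n1, med_n2,
                                                   n_sig_down - length(mediators))))
  down_core <- c(down_core, sample_n(setdiff(down_pool, down_core),
                                     n_sig_down - length(down_core)))

  passenger_pool <- setdiff(genes, c(drivers, mediators))
  n_pass_total <- cfg$n_samples * cfg$passengers_per_sample
  if (length(passenger_pool) < n_pass_total) stop("not enough genes for private passengers")
  passengers <- matrix(sample(passenger_pool, n_pass_total),
                       nrow = cfg$n_samples)

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  mut_rows <- list()
  layer_rows <- list(mrna = list(), mirna = list(), protein = list(),
                     phosphosite = list())
  truth_events <- list()

  for (i in seq_len(cfg$n_samples)) {
    sid <- samples[i]
    mut_genes <- c(drivers, passengers[i, ])
    mut_rows[[i]] <- data.frame(
      TUMOR_SAMPLE = sid, NORMAL_SAMPLE = paste0(sid, "norm"),
      CHROM = as.character(sample(1:19, length(mut_genes), replace = TRUE)),
      POS = sample.int(1e8, length(mut_genes)),
      REF = sample(c("A", "C", "G", "T"), length(mut_genes), replace = TRUE),
      ALT = sample(c("A", "C", "G", "T"), length(mut_genes), replace = TRUE),
      GENE = mut_genes,
      EFFECT = c(rep("frameshift_variant", length(drivers)),
                 rep("missense_variant", cfg$passengers_per_sample)),
      DEPTH_TUMOR = sample(30:150, length(mut_genes), replace = TRUE),
      VAF_TUMOR = sprintf("%.2f%%", stats::runif(length(mut_genes), 5, 40)),
      stringsAsFactors = FALSE)

    # miRNA events: the shared signal core plus per-sample uniform noise
    de_mir <- c(mir_core, sample_n(setdiff(mirnas, mir_core),
                                   n_mir_all - length(mir_core)))
    layer_rows$mirna[[i]] <- sig_table(sid, mirnas, de_mir)

    # downstream events: shared signal core plus per-sample uniform noise
    n_noise_down <- cfg$downstream_per_sample - length(down_core)
    down <- c(down_core, sample_n(setdiff(genes, down_core),
                                  min(n_noise_down, length(genes) - length(down_core))))
    # evidence routes per Table-7 semantics: protein- or phospho-significant,
    # or RNA-significant with protein/phospho undetected
    route <- sample(c("protein", "phospho", "rna"), length(down), replace = TRUE,
                    prob = c(0.45, 0.25, 0.30))
    prot_sig <- down[route == "protein"]
    phos_sig <- down[route == "phospho"]
    rna_sig <- down[route == "rna"]
    # distractors: detected-but-insignificant protein with significant RNA
    # (excluded by the combination rule), sprinkled over non-event genes
    bg <- setdiff(genes, down)
    distract <- sample_n(bg, min(50L, length(bg)))
    prot_universe <- c(prot_sig, distract,
                       sample_n(setdiff(bg, distract), min(200L, length(setdiff(bg, distract)))))
    layer_rows$protein[[i]] <- sig_table(sid, prot_universe, prot_sig)
    layer_rows$mrna[[i]] <- sig_table(sid, genes, c(rna_sig, distract))
    layer_rows$phosphosite[[i]] <- phospho_table(sid, phos_sig)

    truth_events[[sid]] <- list(
      upstream = sort(c(mut_genes, de_mir), method = "radix"),
      downstream = sort(down, method = "radix"))
  }

  mutations <- do.call(rbind, mut_rows)
  layers <- lapply(layer_rows, function(lst) do.call(rbind, lst))
  truth <- structure(list(mediators = sort(mediators, method = "radix"),
                          drivers = sort(drivers, method = "radix"),
                          events = truth_events, config = unclass(cfg)),
                     class = "medinet_truth")
  structure(list(mutations = mutations, layers = layers, truth = truth,
                 network = scc),
            class = "medinet_cohort")
}

sample_n <- function(pool, n) {
  if (n <= 0L || length(pool) == 0L) return(character(0))
  sample(pool, min(n, length(pool)))
}

# distribute n event draws evenly over mediators, sampling each mediator's
# share from its 1-hop neighbourhood (70%) and 2-hop shell (30%); returns a
# unique event set (duplicates across mediators collapse)
allocate_events <- function(n1_list, n2_list, n) {
  if (n <= 0L) return(character(0))
  k <- length(n1_list)
  share <- diff(round(seq(0, n, length.out = k + 1L)))
  picked <- character(0)
  for (i in sample.int(k)) {
    want <- share[i]
    if (want <= 0L) next
    a <- sample_n(setdiff(n1_list[[i]], picked), max(1L, round(0.7 * want)))
    b <- sample_n(setdiff(n2_list[[i]], c(picked, a)), want - length(a))
    picked <- c(picked, a, b)
  }
  unique(picked)
}

# differential table: all features in `universe` detected; those in `sig`
# get padj < 0.05, the rest padj >= 0.05
sig_table <- function(sid, universe, sig) {
  sig <- unique(sig)
  is_sig <- universe %in% sig
  data.frame(sample = sid, feature = universe,
             log2fc = round(ifelse(is_sig, sample(c(-1, 1), length(universe), replace = TRUE) *
                                     stats::runif(length(universe), 1, 4),
                                   stats::rnorm(length(universe), 0, 0.3)), 4),
             padj = round(ifelse(is_sig, stats::runif(length(universe), 1e-6, 0.045),
                                 stats::runif(length(universe), 0.06, 1)), 6),
             detected = TRUE, stringsAsFactors = FALSE)
}

# 1-5 sites per gene, at least one significant
phospho_table <- function(sid, genes) {
  if (length(genes) == 0L) {
    return(data.frame(sample = character(0), feature = character(0),
                      log2fc = numeric(0), padj = numeric(0),
                      detected = logical(0), gene = character(0),
                      stringsAsFactors = FALSE))
  }
  n_sites <- sample(1:5, length(genes), replace = TRUE)
  gene <- rep(genes, n_sites)
  first <- !duplicated(gene)
  is_sig <- first | stats::runif(length(gene)) < 0.3
  data.frame(sample = sid,
             feature = paste0(gene, "_S", unlist(lapply(n_sites, seq_len)) * 17L),
             log2fc = round(stats::rnorm(length(gene), 0, 2), 4),
             padj = round(ifelse(is_sig, stats::runif(length(gene), 1e-6, 0.045),
                                 stats::runif(length(gene), 0.06, 1)), 6),
             detected = TRUE, gene = gene, stringsAsFactors = FALSE)
}

#' Recovery metrics for a ranking against the planted truth
#'
#' @param ranking A `medinet_ranking` over the cohort's scoring network.
#' @param truth The `medinet_truth` from [simulate_cohort()].
#' @param selected Optional data.frame of selected mediators (from
#'   [select_top_fraction()]); recall/precision are computed against it when
#'   given, otherwise against the top 5% of the cohort order.
#' @return List with `recall`, `precision`, `median_rank` (of planted
#'   mediators in the cohort order), and `auroc` of the aggregated statistic
#'   against the planted labels.
#' @export
recovery_metrics <- function(ranking, truth, selected = NULL) {
  stopifnot(inherits(ranking, "medinet_ranking"), inherits(truth, "medinet_truth"))
  planted <- truth$mediators
  if (length(planted) == 0L) stop("truth has an empty planted mediator set")
  tab <- ranking$table
  if (!any(planted %in% tab$gene)) stop("planted mediators not in the ranking's node set")
  if (is.null(selected)) selected <- select_top_fraction(ranking, 0.05)
  hit <- planted %in% selected$gene
  pos <- tab$gene %in% planted
  # AUROC: probability a planted gene outranks (smaller cohort_rank) a random
  # non-planted gene, via the rank-sum identity
  score_rank <- rank(-tab$cohort_rank)  # higher = better
  n1 <- sum(pos); n0 <- sum(!pos)
  auroc <- (sum(score_rank[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(recall = mean(hit),
       precision = if (nrow(selected) > 0L) sum(selected$gene %in% planted) / nrow(selected) else NA_real_,
       median_rank = stats::median(tab$cohort_rank[pos]),
       auroc = auroc)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits the same dialects the readers consume: `mutations.tsv`, one
#' `<layer>_<sample>.tsv` per layer and sample, `network.tsv` (edge table),
#' and `truth.json`.
#'
#' @param cohort A `medinet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "medinet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  net <- cohort$network
  write_tsv(data.frame(source = net$nodes[net$edges$from],
                       target = net$nodes[net$edges$to],
                       directed = 1L, type = net$edges$type),
            file.path(dir, "network.tsv"))
  for (layer in names(cohort$layers)) {
    tab <- cohort$layers[[layer]]
    for (sid in unique(tab$sample)) {
      sub <- tab[tab$sample == sid, setdiff(names(tab), "sample"), drop = FALSE]
      write_tsv(sub, file.path(dir, sprintf("%s_%s.tsv", layer, sid)))
    }
  }
  jsonlite::write_json(list(mediators = cohort$truth$mediators,
                            drivers = cohort$truth$drivers,
                            events = cohort$truth$events,
                            config = cohort$truth$config),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
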