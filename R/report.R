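#' Path to a packaged reference fixture
#'
#' The package ships three plain-text fixtures reconstructed from a published
#' 12-tumor mouse HCC study: `exome_mutations.tsv` (157 somatic calls),
#' `layer_counts.tsv` (per-nodule up/down/unchanged counts for mRNA, protein,
#' phosphosite and miRNA layers) and `single_layer_flags.tsv` (74 mediators
#' with single-layer top-5% detectability flags).
#'
#' @param file Fixture file name.
#' @return Absolute path to the installed fixture.
#' @export
medinet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "medinet")
  if (path == "") stop("fixture not found: ", file)
  path
}

#' Parse a mutation table and summarise it
#'
#' Reads a mutation table (see [read_mutation_table()]) and tallies records
#' per tumor sample and per mouse (the mouse id is the tumor-sample prefix
#' before the nodule tag). Also computes, per mouse, the intersection of
#' mutated gene sets across its nodules, excluding `exclude_genes` — with
#' passenger-only mutations this intersection is expected to be empty.
#'
#' @param path Mutation table TSV.
#' @param exclude_genes Genes excluded from the intersection check (the
#'   engineered drivers; default `c("Pten", "Tsc1")`).
#' @return List with `records`, `n_total`, `per_sample` (named counts), and
#'   `common_genes_per_mouse` (named list of character vectors).
#' @export
parse_mutation_table <- function(path, exclude_genes = c("Pten", "Tsc1")) {
  records <- read_mutation_table(path)
  per_sample <- table(records$tumor_sample)
  mouse <- sub("N.*$", "", records$tumor_sample)
  common <- lapply(split(records, mouse), function(df) {
    sets <- lapply(split(df$gene, df$tumor_sample), unique)
    sets <- lapply(sets, setdiff, y = exclude_genes)
    if (length(sets) < 2L) return(character(0))
    inter <- character(0)
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i < j) inter <- union(inter, intersect(sets[[i]], sets[[j]]))
      }
    }
    sort(inter, method = "radix")
  })
  list(records = records, n_total = nrow(records),
       per_sample = c(per_sample), common_genes_per_mouse = common)
}

#' Mean dysregulated feature counts per omics layer
#'
#' From a per-sample layer-count table (columns `SAMPLE` and
#' `<LAYER>_{DOWN,NOT,UP}` for layers RNA, PROT, PHOS, MIRNA), computes the
#' mean over samples of (up + down) per layer, rounded to the nearest
#' integer.
#'
#' @param x Path to a layer-count TSV, or an equivalent data.frame.
#' @param expected_samples Required number of samples (default 12); fewer is
#'   a validation error, `NULL` disables the check.
#' @return Named numeric vector of rounded means: `mrna`, `protein`,
#'   `phosphosite`, `mirna`.
#' @export
summarize_events_per_sample <- function(x, expected_samples = 12L) {
  if (is.character(x)) {
    x <- data.table::fread(x, sep = "\t", header = TRUE, data.table = FALSE)
  }
  if (!is.null(expected_samples) && nrow(x) != expected_samples) {
    stop("expected ", expected_samples, " samples, found ", nrow(x))
  }
  layer_cols <- c(mrna = "RNA", protein = "PROT", phosphosite = "PHOS", mirna = "MIRNA")
  out <- vapply(layer_cols, function(prefix) {
    dn <- x[[paste0(prefix, "_DOWN")]]
    up <- x[[paste0(prefix, "_UP")]]
    if (is.null(dn) || is.null(up)) stop("missing columns for layer ", prefix)
    round(mean(dn + up))
  }, numeric(1))
  names(out) <- names(layer_cols)
  out
}

#' Classify mediators by single-layer detectability
#'
#' Given per-gene flags saying whether each mediator would be ranked in the
#' top 5% by a single-omics analysis (RNA, proteome, phosphoproteome alone),
#' classifies every mediator as detectable by exactly one layer, several
#' (`multi`), or none — quantifying what the multi-omics integration adds.
#'
#' @param x Path to a flags TSV (columns `GENE`, `RNA_TOP5`, `PROT_TOP5`,
#'   `PHOS_TOP5`), or an equivalent data.frame.
#' @param mediators Optional character vector restricting/validating the
#'   mediator list; an entry absent from the flag table is an error.
#' @return List with `classification` (named character) and `counts` (table
#'   over `rna_only`, `protein_only`, `phospho_only`, `multi`, `none`).
#' @export
single_layer_detectability <- function(x, mediators = NULL) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- data.table::fread(x, sep = "\t", header = TRUE, data.table = FALSE)
  }
  required <- c("GENE", "RNA_TOP5", "PROT_TOP5", "PHOS_TOP5")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) stop("flag table missing column(s): ", paste(missing, collapse = ", "))
  if (!is.null(mediators)) {
    absent <- setdiff(mediators, x$GENE)
    if (length(absent) > 0L) {
      stop("mediator(s) absent from flag table: ", paste(absent, collapse = ", "))
    }
    x <- x[x$GENE %in% mediators, , drop = FALSE]
  }
  n_layers <- (x$RNA_TOP5 > 0) + (x$PROT_TOP5 > 0) + (x$PHOS_TOP5 > 0)
  cls <- ifelse(n_layers == 0L, "none",
         ifelse(n_layers > 1L, "multi",
         ifelse(x$RNA_TOP5 > 0, "rna_only",
         ifelse(x$PROT_TOP5 > 0, "protein_only", "phospho_only"))))
  names(cls) <- x$GENE
  counts <- table(factor(cls, levels = c("rna_only", "protein_only",
                                         "phospho_only", "multi", "none")))
  list(classification = cls, counts = counts)
}

#' Per-layer dysregulation direction matrix for selected genes
#'
#' Builds the +1/-1/0 display convention: for each (gene, sample, layer),
#' +1 marks significant upregulation, -1 significant downregulation, 0 no
#' significant change (or not detected).
#'
#' @param layers Named list of differential tables with a `sample` column
#'   (names among `mrna`, `protein`, `phosphosite`).
#' @param genes Genes (rows of the output matrices).
#' @param alpha Significance threshold (default 0.05).
#' @return Named list of genes x samples integer matrices, one per layer.
#' @export
layer_direction_matrix <- function(layers, genes, alpha = 0.05) {
  lapply(layers[intersect(names(layers), c("mrna", "protein", "phosphosite"))],
         function(tab) {
    samples <- sort(unique(tab$sample), method = "radix")
    m <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
    key <- if (!is.null(tab$gene)) tab$gene else tab$feature
    sig <- tab$detected & !is.na(tab$padj) & tab$padj < alpha
    sub <- tab[sig & norm_gene(key) %in% norm_gene(genes), , drop = FALSE]
    if (nrow(sub) > 0L) {
      subkey <- if (!is.null(sub$gene)) sub$gene else sub$feature
      gi <- match(norm_gene(subkey), norm_gene(genes))
      si <- match(sub$sample, samples)
      dir <- ifelse(sub$log2fc >= 0, 1L, -1L)
      for (k in seq_len(nrow(sub))) {
        cur <- m[gi[k], si[k]]
        m[gi[k], si[k]] <- if (cur == 0L) dir[k] else cur
      }
    }
    m
  })
}
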