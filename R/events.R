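#' Read a somatic mutation table
#'
#' Parses the exome-sequencing mutation table dialect used throughout the
#' package: one row per somatic call with tumor/normal sample ids, locus,
#' alleles, gene symbol, effect and tumor depth/VAF. Percent-suffixed VAF
#' strings ("8.80%") are converted to fractions. Optional columns
#' (`DEPTH_NORMAL`, `VAF_NORMAL`, `PON_COUNT`) are carried through when
#' present and treated as missing otherwise.
#'
#' @param path TSV file in the mutation-table layout (header required).
#' @return A data.frame with columns `tumor_sample`, `normal_sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `effect`, `depth_tumor`, `vaf_tumor`, and
#'   optionally `depth_normal`, `vaf_normal`, `pon_count`.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           colClasses = "character", quote = "\"")
  as_mutation_records(raw, origin = path)
}

#' Coerce a raw mutation data.frame into validated mutation records
#'
#' @param raw Data.frame in the mutation-table column layout (see
#'   [read_mutation_table()]); values may be character.
#' @param origin Label used in error messages (default `"mutation table"`).
#' @return Validated mutation record data.frame.
#' @export
as_mutation_records <- function(raw, origin = "mutation table") {
  path <- origin
  cmap <- c(tumor_sample = "TUMOR_SAMPLE", normal_sample = "NORMAL_SAMPLE",
            chrom = "CHROM", pos = "POS", ref = "REF", alt = "ALT",
            gene = "GENE", effect = "EFFECT",
            depth_tumor = "DEPTH_TUMOR", vaf_tumor = "VAF_TUMOR")
  have <- toupper(names(raw))
  missing <- cmap[!cmap %in% have]
  if (length(missing) > 0L) {
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(cmap, have)
  out <- stats::setNames(raw[idx], names(cmap))
  out$pos <- parse_int_column(out$pos, path, "POS")
  out$depth_tumor <- parse_int_column(out$depth_tumor, path, "DEPTH_TUMOR")
  out$vaf_tumor <- parse_vaf_column(out$vaf_tumor, path, "VAF_TUMOR")
  for (opt in c("DEPTH_NORMAL", "VAF_NORMAL", "PON_COUNT")) {
    j <- match(opt, have)
    if (!is.na(j)) {
      col <- tolower(opt)
      out[[col]] <- if (opt == "VAF_NORMAL") {
        parse_vaf_column(raw[[j]], path, opt)
      } else {
        parse_int_column(raw[[j]], path, opt)
      }
    }
  }
  validate_mutation_records(out)
  out
}

parse_int_column <- function(x, path, col) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x) & x != "" & x != "NA")
  if (length(bad) > 0L) {
    stop(sprintf("%s: unparseable %s at line %d: '%s'", path, col, bad[1L] + 1L, x[bad[1L]]))
  }
  v
}

parse_vaf_column <- function(x, path, col) {
  pct <- grepl("%$", x)
  v <- suppressWarnings(as.numeric(sub("%$", "", x)))
  v[pct] <- v[pct] / 100
  bad <- which(is.na(v) & !is.na(x) & x != "" & x != "NA")
  if (length(bad) > 0L) {
    stop(sprintf("%s: unparseable %s at line %d: '%s'", path, col, bad[1L] + 1L, x[bad[1L]]))
  }
  v
}

validate_mutation_records <- function(records) {
  if (any(records$depth_tumor < 0L, na.rm = TRUE)) stop("negative tumor depth in mutation records")
  if (any(records$vaf_tumor < 0 | records$vaf_tumor > 1, na.rm = TRUE)) {
    stop("tumor VAF outside [0, 1] in mutation records")
  }
  if (any(records$pos < 1L, na.rm = TRUE)) stop("position < 1 in mutation records")
  if (!is.null(records$depth_normal) && any(records$depth_normal < 0L, na.rm = TRUE)) {
    stop("negative normal depth in mutation records")
  }
  if (!is.null(records$vaf_normal) &&
      any(records$vaf_normal < 0 | records$vaf_normal > 1, na.rm = TRUE)) {
    stop("normal VAF outside [0, 1] in mutation records")
  }
  invisible(records)
}

#' Filter somatic variant calls
#'
#' Applies the study-style somatic filters to a mutation record table:
#' * tumor depth >= `min_depth_tumor` (default 10 reads)
#' * normal depth >= `min_depth_normal` (default 5 reads)
#' * supporting reads, `round(depth_tumor * vaf_tumor)`, >= `min_alt_reads`
#'   (default 3)
#' * tumor VAF at least `min_vaf_ratio` times the normal VAF (default 5x;
#'   a record with normal VAF 0 always passes this ratio filter)
#' * present in fewer than `max_pon_hits` panel-of-normals samples
#'   (default: dropped when seen in >= 2 of the 4 normals)
#'
#' Records lacking an optional field (normal depth/VAF, panel counts) pass
#' the corresponding filter. Input order is preserved.
#'
#' @param records Mutation record data.frame from [read_mutation_table()].
#' @param min_depth_tumor,min_depth_normal,min_alt_reads,min_vaf_ratio,max_pon_hits
#'   Filter thresholds; see description for defaults.
#' @return The surviving records, with a `n_alt_reads` column added.
#' @export
filter_somatic_variants <- function(records,
                                    min_depth_tumor = 10L,
                                    min_depth_normal = 5L,
                                    min_alt_reads = 3L,
                                    min_vaf_ratio = 5,
                                    max_pon_hits = 2L) {
  validate_mutation_records(records)
  n <- nrow(records)
  pass <- rep(TRUE, n)
  pass <- pass & records$depth_tumor >= min_depth_tumor
  alt_reads <- round(records$depth_tumor * records$vaf_tumor)
  pass <- pass & alt_reads >= min_alt_reads
  if (!is.null(records$depth_normal)) {
    dn <- records$depth_normal
    pass <- pass & (is.na(dn) | dn >= min_depth_normal)
  }
  if (!is.null(records$vaf_normal)) {
    vn <- records$vaf_normal
    ratio_ok <- is.na(vn) | vn == 0 | records$vaf_tumor >= min_vaf_ratio * vn
    pass <- pass & ratio_ok
  }
  if (!is.null(records$pon_count)) {
    pc <- records$pon_count
    pass <- pass & (is.na(pc) | pc < max_pon_hits)
  }
  out <- records[pass, , drop = FALSE]
  out$n_alt_reads <- alt_reads[pass]
  rownames(out) <- NULL
  out
}

#' Read a per-sample differential table for one omics layer
#'
#' Layer tables are TSV with columns `feature`, `log2fc`, `padj`, `detected`
#' and, for the phosphosite layer, an additional `gene` column mapping each
#' site to its parent protein. A feature with `detected = 0` was not measured
#' in that sample (its `padj` may be NA); a detected feature must carry an
#' adjusted p-value.
#'
#' @param path TSV file.
#' @param layer One of `"mrna"`, `"mirna"`, `"protein"`, `"phosphosite"`.
#' @return A data.frame with a `layer` attribute.
#' @export
read_differential_table <- function(path, layer = c("mrna", "mirna", "protein", "phosphosite")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("differential table not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           quote = "\"")
  required <- c("feature", "log2fc", "padj", "detected")
  if (layer == "phosphosite") required <- c(required, "gene")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(layer, " table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab$feature <- as.character(tab$feature)
  tab$detected <- as.logical(tab$detected)
  if (any(tab$detected & is.na(tab$padj))) {
    stop(layer, " table has detected features without an adjusted p-value")
  }
  if (any(!is.na(tab$padj) & (tab$padj < 0 | tab$padj > 1))) {
    stop(layer, " table has adjusted p-values outside [0, 1]")
  }
  if (anyDuplicated(tab$feature)) {
    stop(layer, " table has duplicate feature rows")
  }
  attr(tab, "layer") <- layer
  tab
}

#' Collapse phosphosite calls to gene level
#'
#' A gene counts as dysregulated at the phosphoproteome level if at least one
#' of its phosphosites is differentially regulated (adjusted p < `alpha`); a
#' gene whose sites are all detected but non-significant is not included.
#'
#' @param phospho Phosphosite differential table (needs `gene`, `padj`,
#'   `detected` columns).
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector of gene symbols with >= 1 significant site.
#' @export
collapse_phosphosites <- function(phospho, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (nrow(phospho) == 0L) return(character(0))
  if (is.null(phospho$gene) || any(is.na(phospho$gene) | phospho$gene == "")) {
    stop("phosphosite rows must carry a parent gene symbol")
  }
  sig <- phospho$detected & !is.na(phospho$padj) & phospho$padj < alpha
  sort(unique(as.character(phospho$gene[sig])), method = "radix")
}

# per-gene layer status: "significant", "insignificant" (detected), "not_detected"
layer_status <- function(tab, genes, alpha, gene_col = "feature") {
  status <- rep("not_detected", length(genes))
  names(status) <- genes
  if (nrow(tab) == 0L) return(status)
  g <- norm_gene(tab[[gene_col]])
  det <- tapply(tab$detected, g, any)
  sig <- tapply(tab$detected & !is.na(tab$padj) & tab$padj < alpha, g, any)
  idx <- match(norm_gene(genes), names(det))
  hit <- !is.na(idx)
  status[hit & sig[idx] %in% TRUE] <- "significant"
  status[hit & det[idx] %in% TRUE & !(sig[idx] %in% TRUE)] <- "insignificant"
  status
}

norm_gene <- function(x) toupper(trimws(as.character(x)))

#' Combine RNA, proteome and phosphoproteome evidence into downstream events
#'
#' Implements the layer-combination rule for downstream differential
#' expression: a gene enters the downstream event set iff
#' * it is significant at the proteome OR phosphoproteome level; or
#' * neither its protein nor any of its phosphosites were detected at all,
#'   and it is significant at the RNA level.
#'
#' A gene whose protein (or phosphosites) were detected but not significant is
#' excluded regardless of its RNA status: measured-and-unchanged protein
#' evidence overrides transcript-level change.
#'
#' @param rna mRNA differential table (`feature` = gene symbol).
#' @param protein Protein differential table (`feature` = gene symbol).
#' @param phospho Phosphosite differential table (site-level rows with a
#'   `gene` column), or `NULL` for none.
#' @param alpha FDR threshold applied at every layer (default 0.05).
#' @return Sorted character vector of downstream event genes, with a
#'   `provenance` attribute (named character: `"protein_or_phospho"` or
#'   `"rna"`).
#' @export
combine_downstream <- function(rna, protein, phospho = NULL, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  genes <- sort(unique(norm_gene(c(rna$feature, protein$feature,
                                   if (!is.null(phospho)) phospho$gene))),
                method = "radix")
  genes <- genes[genes != ""]
  rna_s <- layer_status(rna, genes, alpha)
  prot_s <- layer_status(protein, genes, alpha)
  phos_s <- if (is.null(phospho) || nrow(phospho) == 0L) {
    stats::setNames(rep("not_detected", length(genes)), genes)
  } else {
    layer_status(phospho, genes, alpha, gene_col = "gene")
  }
  # merge proteome and phosphoproteome with OR before applying the rule
  pp <- ifelse(prot_s == "significant" | phos_s == "significant", "significant",
        ifelse(prot_s == "insignificant" | phos_s == "insignificant",
               "insignificant", "not_detected"))
  take_pp <- pp == "significant"
  take_rna <- pp == "not_detected" & rna_s == "significant"
  out <- genes[take_pp | take_rna]
  prov <- ifelse(take_pp[take_pp | take_rna], "protein_or_phospho", "rna")
  names(prov) <- out
  attr(out, "provenance") <- prov
  out
}

#' Assemble the per-sample upstream and downstream event sets
#'
#' Upstream causal events are the genes carrying surviving somatic mutations
#' plus the significantly differentially expressed miRNAs; downstream events
#' are the genes produced by [combine_downstream()]. Both sets are intersected
#' with the scoring network's node set (matching is case-insensitive after
#' trimming); off-network events are counted and reported via attributes.
#'
#' @param mutations Filtered mutation records for one sample (may have 0 rows).
#' @param mirna miRNA differential table for the same sample.
#' @param downstream Downstream gene set from [combine_downstream()].
#' @param sample Sample id.
#' @param net The scoring `medinet_network` (usually the largest SCC).
#' @param alpha FDR threshold for miRNA significance (default 0.05).
#' @return A `medinet_sample_events` object: list with `sample`, `upstream`,
#'   `downstream` (node ids as spelled in the network), `provenance` (named
#'   character vector over both sets), `scoreable` flag, and counts of
#'   off-network events dropped.
#' @export
build_sample_events <- function(mutations, mirna, downstream, sample, net,
                                alpha = 0.05) {
  stopifnot(inherits(net, "medinet_network"))
  node_key <- norm_gene(net$nodes)
  to_node <- function(ids) {
    hit <- match(norm_gene(ids), node_key)
    list(on = net$nodes[hit[!is.na(hit)]], n_off = sum(is.na(hit)))
  }
  mut_genes <- unique(as.character(mutations$gene))
  mir_sig <- character(0)
  if (!is.null(mirna) && nrow(mirna) > 0L) {
    sig <- mirna$detected & !is.na(mirna$padj) & mirna$padj < alpha
    mir_sig <- unique(as.character(mirna$feature[sig]))
  }
  mu <- to_node(mut_genes)
  mi <- to_node(mir_sig)
  dn <- to_node(unique(as.character(downstream)))
  upstream <- sort(unique(c(mu$on, mi$on)), method = "radix")
  down <- sort(unique(dn$on), method = "radix")
  prov <- c(stats::setNames(rep("mutation", length(mu$on)), mu$on),
            stats::setNames(rep("mirna", length(mi$on)), mi$on),
            stats::setNames(rep("downstream", length(dn$on)), dn$on))
  n_off <- mu$n_off + mi$n_off + dn$n_off
  scoreable <- length(upstream) > 0L && length(down) > 0L
  if (!scoreable) {
    warning(sprintf("sample %s is unscoreable: %d upstream / %d downstream events on the network",
                    sample, length(upstream), length(down)))
  }
  if (n_off > 0L) {
    message(sprintf("sample %s: %d event(s) not on the scoring network were dropped",
                    sample, n_off))
  }
  structure(list(sample = sample, upstream = upstream, downstream = down,
                 provenance = prov, scoreable = scoreable, n_off_network = n_off),
            class = "medinet_sample_events")
}

#' @export
print.medinet_sample_events <- function(x, ...) {
  cat(sprintf("medinet_sample_events[%s]: %d upstream, %d downstream%s\n",
              x$sample, length(x$upstream), length(x$downstream),
              if (x$scoreable) "" else " (unscoreable)"))
  invisible(x)
}
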