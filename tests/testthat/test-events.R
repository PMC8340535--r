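mut_record <- function(gene = "G1", depth_tumor = 50L, vaf_tumor = 0.2,
                       depth_normal = 30L, vaf_normal = 0, pon_count = 0L,
                       sample = "T1") {
  data.frame(tumor_sample = sample, normal_sample = "N1", chrom = "1",
             pos = 100L, ref = "C", alt = "A", gene = gene, effect = "missense",
             depth_tumor = depth_tumor, vaf_tumor = vaf_tumor,
             depth_normal = depth_normal, vaf_normal = vaf_normal,
             pon_count = pon_count, stringsAsFactors = FALSE)
}

test_that("somatic filter applies each study threshold", {
  keep <- mut_record()
  expect_equal(nrow(filter_somatic_variants(keep)), 1L)
  expect_equal(nrow(filter_somatic_variants(mut_record(depth_tumor = 9L))), 0L)
  expect_equal(nrow(filter_somatic_variants(mut_record(depth_normal = 4L))), 0L)
  # supporting reads = round(depth * vaf) must reach 3
  expect_equal(nrow(filter_somatic_variants(mut_record(depth_tumor = 20L, vaf_tumor = 0.1))), 0L)
  # tumor VAF must be >= 5x normal VAF; normal VAF 0 always passes
  expect_equal(nrow(filter_somatic_variants(mut_record(vaf_tumor = 0.2, vaf_normal = 0.1))), 0L)
  expect_equal(nrow(filter_somatic_variants(mut_record(vaf_tumor = 0.2, vaf_normal = 0))), 1L)
  expect_equal(nrow(filter_somatic_variants(mut_record(pon_count = 2L))), 0L)
  expect_equal(nrow(filter_somatic_variants(mut_record(pon_count = 1L))), 1L)
  expect_error(filter_somatic_variants(mut_record(depth_tumor = -1L)), "negative")
})

test_that("somatic filter equals an independent per-predicate oracle", {
  set.seed(42)
  n <- 200
  recs <- do.call(rbind, replicate(n, mut_record(), simplify = FALSE))
  recs$depth_tumor <- sample(0:40, n, replace = TRUE)
  recs$vaf_tumor <- round(runif(n, 0, 0.6), 3)
  recs$depth_normal <- sample(0:20, n, replace = TRUE)
  recs$vaf_normal <- round(runif(n, 0, 0.1), 3)
  recs$pon_count <- sample(0:4, n, replace = TRUE)
  recs$gene <- sprintf("G%03d", seq_len(n))
  got <- filter_somatic_variants(recs)
  oracle <- recs[recs$depth_tumor >= 10 &
                 recs$depth_normal >= 5 &
                 round(recs$depth_tumor * recs$vaf_tumor) >= 3 &
                 (recs$vaf_normal == 0 | recs$vaf_tumor >= 5 * recs$vaf_normal) &
                 recs$pon_count < 2, ]
  expect_equal(got$gene, oracle$gene)  # order preserved

  # monotone: relaxing any threshold never removes a survivor
  relaxed <- filter_somatic_variants(recs, min_depth_tumor = 5L,
                                     min_alt_reads = 1L, min_vaf_ratio = 2,
                                     min_depth_normal = 2L, max_pon_hits = 4L)
  expect_true(all(got$gene %in% relaxed$gene))
})

test_that("missing optional fields pass their filters", {
  rec <- mut_record()
  rec$depth_normal <- NULL; rec$vaf_normal <- NULL; rec$pon_count <- NULL
  expect_equal(nrow(filter_somatic_variants(rec)), 1L)
})

test_that("phosphosite collapse keeps genes with >= 1 significant site", {
  tab <- data.frame(feature = c("s1", "s2", "s3", "s4"),
                    log2fc = 0, padj = c(0.01, 0.9, 0.9, 0.7),
                    detected = TRUE, gene = c("G", "G", "H", "H"))
  expect_equal(collapse_phosphosites(tab), "G")
  expect_equal(collapse_phosphosites(tab[0, ]), character(0))
  tab$gene[1] <- ""
  expect_error(collapse_phosphosites(tab), "parent gene")
})

test_that("combine_downstream matches the 9-case truth table", {
  # statuses: significant (padj 0.01), insignificant (padj 0.5), not detected
  status_row <- function(gene, status) {
    switch(status,
           sig = data.frame(feature = gene, log2fc = 1, padj = 0.01, detected = TRUE),
           insig = data.frame(feature = gene, log2fc = 0, padj = 0.5, detected = TRUE),
           nd = NULL)
  }
  states <- c("sig", "insig", "nd")
  cases <- expand.grid(rna = states, pp = states, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    rna <- status_row("G", cases$rna[i])
    prot <- status_row("G", cases$pp[i])
    rna <- if (is.null(rna)) data.frame(feature = character(0), log2fc = numeric(0),
                                        padj = numeric(0), detected = logical(0)) else rna
    prot <- if (is.null(prot)) data.frame(feature = character(0), log2fc = numeric(0),
                                          padj = numeric(0), detected = logical(0)) else prot
    got <- combine_downstream(rna, prot, NULL)
    # oracle: the literal combination rule
    want <- if (cases$pp[i] == "sig") "G"
            else if (cases$pp[i] == "nd" && cases$rna[i] == "sig") "G"
            else character(0)
    expect_equal(as.character(got), want,
                 info = paste(cases$rna[i], cases$pp[i]))
  }
})

test_that("phosphoproteome evidence merges with protein by OR", {
  rna <- data.frame(feature = "G", log2fc = 1, padj = 0.01, detected = TRUE)
  prot_insig <- data.frame(feature = "G", log2fc = 0, padj = 0.6, detected = TRUE)
  phos_sig <- data.frame(feature = "G_s1", log2fc = 2, padj = 0.02,
                         detected = TRUE, gene = "G")
  # phospho significant rescues a detected-insignificant protein
  expect_equal(as.character(combine_downstream(rna, prot_insig, phos_sig)), "G")
  # phospho detected-insignificant blocks the RNA route
  phos_insig <- transform(phos_sig, padj = 0.9)
  empty <- data.frame(feature = character(0), log2fc = numeric(0),
                      padj = numeric(0), detected = logical(0))
  expect_equal(as.character(combine_downstream(rna, empty, phos_insig)), character(0))
})

test_that("build_sample_events assembles and intersects with the network", {
  net <- network_from_edges(c("Pten", "Tsc1", "mmu-miR-375", "Yap1"),
                            c("Yap1", "Yap1", "Yap1", "Pten"))
  muts <- data.frame(gene = c("Pten", "Tsc1", "Xyz"))
  mirna <- data.frame(feature = c("mmu-miR-375", "mmu-miR-999"),
                      log2fc = c(-2, -1), padj = c(0.001, 0.5), detected = TRUE)
  ev <- suppressMessages(
    build_sample_events(muts, mirna, downstream = "Yap1", sample = "T1", net = net))
  expect_setequal(ev$upstream, c("Pten", "Tsc1", "mmu-miR-375"))
  expect_equal(ev$downstream, "Yap1")
  expect_true(ev$scoreable)
  expect_equal(ev$n_off_network, 1L)

  # all events off-network: unscoreable, warned, not fatal
  expect_warning(
    ev2 <- suppressMessages(
      build_sample_events(data.frame(gene = "Nope"),
                          mirna[0, ], downstream = character(0),
                          sample = "T2", net = net)),
    "unscoreable")
  expect_false(ev2$scoreable)
})

test_that("mutation table reader parses percent VAF and validates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TUMOR_SAMPLE\tNORMAL_SAMPLE\tCHROM\tPOS\tREF\tALT\tGENE\tEFFECT\tDEPTH_TUMOR\tVAF_TUMOR",
               "T1\tN1\t1\t100\tC\tA\tPten\tmissense\t58\t8.80%"), tf)
  rec <- read_mutation_table(tf)
  expect_equal(rec$vaf_tumor, 0.088)
  expect_equal(rec$depth_tumor, 58L)

  writeLines(c("TUMOR_SAMPLE\tNORMAL_SAMPLE\tCHROM\tPOS\tREF\tALT\tGENE\tEFFECT\tDEPTH_TUMOR\tVAF_TUMOR",
               "T1\tN1\t1\tabc\tC\tA\tPten\tmissense\t58\t8.80%"), tf)
  expect_error(read_mutation_table(tf), "POS at line 2")
})

test_that("differential table reader enforces its contract", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\tlog2fc\tpadj\tdetected",
               "G1\t1.5\t0.01\t1", "G2\t0.1\tNA\t0"), tf)
  tab <- read_differential_table(tf, "mrna")
  expect_equal(nrow(tab), 2L)
  writeLines(c("feature\tlog2fc\tpadj\tdetected", "G1\t1.5\tNA\t1"), tf)
  expect_error(read_differential_table(tf, "mrna"), "without an adjusted p-value")
})
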