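peak_df <- function(summits, chrom = "chr1", halfw = 500) {
  data.frame(chrom = chrom, start = summits - halfw, end = summits + halfw,
             name = sprintf("p%d", seq_along(summits)), summit = halfw,
             stringsAsFactors = FALSE)
}

test_that("CRE windows are +/-W around the summit and merge within windows", {
  cres <- define_cres(peak_df(100000), half_width = 2500)
  expect_equal(cres$start, 97500)
  expect_equal(cres$end, 102500)
  ## second summit inside the first window is absorbed
  expect_equal(nrow(define_cres(peak_df(c(100000, 100400)))), 1L)
  ## summits 6 kb apart give two CREs
  expect_equal(nrow(define_cres(peak_df(c(100000, 106000)))), 2L)
  ## merging applies across time-point rounds, first window kept
  two_rounds <- define_cres(list(peak_df(100000), peak_df(101000)))
  expect_equal(nrow(two_rounds), 1L)
  expect_equal(two_rounds$summit, 100000)
  ## a peak without a summit is an error
  bad <- peak_df(100000); bad$summit <- NA_integer_
  expect_error(define_cres(bad), "summit")
})

test_that("CRE ids are unique and classes partition the CRE set", {
  set.seed(2)
  cres <- define_cres(peak_df(sort(sample(seq(1e5, 5e6, by = 1000), 200))))
  expect_equal(anyDuplicated(cres$cre_id), 0L)
  cres <- classify_cres(cres)
  expect_true(all(cres$cre_class %in% c("promoter", "enhancer")))
})

tx_df <- function(gene, transcript, start, end, strand, tpms) {
  out <- data.frame(transcript = transcript, gene = gene, chrom = "chr1",
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  out[tpm_cols <- paste0("tpm_", default_timepoints())] <-
    matrix(tpms, nrow = length(gene), ncol = 5)
  out
}

test_that("the highest-expressed isoform defines the promoter TSS", {
  cres <- make_cres(c(100000, 300000))
  tx <- tx_df(c("gA", "gA"), c("gA.t1", "gA.t2"),
              start = c(100000, 300000), end = c(105000, 305000),
              strand = "+", tpms = c(5, 10))
  pa <- assign_promoters(cres, tx)
  expect_equal(pa$map$transcript, "gA.t2")
  expect_equal(pa$map$cre_id, cres$cre_id[2])
  expect_equal(pa$cres$cre_class[2], "promoter")
  expect_equal(pa$cres$gene[2], "gA")
})

test_that("genes without an overlapping CRE are excluded and logged", {
  cres <- make_cres(100000)
  tx <- tx_df("gB", "gB.t1", 500000, 510000, "+", 3)
  expect_message(pa <- assign_promoters(cres, tx), "excluded")
  expect_equal(pa$excluded_genes, "gB")
  expect_equal(nrow(pa$map), 0L)
})

test_that("minus-strand TSS is the last covered base and ambiguity resolves by overlap", {
  cres <- make_cres(c(100000, 104000))
  ## minus-strand transcript [95001, 104001): TSS = 104000
  tx <- tx_df("gC", "gC.t1", 95001, 104001, "-", 2)
  expect_message(pa <- assign_promoters(cres, tx), "multiple CREs")
  expect_equal(pa$map$tss, 104000)
  ## TSS window [101500,106500) overlaps CRE2 fully, CRE1 partially
  expect_equal(pa$map$cre_id, cres$cre_id[2])
})

test_that("binding flags use any-timepoint overlap and are monotone", {
  cres <- make_cres(c(100000, 200000))
  ar_t72 <- peak_df(100200, halfw = 100)
  out <- classify_cres(cres, ar_peaks = list(data.frame(peak_df(1)[0, ]),
                                             ar_t72))
  expect_equal(out$ar_bound, c(TRUE, FALSE))
  ## adding more peaks can only flip FALSE -> TRUE
  out2 <- classify_cres(out, ar_peaks = peak_df(200000))
  expect_equal(out2$ar_bound, c(TRUE, TRUE))
  ## a promoter overlapping an AR peak keeps its class
  cres$cre_class <- c("promoter", NA)
  out3 <- classify_cres(cres, ar_peaks = ar_t72)
  expect_equal(out3$cre_class, c("promoter", "enhancer"))
  expect_true(out3$ar_bound[1])
})

test_that("gene sets: downregulation LFC and expression quartiles", {
  tps <- default_timepoints()
  expr <- data.frame(gene = sprintf("g%03d", 1:100))
  expr[paste0("tpm_", tps)] <- matrix(rep(100:1, 5), ncol = 5)
  expr$tpm_16h[1] <- 100 / 5.1   # clear 16h drop for gene 1
  g <- define_gene_sets(expr, hallmark_genes = c("g001", "g002"))
  expect_true(g$hallmark[1] && g$hallmark[2] && !any(g$hallmark[-(1:2)]))
  expect_equal(as.integer(table(g$quartile)), rep(25L, 4))
  expect_true(g$downregulated[1])
  expect_false(any(g$downregulated[-1]))
  ## LFC arithmetic: 10 -> 2 with eps 0.01
  e2 <- data.frame(gene = "x")
  e2[paste0("tpm_", tps)] <- as.list(c(10, 10, 10, 2, 10))
  suppressWarnings(g2 <- define_gene_sets(e2, "none"))
  expect_equal(g2$lfc, log2(2.01 / 10.01), tolerance = 1e-12)
  expect_true(g2$downregulated)
  ## flat expression is not downregulated
  e2[paste0("tpm_", tps)] <- as.list(rep(10, 5))
  suppressWarnings(g3 <- define_gene_sets(e2, "none"))
  expect_equal(g3$lfc, 0)
  expect_false(g3$downregulated)
})

test_that("background gene sampling is seeded and hallmark-free", {
  tps <- default_timepoints()
  expr <- data.frame(gene = sprintf("g%03d", 1:100))
  expr[paste0("tpm_", tps)] <- matrix(rep(100:1, 5), ncol = 5)
  g <- define_gene_sets(expr, hallmark_genes = c("g001"))
  s1 <- sample_background_genes(g, 10, quartiles = "Q1", seed = 3)
  s2 <- sample_background_genes(g, 10, quartiles = "Q1", seed = 3)
  expect_identical(s1, s2)
  expect_false("g001" %in% s1)
  expect_true(all(g$quartile[match(s1, g$gene)] == "Q1"))
})
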