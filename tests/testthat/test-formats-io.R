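test_that("narrowPeak parsing maps fields and summit offsets", {
  p <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t1000\t2000\tp1\t.\t.\t5\t4\t3\t500", p)
  iv <- read_intervals(p, format = "narrowPeak")
  expect_equal(iv$chrom, "chr1")
  expect_equal(iv$start, 1000L)
  expect_equal(iv$end, 2000L)
  expect_equal(iv$summit, 500L)
})

test_that("BED without a summit column falls back to the midpoint", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000", "chr2\t10\t15"), p)
  iv <- read_intervals(p, format = "bed")
  expect_equal(iv$summit, c(500L, 2L))
})

test_that("malformed interval lines error with the line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1000", p)
  expect_error(read_intervals(p), "line 1")
  writeLines(c("chr1\t10\t20\tx", "chr1\t30"), p)
  expect_error(read_intervals(p), "line 2")
})

test_that("empty interval files warn and return an empty table", {
  p <- withr::local_tempfile(fileext = ".bed")
  file.create(p)
  expect_warning(iv <- read_intervals(p), "empty")
  expect_equal(nrow(iv), 0L)
})

make_loop_file <- function(rows) {
  p <- withr::local_tempfile(fileext = ".bedpe", .local_envir = parent.frame())
  header <- paste(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "name", "mark", paste0("cf_", default_timepoints())),
                  collapse = "\t")
  writeLines(c(header, rows), p)
  p
}

test_that("loop reading canonicalizes anchors and maps counts in time order", {
  p <- make_loop_file(
    "chr1\t900000\t905000\tchr1\t100000\t105000\tl1\tH3K27ac\t3.0\t0\t1\t2\t5")
  ls <- read_loops(p)
  expect_equal(ls$loops$start1, 100000)
  expect_equal(ls$loops$start2, 900000)
  expect_equal(unname(unlist(ls$loops[paste0("cf_", default_timepoints())])),
               c(3, 0, 1, 2, 5))
})

test_that("inter-chromosomal loops are skipped and counted", {
  p <- make_loop_file(c(
    "chr1\t100000\t105000\tchr1\t200000\t205000\tl1\tH3K27ac\t1\t1\t1\t1\t1",
    "chr1\t100000\t105000\tchr2\t200000\t205000\tl2\tH3K27ac\t1\t1\t1\t1\t1",
    "chr1\t300000\t305000\tchr1\t400000\t405000\tl3\tH3K27ac\t2\t2\t2\t2\t2"))
  ls <- read_loops(p)
  expect_equal(nrow(ls$loops), 2L)
  expect_equal(ls$skip$inter_chromosomal, 1L)
  expect_equal(ls$n_input, 3L)
})

test_that("a missing per-timepoint count column is an error", {
  p <- withr::local_tempfile(fileext = ".bedpe")
  header <- paste(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "name", "mark", paste0("cf_", c("0m", "30m", "4h", "72h"))),
                  collapse = "\t")
  writeLines(c(header,
               "chr1\t100000\t105000\tchr1\t200000\t205000\tl1\tH3K27ac\t1\t1\t1\t1"),
             p)
  expect_error(read_loops(p), "cf_16h")
})

test_that("loop distance bounds are enforced via the skip report", {
  p <- make_loop_file(c(
    "chr1\t100000\t105000\tchr1\t101000\t106000\tl1\tH3K27ac\t1\t1\t1\t1\t1",
    "chr1\t100000\t105000\tchr1\t9000000\t9005000\tl2\tH3K27ac\t1\t1\t1\t1\t1",
    "chr1\t100000\t105000\tchr1\t200000\t205000\tl3\tH3K27ac\t1\t1\t1\t1\t1"))
  ls <- read_loops(p)
  expect_equal(nrow(ls$loops), 1L)
  expect_equal(ls$skip$out_of_range, 2L)
})

test_that("typed table reading enforces the schema", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttpm_0m\ttpm_16h", "g1\t1.5\t2.5", "g2\tNA\t3"), p)
  schema <- c(gene = "character", tpm_0m = "numeric", tpm_16h = "numeric")
  expect_error(read_table(p, schema), "row 2")
  writeLines(c("gene\ttpm_0m", "g1\t1.5"), p)
  expect_error(read_table(p, schema), "missing column tpm_16h")
  writeLines(c("gene\ttpm_0m\ttpm_16h", "g1\t1.5\t2.5"), p)
  tab <- read_table(p, schema)
  expect_identical(tab$tpm_16h, 2.5)
})

test_that("interval and loop writes round-trip exactly", {
  iv <- data.frame(chrom = "chr1", start = 1234L, end = 9876L, name = "p1",
                   summit = 4321L, stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".narrowPeak")
  write_intervals(iv, p, format = "narrowPeak")
  expect_equal(read_intervals(p, format = "narrowPeak"), iv)

  cres <- make_cres(c(100000, 200000))
  cf <- matrix(c(0.1234567890123, 2, 3, 4, 5), 1, 5)
  ls <- make_loop_set(cres, cbind(1, 2), cf)
  p2 <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(ls, p2)
  back <- read_loops(p2)
  expect_identical(back$loops[paste0("cf_", default_timepoints())],
                   ls$loops[paste0("cf_", default_timepoints())])
  ## canonicalization is idempotent
  p3 <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(back, p3)
  expect_identical(readLines(p2), readLines(p3))
})
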