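triangle_network <- function() {
  cres <- make_cres(c(100000, 200000, 300000))
  ls <- make_loop_set(cres, rbind(c(1, 2), c(2, 3), c(1, 3)),
                      matrix(1, 3, 5))
  list(cres = cres, net = build_network(ls, cres))
}

test_that("a loop triangle yields three edges of degree two", {
  tr <- triangle_network()
  expect_equal(nrow(tr$net$edges), 3L)
  deg <- loop_count_distribution(tr$net)
  expect_equal(deg$degree, c(2L, 2L, 2L))
})

test_that("unmapped and self-mapping loops are skipped and counted", {
  cres <- make_cres(c(100000, 200000))
  far <- make_cres(900000)  # not part of the CRE universe handed to build
  ls <- make_loop_set(rbind(cres, far),
                      rbind(c(1, 2), c(1, 3)), matrix(1, 2, 5))
  net <- build_network(ls, cres)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$skip$H3K27ac$unmapped, 1L)
  ## both anchors inside one CRE window -> self loop skipped
  cres1 <- make_cres(100000)
  ls2 <- make_loop_set(rbind(cres1, cres1), rbind(c(1, 2)), matrix(1, 1, 5))
  net2 <- build_network(ls2, cres1)
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(net2$skip$H3K27ac$self, 1L)
})

test_that("parallel loops collapse with summed counts and rows reconcile", {
  cres <- make_cres(c(100000, 200000))
  ls <- make_loop_set(cres, rbind(c(1, 2), c(2, 1)),
                      rbind(rep(2, 5), rep(3, 5)))
  net <- build_network(ls, cres)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$cf_0m, 5)
  sk <- net$skip$H3K27ac
  expect_equal(nrow(net$edges) + sk$unmapped + sk$self + sk$collapsed +
                 sk$inter_chromosomal, net$n_input$H3K27ac)
})

test_that("network construction is invariant to input row order", {
  cres <- make_cres(seq(1e5, 9e5, by = 1e5))
  set.seed(5)
  pairs <- t(combn(9, 2))[sample(36, 12), ]
  cf <- matrix(runif(60), 12, 5)
  n1 <- build_network(make_loop_set(cres, pairs, cf), cres)
  o <- sample(12)
  n2 <- build_network(make_loop_set(cres, pairs[o, ], cf[o, ]), cres)
  key <- function(n) n$edges[order(n$edges$node1, n$edges$node2), ]
  expect_equal(key(n1), key(n2), ignore_attr = TRUE)
})

test_that("loop class fractions are computed per mark and sum to one", {
  cres <- make_cres(c(100000, 200000, 300000, 400000),
                    cre_class = c("promoter", "promoter", "enhancer",
                                  "enhancer"))
  ls <- make_loop_set(cres, rbind(c(1, 2), c(1, 3), c(3, 4)), matrix(1, 3, 5))
  cl <- classify_loops(build_network(ls, cres), cres)
  expect_equal(sort(cl$class), c("E-E", "E-P", "P-P"))
  expect_equal(cl$fraction, rep(1 / 3, 3))
  expect_lt(abs(sum(cl$fraction) - 1), 1e-12)
  ## all-enhancer graph
  cres2 <- make_cres(c(100000, 200000), cre_class = "enhancer")
  cl2 <- classify_loops(build_network(
    make_loop_set(cres2, rbind(c(1, 2)), matrix(1, 1, 5)), cres2), cres2)
  expect_equal(cl2$fraction[cl2$class == "E-E"], 1)
})

test_that("first-degree queries return neighbors with weights", {
  tr <- triangle_network()
  fd <- first_degree(tr$net, tr$cres$cre_id[1])
  expect_setequal(fd$neighbor, tr$cres$cre_id[2:3])
  expect_error(first_degree(tr$net, "chrX:1-2"), "unknown")
  ## star graph with 15 leaves emulates the typical per-gene contact count
  cres <- make_cres(seq(1e5, 16e5, by = 1e5))
  star <- make_loop_set(cres, cbind(1, 2:16), matrix(1, 15, 5))
  net <- build_network(star, cres)
  expect_equal(nrow(first_degree(net, cres$cre_id[1])), 15L)
  expect_equal(nrow(first_degree(net, cres$cre_id[2])), 1L)
  ## isolated node
  cres2 <- rbind(cres, make_cres(5e6))
  net2 <- build_network(star, cres2)
  expect_equal(nrow(first_degree(net2, cres2$cre_id[17])), 0L)
})

test_that("signal aggregation is a length-weighted mean with zero fill", {
  cres <- make_cres(100000)  # window [97500, 102500)
  full <- data.frame(chrom = "chr1", start = 90000, end = 110000, value = 5)
  expect_equal(unname(aggregate_signal(full, cres)), 5)
  half <- data.frame(chrom = "chr1", start = 97500, end = 100000, value = 10)
  expect_equal(unname(aggregate_signal(half, cres)), 5)
  none <- data.frame(chrom = "chr1", start = 1, end = 10, value = 10)
  expect_equal(unname(aggregate_signal(none, cres)), 0)
  other <- data.frame(chrom = "chr9", start = 97500, end = 102500, value = 7)
  expect_message(v <- aggregate_signal(other, cres), "chr9")
  expect_equal(unname(v), 0)
})

test_that("degree distributions honor the presence threshold", {
  cres <- make_cres(seq(1e5, 4e5, by = 1e5))
  ls <- make_loop_set(cres, rbind(c(1, 2), c(2, 3), c(3, 4)),
                      matrix(0.5, 3, 5))
  net <- build_network(ls, cres)
  d0 <- loop_count_distribution(net, timepoint = "16h",
                                presence_threshold = 1)
  expect_equal(d0$degree, rep(0L, 4))
  d1 <- loop_count_distribution(net, timepoint = "16h",
                                presence_threshold = 0.1)
  expect_equal(sum(d1$degree), 6L)
})
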