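test_that("Gini matches hand-computed values and conventions", {
  expect_equal(gini_index(rep(3.7, 4)), 0)
  expect_equal(gini_index(c(0, 1)), 0.5, tolerance = 1e-15)
  expect_equal(gini_index(c(4, 0, 0, 0)), 0.75, tolerance = 1e-15)
  expect_equal(gini_index(1), 0)
  expect_error(gini_index(c(0, 0)), "all-zero")
  expect_error(gini_index(c(1, -1)), "negative")
})

test_that("Gini is scale-invariant and matches the brute-force double loop", {
  set.seed(13)
  for (i in 1:50) {
    x <- runif(sample(2:50, 1), 0, 10)
    expect_equal(gini_index(x), gini_brute_force(x), tolerance = 1e-12)
    expect_equal(gini_index(x), gini_index(x * runif(1, 0.01, 100)),
                 tolerance = 1e-12)
  }
})

## one promoter with three neighbors at given 16h-constant CFs
dom_fixture <- function(cfs) {
  k <- length(cfs)
  cres <- make_cres(c(100000, seq(200000, by = 1e5, length.out = k)),
                    cre_class = c("promoter", rep("enhancer", k)))
  ls <- make_loop_set(cres, cbind(1, 1 + seq_len(k)), matrix(cfs, k, 5))
  call_dominant_loops(build_network(ls, cres), cres)
}

test_that("min-max scaling and the 0.8 threshold pick dominant neighbors", {
  d <- dom_fixture(c(10, 9.5, 3))
  expect_equal(d$loops$scaled_16h, c(1, (9.5 - 3) / 7, 0))
  expect_equal(d$loops$dominant, c(TRUE, TRUE, FALSE))
  expect_equal(d$promoters$n_neighbors, 3L)
  expect_false(d$promoters$balanced)
})

test_that("degenerate neighborhoods follow the documented conventions", {
  single <- dom_fixture(5)
  expect_equal(single$loops$scaled_16h, 1)
  expect_true(single$loops$dominant)
  flat <- dom_fixture(c(2, 2, 2))
  expect_false(any(flat$loops$dominant))
  expect_true(flat$promoters$balanced)
  expect_true(all(is.na(flat$loops$scaled_16h)))
})

test_that("the timepoint policy restricts aggregate dominance", {
  k <- 3
  cres <- make_cres(c(100000, 200000, 300000, 400000),
                    cre_class = c("promoter", rep("enhancer", k)))
  ## neighbor 1 dominates only at 0m, neighbor 3 only at 16h
  cf <- rbind(c(10, 1, 1, 1, 1), c(1, 1, 1, 1, 1), c(1, 1, 1, 10, 1))
  net <- build_network(make_loop_set(cres, cbind(1, 2:4), cf), cres)
  any_pol <- call_dominant_loops(net, cres, policy = "any")
  expect_equal(any_pol$loops$dominant, c(TRUE, FALSE, TRUE))
  at16 <- call_dominant_loops(net, cres, policy = "16h")
  expect_equal(at16$loops$dominant, c(FALSE, FALSE, TRUE))
  expect_error(call_dominant_loops(net, cres, policy = "8h"), "policy")
})

test_that("per-promoter Gini is reported at the configured timepoint", {
  d <- dom_fixture(c(4, 0.0001, 0.0001))
  expect_equal(d$promoters$gini, gini_brute_force(c(4, 0.0001, 0.0001)),
               tolerance = 1e-9)
})

test_that("dominant dynamics comparison uses the exact Mann-Whitney floor", {
  d <- dom_fixture(c(10, 9.5, 3, 2.9, 2.8))
  dyn <- data.frame(promoter = d$loops$promoter, neighbor = d$loops$neighbor,
                    sd = c(5, 4, 1, 0.5, 0.2))
  r <- compare_dominant_dynamics(d, dyn)
  ## complete separation, n1=2 vs n2=3, two-sided exact: 2 / choose(5, 2)
  expect_equal(r$p, 2 / choose(5, 2))
  expect_gt(r$median_dominant, r$median_nondominant)
  dyn_zero <- dyn[d$loops$dominant, ]
  expect_error(compare_dominant_dynamics(d, dyn_zero), "D-")
})

test_that("dominance recovers planted truth and separates planted dynamics", {
  sim <- simulate_dataset(small_sim_config())
  net <- build_network(sim$loops$H3K27ac, sim$cres)
  calls <- call_dominant_loops(net, sim$cres)
  got <- calls$loops[calls$loops$dominant, ]
  truth <- sim$truth$dominant_loops
  truth <- truth[truth$mark == "H3K27ac", ]
  ckey <- paste0(got$promoter, "|", got$neighbor)
  tkey <- paste0(truth$promoter, "|", truth$neighbor)
  expect_gt(mean(ckey %in% tkey), 0.85)
  expect_gt(mean(tkey %in% ckey), 0.85)
  ## boosted dominants move more over time than non-dominant AR-bound CREs
  tp <- paste0("cf_", default_timepoints())
  dyn <- temporal_sd_profile(as.matrix(calls$loops[tp]),
                             groups = calls$loops$promoter)
  dyn <- cbind(calls$loops[c("promoter", "neighbor")], sd = dyn$sd)
  up_prom <- sim$genes$promoter[sim$genes$class == "up"]
  r <- compare_dominant_dynamics(calls, dyn,
                                 neighbors = sim$cres$cre_id[sim$cres$ar_bound],
                                 promoters = up_prom)
  expect_gt(r$median_dominant, r$median_nondominant)
})

test_that("proximity of dominant loops is scored by genomic gap", {
  ## two promoters: one with dominant = closest, one with dominant farther
  cres <- make_cres(c(1e5, 2e5, 8e5, 20e5, 21e5, 27e5),
                    cre_class = rep(c("promoter", "enhancer", "enhancer"), 2))
  ls <- make_loop_set(cres, rbind(c(1, 2), c(1, 3), c(4, 5), c(4, 6)),
                      rbind(rep(10, 5), rep(1, 5),
                            rep(1, 5), rep(10, 5)))
  calls <- call_dominant_loops(build_network(ls, cres), cres)
  pr <- dominant_proximity_fraction(calls, cres)
  expect_equal(pr$fraction, 0.5)
  expect_equal(pr$n_promoters, 2L)
  ## overlapping windows count as distance zero
  cres2 <- make_cres(c(1e5, 1.04e5, 3e5),
                     cre_class = c("promoter", "enhancer", "enhancer"))
  ls2 <- make_loop_set(cres2, rbind(c(1, 2), c(1, 3)),
                       rbind(rep(10, 5), rep(1, 5)), )
  calls2 <- call_dominant_loops(build_network(ls2, cres2), cres2)
  expect_equal(dominant_proximity_fraction(calls2, cres2)$fraction, 1)
})
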