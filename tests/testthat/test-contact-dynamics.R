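## a star network: one hub promoter per gene-like unit with constant CFs
two_pool_network <- function(q_cf = 2, r_cf = 1, n_query = 5, n_ref = 12) {
  n <- n_query + n_ref
  prom <- make_cres(seq(1e5, by = 1e6, length.out = n),
                    cre_class = "promoter")
  enh <- make_cres(seq(1e5, by = 1e6, length.out = n) + 2e5,
                   cre_class = "enhancer")
  cres <- rbind(prom, enh)
  cf <- matrix(c(rep(q_cf, n_query), rep(r_cf, n_ref)), n, 5)
  ls <- make_loop_set(cres, cbind(seq_len(n), n + seq_len(n)), cf)
  list(cres = cres, net = build_network(ls, cres),
       query = prom$cre_id[seq_len(n_query)],
       pool = prom$cre_id[n_query + seq_len(n_ref)])
}

test_that("constant contact frequencies give an exact degenerate fold change", {
  tw <- two_pool_network(q_cf = 2, r_cf = 1)
  cfg <- bootstrap_config(iterations = 100, n_promoters = 5, seed = 1)
  r <- bootstrap_fc_promoter_view(tw$net, tw$query, tw$pool, config = cfg)
  expect_equal(r$summary$mean_fc, rep(2, 5))
  expect_equal(r$summary$ci_hi - r$summary$ci_lo, rep(0, 5))
})

test_that("bootstrap results are reproducible and validate their inputs", {
  tw <- two_pool_network(q_cf = 1.5)
  cfg <- bootstrap_config(iterations = 120, n_promoters = 4, seed = 9)
  r1 <- bootstrap_fc_promoter_view(tw$net, tw$query, tw$pool, config = cfg)
  r2 <- bootstrap_fc_promoter_view(tw$net, tw$query, tw$pool, config = cfg)
  expect_identical(r1$summary, r2$summary)
  expect_error(bootstrap_fc_promoter_view(
    tw$net, tw$query, tw$pool, config = bootstrap_config(100, 100, 1)),
    "smaller than n_promoters")
  expect_error(bootstrap_config(iterations = 50), ">= 100")
})

test_that("fold changes are invariant to per-timepoint scaling of all weights", {
  ## normalization rescales each timepoint column by a constant, which
  ## cancels in every FC ratio computed at that timepoint
  sim <- simulate_dataset(small_sim_config())
  net <- build_network(sim$loops$H3K27ac, sim$cres)
  net2 <- net
  sc <- c(0.5, 2, 3, 0.25, 1.7)
  for (i in 1:5) {
    cc <- paste0("cf_", default_timepoints()[i])
    net2$edges[[cc]] <- net2$edges[[cc]] * sc[i]
  }
  genes <- sim$genes
  cfg <- bootstrap_config(iterations = 150, n_promoters = 40, seed = 7)
  q <- genes$promoter[genes$class == "up"]
  pool <- genes$promoter[genes$class == "independent"]
  r1 <- bootstrap_fc_promoter_view(net, q, pool, config = cfg)
  r2 <- bootstrap_fc_promoter_view(net2, q, pool, config = cfg)
  expect_equal(r1$summary, r2$summary, tolerance = 1e-12)
})

test_that("planted boosts are recovered and doubling the boost increases FC", {
  cfg_small <- small_sim_config()
  sim <- simulate_dataset(cfg_small)
  net <- build_network(sim$loops$H3K27ac, sim$cres)
  genes <- sim$genes
  strata <- stats::setNames(genes$quartile, genes$promoter)
  bs <- bootstrap_config(iterations = 300, n_promoters = 50, seed = 7)
  r <- bootstrap_fc_enhancer_view(net, sim$cres, "E+AR->P+AR",
                                  genes$promoter[genes$class == "up"],
                                  genes$promoter[genes$class == "independent"],
                                  config = bs, strata = strata)
  expect_equal(r$peak_timepoint, "16h")
  ## doubled 16h boost, same seed -> strictly larger mean FC at 16h
  prof <- c("0m" = 1, "30m" = 1.2, "4h" = 1.6, "16h" = 4.4, "72h" = 1.5)
  sim2 <- simulate_dataset(small_sim_config(cf_boost_profile = prof))
  net2 <- build_network(sim2$loops$H3K27ac, sim2$cres)
  r2 <- bootstrap_fc_enhancer_view(net2, sim2$cres, "E+AR->P+AR",
                                   genes$promoter[genes$class == "up"],
                                   genes$promoter[genes$class == "independent"],
                                   config = bs, strata = strata)
  expect_gt(r2$summary$mean_fc[4], r$summary$mean_fc[4])
})

test_that("a selector matching no loops errors with its name", {
  sim <- simulate_dataset(small_sim_config())
  net <- build_network(sim$loops$H3K27ac, sim$cres)
  cres_no_ar <- sim$cres
  cres_no_ar$ar_bound <- FALSE
  genes <- sim$genes
  expect_error(bootstrap_fc_enhancer_view(
    net, cres_no_ar, "E+AR->P+AR", genes$promoter[genes$class == "up"],
    genes$promoter[genes$class == "independent"]),
    "E\\+AR->P\\+AR")
})

test_that("temporal SD and min-max normalization follow the conventions", {
  m <- rbind(a = c(4, 4, 4, 4, 4), b = c(1, 1, 1, 1, 3), c = c(0, 2, 4, 6, 8))
  prof <- temporal_sd_profile(m)
  expect_equal(prof$sd[1], 0)
  expect_equal(prof$sd[2], sd(c(1, 1, 1, 1, 3)), tolerance = 1e-12)
  expect_equal(prof$sd[2], 0.8944272, tolerance = 1e-6)
  ## group with SDs {0, 2} scales to {0, 1}
  g2 <- temporal_sd_profile(m[c(1, 3), ], groups = c("g", "g"))
  expect_equal(g2$sd_scaled, c(0, 1))
  expect_message(one <- temporal_sd_profile(m[2, , drop = FALSE],
                                            groups = "solo"),
                 "single-item")
  expect_equal(one$sd_scaled, 1)
})

test_that("perturbation effects correlate with loop dynamics as constructed", {
  dyn <- data.frame(cre_id = letters[1:6], sd = 1:6)
  eff <- data.frame(cre_id = letters[1:6], effect = -(1:6)^2)
  r <- correlate_perturbation(dyn, eff)
  expect_equal(r$rho, -1)
  ## permuted effects decorrelate
  set.seed(8)
  eff2 <- data.frame(cre_id = letters[1:6], effect = sample(6))
  expect_lt(abs(correlate_perturbation(dyn, eff2)$rho), 1)
  expect_error(correlate_perturbation(
    dyn, data.frame(cre_id = LETTERS[1:3], effect = 1:3)), "shared")
})
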