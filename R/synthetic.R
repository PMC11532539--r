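## Synthetic multi-omics generator with planted ground truth. Emulates the
## structure of a five-timepoint stimulation time course: accessibility
## summits defining CREs, two mark-specific reference loop sets with
## per-timepoint contact frequencies, per-assay coverage, isoform-level
## expression, strand-specific nascent TSS signal, and a truth record
## sufficient to score recovery of everything planted.

#' Configuration of the synthetic dataset generator
#'
#' The defaults encode the study conditions the generator emulates: five
#' ordered time points; transcription-factor and co-factor ChIP signal at
#' bound enhancers peaking at 4 h; accessibility and the contact-frequency
#' boost of regulated enhancer-promoter loops peaking at 16 h; strongly
#' unbalanced per-promoter contact allocation (symmetric Dirichlet with a
#' small concentration parameter); and expression additive in the summed
#' first-degree contact frequency of a gene's promoter.
#'
#' Per-promoter contact totals factorize as `K_g * L_g` (number of contacts
#' times a per-loop intensity `L_g`), and the total is split across the
#' gene's enhancers by a `Dirichlet(dirichlet_alpha)` draw, so low alpha
#' yields "dominant" loops.
#'
#' @param seed Integer RNG seed; the whole bundle is deterministic given it.
#' @param n_genes Number of genes.
#' @param frac_ar_up,frac_ar_down Fractions of genes planted as up-/
#'   down-regulated by the stimulated factor (AR).
#' @param cres_per_gene_mean Mean number of first-degree enhancer CREs per
#'   promoter (negative-binomial with dispersion `cre_dispersion`, minimum 2).
#' @param cre_dispersion NB size parameter of the contact-count distribution.
#' @param frac_ar_bound Fraction of a regulated gene's enhancers bound by AR
#'   (at least one is forced).
#' @param frac_ar_bound_background AR-binding rate at enhancers of
#'   independent genes (binding without an expression effect).
#' @param frac_foxa1_extra Extra FOXA1-only binding rate.
#' @param dirichlet_alpha Concentration of the per-promoter allocation.
#' @param cf_boost_profile Named multiplicative boost per time point applied
#'   to AR-bound-enhancer loops of upregulated genes (default peaks at 16 h).
#' @param chip_boost_profile Boost of AR/FOXA1/H3K27ac signal at AR-bound
#'   CREs (default peaks at 4 h).
#' @param atac_boost_profile Accessibility boost at AR-bound CREs (default
#'   peaks at 16 h).
#' @param down_profile Expression multiplier over time for downregulated
#'   genes (default bottoms at 16 h, LFC < -1).
#' @param expr_gain Coefficient linking log expression to log summed contact
#'   frequency.
#' @param intercept Intercept of the log-expression model.
#' @param noise_sd Log-scale expression noise per gene and time point.
#' @param cf_noise_sd Log-scale per-loop, per-timepoint contact-frequency
#'   measurement noise.
#' @param loop_intensity_sd Log-scale spread of the per-loop intensity `L_g`.
#' @param mark_cf_sd Log-scale spread between the two marks' contact
#'   frequencies for the same loop.
#' @param class_mix Per-mark target composition of E-P / E-E / P-P loops.
#' @param frac_two_isoforms Fraction of genes with a second, weaker isoform.
#' @param nascent_peak,nascent_off Nascent-signal profile values at the
#'   planted peak time point and at other stimulated time points (baseline
#'   0 m is 1).
#' @param nascent_base_meanlog,nascent_base_sd,nascent_noise_sd Log-normal
#'   base level and noise of the nascent TSS signal.
#' @param genes_per_chrom,lattice,jitter Genome layout: genes per synthetic
#'   chromosome, CRE lattice spacing (bases) and uniform summit jitter.
#' @param window_half_width CRE window half-width W (+/- W around summits).
#' @param integer_counts Emit Poisson-sampled integer counts (scaled by
#'   `count_scale`) instead of continuous contact frequencies.
#' @param count_scale Poisson scale for `integer_counts`.
#' @param timepoints Ordered time-point labels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 7, n_genes = 2000,
                       frac_ar_up = 0.05, frac_ar_down = 0.05,
                       cres_per_gene_mean = 15, cre_dispersion = 2,
                       frac_ar_bound = 0.15, frac_ar_bound_background = 0.02,
                       frac_foxa1_extra = 0.10,
                       dirichlet_alpha = 0.3,
                       cf_boost_profile = c("0m" = 1, "30m" = 1.2, "4h" = 1.6,
                                            "16h" = 2.2, "72h" = 1.5),
                       chip_boost_profile = c("0m" = 1, "30m" = 2.5, "4h" = 4,
                                              "16h" = 2.5, "72h" = 1.5),
                       atac_boost_profile = c("0m" = 1, "30m" = 1.2, "4h" = 1.8,
                                              "16h" = 2.5, "72h" = 1.8),
                       down_profile = c("0m" = 1, "30m" = 0.85, "4h" = 0.5,
                                        "16h" = 0.2, "72h" = 0.35),
                       expr_gain = 1, intercept = log(10), noise_sd = 0.3,
                       cf_noise_sd = 0.03, loop_intensity_sd = 0.2,
                       mark_cf_sd = 0.15,
                       class_mix = list(
                         H3K27ac = c(EP = 0.404, EE = 0.432, PP = 0.164),
                         H3K4me3 = c(EP = 0.588, EE = 0.172, PP = 0.240)),
                       frac_two_isoforms = 0.3,
                       nascent_peak = 6, nascent_off = 1.5,
                       nascent_base_meanlog = log(20), nascent_base_sd = 0.5,
                       nascent_noise_sd = 0.2,
                       genes_per_chrom = 250, lattice = 10000, jitter = 1000,
                       window_half_width = 2500,
                       integer_counts = FALSE, count_scale = 50,
                       timepoints = default_timepoints()) {
  cfg <- as.list(environment())
  assert_timepoints(timepoints)
  fr <- c(frac_ar_up, frac_ar_down, frac_ar_bound, frac_ar_bound_background,
          frac_foxa1_extra, frac_two_isoforms)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0", call. = FALSE)
  for (nm in c("cf_boost_profile", "chip_boost_profile", "atac_boost_profile",
               "down_profile")) {
    prof <- cfg[[nm]]
    if (!identical(sort(names(prof)), sort(timepoints))) {
      stop("invalid profile keys in ", nm, "; must match timepoints",
           call. = FALSE)
    }
    cfg[[nm]] <- prof[timepoints]
  }
  if (n_genes < 25) {
    warning("n_genes < 25: too few genes for the k = 25 binned models",
            call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

## index i -> gene id
gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a synthetic multi-omics dataset in memory
#'
#' @param config A [sim_config()].
#' @param null Generate the matched null: all boost/effect profiles are
#'   identically 1, no gene class receives any effect, and the truth lists
#'   zero boosted loops and no nascent groups.
#' @return A `loop_sim` object: `cres`, `transcripts`, `genes`, `loops`
#'   (list of `loop_set` per mark, observed counts), `signals` (per-assay
#'   CRE x timepoint matrices), `nascent` (per-transcript planted and
#'   observed TSS signal), and `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), null = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, simulate_dataset_impl(config, null))
}

simulate_dataset_impl <- function(config, null) {
  tp <- config$timepoints
  ntp <- length(tp)
  n <- config$n_genes
  W <- config$window_half_width
  gid <- gene_ids(n)

  ## --- genome layout -------------------------------------------------
  K <- 2L + stats::rnbinom(n, size = config$cre_dispersion,
                           mu = max(config$cres_per_gene_mean - 2, 0.1))
  chrom <- paste0("chr", ceiling(seq_len(n) / config$genes_per_chrom))
  width_g <- (K + 2) * config$lattice
  offset <- stats::ave(width_g, chrom,
                       FUN = function(w) cumsum(c(0, w[-length(w)])))
  prom_pos <- as.integer(1e5 + offset + config$lattice)

  gene_of_enh <- rep(seq_len(n), K)
  enh_rank <- sequence(K)
  pos_enh <- as.integer(prom_pos[gene_of_enh] + config$lattice * enh_rank +
                          round(stats::runif(sum(K), -config$jitter,
                                             config$jitter)))
  n_enh <- length(pos_enh)

  ## --- gene classes and binding --------------------------------------
  perm <- sample.int(n)
  n_up <- round(n * config$frac_ar_up)
  n_down <- round(n * config$frac_ar_down)
  gclass <- rep("independent", n)
  gclass[perm[seq_len(n_up)]] <- "up"
  if (n_down > 0) gclass[perm[n_up + seq_len(n_down)]] <- "down"
  regulated <- gclass != "independent"

  ar_enh <- ifelse(regulated[gene_of_enh],
                   stats::runif(n_enh) < config$frac_ar_bound,
                   stats::runif(n_enh) < config$frac_ar_bound_background)
  ## force >= 1 AR-bound enhancer per regulated gene
  has_ar <- rowsum(as.integer(ar_enh), gene_of_enh)[, 1] > 0
  force_first <- which(regulated & !has_ar)
  if (length(force_first)) {
    first_idx <- match(force_first, gene_of_enh)
    ar_enh[first_idx] <- TRUE
  }
  foxa1_enh <- ar_enh | stats::runif(n_enh) < config$frac_foxa1_extra
  ar_prom <- regulated & stats::runif(n) < 0.3
  foxa1_prom <- ar_prom | stats::runif(n) < config$frac_foxa1_extra

  ## --- CRE table (planted) --------------------------------------------
  cre_chrom <- c(chrom, chrom[gene_of_enh])
  cre_summit <- c(prom_pos, pos_enh)
  cre_start <- cre_summit - W
  cre_end <- cre_summit + W
  cre_id <- sprintf("%s:%d-%d", cre_chrom, cre_start, cre_end)
  prom_key <- cre_id[seq_len(n)]
  enh_key <- cre_id[n + seq_len(n_enh)]
  cres <- data.frame(cre_id = cre_id, chrom = cre_chrom, start = cre_start,
                     end = cre_end, summit = cre_summit,
                     cre_class = c(rep("promoter", n), rep("enhancer", n_enh)),
                     ar_bound = c(ar_prom, ar_enh),
                     foxa1_bound = c(foxa1_prom, foxa1_enh),
                     gene = c(gid, rep(NA_character_, n_enh)),
                     stringsAsFactors = FALSE)
  o <- order(cres$chrom, cres$start)
  cres <- cres[o, ]
  rownames(cres) <- NULL

  ## --- E-P contact frequencies ----------------------------------------
  alloc <- stats::rgamma(n_enh, shape = config$dirichlet_alpha)
  alloc <- alloc / rowsum(alloc, gene_of_enh)[gene_of_enh, 1]
  L <- exp(stats::rnorm(n, 0, config$loop_intensity_sd))
  cf_base <- K[gene_of_enh] * L[gene_of_enh] * alloc

  boost_vec <- if (null) rep(1, ntp) else as.numeric(config$cf_boost_profile)
  boosted <- gclass[gene_of_enh] == "up" & ar_enh & !null
  cf_true_ep <- outer(cf_base, rep(1, ntp))
  cf_true_ep[boosted, ] <- cf_base[boosted] %o% boost_vec
  colnames(cf_true_ep) <- cf_cols(tp)

  ## --- extra E-E and P-P loops per mark --------------------------------
  marks <- names(config$class_mix)
  sample_ee <- function(target) {
    per_gene <- round(target * K / sum(K))
    per_gene <- pmin(per_gene, K * (K - 1) %/% 2)
    g <- rep(seq_len(n), per_gene)
    m <- length(g)
    if (!m) {
      return(data.frame(gene = integer(), i = integer(), j = integer()))
    }
    a <- 1L + floor(stats::runif(m) * K[g])
    b <- 1L + floor(stats::runif(m) * (K[g] - 1))
    b <- b + (b >= a)
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste0(g, "_", lo, "_", hi))
    data.frame(gene = g[keep], i = lo[keep], j = hi[keep])
  }
  enh_index <- function(g, r) {
    (c(0, cumsum(K))[g]) + r
  }
  pp_candidates <- do.call(rbind, lapply(seq_len(min(7, n - 1)), function(d) {
    g1 <- seq_len(n - d)
    ok <- chrom[g1] == chrom[g1 + d]
    data.frame(g1 = g1[ok], g2 = g1[ok] + d)
  }))

  loops <- list()
  truth_edges <- list()
  mark_noise <- list()
  for (mk in marks) {
    mix <- config$class_mix[[mk]]
    total <- n_enh / mix[["EP"]]
    ee <- sample_ee(round(total * mix[["EE"]]))
    n_pp <- min(round(total * mix[["PP"]]), nrow(pp_candidates))
    pp <- pp_candidates[sample.int(nrow(pp_candidates), n_pp), , drop = FALSE]

    mn <- exp(stats::rnorm(n_enh, 0, config$mark_cf_sd))
    mark_noise[[mk]] <- mn
    cf_ep <- cf_true_ep * mn
    ee_level <- L[ee$gene] * exp(stats::rnorm(nrow(ee), 0, 0.4))
    pp_level <- exp(stats::rnorm(nrow(pp), 0, 0.4))

    node1 <- c(prom_key[gene_of_enh], enh_key[enh_index(ee$gene, ee$i)],
               prom_key[pp$g1])
    node2 <- c(enh_key, enh_key[enh_index(ee$gene, ee$j)], prom_key[pp$g2])
    cf_true <- rbind(cf_ep,
                     outer(ee_level, rep(1, ntp)),
                     outer(pp_level, rep(1, ntp)))
    nrow_all <- nrow(cf_true)
    cf_obs <- cf_true * exp(matrix(stats::rnorm(nrow_all * ntp, 0,
                                                config$cf_noise_sd),
                                   nrow_all, ntp))
    if (config$integer_counts) {
      cf_obs[] <- stats::rpois(length(cf_obs), config$count_scale * cf_obs)
    }
    ## anchors = CRE windows of the endpoints
    m1 <- match(node1, cres$cre_id)
    m2 <- match(node2, cres$cre_id)
    df <- data.frame(chrom1 = cres$chrom[m1], start1 = cres$start[m1],
                     end1 = cres$end[m1], chrom2 = cres$chrom[m2],
                     start2 = cres$start[m2], end2 = cres$end[m2],
                     name = sprintf("%s_loop%d", mk, seq_len(nrow_all)),
                     mark = mk, stringsAsFactors = FALSE)
    df[cf_cols(tp)] <- as.data.frame(cf_obs)
    df <- canonicalize_anchors(df)
    loops[[mk]] <- structure(list(loops = df, mark = mk, timepoints = tp,
                                  skip = list(inter_chromosomal = 0L,
                                              out_of_range = 0L),
                                  n_input = nrow_all),
                             class = "loop_set")
    ## promoter-viewpoint truth edges (P-P loops seen from both promoters)
    truth_edges[[mk]] <- data.frame(
      promoter = c(prom_key[gene_of_enh], prom_key[pp$g1], prom_key[pp$g2]),
      neighbor = c(enh_key, prom_key[pp$g2], prom_key[pp$g1]),
      mark = mk, stringsAsFactors = FALSE)
    truth_edges[[mk]] <- cbind(truth_edges[[mk]],
                               as.data.frame(rbind(cf_ep,
                                                   outer(pp_level, rep(1, ntp)),
                                                   outer(pp_level, rep(1, ntp)))))
  }

  ## --- expression ------------------------------------------------------
  sum_cf <- rowsum(cf_true_ep, gene_of_enh)  # n x ntp planted additive sums
  down_vec <- if (null) rep(1, ntp) else as.numeric(config$down_profile)
  down_term <- outer(as.integer(gclass == "down" & !null), log(down_vec))
  log_expr <- config$intercept + config$expr_gain * log(sum_cf) + down_term +
    matrix(stats::rnorm(n * ntp, 0, config$noise_sd), n, ntp)
  tpm_gene <- exp(log_expr)
  colnames(tpm_gene) <- tpm_cols(tp)

  two_iso <- stats::runif(n) < config$frac_two_isoforms
  share <- ifelse(two_iso, stats::runif(n, 0.1, 0.4), 0)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tx_len <- as.integer(round(stats::runif(n, 2000, 20000)))
  mk_tx <- function(idx, tss, tpm, suffix) {
    s <- strand[idx]
    start <- ifelse(s == "+", tss, tss + 1L - tx_len[idx])
    end <- ifelse(s == "+", tss + tx_len[idx], tss + 1L)
    out <- data.frame(transcript = paste0(gid[idx], suffix), gene = gid[idx],
                      chrom = chrom[idx], start = as.integer(start),
                      end = as.integer(end), strand = s,
                      stringsAsFactors = FALSE)
    out[tpm_cols(tp)] <- as.data.frame(tpm)
    out
  }
  tx1 <- mk_tx(seq_len(n), prom_pos, tpm_gene * (1 - share), ".t1")
  tx2 <- mk_tx(which(two_iso), prom_pos[two_iso] + 1200L,
               tpm_gene[two_iso, , drop = FALSE] * share[two_iso], ".t2")
  transcripts <- rbind(tx1, tx2)
  transcripts <- transcripts[order(transcripts$transcript), ]
  rownames(transcripts) <- NULL

  ## --- nascent TSS signal ---------------------------------------------
  upreg <- gclass == "up" & !null
  group <- rep(NA_character_, n)
  group[upreg] <- sample(tp[-1], sum(upreg), replace = TRUE)
  nas_base <- exp(stats::rnorm(n, config$nascent_base_meanlog,
                               config$nascent_base_sd))
  profile <- matrix(1, n, ntp)
  if (any(upreg)) {
    profile[upreg, ] <- config$nascent_off
    profile[upreg, 1] <- 1
    profile[cbind(which(upreg), match(group[upreg], tp))] <- config$nascent_peak
  }
  nas_true <- nas_base * profile
  nas_obs <- nas_true * exp(matrix(stats::rnorm(n * ntp, 0,
                                                config$nascent_noise_sd),
                                   n, ntp))
  nascent <- data.frame(transcript = tx1$transcript, gene = gid,
                        chrom = chrom, tss = prom_pos, strand = strand,
                        group = group, stringsAsFactors = FALSE)
  nascent[paste0("sig_", tp)] <- as.data.frame(nas_obs)

  ## --- per-assay CRE signal --------------------------------------------
  is_prom <- cres$cre_class == "promoter"
  chip_vec <- if (null) rep(1, ntp) else as.numeric(config$chip_boost_profile)
  atac_vec <- if (null) rep(1, ntp) else as.numeric(config$atac_boost_profile)
  mk_signal <- function(base, boost_vec) {
    m <- outer(base, rep(1, ntp))
    m[cres$ar_bound, ] <- base[cres$ar_bound] %o% boost_vec
    m <- m * exp(matrix(stats::rnorm(length(m), 0, 0.1), nrow(m)))
    colnames(m) <- paste0("sig_", tp)
    rownames(m) <- cres$cre_id
    m
  }
  signals <- list(
    AR = mk_signal(ifelse(cres$ar_bound, 2, 0.5), chip_vec),
    FOXA1 = mk_signal(ifelse(cres$foxa1_bound, 3, 1), chip_vec),
    H3K27ac = mk_signal(ifelse(is_prom, 6, 3), chip_vec),
    H3K4me3 = mk_signal(ifelse(is_prom, 8, 1), rep(1, ntp)),
    ATAC = mk_signal(ifelse(is_prom, 6, 4), atac_vec))

  ## --- truth ------------------------------------------------------------
  max_tpm <- apply(tpm_gene, 1, max)
  r <- rank(-max_tpm, ties.method = "first")
  quartile <- paste0("Q", ceiling(r * 4 / n))
  genes <- data.frame(gene = gid, class = gclass, chrom = chrom,
                      promoter = prom_key, n_contacts = K,
                      quartile = quartile, nascent_group = group,
                      stringsAsFactors = FALSE)
  genes[tpm_cols(tp)] <- as.data.frame(tpm_gene)

  dom_truth <- do.call(rbind, lapply(marks, function(mk) {
    te <- truth_edges[[mk]]
    cf <- as.matrix(te[, -(1:3)])
    flags <- dominance_flags(te$promoter, cf, threshold = 0.8)
    data.frame(mark = mk, promoter = te$promoter[flags$dominant_any],
               neighbor = te$neighbor[flags$dominant_any],
               stringsAsFactors = FALSE)
  }))
  boosted_keys <- if (any(boosted)) {
    k1 <- prom_key[gene_of_enh[boosted]]
    k2 <- enh_key[boosted]
    sprintf("%s|%s", pmin(k1, k2), pmax(k1, k2))
  } else character(0)

  truth <- list(
    seed = config$seed, null = null,
    n_genes = n, n_cres = nrow(cres),
    classes = stats::setNames(as.list(table(gclass)), names(table(gclass))),
    genes = genes[c("gene", "class", "promoter", "quartile", "nascent_group")],
    boosted_loops = data.frame(key = boosted_keys,
                               baseline_cf = cf_base[boosted],
                               stringsAsFactors = FALSE),
    cf_boost_profile = as.list(stats::setNames(boost_vec, tp)),
    dominant_loops = dom_truth,
    nascent_groups = nascent[!is.na(nascent$group),
                             c("transcript", "gene", "group")],
    max_expression_timepoint = data.frame(
      gene = gid, timepoint = tp[max.col(tpm_gene, ties.method = "first")],
      stringsAsFactors = FALSE))

  structure(list(config = config, null = null, cres = cres,
                 transcripts = transcripts, genes = genes, loops = loops,
                 signals = signals, nascent = nascent, truth = truth),
            class = "loop_sim")
}

#' @export
print.loop_sim <- function(x, ...) {
  cat(sprintf("<loop_sim> %d genes, %d CREs, loops: %s%s\n",
              x$config$n_genes, nrow(x$cres),
              paste(sprintf("%s=%d", names(x$loops),
                            vapply(x$loops, function(l) nrow(l$loops), 1L)),
                    collapse = " "),
              if (x$null) " [null]" else ""))
  invisible(x)
}

#' Write a simulated dataset to a directory as plain-text files
#'
#' Emits the file layout [run_pipeline()] consumes: per-timepoint
#' accessibility narrowPeak files, AR/FOXA1 peak BEDs, one BEDPE loop table
#' per mark, per-assay per-timepoint coverage bedGraphs, a transcript
#' expression TSV, strand-specific nascent bedGraphs, the hallmark gene list
#' and `truth.json`.
#'
#' @param sim A `loop_sim`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- sim$config$timepoints
  cres <- sim$cres
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  ## accessibility peaks: every CRE at t1; a deterministic subset re-called
  ## with jittered summits at later time points (exercises summit merging)
  with_rng(sim$config$seed + 1L, {
    for (i in seq_along(tp)) {
      if (i == 1) {
        idx <- seq_len(nrow(cres))
        jit <- 0L
      } else {
        idx <- which(stats::runif(nrow(cres)) < 0.3)
        jit <- as.integer(round(stats::runif(length(idx), -400, 400)))
      }
      s <- cres$summit[idx] + jit
      pk <- data.frame(chrom = cres$chrom[idx], start = s - 500L,
                       end = s + 500L,
                       name = sprintf("peak_%s_%d", tp[i], seq_along(idx)),
                       summit = 500L)
      p <- file.path(dir, sprintf("atac_peaks_%s.narrowPeak", tp[i]))
      write_intervals(pk, p, format = "narrowPeak")
      add(p)
    }
  })

  chip_bed <- function(flag, label, tps) {
    idx <- which(flag)
    for (t in tps) {
      pk <- data.frame(chrom = cres$chrom[idx], start = cres$summit[idx] - 300L,
                       end = cres$summit[idx] + 300L,
                       name = sprintf("%s_%s_%d", label, t, seq_along(idx)),
                       summit = 300L)
      p <- file.path(dir, sprintf("%s_peaks_%s.bed", label, t))
      write_intervals(pk, p, format = "bed")
      add(p)
    }
  }
  chip_bed(cres$ar_bound, "ar", c("30m", "4h", "16h"))
  chip_bed(cres$foxa1_bound, "foxa1", c("0m", "30m", "4h", "16h"))

  for (mk in names(sim$loops)) {
    p <- file.path(dir, sprintf("loops_%s.bedpe", mk))
    write_loops(sim$loops[[mk]], p)
    add(p)
  }

  for (assay in names(sim$signals)) {
    m <- sim$signals[[assay]]
    for (i in seq_along(tp)) {
      track <- data.frame(chrom = cres$chrom, start = cres$start,
                          end = cres$end, value = m[, i])
      p <- file.path(dir, sprintf("signal_%s_%s.bedgraph", assay, tp[i]))
      write_bedgraph(track, p)
      add(p)
    }
  }

  p <- file.path(dir, "expression.tsv")
  write_table(sim$transcripts, p); add(p)

  ## nascent: stepped TSS-proximal peak on the strand-appropriate track,
  ## maximum within +/-500 bp equals the planted level
  nas <- sim$nascent
  for (i in seq_along(tp)) {
    h <- nas[[paste0("sig_", tp[i])]]
    tri <- data.frame(
      chrom = rep(nas$chrom, 3),
      start = c(nas$tss - 100L, nas$tss - 50L, nas$tss + 51L),
      end = c(nas$tss - 50L, nas$tss + 51L, nas$tss + 101L),
      value = c(h / 2, h, h / 2),
      strand = rep(nas$strand, 3))
    for (s in c("+", "-")) {
      lab <- if (s == "+") "fwd" else "rev"
      p <- file.path(dir, sprintf("nascent_%s_%s.bedgraph", lab, tp[i]))
      write_bedgraph(tri[tri$strand == s, c("chrom", "start", "end", "value")],
                     p)
      add(p)
    }
  }

  p <- file.path(dir, "hallmark_genes.txt")
  writeLines(sort(sim$genes$gene[sim$genes$class == "up"]), p); add(p)

  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(p)
  invisible(files)
}

#' Generate a synthetic dataset bundle on disk
#'
#' @param config A [sim_config()].
#' @param dir Output directory; `NULL` returns the in-memory simulation only.
#' @param null Generate the matched null dataset (see [simulate_dataset()]).
#' @return The `loop_sim`, invisibly.
#' @export
generate_dataset <- function(config = sim_config(), dir = NULL, null = FALSE) {
  sim <- simulate_dataset(config, null = null)
  if (!is.null(dir)) write_dataset(sim, dir)
  invisible(sim)
}

#' Generate the matched null dataset (all effects off)
#'
#' Identical generator with every boost profile identically 1: loop counts
#' differ across time points only by sampling noise, and the truth lists zero
#' boosted loops. Used for calibration of the bootstrap fold-change
#' machinery.
#'
#' @inheritParams generate_dataset
#' @return The `loop_sim`, invisibly.
#' @export
plant_null_dataset <- function(config = sim_config(), dir = NULL) {
  generate_dataset(config, dir = dir, null = TRUE)
}
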