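## Pipeline orchestration: run every stage on a dataset directory, emit the
## summary artifacts as tables, and score recovery against a planted truth.

#' Pipeline configuration
#'
#' @param timepoints Ordered time-point labels.
#' @param half_width CRE window half-width (bases).
#' @param marks Loop marks expected as `loops_<mark>.bedpe`.
#' @param assays Signal assays expected as `signal_<assay>_<tp>.bedgraph`.
#' @param bootstrap A [bootstrap_config()].
#' @param background_seed Seed of the fixed background-promoter draw.
#' @param dominance_threshold,dominance_policy,gini_timepoint Dominant-loop
#'   call parameters (see [call_dominant_loops()]).
#' @param model_timepoint,k,expr_eps Multi-enhancer model parameters.
#' @param nascent_eps Nascent LFC pseudocount.
#' @param lfc_threshold,lfc_ref,lfc_cmp Downregulation call parameters.
#' @param rf_seed Random-forest seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(timepoints = default_timepoints(),
                            half_width = 2500,
                            marks = c("H3K27ac", "H3K4me3"),
                            assays = c("AR", "FOXA1", "H3K27ac", "H3K4me3",
                                       "ATAC"),
                            bootstrap = bootstrap_config(),
                            background_seed = 7,
                            dominance_threshold = 0.8,
                            dominance_policy = "any",
                            gini_timepoint = "16h",
                            model_timepoint = "16h", k = 25, expr_eps = 0.01,
                            nascent_eps = 0.5,
                            lfc_threshold = -1, lfc_ref = "0m",
                            lfc_cmp = "16h", rf_seed = 0) {
  cfg <- as.list(environment())
  assert_timepoints(timepoints)
  structure(cfg, class = "pipeline_config")
}

pipeline_files <- function(data_dir, config) {
  tp <- config$timepoints
  list(
    atac = file.path(data_dir, sprintf("atac_peaks_%s.narrowPeak", tp)),
    loops = file.path(data_dir, sprintf("loops_%s.bedpe", config$marks)),
    expression = file.path(data_dir, "expression.tsv"),
    hallmark = file.path(data_dir, "hallmark_genes.txt"),
    signal = as.character(outer(config$assays, tp, function(a, t)
      file.path(data_dir, sprintf("signal_%s_%s.bedgraph", a, t)))),
    nascent = as.character(outer(c("fwd", "rev"), tp, function(s, t)
      file.path(data_dir, sprintf("nascent_%s_%s.bedgraph", s, t)))))
}

stage_log <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- expr
  message(sprintf("[loopdyn] %-18s %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Consumes the file layout written by [write_dataset()] (documented in the
#' README) and writes: `cres.tsv`, `net.json`, `edges.tsv`,
#' `loop_classes.tsv`, `signal_kinetics.tsv`, `fc_promoter.tsv`,
#' `fc_enhancer.tsv`, `dominance.tsv`, `dominance_summary.tsv`,
#' `models.tsv`, `nascent_groups.tsv` and `manifest.json`. All randomness is
#' seeded through the configuration, so a rerun with identical inputs is
#' byte-identical.
#'
#' @param data_dir Input dataset directory.
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(data_dir, out_dir, config = pipeline_config()) {
  tp <- config$timepoints
  files <- pipeline_files(data_dir, config)
  flat <- unlist(files, use.names = FALSE)
  missing_f <- flat[!file.exists(flat)]
  if (length(missing_f)) {
    stop("missing input file: ", missing_f[1], call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "bootstrap")],
                   bootstrap = unclass(config$bootstrap),
                   inputs = as.list(tools::md5sum(flat)),
                   version = as.character(utils::packageVersion("loopdyn")),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## --- CRE annotation ---------------------------------------------------
  cres <- stage_log("define_cres", {
    peaks <- lapply(files$atac, read_intervals, format = "narrowPeak")
    define_cres(peaks, half_width = config$half_width)
  })
  tx_schema <- c(transcript = "character", gene = "character",
                 chrom = "character", start = "integer", end = "integer",
                 strand = "character",
                 stats::setNames(rep("numeric", length(tp)), tpm_cols(tp)))
  transcripts <- read_table(files$expression, tx_schema)
  pa <- stage_log("assign_promoters",
                  assign_promoters(cres, transcripts, timepoints = tp,
                                   half_width = config$half_width))
  cres <- pa$cres
  read_bed_set <- function(pattern) {
    lapply(Sys.glob(file.path(data_dir, pattern)), read_intervals,
           format = "bed")
  }
  cres <- stage_log("classify_cres",
                    classify_cres(cres, ar_peaks = read_bed_set("ar_peaks_*.bed"),
                                  foxa1_peaks = read_bed_set("foxa1_peaks_*.bed")))
  write_table(cres, file.path(out_dir, "cres.tsv"))
  note("cres", n = nrow(cres), promoters = sum(cres$cre_class == "promoter"),
       ar_bound = sum(cres$ar_bound),
       excluded_genes = length(pa$excluded_genes))

  ## --- gene sets ---------------------------------------------------------
  hallmark <- readLines(files$hallmark)
  genes <- define_gene_sets(gene_expression(transcripts, tp), hallmark,
                            timepoints = tp,
                            lfc_threshold = config$lfc_threshold,
                            t_ref = config$lfc_ref, t_cmp = config$lfc_cmp,
                            pseudocount = config$expr_eps)
  note("gene_sets", n = nrow(genes), hallmark = sum(genes$hallmark),
       downregulated = sum(genes$downregulated))

  ## --- network ------------------------------------------------------------
  loop_sets <- stage_log("read_loops", lapply(seq_along(config$marks),
    function(i) read_loops(files$loops[i], timepoints = tp,
                           mark = config$marks[i])))
  loop_sets <- lapply(loop_sets, tmm_normalize_loops)
  net <- stage_log("build_network", build_network(loop_sets, cres))
  write_table(net$edges, file.path(out_dir, "edges.tsv"))
  jsonlite::write_json(list(nodes = net$nodes, timepoints = tp,
                            n_edges = nrow(net$edges), skip = net$skip,
                            edges = net$edges),
                       file.path(out_dir, "net.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  classes <- classify_loops(net, cres)
  write_table(classes, file.path(out_dir, "loop_classes.tsv"))
  note("network", edges = nrow(net$edges), skip = net$skip)

  ## --- signal kinetics ----------------------------------------------------
  prom_hm <- pa$map$cre_id[pa$map$gene %in% genes$gene[genes$hallmark]]
  prom_bg <- setdiff(cres$cre_id[cres$cre_class == "promoter"], prom_hm)
  grp <- ifelse(cres$cre_class == "promoter",
                ifelse(cres$cre_id %in% prom_hm, "P+AR", "P-AR"),
                ifelse(cres$ar_bound, "E+AR", "E-AR"))
  kinetics <- stage_log("aggregate_signal", {
    do.call(rbind, lapply(config$assays, function(a) {
      m <- vapply(tp, function(t) {
        track <- read_bedgraph(file.path(
          data_dir, sprintf("signal_%s_%s.bedgraph", a, t)))
        aggregate_signal(track, cres)
      }, numeric(nrow(cres)))
      m <- as.matrix(tmm_normalize(m)$normalized)
      agg <- rowsum(m, grp) / as.vector(table(grp)[sort(unique(grp))])
      data.frame(assay = a, group = rownames(agg),
                 stats::setNames(as.data.frame(agg), paste0("sig_", tp)),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  })
  write_table(kinetics, file.path(out_dir, "signal_kinetics.tsv"))

  ## --- bootstrap fold changes --------------------------------------------
  strata <- stats::setNames(genes$quartile[match(pa$map$gene, genes$gene)],
                            pa$map$cre_id)
  pool <- prom_bg
  bg_fixed <- with_rng(config$background_seed,
                       pool[sample.int(length(pool),
                                       min(config$bootstrap$n_promoters,
                                           length(pool)))])
  fc_promoter <- stage_log("fc_promoter", do.call(rbind, lapply(
    config$marks, function(mk) {
      do.call(rbind, lapply(c("P+AR", "P-AR"), function(q) {
        qp <- if (q == "P+AR") prom_hm else bg_fixed
        qp <- qp[vapply(qp, function(p) any(net$edges$node1 == p |
                                              net$edges$node2 == p), TRUE)]
        r <- bootstrap_fc_promoter_view(net, qp, pool, mark = mk,
                                        config = config$bootstrap,
                                        strata = strata)
        cbind(mark = mk, query = q, r$summary,
              peak_timepoint = r$peak_timepoint, p_peak = r$p_peak)
      }))
    })))
  write_table(fc_promoter, file.path(out_dir, "fc_promoter.tsv"))

  selectors <- c("E+AR->P+AR", "E-AR->P+AR", "E-AR->P-AR")
  fc_enhancer <- stage_log("fc_enhancer", do.call(rbind, lapply(
    config$marks, function(mk) {
      do.call(rbind, lapply(selectors, function(sel) {
        r <- bootstrap_fc_enhancer_view(net, cres, selector = sel,
                                        query_promoters = prom_hm,
                                        reference_promoters = pool,
                                        mark = mk, config = config$bootstrap,
                                        strata = strata)
        cbind(mark = mk, selector = sel, r$summary,
              peak_timepoint = r$peak_timepoint, p_peak = r$p_peak)
      }))
    })))
  write_table(fc_enhancer, file.path(out_dir, "fc_enhancer.tsv"))

  ## --- dominance -----------------------------------------------------------
  dom <- stage_log("dominance", lapply(stats::setNames(config$marks,
                                                       config$marks),
    function(mk) call_dominant_loops(net, cres, promoters = prom_hm,
                                     mark = mk,
                                     threshold = config$dominance_threshold,
                                     policy = config$dominance_policy,
                                     gini_timepoint = config$gini_timepoint)))
  dom_loops <- do.call(rbind, lapply(config$marks, function(mk)
    cbind(mark = mk, dom[[mk]]$loops)))
  write_table(dom_loops, file.path(out_dir, "dominance.tsv"))
  dom_summary <- do.call(rbind, lapply(config$marks, function(mk) {
    d <- dom[[mk]]
    dyn <- temporal_sd_profile(as.matrix(d$loops[cf_cols(tp)]),
                               groups = d$loops$promoter)
    dyn <- cbind(d$loops[c("promoter", "neighbor")], sd = dyn$sd)
    ar_nb <- cres$cre_id[cres$ar_bound]
    cmp <- tryCatch(compare_dominant_dynamics(d, dyn, neighbors = ar_nb),
                    error = function(e) list(U = NA, p = NA,
                                             median_dominant = NA,
                                             median_nondominant = NA))
    prox <- dominant_proximity_fraction(d, cres)
    data.frame(mark = mk, n_promoters = nrow(d$promoters),
               n_dominant = sum(d$loops$dominant),
               mean_gini = mean(d$promoters$gini, na.rm = TRUE),
               proximity_fraction = prox$fraction,
               dplus_dminus_U = cmp$U, dplus_dminus_p = cmp$p,
               median_sd_dominant = cmp$median_dominant,
               median_sd_nondominant = cmp$median_nondominant,
               stringsAsFactors = FALSE)
  }))
  write_table(dom_summary, file.path(out_dir, "dominance_summary.tsv"))

  ## --- multi-enhancer models ----------------------------------------------
  models <- stage_log("models", do.call(rbind, lapply(config$marks,
    function(mk) {
      summ <- summarize_models(net, pa$map, mark = mk,
                               timepoint = config$model_timepoint)
      fits <- lapply(c("avg", "max", "sum"), function(md)
        bin_and_correlate(summ, genes, model = md,
                          timepoint = config$model_timepoint, k = config$k,
                          eps = config$expr_eps))
      names(fits) <- c("avg", "max", "sum")
      feats <- data.frame(avg = fits$avg$bins$mean_cf,
                          max = fits$max$bins$mean_cf,
                          sum = fits$sum$bins$mean_cf)
      fi <- feature_importance(feats, fits$sum$bins$mean_log_expr,
                               seed = config$rf_seed)
      data.frame(mark = mk, model = names(fits),
                 rho = vapply(fits, function(f) f$rho, 1),
                 p = vapply(fits, function(f) f$p, 1),
                 rho_gene = vapply(fits, function(f) f$rho_gene, 1),
                 n_genes = vapply(fits, function(f) f$n_genes, 1),
                 rf_importance = fi$importance[names(fits)],
                 rf_rank = match(names(fits), fi$ranking),
                 rf_r2 = fi$r2, stringsAsFactors = FALSE)
    })))
  write_table(models, file.path(out_dir, "models.tsv"))

  ## --- nascent grouping -----------------------------------------------------
  nascent <- stage_log("nascent", {
    read_tracks <- function(s) {
      stats::setNames(lapply(tp, function(t) read_bedgraph(
        file.path(data_dir, sprintf("nascent_%s_%s.bedgraph", s, t)))), tp)
    }
    sig <- tss_signal(read_tracks("fwd"), read_tracks("rev"), transcripts,
                      timepoints = tp)
    up <- classify_upregulated(sig, eps = config$nascent_eps)
    grpres <- assign_time_group(sig, up$upregulated)
    out <- grpres$groups
    out$gene <- transcripts$gene[match(out$transcript,
                                       transcripts$transcript)]
    note("nascent", upregulated = sum(up$upregulated),
         grouped = nrow(out), dropped_constant = grpres$dropped_constant,
         dropped_reference_max = grpres$dropped_reference_max)
    out
  })
  write_table(nascent, file.path(out_dir, "nascent_groups.tsv"))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cres = cres, genes = genes, network = net,
                 promoter_map = pa$map, fc_promoter = fc_promoter,
                 fc_enhancer = fc_enhancer, dominance = dom,
                 dominance_summary = dom_summary, models = models,
                 nascent = nascent, manifest = manifest))
}

#' Score pipeline outputs against a planted truth
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param truth Path to a `truth.json` (or the already-parsed list).
#' @return list with `dominance` (per-mark precision/recall),
#'   `fc_peak_match` (per mark; `NA` on a null truth), `nascent_accuracy`,
#'   `model_ranking_match`; also written to `recovery.json` in `out_dir`.
#' @export
score_recovery <- function(out_dir, truth) {
  if (is.character(truth)) {
    truth <- jsonlite::read_json(truth, simplifyVector = TRUE)
  }
  read_out <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) stop("missing pipeline output: ", p, call. = FALSE)
    data.table::fread(p, sep = "\t", data.table = FALSE)
  }
  dom <- read_out("dominance.tsv")
  td <- as.data.frame(truth$dominant_loops)
  scored_proms <- unique(dom$promoter)
  if (!any(scored_proms %in% td$promoter) && nrow(td) > 0) {
    stop("truth/output promoter id mismatch", call. = FALSE)
  }
  dominance <- do.call(rbind, lapply(unique(dom$mark), function(mk) {
    calls <- dom[dom$mark == mk & dom$dominant, ]
    tset <- td[td$mark == mk & td$promoter %in% scored_proms, ]
    ckey <- paste0(calls$promoter, "|", calls$neighbor)
    tkey <- paste0(tset$promoter, "|", tset$neighbor)
    data.frame(mark = mk,
               precision = if (length(ckey)) mean(ckey %in% tkey) else NA,
               recall = if (length(tkey)) mean(tkey %in% ckey) else NA,
               n_called = length(ckey), n_truth = length(tkey))
  }))

  fc <- read_out("fc_enhancer.tsv")
  boost <- unlist(truth$cf_boost_profile)
  planted_peak <- if (max(boost) > min(boost)) {
    names(boost)[which.max(boost)]
  } else NA_character_
  fc_peak <- do.call(rbind, lapply(unique(fc$mark), function(mk) {
    sub <- fc[fc$mark == mk & fc$selector == "E+AR->P+AR", ]
    obs <- sub$timepoint[which.max(sub$mean_fc)]
    data.frame(mark = mk, observed_peak = obs, planted_peak = planted_peak,
               match = if (is.na(planted_peak)) NA else obs == planted_peak)
  }))

  ng <- read_out("nascent_groups.tsv")
  tg <- as.data.frame(truth$nascent_groups)
  nascent_accuracy <- if (!nrow(tg)) NA_real_ else {
    shared <- intersect(ng$transcript, tg$transcript)
    if (!length(shared) && nrow(tg)) {
      stop("truth/output transcript id mismatch", call. = FALSE)
    }
    hits <- ng$group[match(shared, ng$transcript)] ==
      tg$group[match(shared, tg$transcript)]
    sum(hits) / nrow(tg)
  }

  mo <- read_out("models.tsv")
  model_match <- vapply(unique(mo$mark), function(mk) {
    sub <- mo[mo$mark == mk, ]
    rho <- stats::setNames(sub$rho, sub$model)
    rho[["sum"]] > rho[["max"]] && rho[["max"]] > rho[["avg"]] &&
      sub$model[sub$rf_rank == 1] == "sum"
  }, logical(1))

  report <- list(dominance = dominance, fc_peak_match = fc_peak,
                 nascent_accuracy = nascent_accuracy,
                 model_ranking_match = as.list(
                   stats::setNames(model_match, unique(mo$mark))))
  jsonlite::write_json(report, file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
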