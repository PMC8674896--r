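#' Default end-to-end pipeline configuration
#'
#' All stage parameters at their standard values: MAF > 0.05, MAC > 4,
#' missingness < 0.15 in >= 3 groups, HWE p < 0.05 in >= 2 sites, LD r^2
#' <= 0.2 in 1000-bp windows; diagnostic thresholds 0.9/0.1 with the 0.9
#' loading quantile; 300 search iterations of 80-100 SNPs toward a
#' 127-SNP panel; purity rule (0.94, 0.06); 1000 bootstrap replicates.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param n_loci Synthetic study size.
#' @param stages Named logical toggles for `synth`, `filter`, `stats`,
#'   `ancestry`, `panel`, `simulate`, `classify`, `cline`.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1, out_dir = NULL, n_loci = 8582,
                                    stages = NULL) {
  cfg <- list(
    seed = seed, out_dir = out_dir, n_loci = n_loci,
    stages = list(synth = TRUE, filter = TRUE, stats = TRUE, ancestry = TRUE,
                  panel = TRUE, simulate = TRUE, classify = TRUE,
                  cline = TRUE),
    filter = list(maf = 0.05, mac = 4, max_missing = 0.15, min_groups = 3,
                  hwe_p = 0.05, hwe_sites = 2, r2_max = 0.2,
                  window_bp = 1000),
    stats = list(n_boot = 1000),
    panel = list(diag_hi = 0.9, diag_lo = 0.1, quantile = 0.9, n_iter = 300,
                 size_range = c(80, 100), target_panel = 127, delta = 0.05),
    classify = list(pure_threshold = 0.94, minor_threshold = 0.06),
    cline = list(ancestry_cut = 0.06)
  )
  if (!is.null(stages)) cfg$stages[names(stages)] <- stages
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

# internal: derived per-stage seed, kept well below .Machine$integer.max
stage_seed <- function(seed, offset) (seed %% 100000L) * 1000L + offset

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — synthetic study generation, SNP
#' filtering, summary statistics, full-data supervised ancestry, diagnostic
#' panel design, hybrid-cohort simulation, Q-threshold classification, and
#' geographic cline modelling — carrying each stage's outputs forward and
#' aggregating a machine-readable summary. A disabled upstream stage whose
#' outputs a later stage needs is an error naming the stage.
#'
#' @param config A [default_pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @return List of class `pipeline_result` with per-stage outputs and a
#'   `summary` list (also written as JSON when `out_dir` is set).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  st <- config$stages
  res <- list()
  summary <- list(seed = config$seed)
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop("stage `", stage, "` needs outputs of disabled/failed stage `",
           what, "`")
    }
  }
  if (isTRUE(st$synth)) {
    model <- default_lineage_model(n_loci = config$n_loci)
    res$study <- generate_study(model = model,
                                seed = stage_seed(config$seed, 1L))
    summary$synth <- list(n_individuals = n_ind(res$study$gm),
                          n_loci = n_loci(res$study$gm))
  }
  if (isTRUE(st$filter)) {
    need("study", "filter")
    f <- config$filter
    flt <- filter_snps(res$study$gm, res$study$popmap, maf = f$maf,
                       mac = f$mac, max_missing = f$max_missing,
                       min_groups = f$min_groups, hwe_p = f$hwe_p,
                       hwe_sites = f$hwe_sites, r2_max = f$r2_max,
                       window_bp = f$window_bp)
    res$filtered <- flt$gm
    res$filter_report <- flt$report
    summary$filter <- list(n_in = flt$report$n_in[1],
                           n_out = utils::tail(flt$report$n_out, 1),
                           removed = stats::setNames(
                             as.list(flt$report$n_removed),
                             flt$report$filter))
  }
  if (isTRUE(st$stats)) {
    need("filtered", "stats")
    pm <- align_popmap(res$filtered, res$study$popmap)
    res$diversity <- diversity(res$filtered, pm$group)
    res$fst <- wc_fst(res$filtered, pm$group)
    freqs <- allele_freqs(res$filtered, pm$group)
    res$fixed <- list(
      DLB.NLB = fixed_snps(freqs, "DLB", "NLB"),
      DLB.FLB = fixed_snps(freqs, "DLB", "FLB"),
      NLB.FLB = fixed_snps(freqs, "NLB", "FLB")
    )
    summary$stats <- list(
      overall_fst = res$fst$overall,
      pairwise_fst = list(DLB.NLB = res$fst$pairwise["DLB", "NLB"],
                          DLB.FLB = res$fst$pairwise["DLB", "FLB"],
                          NLB.FLB = res$fst$pairwise["NLB", "FLB"]),
      n_fixed = lapply(res$fixed, length)
    )
  }
  if (isTRUE(st$ancestry)) {
    need("filtered", "ancestry")
    res$ref_panel <- build_ref_panel(res$filtered, res$study$popmap)
    res$q_full <- estimate_q_supervised(res$filtered, res$ref_panel)
    summary$ancestry <- list(
      mean_q = as.list(colMeans(unclass_q(res$q_full)))
    )
  }
  if (isTRUE(st$panel)) {
    need("q_full", "panel")
    p <- config$panel
    pm <- align_popmap(res$filtered, res$study$popmap)
    ref_freqs <- allele_freqs(res$filtered[pm$is_reference, ],
                              pm$group[pm$is_reference])
    diag <- find_diagnostic_snps(ref_freqs, hi = p$diag_hi, lo = p$diag_lo)
    pure <- pm$group != "ILB"
    imp <- impute_by_group_freq(res$filtered[pure, diag],
                                res$study$popmap,
                                seed = stage_seed(config$seed, 2L))
    pc <- pca(imp)
    cand <- top_loading_snps(pc, pcs = c(1, 2), quantile = p$quantile)
    res$panel <- iterative_search(cand, res$filtered, res$ref_panel,
                                  res$q_full, n_iter = p$n_iter,
                                  size_range = p$size_range,
                                  target_panel = min(p$target_panel,
                                                     length(cand)),
                                  delta = p$delta,
                                  seed = stage_seed(config$seed, 3L))
    summary$panel <- list(n_diagnostic = length(diag),
                          n_candidates = length(cand),
                          panel_size = length(res$panel$loci))
  }
  if (isTRUE(st$simulate)) {
    need("panel", "simulate")
    panel_ref <- build_ref_panel(res$filtered[, res$panel$loci],
                                 res$study$popmap)
    res$sim <- simulate_design(default_sim_design(), panel_ref,
                               seed = stage_seed(config$seed, 4L))
    res$panel_ref <- panel_ref
    summary$simulate <- list(n_simulated = n_ind(res$sim$gm))
  }
  if (isTRUE(st$classify)) {
    need("sim", "classify")
    cl <- config$classify
    q_sim <- estimate_q_supervised(res$sim$gm, res$panel_ref)
    rule <- category_rule(cl$pure_threshold, cl$minor_threshold)
    res$assignment <- evaluate(confusion_matrix(
      res$sim$category, assign_category(q_sim, rule)))
    m <- res$assignment$metrics
    summary$classify <- stats::setNames(
      lapply(seq_len(nrow(m)), function(i) list(
        efficiency = m$efficiency[i], accuracy = m$accuracy[i],
        performance = m$performance[i])),
      m$category)
  }
  if (isTRUE(st$cline)) {
    need("q_full", "cline")
    cd <- build_cline_data(res$q_full, res$study$popmap, res$study$sites,
                           ref_site = "StJohnsRiver", lineage = "FLB")
    res$cline_full <- fit_fractional_logit(cd, "full")
    res$cline_reduced <- fit_fractional_logit(cd, "distance_only")
    summary$cline <- list(
      coefficients = as.list(res$cline_full$coefficients),
      stocking_p = deviance_test(res$cline_full, res$cline_reduced),
      extent_shift_km = tryCatch(
        extent_shift(res$cline_full, config$cline$ancestry_cut),
        error = function(e) NA_real_)
    )
  } else {
    summary$cline <- "skipped"
  }
  res$summary <- summary
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$filtered)) {
      write_vcf(res$filtered, file.path(config$out_dir, "filtered.vcf"))
    }
    if (!is.null(res$q_full)) {
      write_q(res$q_full, file.path(config$out_dir, "q_full.tsv"))
    }
    if (!is.null(res$panel)) {
      utils::write.table(
        data.frame(locus = res$panel$loci,
                   selection_count = res$panel$selection_count),
        file.path(config$out_dir, "panel.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:",
      paste(setdiff(names(x), "summary"), collapse = ", "), "\n")
  invisible(x)
}
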