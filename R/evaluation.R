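#' Complete synthetic panel-evaluation study
#'
#' Runs the whole evaluation protocol on synthetic data in one call:
#' generate a calibrated three-lineage study, estimate full-data supervised
#' ancestry, design a diagnostic panel (candidate screen, PCA loading
#' filter, iterative subset search), simulate the labelled hybrid cohort on
#' the panel loci, re-estimate ancestry, and score the Q-threshold
#' assignment. This is the computation behind the package's headline
#' performance numbers.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param model A [lineage_model()] (default: calibrated 8582-locus model).
#' @param target_panel Panel size to design.
#' @param n_iter Subset-search iterations.
#' @param rule A [category_rule()].
#' @return List with `report` (the [evaluate()] output), `panel`, `q_full`,
#'   `study`, plus convenience numbers: `performance` (named percent vector
#'   by category), `min_pure`, `min_pair`, `triple` (percent), `rmse_truth`
#'   (full-data supervised Q vs true ancestry), and `panel_concordance`
#'   (fraction of individuals whose panel Q is within 0.1 of full-data Q).
#' @export
panel_evaluation_study <- function(seed = 1, model = default_lineage_model(),
                                   target_panel = 73, n_iter = 300,
                                   rule = category_rule()) {
  base <- seed %% 100000L
  study <- generate_study(model = model, seed = base)
  ref <- build_ref_panel(study$gm, study$popmap)
  q_full <- estimate_q_supervised(study$gm, ref)
  pm <- study$popmap
  ref_freqs <- allele_freqs(study$gm[pm$is_reference, ],
                            pm$group[pm$is_reference])
  diag <- find_diagnostic_snps(ref_freqs)
  imp <- impute_by_group_freq(study$gm[pm$group != "ILB", diag],
                              study$popmap, seed = base + 1L)
  cand <- top_loading_snps(pca(imp))
  panel <- iterative_search(cand, study$gm, ref, q_full, n_iter = n_iter,
                            size_range = c(80, 100),
                            target_panel = target_panel, seed = base + 2L)
  panel_ref <- build_ref_panel(study$gm[, panel$loci], study$popmap)
  sim <- simulate_design(default_sim_design(), panel_ref, seed = base + 3L)
  q_sim <- estimate_q_supervised(sim$gm, panel_ref)
  report <- evaluate(confusion_matrix(sim$category,
                                      assign_category(q_sim, rule)))
  m <- report$metrics
  perf <- stats::setNames(100 * m$performance, m$category)
  truth <- as.matrix(study$truth[, colnames(q_full)])
  rmse <- sqrt(mean((unclass_q(q_full) - truth)^2))
  q_panel <- estimate_q_supervised(study$gm[, panel$loci], ref)
  dq <- apply(abs(unclass_q(q_panel) - unclass_q(q_full)), 1, max)
  list(
    report = report, panel = panel, q_full = q_full, q_panel = q_panel,
    study = study, sim = sim,
    performance = perf,
    min_pure = min(perf[c("DLB", "NLB", "FLB")]),
    min_pair = min(perf[c("DLB-NLB", "DLB-FLB", "NLB-FLB")]),
    triple = unname(perf["Triple Hybrid"]),
    rmse_truth = rmse,
    panel_concordance = mean(dq <= 0.1)
  )
}

#' Realized pairwise F_ST of the calibrated generator
#'
#' Regenerates lineage frequencies and samples of diploids over several
#' seeds, returning the average multi-locus Weir-Cockerham theta per
#' lineage pair — the generator's calibration check.
#'
#' @param model A [lineage_model()].
#' @param n_seeds Number of independent generations to average.
#' @param n_dip Diploids sampled per lineage.
#' @param seed Base seed.
#' @return Named numeric: mean `DLB.NLB`, `DLB.FLB`, `NLB.FLB` theta.
#' @export
realized_fst <- function(model = default_lineage_model(), n_seeds = 10,
                         n_dip = 30, seed = 1) {
  base <- seed %% 100000L
  th <- vapply(seq_len(n_seeds), function(s) {
    fr <- generate_lineage_freqs(model, seed = base + s)
    smp <- sample_lineages(fr, n_dip, seed = base + 5000L + s)
    fst <- wc_fst(smp$gm, smp$grouping)
    c(DLB.NLB = fst$pairwise["DLB", "NLB"],
      DLB.FLB = fst$pairwise["DLB", "FLB"],
      NLB.FLB = fst$pairwise["NLB", "FLB"])
  }, numeric(3))
  rowMeans(th)
}
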