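#' Candidate diagnostic SNPs from lineage allele frequencies
#'
#' A locus is a diagnostic candidate when some pair of lineages is strongly
#' contrasted: frequency above `hi` in one and below `lo` in the other, on
#' either allele orientation. (A literal "extreme in two of three lineages"
#' reading would also admit loci extreme in the same direction in two
#' lineages, which carry no between-lineage information; the pair rule is
#' used instead.)
#'
#' @param freqs An [allele_freqs()] table over the three pure lineages.
#' @param hi,lo Frequency thresholds (strict `>` hi, strict `<` lo).
#' @param lineages Which three groups to use.
#' @return Character vector of candidate locus ids.
#' @export
find_diagnostic_snps <- function(freqs, hi = 0.9, lo = 0.1,
                                 lineages = LINEAGES) {
  if (!all(lineages %in% rownames(freqs$p))) {
    stop("frequency table must contain groups: ",
         paste(lineages, collapse = ", "))
  }
  p <- freqs$p[lineages, , drop = FALSE]
  undef <- colSums(is.na(p)) > 0
  if (any(undef)) {
    message("find_diagnostic_snps: skipping ", sum(undef),
            " locus/loci with undefined frequency")
  }
  pairs <- utils::combn(length(lineages), 2)
  hit <- rep(FALSE, ncol(p))
  for (c in seq_len(ncol(pairs))) {
    a <- p[pairs[1, c], ]
    b <- p[pairs[2, c], ]
    hit <- hit | (a > hi & b < lo) | (b > hi & a < lo) |
      ((1 - a) > hi & (1 - b) < lo) | ((1 - b) > hi & (1 - a) < lo)
  }
  freqs$loci[which(hit & !undef)]
}

#' Top-loading SNPs from a PCA
#'
#' Union, over the chosen principal components, of loci whose absolute
#' loading is at or above the given quantile of absolute loadings for that
#' component.
#'
#' @param pca_fit A [pca()] result (or a loci-by-PC loadings matrix with
#'   locus row names).
#' @param pcs Which components to use.
#' @param quantile Quantile threshold in (0, 1).
#' @return Character vector of locus ids.
#' @export
top_loading_snps <- function(pca_fit, pcs = c(1, 2), quantile = 0.9) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  loadings <- if (inherits(pca_fit, "pca_result")) pca_fit$loadings else pca_fit
  if (max(pcs) > ncol(loadings)) stop("requested PC beyond available components")
  m <- ceiling((1 - quantile) * nrow(loadings))
  sel <- character(0)
  for (pc in pcs) {
    a <- abs(loadings[, pc])
    # rank-based: exactly the top (1-quantile) share per PC, ties broken by
    # locus order so tied blocks cannot inflate the selection
    top <- order(-a, seq_along(a))[seq_len(m)]
    sel <- union(sel, rownames(loadings)[top])
  }
  sel[order(match(sel, rownames(loadings)))]
}

#' Score a SNP subset against full-data ancestry
#'
#' Re-estimates supervised ancestry from the subset loci alone and counts
#' individuals whose largest per-lineage deviation from the full-data Q
#' exceeds `delta`.
#'
#' @param subset Locus ids (must be present in `gm`).
#' @param gm A [genotype_matrix()].
#' @param ref A [build_ref_panel()].
#' @param q_full [q_matrix()] estimated once from the full SNP set.
#' @param delta Q-difference threshold.
#' @return List with `subset` and `n_discordant`.
#' @export
score_subset <- function(subset, gm, ref, q_full, delta = 0.05) {
  if (!all(subset %in% gm$loci$id)) stop("subset loci not present in matrix")
  q_sub <- estimate_q_supervised(gm[, subset], ref)
  dq <- abs(unclass_q(q_sub)[rownames(q_full), colnames(q_full), drop = FALSE] -
              unclass_q(q_full))
  list(subset = subset,
       n_discordant = sum(apply(dq, 1, max) > delta))
}

#' Iterative random-subset search for a diagnostic panel
#'
#' Draws `n_iter` random subsets of the candidate loci (sizes uniform on
#' `size_range`), scores each against the full-data ancestry with
#' [score_subset()], ranks iterations by the number of discordant
#' individuals (ties to the earlier iteration), and assembles the panel as
#' the union of loci from the best iterations. The union is grown until it
#' reaches `target_panel` unique loci and then truncated by dropping the
#' loci selected by the fewest of the included iterations.
#'
#' @param candidates Candidate locus ids (at least `max(size_range)`).
#' @param gm,ref,q_full As in [score_subset()].
#' @param n_iter Number of random subsets.
#' @param size_range Integer range of subset sizes.
#' @param target_panel Final panel size.
#' @param delta Q-difference threshold for discordance.
#' @param seed Random seed (the search is deterministic given the seed).
#' @return A `diagnostic_panel`: list with `loci`, per-locus `freq` (from
#'   the reference panel), `selection_count`, and the iteration `scores`.
#' @export
iterative_search <- function(candidates, gm, ref, q_full, n_iter = 300,
                             size_range = c(80, 100), target_panel = 127,
                             delta = 0.05, seed = 1) {
  if (length(candidates) < max(size_range)) {
    stop("fewer candidates than the maximum subset size")
  }
  if (target_panel > length(candidates)) {
    stop("target_panel exceeds the number of candidates")
  }
  subsets <- withr::with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_iter, replace = TRUE)
    lapply(sizes, function(s) sample(candidates, s))
  })
  scores <- vapply(subsets, function(s) {
    score_subset(s, gm, ref, q_full, delta = delta)$n_discordant
  }, numeric(1))
  rank_order <- order(scores, seq_along(scores))
  # grow the union from the best-ranked iterations
  included <- integer(0)
  pool <- character(0)
  for (i in rank_order) {
    included <- c(included, i)
    pool <- union(pool, subsets[[i]])
    if (length(pool) >= target_panel) break
  }
  counts <- table(factor(unlist(subsets[included]), levels = pool))
  # deterministic truncation: keep the loci selected by the most included
  # iterations; ties resolved by each locus's marginal quality (the mean
  # discordance of all search iterations that sampled it), then candidate
  # order
  marginal <- vapply(pool, function(l) {
    hit <- vapply(subsets, function(s) l %in% s, logical(1))
    if (any(hit)) mean(scores[hit]) else Inf
  }, numeric(1))
  ord <- order(-as.integer(counts), marginal, match(pool, candidates))
  loci <- pool[ord][seq_len(target_panel)]
  loci <- loci[order(match(loci, candidates))]
  structure(list(
    loci = loci,
    freq = ref$freq[, match(loci, ref$loci$id), drop = FALSE],
    selection_count = as.integer(counts[loci]),
    scores = data.frame(iteration = seq_along(scores), size = lengths(subsets),
                        n_discordant = scores),
    included_iterations = included
  ), class = "diagnostic_panel")
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf(
    "diagnostic_panel: %d loci assembled from %d of %d search iterations\n",
    length(x$loci), length(x$included_iterations), nrow(x$scores)))
  cat(sprintf("  best iteration discordance: %d individual(s)\n",
              min(x$scores$n_discordant)))
  invisible(x)
}

#' Two-lineage allele-counting ancestry
#'
#' Legacy-style ancestry estimate for a two-lineage panel: the fraction of
#' an individual's called panel alleles that are diagnostic for `lineage`
#' (vs `other`). Panel loci are oriented per locus by the reference-panel
#' frequencies.
#'
#' @param gm A [genotype_matrix()] restricted to (or containing) the panel.
#' @param panel_loci Locus ids of the two-lineage panel.
#' @param ref A [build_ref_panel()] used to orient alleles.
#' @param lineage Focal lineage whose allele fraction is returned.
#' @param other Contrasting lineage.
#' @return Named numeric vector of focal-allele fractions (`NA` when all
#'   panel genotypes are missing, with a warning).
#' @export
allele_count_ancestry <- function(gm, panel_loci, ref, lineage = "FLB",
                                  other = "NLB") {
  if (!all(panel_loci %in% gm$loci$id)) stop("panel loci not present in matrix")
  sub <- gm[, panel_loci]
  ridx <- match(panel_loci, ref$loci$id)
  if (anyNA(ridx)) stop("panel loci missing from reference panel")
  focal_is_alt <- ref$freq[lineage, ridx] > ref$freq[other, ridx]
  dos <- sub$calls
  focal <- sweep(dos, 2, ifelse(focal_is_alt, 1, -1), `*`) +
    matrix(ifelse(focal_is_alt, 0, 2), nrow(dos), ncol(dos), byrow = TRUE)
  called <- 2 * rowSums(!is.na(dos))
  out <- rowSums(focal, na.rm = TRUE) / called
  if (any(called == 0)) {
    warning(sum(called == 0), " individual(s) with all panel genotypes missing")
    out[called == 0] <- NA_real_
  }
  out
}
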