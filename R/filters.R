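#' SNP quality-control filters
#'
#' The post-calling filter cascade applied before any population-genetic
#' analysis: minor-allele frequency/count, per-group call and missingness
#' rates, Hardy-Weinberg departures replicated across sampling sites, excess
#' heterozygosity, and linkage-disequilibrium pruning. Each filter returns
#' the reduced matrix together with a small report so every removed locus is
#' attributable to exactly one step.
#'
#' @name snp_filters
NULL

new_filter_report <- function(filter, n_in, n_out, params) {
  data.frame(
    filter = filter, n_in = n_in, n_removed = n_in - n_out, n_out = n_out,
    params = params, stringsAsFactors = FALSE
  )
}

#' Filter on minor-allele frequency and count
#'
#' Retains loci whose pooled minor-allele frequency is strictly greater than
#' `maf` and whose minor-allele count is strictly greater than `mac`,
#' computed over called genotypes only.
#'
#' @param gm A [genotype_matrix()].
#' @param maf Minor-allele frequency threshold (strict `>`).
#' @param mac Minor-allele count threshold (strict `>`).
#' @return `list(gm =, report =)`.
#' @export
filter_maf_mac <- function(gm, maf = 0.05, mac = 4) {
  if (n_loci(gm) == 0) stop("empty genotype matrix")
  alt <- colSums(gm$calls, na.rm = TRUE)
  called <- 2 * colSums(!is.na(gm$calls))
  minor <- pmin(alt, called - alt)
  keep <- called > 0 & minor / pmax(called, 1) > maf & minor > mac
  out <- gm[, keep]
  if (n_loci(out) == 0) warning("all loci removed by MAF/MAC filter")
  list(gm = out,
       report = new_filter_report("maf_mac", n_loci(gm), n_loci(out),
                                  sprintf("maf>%g, mac>%g", maf, mac)))
}

#' Filter on per-group call status and overall missingness
#'
#' Retains loci with at least one called genotype in `min_groups` of the
#' four population groups and a missing fraction below `max_missing` across
#' all individuals.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Population map covering all individuals.
#' @param max_missing Maximum missing fraction (strict `<`).
#' @param min_groups Minimum number of groups with a called genotype.
#' @return `list(gm =, report =)`.
#' @export
filter_missing_groups <- function(gm, popmap, max_missing = 0.15, min_groups = 3) {
  pm <- align_popmap(gm, popmap)
  absent <- setdiff(GROUPS, unique(pm$group))
  if (length(absent)) {
    stop("group(s) absent from popmap: ", paste(absent, collapse = ", "))
  }
  called <- !is.na(gm$calls)
  groups_called <- Reduce(`+`, lapply(unique(pm$group), function(g) {
    as.integer(colSums(called[pm$group == g, , drop = FALSE]) > 0)
  }))
  miss_frac <- 1 - colSums(called) / n_ind(gm)
  keep <- groups_called >= min_groups & miss_frac < max_missing
  out <- gm[, keep]
  list(gm = out,
       report = new_filter_report("missing_groups", n_loci(gm), n_loci(out),
                                  sprintf("missing<%g, groups>=%d",
                                          max_missing, min_groups)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts at a biallelic locus, summing the
#' probabilities of all heterozygote configurations no more likely than the
#' observed one, conditional on the allele counts (the standard exact-test
#' convention used by variant-QC tools).
#'
#' @param n_het Observed heterozygotes.
#' @param n_hom1,n_hom2 Observed counts of the two homozygote classes.
#' @return Exact p-value.
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities by recurrence on the heterozygote count
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    # P(h) / P(h-2) = 4 * n_rare_hom(h-2) * n_common_hom(h-2) / (h * (h-1))
    hr <- (rare - (h - 2)) / 2
    hc <- n - hr - (h - 2)
    lp[i] <- lp[i - 1] + log(4 * hr * hc) - log(h) - log(h - 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Filter loci out of Hardy-Weinberg equilibrium in multiple sites
#'
#' A locus is removed when its exact-test p-value falls below `p_cut` in at
#' least `min_sites` sampling sites. Sites with fewer than `min_n`
#' individuals are skipped (and reported via a message).
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Population map with sampling sites.
#' @param p_cut Exact-test p-value cutoff (strict `<`).
#' @param min_sites Number of offending sites required for removal.
#' @param min_n Minimum individuals for a site to be tested.
#' @return `list(gm =, report =)`.
#' @export
filter_hwe <- function(gm, popmap, p_cut = 0.05, min_sites = 2, min_n = 5) {
  pm <- align_popmap(gm, popmap)
  sites <- unique(pm$site)
  use <- sites[vapply(sites, function(s) sum(pm$site == s) >= min_n, logical(1))]
  if (length(use) < length(sites)) {
    message("filter_hwe: skipping ", length(sites) - length(use),
            " site(s) with fewer than ", min_n, " individuals")
  }
  n_offend <- integer(n_loci(gm))
  for (s in use) {
    sub <- gm$calls[pm$site == s, , drop = FALSE]
    het <- colSums(sub == 1L, na.rm = TRUE)
    hom0 <- colSums(sub == 0L, na.rm = TRUE)
    hom2 <- colSums(sub == 2L, na.rm = TRUE)
    p <- vapply(seq_len(ncol(sub)), function(l) {
      hwe_exact_p(het[l], hom0[l], hom2[l])
    }, numeric(1))
    n_offend <- n_offend + (p < p_cut)
  }
  keep <- n_offend < min_sites
  out <- gm[, keep]
  list(gm = out,
       report = new_filter_report("hwe", n_loci(gm), n_loci(out),
                                  sprintf("p<%g in >=%d sites, min_n=%d",
                                          p_cut, min_sites, min_n)))
}

#' Filter loci with excess observed heterozygosity
#'
#' @param gm A [genotype_matrix()].
#' @param max_het Maximum heterozygote fraction among called genotypes
#'   (strict `<`).
#' @return `list(gm =, report =)`.
#' @export
filter_max_het <- function(gm, max_het = 0.7) {
  het <- colSums(gm$calls == 1L, na.rm = TRUE)
  called <- colSums(!is.na(gm$calls))
  keep <- called > 0 & het / pmax(called, 1) < max_het
  out <- gm[, keep]
  list(gm = out,
       report = new_filter_report("max_het", n_loci(gm), n_loci(out),
                                  sprintf("het<%g", max_het)))
}

#' Prune SNPs in linkage disequilibrium or within a base-pair window
#'
#' Greedy left-to-right pruning by position within each chromosome: a locus
#' is dropped if it lies within `window_bp` of the last retained locus, or if
#' its genotype-dosage squared correlation with any retained locus on the
#' same chromosome exceeds `r2_max` (composite, unphased r-squared).
#'
#' @param gm A [genotype_matrix()] (loci need not be pre-sorted).
#' @param r2_max Maximum allowed pairwise dosage r-squared.
#' @param window_bp Window size in base pairs.
#' @return `list(gm =, report =)`.
#' @export
ld_prune <- function(gm, r2_max = 0.2, window_bp = 1000) {
  loci <- gm$loci
  ord <- order(loci$chrom, loci$pos)
  keep_idx <- integer(0)
  for (chr in unique(loci$chrom[ord])) {
    idx <- ord[loci$chrom[ord] == chr]
    kept <- integer(0)
    last_pos <- -Inf
    for (l in idx) {
      if (loci$pos[l] - last_pos < window_bp) next
      if (length(kept)) {
        r <- suppressWarnings(
          stats::cor(gm$calls[, l], gm$calls[, kept, drop = FALSE],
                     use = "pairwise.complete.obs")
        )
        r2 <- r^2
        if (any(r2 > r2_max, na.rm = TRUE)) next
      }
      kept <- c(kept, l)
      last_pos <- loci$pos[l]
    }
    keep_idx <- c(keep_idx, kept)
  }
  out <- gm[, sort(keep_idx)]
  list(gm = out,
       report = new_filter_report("ld_prune", n_loci(gm), n_loci(out),
                                  sprintf("r2<=%g, window=%dbp",
                                          r2_max, as.integer(window_bp))))
}

#' Run the full SNP filter cascade
#'
#' Applies, in order: MAF/MAC, per-group call/missingness, Hardy-Weinberg
#' replication, and LD/window pruning, collecting per-filter reports.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Population map.
#' @param maf,mac,max_missing,min_groups,hwe_p,hwe_sites,r2_max,window_bp
#'   Parameters passed to the individual filters.
#' @return `list(gm =, report =)` where `report` stacks the per-filter rows.
#' @export
filter_snps <- function(gm, popmap, maf = 0.05, mac = 4, max_missing = 0.15,
                        min_groups = 3, hwe_p = 0.05, hwe_sites = 2,
                        r2_max = 0.2, window_bp = 1000) {
  s1 <- filter_maf_mac(gm, maf = maf, mac = mac)
  s2 <- filter_missing_groups(s1$gm, popmap, max_missing = max_missing,
                              min_groups = min_groups)
  s3 <- filter_hwe(s2$gm, popmap, p_cut = hwe_p, min_sites = hwe_sites)
  s4 <- ld_prune(s3$gm, r2_max = r2_max, window_bp = window_bp)
  list(gm = s4$gm,
       report = rbind(s1$report, s2$report, s3$report, s4$report))
}
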