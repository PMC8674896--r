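#' Per-group allele frequencies
#'
#' Alternate-allele frequency and called-allele count for each group at each
#' locus. Cells with no called alleles have frequency `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Character/factor vector assigning each individual (in
#'   matrix order) to a group.
#' @return An `allele_freq_table`: list with matrices `p` (groups x loci,
#'   alt-allele frequency) and `n_alleles` (called allele counts).
#' @export
allele_freqs <- function(gm, grouping) {
  grouping <- as.character(grouping)
  if (length(grouping) != n_ind(gm)) {
    stop("grouping length does not match number of individuals")
  }
  groups <- unique(grouping)
  if (any(table(grouping) == 0) || length(groups) == 0) stop("empty group")
  p <- matrix(NA_real_, length(groups), n_loci(gm),
              dimnames = list(groups, gm$loci$id))
  n2 <- matrix(0L, length(groups), n_loci(gm),
               dimnames = list(groups, gm$loci$id))
  for (g in groups) {
    sub <- gm$calls[grouping == g, , drop = FALSE]
    called <- 2L * colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    n2[g, ] <- called
    p[g, ] <- ifelse(called > 0, alt / called, NA_real_)
  }
  structure(list(p = p, n_alleles = n2, loci = gm$loci$id),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d groups x %d loci (%d undefined cells)\n",
              nrow(x$p), ncol(x$p), sum(is.na(x$p))))
  invisible(x)
}

# internal: per-locus Ho and small-sample-corrected gene diversity Hs
# (Nei & Chesser) for one group of genotypes; loci with <2 called
# individuals get NA
nei_chesser_locus <- function(calls) {
  n <- colSums(!is.na(calls))
  ho <- ifelse(n > 0, colSums(calls == 1L, na.rm = TRUE) / n, NA_real_)
  p <- ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), NA_real_)
  hs <- ifelse(n >= 2,
               n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n)),
               NA_real_)
  ho[n < 2] <- NA_real_
  list(ho = ho, hs = hs, n = n)
}

#' Diversity statistics per group
#'
#' Observed heterozygosity, Nei-Chesser small-sample-corrected expected
#' heterozygosity (gene diversity), and the inbreeding coefficient
#' `F_IS = 1 - mean(Ho)/mean(Hs)`, averaged across loci with at least two
#' called individuals. Groups with fewer than `min_n` individuals are
#' skipped, mirroring the convention of reporting summary statistics only
#' for samples of five or more.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Group assignment vector (groups or sampling sites).
#' @param min_n Minimum group size to report.
#' @return `data.frame` with columns `group`, `n`, `n_loci`, `Ho`, `He`,
#'   `Fis` (NA when mean `He` is zero).
#' @export
diversity <- function(gm, grouping, min_n = 5) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  keep <- groups[vapply(groups, function(g) sum(grouping == g) >= min_n,
                        logical(1))]
  if (length(keep) < length(groups)) {
    message("diversity: skipping ", length(groups) - length(keep),
            " group(s) with fewer than ", min_n, " individuals")
  }
  rows <- lapply(keep, function(g) {
    st <- nei_chesser_locus(gm$calls[grouping == g, , drop = FALSE])
    use <- !is.na(st$hs)
    mho <- mean(st$ho[use])
    mhs <- mean(st$hs[use])
    data.frame(group = g, n = sum(grouping == g), n_loci = sum(use),
               Ho = mho, He = mhs,
               Fis = if (isTRUE(mhs > 0)) 1 - mho / mhs else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bootstrap confidence interval for F_IS
#'
#' Percentile interval over locus resampling (loci, not individuals, are
#' resampled, following the convention of `boot.ppfis`-style intervals).
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Group assignment vector.
#' @param group Which group to bootstrap.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Random seed.
#' @param conf Confidence level.
#' @return Named numeric `c(lo, hi)`.
#' @export
fis_bootstrap_ci <- function(gm, grouping, group, n_boot = 1000, seed = 1,
                             conf = 0.95) {
  grouping <- as.character(grouping)
  st <- nei_chesser_locus(gm$calls[grouping == group, , drop = FALSE])
  use <- which(!is.na(st$hs))
  ho <- st$ho[use]
  hs <- st$hs[use]
  if (length(use) < 1) stop("no usable loci for group ", group)
  fis_of <- function(idx) {
    m <- mean(hs[idx])
    if (m > 0) 1 - mean(ho[idx]) / m else NA_real_
  }
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      fis_of(sample.int(length(use), replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  c(lo = ci[1], hi = ci[2])
}

# internal: Weir-Cockerham (1984) variance components a, b, c per locus for
# a set of groups; inputs are per-group per-locus called sample sizes n,
# alt frequencies p, and observed het fractions h (groups x loci matrices).
# Loci where fewer than two groups have n >= 2 are dropped (NA components).
wc_components <- function(n, p, h) {
  ok <- n >= 2
  r_l <- colSums(ok)
  n[!ok] <- 0
  usable <- r_l >= 2
  nbar <- colSums(n) / r_l
  sum_n2 <- colSums(n^2)
  nc <- (colSums(n) - sum_n2 / colSums(n)) / (r_l - 1)
  pw <- n * p
  pw[!ok] <- 0
  pbar <- colSums(pw) / colSums(n)
  dev <- sweep(p, 2, pbar, `-`)^2 * n
  dev[!ok] <- 0
  s2 <- colSums(dev) / ((r_l - 1) * nbar)
  hw <- n * h
  hw[!ok] <- 0
  hbar <- colSums(hw) / colSums(n)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r_l - 1) / r_l * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r_l - 1) / r_l * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cc[!usable] <- NA_real_
  list(a = a, b = b, c = cc)
}

# internal: per-group per-locus n, p, h matrices for wc_components
group_locus_stats <- function(gm, grouping, groups) {
  L <- n_loci(gm)
  n <- p <- h <- matrix(0, length(groups), L)
  for (i in seq_along(groups)) {
    sub <- gm$calls[grouping == groups[i], , drop = FALSE]
    ni <- colSums(!is.na(sub))
    n[i, ] <- ni
    p[i, ] <- ifelse(ni > 0, colSums(sub, na.rm = TRUE) / (2 * ni), 0)
    h[i, ] <- ifelse(ni > 0, colSums(sub == 1L, na.rm = TRUE) / ni, 0)
  }
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham F_ST
#'
#' Multi-locus theta as the ratio of summed variance components
#' (`sum(a) / sum(a + b + c)`), with negative per-locus components retained
#' in the sums. Returns the pairwise matrix between all groups plus the
#' overall multi-group estimate.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Group assignment vector; at least two groups with at
#'   least two individuals each.
#' @return An `fst_matrix`: list with `pairwise` (symmetric matrix, zero
#'   diagonal), `overall` (multi-group theta) and `n_loci_used`.
#' @export
wc_fst <- function(gm, grouping) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- vapply(groups, function(g) sum(grouping == g), integer(1))
  if (any(sizes < 2)) {
    stop("each group needs >= 2 individuals; too small: ",
         paste(groups[sizes < 2], collapse = ", "))
  }
  gs <- group_locus_stats(gm, grouping, groups)
  poly <- colSums(gs$n * gs$p) > 0 &
    colSums(gs$n * gs$p) < colSums(gs$n)  # pooled alt frequency in (0, 1)
  # variability assessed on pooled frequencies; monomorphic loci contribute 0
  if (sum(poly) < 2) stop("fewer than two polymorphic loci")
  theta_of <- function(idx) {
    comp <- wc_components(gs$n[idx, , drop = FALSE], gs$p[idx, , drop = FALSE],
                          gs$h[idx, , drop = FALSE])
    num <- sum(comp$a, na.rm = TRUE)
    den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
    if (den == 0) NA_real_ else num / den
  }
  pw <- matrix(0, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in seq((i + 1), length(groups))) {
      pw[i, j] <- pw[j, i] <- theta_of(c(i, j))
    }
  }
  structure(list(pairwise = pw, overall = theta_of(seq_along(groups)),
                 n_loci_used = sum(poly)),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Weir-Cockerham F_ST (overall theta =",
      format(x$overall, digits = 4), ")\n")
  print(round(x$pairwise, 4))
  invisible(x)
}

#' Fixed SNPs between two groups
#'
#' A locus is fixed between groups when one has allele frequency at or above
#' `hi` while the other is strictly below `lo`, on either allele
#' orientation. Loci with an undefined frequency in either group are
#' skipped.
#'
#' @param freqs An [allele_freqs()] table.
#' @param g1,g2 Group names.
#' @param hi,lo Frequency thresholds (`>= hi`, strict `< lo`).
#' @return Character vector of fixed locus ids.
#' @export
fixed_snps <- function(freqs, g1, g2, hi = 0.98, lo = 0.02) {
  if (!all(c(g1, g2) %in% rownames(freqs$p))) {
    stop("group(s) not present in frequency table")
  }
  p1 <- freqs$p[g1, ]
  p2 <- freqs$p[g2, ]
  ok <- !is.na(p1) & !is.na(p2)
  if (any(!ok)) {
    message("fixed_snps: skipping ", sum(!ok),
            " locus/loci with undefined frequency")
  }
  rule <- function(a, b) (a >= hi & b < lo) | (b >= hi & a < lo)
  fixed <- ok & (rule(p1, p2) | rule(1 - p1, 1 - p2))
  freqs$loci[which(fixed)]
}

#' Genotype concordance between two matrices
#'
#' Fraction of matching calls over the shared individuals-by-loci
#' intersection; cells missing in either matrix are excluded from the
#' denominator.
#'
#' @param gm1,gm2 Two [genotype_matrix()] objects.
#' @return Fraction in `[0, 1]`.
#' @export
genotype_concordance <- function(gm1, gm2) {
  ids <- intersect(individuals(gm1), individuals(gm2))
  loc <- intersect(gm1$loci$id, gm2$loci$id)
  if (!length(ids) || !length(loc)) {
    stop("no shared individuals x loci between matrices")
  }
  a <- gm1[ids, loc]$calls
  b <- gm2[ids, loc]$calls
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop("no jointly called genotypes")
  sum(a[both] == b[both]) / sum(both)
}
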