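# shared fixture builders

make_loci <- function(n, chrom = sprintf("chr%d", seq_len(n)), pos = rep(100L, n)) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref = rep("A", n), alt = rep("C", n),
             id = sprintf("L%03d", seq_len(n)), stringsAsFactors = FALSE)
}

make_gm <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  n <- ncol(calls)
  if (is.null(chrom)) chrom <- sprintf("chr%d", seq_len(n))
  if (is.null(pos)) pos <- rep(100L, n)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ind%02d", seq_len(nrow(calls)))
  }
  genotype_matrix(calls, make_loci(n, chrom, pos))
}

random_gm <- function(n_ind, n_loci, seed = 1, miss_rate = 0,
                      chrom = NULL, pos = NULL) {
  withr::with_seed(seed, {
    p <- stats::runif(n_loci, 0.05, 0.95)
    calls <- matrix(stats::rbinom(n_ind * n_loci, 2, rep(p, each = n_ind)),
                    n_ind, n_loci)
    if (miss_rate > 0) {
      calls[matrix(stats::runif(length(calls)) < miss_rate,
                   n_ind, n_loci)] <- NA_integer_
    }
    rownames(calls) <- sprintf("ind%02d", seq_len(n_ind))
    make_gm(calls, chrom = chrom, pos = pos)
  })
}

make_popmap <- function(ids, site = "siteA", group = "DLB",
                        is_reference = FALSE) {
  data.frame(individual = ids,
             site = rep_len(site, length(ids)),
             group = rep_len(group, length(ids)),
             is_reference = rep_len(is_reference, length(ids)),
             stringsAsFactors = FALSE)
}

# a small reference panel with fully lineage-diagnostic loci: patterns
# (1,0,0), (0,1,0), (0,0,1) repeated; `contrast` < 1 softens the patterns
# (e.g. 0.9 vs 0.1) for fixtures that need estimation noise
make_fixed_ref <- function(n_per_pattern = 20, eps = 1e-6, contrast = 1) {
  hi <- (1 + contrast) / 2
  pat <- rbind(DLB = c(hi, 1 - hi, 1 - hi),
               NLB = c(1 - hi, hi, 1 - hi),
               FLB = c(1 - hi, 1 - hi, hi))
  freq <- pat[, rep(1:3, each = n_per_pattern), drop = FALSE]
  freq <- pmin(pmax(freq, eps), 1 - eps)
  n <- ncol(freq)
  colnames(freq) <- sprintf("L%03d", seq_len(n))
  structure(list(freq = freq, loci = make_loci(n),
                 n_ref = c(DLB = 20L, NLB = 20L, FLB = 20L)),
            class = "ref_panel")
}
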