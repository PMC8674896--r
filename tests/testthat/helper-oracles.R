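# independent brute-force oracles, written as literal scalar translations of
# the defining formulas, deliberately separate from the package's vectorized
# implementations

# Weir & Cockerham (1984) theta by per-locus scalar loops
oracle_wc_fst <- function(gm, grouping) {
  groups <- unique(grouping)
  num <- den <- 0
  for (l in seq_len(ncol(gm$calls))) {
    n <- p <- h <- numeric(0)
    for (g in groups) {
      sub <- gm$calls[grouping == g, l]
      sub <- sub[!is.na(sub)]
      if (length(sub) >= 2) {
        n <- c(n, length(sub))
        p <- c(p, sum(sub) / (2 * length(sub)))
        h <- c(h, mean(sub == 1))
      }
    }
    r <- length(n)
    if (r < 2) next
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Nei-Chesser per-group means by scalar loops
oracle_diversity <- function(calls) {
  hos <- hss <- numeric(0)
  for (l in seq_len(ncol(calls))) {
    g <- calls[, l]
    g <- g[!is.na(g)]
    n <- length(g)
    if (n < 2) next
    ho <- mean(g == 1)
    pfreq <- sum(g) / (2 * n)
    hs <- n / (n - 1) * (1 - pfreq^2 - (1 - pfreq)^2 - ho / (2 * n))
    hos <- c(hos, ho)
    hss <- c(hss, hs)
  }
  list(Ho = mean(hos), He = mean(hss), Fis = 1 - mean(hos) / mean(hss))
}

# exact HWE p-value by full enumeration of the conditional distribution
# P(n_AB | n, minor allele count) via log-multinomial probabilities
oracle_hwe_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (rare == 0 || n == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    n_r <- (rare - h) / 2
    n_c <- n - n_r - h
    lgamma(n + 1) - lgamma(n_r + 1) - lgamma(h + 1) - lgamma(n_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# fixed-SNP rule as a set comprehension over loci
oracle_fixed_set <- function(p1, p2, ids, hi = 0.98, lo = 0.02) {
  out <- character(0)
  for (l in seq_along(ids)) {
    a <- p1[l]; b <- p2[l]
    if (is.na(a) || is.na(b)) next
    direct <- (a >= hi && b < lo) || (b >= hi && a < lo)
    flipped <- ((1 - a) >= hi && (1 - b) < lo) || ((1 - b) >= hi && (1 - a) < lo)
    if (direct || flipped) out <- c(out, ids[l])
  }
  out
}

# all-pairs r^2 check: TRUE when no retained pair on a chromosome exceeds
# the threshold and no pair sits within the window
oracle_ld_ok <- function(gm, r2_max = 0.2, window_bp = 1000) {
  loci <- gm$loci
  for (i in seq_len(nrow(loci) - 1)) {
    for (j in seq(i + 1, nrow(loci))) {
      if (loci$chrom[i] != loci$chrom[j]) next
      if (abs(loci$pos[i] - loci$pos[j]) < window_bp) return(FALSE)
      r <- suppressWarnings(stats::cor(gm$calls[, i], gm$calls[, j],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) return(FALSE)
    }
  }
  TRUE
}

# grid search of the 3-simplex for the supervised admixture likelihood
oracle_grid_q <- function(g, P, step = 0.001) {
  q1 <- seq(0, 1, by = step)
  best <- c(NA, NA, NA)
  best_ll <- -Inf
  for (a in q1) {
    b <- seq(0, 1 - a, by = step)
    for (bb in b) {
      cc <- 1 - a - bb
      pi <- a * P[1, ] + bb * P[2, ] + cc * P[3, ]
      pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
      ll <- sum(g * log(pi) + (2 - g) * log(1 - pi), na.rm = TRUE)
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(a, bb, cc)
      }
    }
  }
  list(q = best, ll = best_ll)
}

# independent greedy LD pruning: scalar loop over position-sorted loci per
# chromosome, keeping a locus only if it clears the window from the last
# kept locus and the r^2 bound against every kept locus
oracle_ld_keep <- function(gm, r2_max = 0.2, window_bp = 1000) {
  loci <- gm$loci
  kept_ids <- character(0)
  for (chr in sort(unique(loci$chrom))) {
    rows <- which(loci$chrom == chr)
    rows <- rows[order(loci$pos[rows])]
    kept <- integer(0)
    for (l in rows) {
      ok <- TRUE
      if (length(kept) && loci$pos[l] - loci$pos[kept[length(kept)]] < window_bp) {
        ok <- FALSE
      }
      if (ok && length(kept)) {
        for (k in kept) {
          r <- suppressWarnings(stats::cor(gm$calls[, l], gm$calls[, k],
                                           use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_max) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) kept <- c(kept, l)
    }
    kept_ids <- c(kept_ids, loci$id[kept])
  }
  kept_ids
}
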