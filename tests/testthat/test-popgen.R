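test_that("allele frequencies are per-group alt-allele tallies", {
  gm <- make_gm(cbind(c(1L, 0L, 2L, NA), c(NA, NA, 0L, 1L)))
  fr <- allele_freqs(gm, c("g1", "g1", "g2", "g2"))
  expect_equal(fr$p["g1", "L001"], 0.25)     # one het of two diploids
  expect_equal(fr$p["g2", "L001"], 1)        # dosage 2 called, NA dropped
  expect_true(is.na(fr$p["g1", "L002"]))     # no called alleles
  expect_equal(fr$n_alleles["g1", "L002"], 0L)
  expect_error(allele_freqs(gm, c("g1", "g1")), "length")

  # random fixture against a scalar tally
  gm2 <- random_gm(12, 30, seed = 2, miss_rate = 0.2)
  grp <- rep(c("a", "b", "c"), each = 4)
  fr2 <- allele_freqs(gm2, grp)
  for (g in c("a", "b", "c")) {
    for (l in c(1, 17, 30)) {
      x <- gm2$calls[grp == g, l]
      x <- x[!is.na(x)]
      expect_equal(fr2$p[g, l], if (length(x)) sum(x) / (2 * length(x)) else NA_real_)
    }
  }
})

test_that("diversity reproduces Nei-Chesser estimators and flags degenerate input", {
  # every individual heterozygous at one locus: Ho = 1
  gm_het <- make_gm(matrix(1L, 6, 1))
  d <- diversity(gm_het, rep("g", 6), min_n = 2)
  expect_equal(d$Ho, 1)
  # identical homozygotes: Ho = He = 0, Fis undefined
  gm_hom <- make_gm(matrix(2L, 6, 2))
  d0 <- diversity(gm_hom, rep("g", 6), min_n = 2)
  expect_equal(d0$Ho, 0)
  expect_equal(d0$He, 0)
  expect_true(is.na(d0$Fis))
  # 20-individual fixture vs formula-by-hand oracle
  gm20 <- random_gm(20, 50, seed = 9, miss_rate = 0.05)
  d20 <- diversity(gm20, rep("g", 20), min_n = 5)
  or <- oracle_diversity(gm20$calls)
  expect_equal(d20$Ho, or$Ho, tolerance = 1e-12)
  expect_equal(d20$He, or$He, tolerance = 1e-12)
  expect_equal(d20$Fis, or$Fis, tolerance = 1e-12)
})

test_that("Fis bootstrap CI is seed-stable, degenerate on one locus, and covers the truth", {
  gm1 <- make_gm(matrix(c(0L, 1L, 1L, 2L, 0L, 1L), 6, 1))
  ci <- fis_bootstrap_ci(gm1, rep("g", 6), "g", n_boot = 50, seed = 1)
  expect_equal(ci[["lo"]], ci[["hi"]])

  gm2 <- random_gm(15, 40, seed = 3)
  ci_a <- fis_bootstrap_ci(gm2, rep("g", 15), "g", n_boot = 200, seed = 42)
  ci_b <- fis_bootstrap_ci(gm2, rep("g", 15), "g", n_boot = 200, seed = 42)
  expect_identical(ci_a, ci_b)
  expect_lte(ci_a[["lo"]], ci_a[["hi"]])

  # coverage: genotypes drawn with true inbreeding f = 0.15
  f_true <- 0.15
  cover <- withr::with_seed(99, {
    vapply(1:60, function(r) {
      p <- stats::runif(250, 0.2, 0.8)
      probs <- rbind(p^2 + f_true * p * (1 - p),
                     2 * p * (1 - p) * (1 - f_true),
                     (1 - p)^2 + f_true * p * (1 - p))
      calls <- sapply(seq_along(p), function(l) {
        sample(c(2L, 1L, 0L), 40, replace = TRUE, prob = probs[, l])
      })
      ci <- fis_bootstrap_ci(make_gm(calls), rep("g", 40), "g",
                             n_boot = 200, seed = r)
      ci[["lo"]] <= f_true && f_true <= ci[["hi"]]
    }, logical(1))
  })
  expect_gte(mean(cover), 0.85)
})

test_that("Weir-Cockerham theta handles fixed, null and toy cases", {
  # opposite fixation at every locus: b = c = 0, theta = 1
  gm_fix <- make_gm(rbind(matrix(0L, 5, 10), matrix(2L, 5, 10)))
  fst <- wc_fst(gm_fix, rep(c("a", "b"), each = 5))
  expect_equal(fst$pairwise["a", "b"], 1)
  expect_equal(diag(fst$pairwise), c(a = 0, b = 0))

  # one panmictic population split at random: theta near zero
  gm_null <- random_gm(100, 1000, seed = 21)
  fst0 <- wc_fst(gm_null, rep(c("a", "b"), 50))
  expect_lt(abs(fst0$pairwise["a", "b"]), 0.05)

  expect_error(wc_fst(gm_fix, rep("a", 10)), "two groups")
  expect_error(wc_fst(make_gm(matrix(2L, 4, 2)), c("a", "a", "b", "b")),
               "polymorphic")
})

test_that("theta equals the brute-force variance-component oracle and is flip-invariant", {
  gm <- random_gm(9, 25, seed = 31, miss_rate = 0.1)
  grp <- rep(c("a", "b", "c"), each = 3)
  fst <- wc_fst(gm, grp)
  expect_equal(fst$overall, oracle_wc_fst(gm, grp), tolerance = 1e-10)
  sub <- grp %in% c("a", "b")
  expect_equal(fst$pairwise["a", "b"],
               oracle_wc_fst(gm[sub, ], grp[sub]), tolerance = 1e-10)
  # swapping ref/alt labels at arbitrary loci leaves theta unchanged
  flipped <- gm
  flip <- c(1, 5, 12, 20)
  flipped$calls[, flip] <- 2L - flipped$calls[, flip]
  fst_f <- wc_fst(flipped, grp)
  expect_equal(fst_f$overall, fst$overall, tolerance = 1e-12)
  expect_equal(fst_f$pairwise, fst$pairwise, tolerance = 1e-12)
})

test_that("fixed-SNP rule applies strict boundaries symmetrically", {
  p <- rbind(g1 = c(0.99, 0.98, 0.01, 0.5, NA),
             g2 = c(0.01, 0.02, 0.995, 0.5, 0.1))
  fr <- structure(list(p = p,
                       n_alleles = matrix(40L, 2, 5,
                                          dimnames = dimnames(p)),
                       loci = sprintf("L%d", 1:5)),
                  class = "allele_freq_table")
  colnames(fr$p) <- fr$loci
  fixed <- suppressMessages(fixed_snps(fr, "g1", "g2"))
  expect_setequal(fixed, c("L1", "L3"))  # L2 fails the strict < 0.02
  expect_setequal(suppressMessages(fixed_snps(fr, "g2", "g1")), fixed)

  # random table vs set-comprehension oracle
  set.seed(8)
  pr <- matrix(stats::runif(400), 2, 200,
               dimnames = list(c("x", "y"), sprintf("M%d", 1:200)))
  pr[, 1:40] <- rbind(stats::runif(40, 0.97, 1), stats::runif(40, 0, 0.03))
  fr2 <- structure(list(p = pr, n_alleles = pr * 0 + 40,
                        loci = colnames(pr)), class = "allele_freq_table")
  expect_setequal(fixed_snps(fr2, "x", "y"),
                  oracle_fixed_set(pr["x", ], pr["y", ], colnames(pr)))
})

test_that("genotype concordance excludes missing cells from the denominator", {
  gm <- random_gm(10, 10, seed = 12)
  expect_equal(genotype_concordance(gm, gm), 1)
  gm2 <- gm
  gm2$calls[1, 1] <- (gm2$calls[1, 1] + 1L) %% 3L
  expect_equal(genotype_concordance(gm, gm2), 99 / 100)
  gm3 <- gm
  gm3$calls[1, ] <- NA_integer_   # whole first row uncalled in one run
  expect_equal(genotype_concordance(gm, gm3), 1)
  gm4 <- make_gm(matrix(1L, 2, 2, dimnames = list(c("other1", "other2"), NULL)))
  gm4$loci$id <- c("Z001", "Z002")
  colnames(gm4$calls) <- gm4$loci$id
  expect_error(genotype_concordance(gm, gm4), "shared")
})
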