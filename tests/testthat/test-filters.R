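test_that("MAF/MAC filter applies strict thresholds over called genotypes", {
  # 50 diploids: locus 1 has a single het (MAF 0.01), locus 2 sits exactly
  # at MAF 0.05 (5/100), locus 3 is comfortably polymorphic
  calls <- cbind(c(1L, rep(0L, 49)),
                 c(rep(1L, 5), rep(0L, 45)),
                 rep(c(0L, 1L, 2L), length.out = 50))
  gm <- make_gm(calls)
  out <- filter_maf_mac(gm, maf = 0.05, mac = 4)
  expect_equal(out$gm$loci$id, "L003")
  expect_equal(out$report$n_removed, 2)

  # a 6/100 locus clears MAF but its count of 6 must also clear mac > 4
  calls2 <- cbind(c(rep(1L, 6), rep(0L, 44)))
  expect_warning(out2 <- filter_maf_mac(make_gm(calls2), mac = 6),
                 "all loci removed")
  expect_equal(n_loci(out2$gm), 0L)
})

test_that("MAF/MAC filter agrees with a brute-force allele tally", {
  gm <- random_gm(30, 200, seed = 7, miss_rate = 0.1)
  out <- filter_maf_mac(gm, maf = 0.05, mac = 4)
  keep <- vapply(seq_len(200), function(l) {
    g <- gm$calls[, l]
    g <- g[!is.na(g)]
    alt <- sum(g)
    minor <- min(alt, 2 * length(g) - alt)
    (minor / (2 * length(g)) > 0.05) && (minor > 4)
  }, logical(1))
  expect_identical(out$gm$loci$id, gm$loci$id[keep])
})

test_that("group-call and missingness filter honours both rules", {
  ids <- sprintf("i%02d", 1:16)
  pm <- data.frame(individual = ids,
                   site = rep(c("s1", "s2", "s3", "s4"), each = 4),
                   group = rep(c("DLB", "NLB", "FLB", "ILB"), each = 4),
                   is_reference = FALSE)
  # locus 1: missing in all FLB and ILB individuals -> only 2 groups called
  l1 <- c(rep(1L, 8), rep(NA_integer_, 8))
  # locus 2: fully called
  l2 <- rep(1L, 16)
  # locus 3: called in all groups but 25% missing overall
  l3 <- c(rep(NA_integer_, 4), rep(1L, 12))
  l3[5] <- NA_integer_
  gm <- make_gm(cbind(l1, l2, l3))
  rownames(gm$calls) <- ids
  gm <- genotype_matrix(gm$calls, gm$loci, ids)
  out <- filter_missing_groups(gm, pm, max_missing = 0.15, min_groups = 3)
  expect_equal(out$gm$loci$id, "L002")
  expect_equal(out$report$n_removed, 2)
  pm_bad <- pm
  pm_bad$group[pm_bad$group == "ILB"] <- "DLB"
  expect_error(filter_missing_groups(gm, pm_bad, min_groups = 3), "absent")
})

test_that("HWE exact test matches enumeration oracle across genotype configurations", {
  cases <- expand.grid(het = 0:12, hom1 = 0:6, hom2 = 0:6)
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      hwe_exact_p(cases$het[i], cases$hom1[i], cases$hom2[i]),
      oracle_hwe_p(cases$het[i], cases$hom1[i], cases$hom2[i]),
      tolerance = 1e-10,
      info = paste(cases[i, ], collapse = "/"))
  }
})

test_that("HWE filter removes loci failing in two or more sites only", {
  ids <- sprintf("i%02d", 1:20)
  pm <- data.frame(individual = ids, site = rep(c("s1", "s2"), each = 10),
                   group = rep(c("DLB", "NLB"), each = 10),
                   is_reference = FALSE)
  # locus 1: all heterozygous in both sites (exact-test p < 0.05 twice)
  l1 <- rep(1L, 20)
  # locus 2: exact HW proportions (p = 0.5) in both sites
  l2 <- rep(c(0L, 1L, 1L, 2L, 1L, 0L, 1L, 1L, 2L, 1L), 2)
  # locus 3: all het in site 1 only; site 2 in HW proportions
  l3 <- c(rep(1L, 10), c(0L, 1L, 1L, 2L, 1L, 0L, 1L, 1L, 2L, 1L))
  gm <- genotype_matrix(cbind(l1, l2, l3), make_loci(3), ids)
  expect_lt(hwe_exact_p(10, 0, 0), 0.05)
  out <- filter_hwe(gm, pm, p_cut = 0.05, min_sites = 2)
  expect_setequal(out$gm$loci$id, c("L002", "L003"))
})

test_that("maximum-heterozygosity filter uses called genotypes", {
  l1 <- c(rep(1L, 8), 0L, 2L)          # 80% het
  l2 <- c(rep(0L, 5), rep(2L, 5))      # 0% het
  l3 <- c(rep(1L, 7), NA, 0L, 2L)      # 7/9 called het > 0.7
  out <- filter_max_het(make_gm(cbind(l1, l2, l3)), max_het = 0.7)
  expect_equal(out$gm$loci$id, "L002")
})

test_that("LD pruning enforces the window and r2 rules greedily by position", {
  # two SNPs 500 bp apart on one chromosome: only the first survives
  gm <- random_gm(40, 2, seed = 3, chrom = c("chr1", "chr1"),
                  pos = c(1000L, 1500L))
  expect_equal(ld_prune(gm)$gm$loci$id, "L001")

  # duplicated genotype columns 10 kb apart: r2 = 1, first kept
  base <- random_gm(40, 1, seed = 4)$calls
  gm2 <- make_gm(cbind(base, base), chrom = c("chr1", "chr1"),
                 pos = c(1000L, 11000L))
  expect_equal(ld_prune(gm2)$gm$loci$id, "L001")

  # independent loci >= 1 kb apart should essentially all survive, and the
  # retained set must satisfy the all-pairs oracle
  gm3 <- random_gm(60, 40, seed = 5, chrom = rep("chr1", 40),
                   pos = seq(1000L, by = 2000L, length.out = 40))
  out <- ld_prune(gm3)
  expect_gt(n_loci(out$gm), 30)
  expect_true(oracle_ld_ok(out$gm))
})

test_that("each filter is idempotent and reports attribute every removal", {
  gm <- random_gm(24, 120, seed = 11, miss_rate = 0.08,
                  chrom = rep(sprintf("c%d", 1:40), 3),
                  pos = rep(c(100L, 5000L, 9000L), each = 40))
  pm <- data.frame(individual = individuals(gm),
                   site = rep(c("s1", "s2"), 12),
                   group = rep(c("DLB", "NLB", "FLB", "ILB"), 6),
                   is_reference = FALSE)
  res <- filter_snps(gm, pm)
  expect_equal(sum(res$report$n_removed), n_loci(gm) - n_loci(res$gm))
  # a second pass through each filter must be a no-op
  again <- filter_snps(res$gm, pm)
  expect_identical(again$gm$calls, res$gm$calls)
  expect_true(all(again$report$n_removed == 0))
})
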