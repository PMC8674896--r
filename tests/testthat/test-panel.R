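freq_table <- function(p, ids = sprintf("L%03d", seq_len(ncol(p)))) {
  colnames(p) <- ids
  structure(list(p = p, n_alleles = p * 0 + 40L, loci = ids),
            class = "allele_freq_table")
}

test_that("diagnostic-SNP rule needs one high and one low lineage", {
  p <- rbind(DLB = c(0.95, 0.95, 0.5, 0.05, NA),
             NLB = c(0.05, 0.95, 0.95, 0.5, 0.5),
             FLB = c(0.50, 0.95, 0.05, 0.5, 0.5))
  fr <- freq_table(p)
  got <- suppressMessages(find_diagnostic_snps(fr))
  # locus 1: DLB high vs NLB low; locus 2: all high -> no contrast;
  # locus 3: NLB high vs FLB low; locus 4: nothing extreme enough;
  # locus 5: undefined DLB frequency -> skipped
  expect_setequal(got, c("L001", "L003"))

  # random table against a set-comprehension oracle
  set.seed(14)
  pr <- matrix(runif(3 * 150), 3, 150,
               dimnames = list(c("DLB", "NLB", "FLB"), NULL))
  fr2 <- freq_table(pr)
  want <- character(0)
  for (l in seq_len(150)) {
    hit <- FALSE
    for (pair in list(1:2, c(1, 3), 2:3)) {
      a <- pr[pair[1], l]; b <- pr[pair[2], l]
      if ((a > 0.9 && b < 0.1) || (b > 0.9 && a < 0.1) ||
          ((1 - a) > 0.9 && (1 - b) < 0.1) || ((1 - b) > 0.9 && (1 - a) < 0.1)) {
        hit <- TRUE
      }
    }
    if (hit) want <- c(want, fr2$loci[l])
  }
  expect_setequal(find_diagnostic_snps(fr2), want)
})

test_that("top-loading selection unions per-PC quantile sets", {
  set.seed(4)
  loadings <- matrix(rnorm(200), 100, 2,
                     dimnames = list(sprintf("L%03d", 1:100), NULL))
  # disjoint top-10 sets on each PC -> 20 loci
  loadings[1:10, 1] <- 5 + runif(10)
  loadings[11:20, 2] <- -5 - runif(10)
  expect_length(top_loading_snps(loadings, quantile = 0.9), 20)
  # identical top-10 sets -> 10 loci
  l2 <- loadings
  l2[11:20, 2] <- 0
  l2[1:10, 2] <- 7 + runif(10)
  expect_length(top_loading_snps(l2, quantile = 0.9), 10)
  expect_error(top_loading_snps(loadings, quantile = 1.2), "quantile")
})

test_that("subset scoring counts individuals deviating from full-data Q", {
  ref <- make_fixed_ref(10)
  set.seed(21)
  calls <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30,
                  dimnames = list(sprintf("i%02d", 1:20), NULL))
  gm <- genotype_matrix(calls, ref$loci)
  q_full <- estimate_q_supervised(gm, ref)
  s_full <- score_subset(gm$loci$id, gm, ref, q_full)
  expect_equal(s_full$n_discordant, 0)
  s_vac <- score_subset(gm$loci$id[1:5], gm, ref, q_full, delta = 1)
  expect_equal(s_vac$n_discordant, 0)
  # a single locus cannot reproduce three-way ancestry for most individuals
  s_one <- score_subset(gm$loci$id[1], gm, ref, q_full, delta = 0.05)
  expect_gt(s_one$n_discordant, 10)
  expect_error(score_subset("nope", gm, ref, q_full), "not present")
})

test_that("iterative search is deterministic, nested in candidates, and beats random subsets", {
  # 15 diagnostic loci plus 30 uninformative ones, so subset quality varies
  ref <- make_fixed_ref(5)
  ref$freq <- cbind(ref$freq,
                    matrix(0.5, 3, 30,
                           dimnames = list(rownames(ref$freq),
                                           sprintf("U%03d", 1:30))))
  ref$loci <- make_loci(45)
  ref$loci$id <- colnames(ref$freq)
  set.seed(31)
  # cohort with genuinely admixed individuals
  qs <- matrix(rgamma(25 * 3, 1), 25, 3)
  qs <- qs / rowSums(qs)
  pi <- qs %*% ref$freq
  calls <- matrix(rbinom(length(pi), 2, pi), 25, 45,
                  dimnames = list(sprintf("i%02d", 1:25), NULL))
  gm <- genotype_matrix(calls, ref$loci)
  q_full <- estimate_q_supervised(gm, ref)
  pan1 <- iterative_search(gm$loci$id, gm, ref, q_full, n_iter = 40,
                           size_range = c(20, 30), target_panel = 25, seed = 7)
  pan2 <- iterative_search(gm$loci$id, gm, ref, q_full, n_iter = 40,
                           size_range = c(20, 30), target_panel = 25, seed = 7)
  expect_identical(pan1$loci, pan2$loci)
  expect_length(pan1$loci, 25)
  expect_true(all(pan1$loci %in% gm$loci$id))
  expect_false(anyDuplicated(pan1$loci) > 0)

  # panel discordance no worse than the median random panel of equal size
  panel_score <- score_subset(pan1$loci, gm, ref, q_full)$n_discordant
  rand_scores <- withr::with_seed(99, {
    vapply(1:100, function(i) {
      score_subset(sample(gm$loci$id, 25), gm, ref, q_full)$n_discordant
    }, numeric(1))
  })
  expect_lte(panel_score, stats::median(rand_scores))

  expect_error(iterative_search(gm$loci$id[1:10], gm, ref, q_full,
                                size_range = c(20, 30)),
               "fewer candidates")
  expect_error(iterative_search(gm$loci$id, gm, ref, q_full, n_iter = 5,
                                size_range = c(20, 30), target_panel = 100),
               "target_panel")
})

test_that("allele-counting ancestry fractions match a tally oracle", {
  ref <- make_fixed_ref(10)
  two_panel <- ref$loci$id[11:30]  # NLB- and FLB-diagnostic loci
  calls <- rbind(
    allF = c(rep(0L, 10), rep(0L, 10), rep(2L, 10)),  # homozygous FLB alleles
    f1 = c(rep(0L, 10), rep(1L, 10), rep(1L, 10)),    # het at every panel locus
    miss = rep(NA_integer_, 30)
  )
  gm <- genotype_matrix(calls, ref$loci)
  expect_warning(
    frac <- allele_count_ancestry(gm, two_panel, ref,
                                  lineage = "FLB", other = "NLB"),
    "missing")
  expect_equal(unname(frac["allF"]), 1)
  expect_equal(unname(frac["f1"]), 0.5)
  expect_true(is.na(frac["miss"]))

  set.seed(77)
  calls2 <- matrix(rbinom(5 * 30, 2, 0.5), 5, 30,
                   dimnames = list(sprintf("x%d", 1:5), NULL))
  gm2 <- genotype_matrix(calls2, ref$loci)
  frac2 <- allele_count_ancestry(gm2, two_panel, ref, "FLB", "NLB")
  for (i in 1:5) {
    cnt <- 0; tot <- 0
    for (l in two_panel) {
      g <- gm2$calls[i, l]
      if (is.na(g)) next
      focal_alt <- ref$freq["FLB", l] > ref$freq["NLB", l]
      cnt <- cnt + if (focal_alt) g else 2 - g
      tot <- tot + 2
    }
    expect_equal(unname(frac2[i]), cnt / tot)
  }
})
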