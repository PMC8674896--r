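test_that("reference panel frequencies come from flagged references only, clamped", {
  calls <- rbind(ref1 = c(2L, 0L, 1L), ref2 = c(2L, 0L, 1L),
                 test1 = c(0L, 2L, 0L))
  gm <- make_gm(calls)
  pm <- data.frame(individual = rownames(calls),
                   site = "s", group = c("DLB", "DLB", "ILB"),
                   is_reference = c(TRUE, TRUE, FALSE))
  pm <- rbind(pm, data.frame(individual = "x", site = "s", group = "NLB",
                             is_reference = TRUE),
              data.frame(individual = "y", site = "s", group = "FLB",
                         is_reference = TRUE))
  gm2 <- make_gm(rbind(calls, x = c(1L, 1L, 1L), y = c(0L, 1L, 2L)))
  ref <- build_ref_panel(gm2, pm)
  expect_equal(ref$freq["DLB", 1], 1 - 1e-6)   # all alt homozygous, clamped
  expect_equal(ref$freq["DLB", 2], 1e-6)
  expect_equal(ref$freq["DLB", 3], 0.5)        # two hets
  expect_equal(ref$freq["NLB", 1], 0.5)        # single het reference
  pm_noref <- pm
  pm_noref$is_reference[pm_noref$group == "FLB"] <- FALSE
  expect_error(build_ref_panel(gm2, pm_noref), "FLB")
})

test_that("supervised EM recovers forced, F1 and grid-search optima", {
  ref <- make_fixed_ref(10)  # 30 loci, patterns fully lineage-diagnostic
  # individual homozygous for the DLB allele everywhere
  calls <- rbind(pureD = c(rep(2L, 10), rep(0L, 20)),
                 f1DN = c(rep(1L, 20), rep(0L, 10)))
  gm <- genotype_matrix(calls, ref$loci)
  q <- estimate_q_supervised(gm, ref)
  expect_true(attr(q, "converged"))
  expect_equal(unclass(q)["pureD", ], c(DLB = 1, NLB = 0, FLB = 0),
               tolerance = 1e-3)
  expect_equal(unclass(q)["f1DN", ], c(DLB = 0.5, NLB = 0.5, FLB = 0),
               tolerance = 1e-3)

  # 3-locus toy against exhaustive simplex grid search
  P <- rbind(c(0.9, 0.2, 0.5), c(0.1, 0.7, 0.5), c(0.4, 0.4, 0.05))
  ref3 <- structure(list(freq = matrix(pmin(pmax(P, 1e-6), 1 - 1e-6), 3, 3,
                                       dimnames = list(c("DLB", "NLB", "FLB"),
                                                       c("L001", "L002", "L003"))),
                         loci = make_loci(3), n_ref = c(1L, 1L, 1L)),
                    class = "ref_panel")
  g <- c(2L, 1L, 0L)
  gm3 <- genotype_matrix(matrix(g, 1, 3, dimnames = list("i1", NULL)),
                         ref3$loci)
  q3 <- estimate_q_supervised(gm3, ref3, tol = 1e-12, max_iter = 20000)
  gr <- oracle_grid_q(g, ref3$freq, step = 0.001)
  expect_lt(max(abs(unclass(q3)[1, ] - gr$q)), 0.005)
})

test_that("supervised estimates are invariant to locus order and allele flips", {
  ref <- make_fixed_ref(8)
  set.seed(5)
  calls <- matrix(rbinom(5 * 24, 2, 0.5), 5, 24,
                  dimnames = list(sprintf("i%d", 1:5), NULL))
  gm <- genotype_matrix(calls, ref$loci)
  q <- estimate_q_supervised(gm, ref)

  perm <- sample(24)
  gm_p <- gm[, perm]
  ref_p <- ref
  ref_p$freq <- ref$freq[, perm]
  ref_p$loci <- ref$loci[perm, ]
  q_p <- estimate_q_supervised(gm_p, ref_p)
  expect_equal(unclass(q_p), unclass(q), tolerance = 1e-9)

  flip <- c(2, 9, 17)
  gm_f <- gm
  gm_f$calls[, flip] <- 2L - gm_f$calls[, flip]
  ref_f <- ref
  ref_f$freq[, flip] <- 1 - ref_f$freq[, flip]
  q_f <- estimate_q_supervised(gm_f, ref_f)
  expect_equal(unclass(q_f), unclass(q), tolerance = 1e-9)
})

test_that("unsupervised clustering: K=1 closed form, planted partitions, nesting", {
  # K = 1: every Q is 1 and the log-likelihood is the binomial likelihood at
  # pooled frequencies
  gm <- random_gm(10, 20, seed = 6)
  q1 <- estimate_q_unsupervised(gm, K = 1)
  expect_true(all(unclass(q1) == 1))
  p_hat <- colMeans(gm$calls) / 2
  p_hat <- pmin(pmax(p_hat, 1e-6), 1 - 1e-6)
  ll_manual <- sum(t(gm$calls) * log(p_hat) + (2 - t(gm$calls)) * log(1 - p_hat))
  expect_equal(attr(q1, "loglik"), ll_manual, tolerance = 1e-6)

  # two perfectly fixed populations are recovered at K = 2
  calls <- rbind(matrix(0L, 8, 30), matrix(2L, 8, 30))
  rownames(calls) <- sprintf("i%02d", 1:16)
  gm2 <- make_gm(calls)
  q2 <- estimate_q_unsupervised(gm2, K = 2, seed = 3)
  m <- unclass(q2)
  # memberships within 0.01 of 0/1 and consistent with the split
  expect_true(all(pmin(m, 1 - m) < 0.01))
  expect_true(all(m[1:8, 1] > 0.99) || all(m[1:8, 2] > 0.99))

  q3 <- estimate_q_unsupervised(gm2, K = 3, seed = 3)
  expect_gte(attr(q3, "loglik"), attr(q2, "loglik") - 1e-3)
  expect_error(estimate_q_unsupervised(gm2, K = 20), "exceeds")
})

test_that("delta-K picks a planted kink and breaks ties to the smallest K", {
  # log-likelihoods with a sharp change of slope at K = 3
  mean_ll <- c(-5000, -4000, -3000, -2950, -2900)
  runs <- expand.grid(K = 1:5, rep = 1:3)
  set.seed(2)
  runs$LL <- mean_ll[runs$K] + rnorm(nrow(runs), sd = 5)
  expect_equal(delta_k(runs)$K, 3)

  # linear decrease: constant second difference, tie broken to smallest K
  runs2 <- expand.grid(K = 1:4, rep = 1:2)
  set.seed(3)
  runs2$LL <- -1000 * runs2$K + rnorm(nrow(runs2), sd = 1e-3)
  # second differences are ~0; any argmax tie resolves to the smallest K
  expect_equal(delta_k(runs2)$K, min(delta_k(runs2)$table$K[
    delta_k(runs2)$table$delta_k == max(delta_k(runs2)$table$delta_k)]))

  expect_error(delta_k(data.frame(K = c(1, 1, 2, 2), rep = c(1, 2, 1, 2),
                                  LL = c(-1, -2, -3, -4))),
               "three consecutive")
  runs3 <- expand.grid(K = 1:3, rep = 1:2)
  runs3$LL <- c(-10, -5, -2, -10, -5, -2)  # K varies fastest in expand.grid
  expect_error(delta_k(runs3), "K = 2")
})

test_that("group-frequency imputation draws binomially and leaves calls untouched", {
  # groups fixed at p = 1 and p = 0
  calls <- rbind(a1 = c(2L, NA), a2 = c(2L, NA),
                 b1 = c(NA, 0L), b2 = c(0L, 0L))
  gm <- make_gm(calls)
  pm <- data.frame(individual = rownames(calls), site = "s",
                   group = c("DLB", "DLB", "NLB", "NLB"),
                   is_reference = FALSE)
  imp <- impute_by_group_freq(gm, pm, seed = 1)
  expect_false(anyNA(imp$calls))
  expect_equal(imp$calls["a2", 1], 2L)   # untouched call
  expect_equal(imp$calls["b1", 1], 0L)   # NLB group fixed ref at locus 1
  expect_equal(unname(imp$calls["a1", 2]), 0L)  # DLB at locus 2: group p = 0

  # imputed mean dosage tracks 2p over many draws
  n <- 10000
  calls2 <- matrix(NA_integer_, n, 1)
  calls2[1:200, 1] <- rbinom(200, 2, 0.3)
  rownames(calls2) <- sprintf("i%05d", seq_len(n))
  gm2 <- make_gm(calls2)
  pm2 <- data.frame(individual = rownames(calls2), site = "s",
                    group = "DLB", is_reference = FALSE)
  imp2 <- impute_by_group_freq(gm2, pm2, seed = 9)
  p_grp <- sum(calls2[1:200, 1]) / 400
  m <- mean(imp2$calls[201:n, 1])
  se <- sqrt(2 * p_grp * (1 - p_grp) / (n - 200))
  expect_lt(abs(m - 2 * p_grp), 3 * se)
})

test_that("PCA separates clusters, satisfies the score identity and matches eigenvalues", {
  calls <- rbind(matrix(0L, 6, 12), matrix(2L, 6, 12))
  rownames(calls) <- sprintf("i%02d", 1:12)
  gm <- make_gm(calls)
  pc <- pca(gm)
  expect_gt(pc$var_frac[1], 0.999)
  expect_true(all(pc$scores[1:6, 1] * pc$scores[7:12, 1] < 0))

  gm2 <- random_gm(8, 5, seed = 13)
  pc2 <- pca(gm2)
  X <- scale(gm2$calls, center = TRUE, scale = FALSE)
  expect_equal(unname(X %*% pc2$loadings), unname(pc2$scores),
               tolerance = 1e-10)
  ev <- eigen(stats::cov(X))$values
  expect_equal(pc2$var_frac, ev / sum(ev), tolerance = 1e-10)

  gm_na <- gm2
  gm_na$calls[1, 1] <- NA_integer_
  expect_error(pca(gm_na), "missing")
})
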