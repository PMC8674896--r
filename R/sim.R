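#' Simulated cohort of genotypes with known history
#'
#' Container for simulated individuals: their genotypes, the generating
#' category label (e.g. `"DLB-FLB F1"`), and the expected ancestry
#' proportions implied by the pedigree.
#'
#' @param gm A [genotype_matrix()].
#' @param category Character vector of truth labels, one per individual.
#' @param expected_q Optional matrix of pedigree-expected ancestry
#'   proportions (individuals x lineages).
#' @return An object of class `sim_cohort`.
#' @export
sim_cohort <- function(gm, category, expected_q = NULL) {
  if (length(category) != n_ind(gm)) {
    stop("one category label per individual is required")
  }
  structure(list(gm = gm, category = as.character(category),
                 expected_q = expected_q),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d individuals x %d loci\n",
              n_ind(x$gm), n_loci(x$gm)))
  print(table(x$category))
  invisible(x)
}

# internal: fresh unique individual ids
sim_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

#' Draw pure individuals from lineage allele frequencies
#'
#' Genotype dosages are independent Binomial(2, p) draws from the lineage's
#' reference frequencies, emulating random mating within the lineage.
#'
#' @param ref A [build_ref_panel()].
#' @param lineage Lineage name present in `ref`.
#' @param n Number of individuals.
#' @param seed Random seed.
#' @param prefix Id prefix.
#' @return A [sim_cohort()].
#' @export
draw_pure <- function(ref, lineage, n, seed = 1, prefix = lineage) {
  if (!lineage %in% rownames(ref$freq)) stop("unknown lineage: ", lineage)
  p <- ref$freq[lineage, ]
  L <- length(p)
  calls <- withr::with_seed(seed, {
    matrix(stats::rbinom(n * L, 2, rep(p, each = n)), n, L)
  })
  rownames(calls) <- sim_ids(prefix, n)
  eq <- matrix(0, n, nrow(ref$freq),
               dimnames = list(rownames(calls), rownames(ref$freq)))
  eq[, lineage] <- 1
  sim_cohort(genotype_matrix(calls, ref$loci), rep(lineage, n), eq)
}

#' Cross two cohorts
#'
#' Each offspring draws one parent from each cohort (with replacement); at
#' every locus each parent transmits one of its two alleles uniformly at
#' random, independently across loci (no linkage). Expected ancestry is the
#' mean of the two parents' expected ancestries.
#'
#' @param cohortA,cohortB Parent [sim_cohort()]s on the same loci.
#' @param n Number of offspring.
#' @param seed Random seed.
#' @param category Truth label for the offspring.
#' @param prefix Id prefix.
#' @return A [sim_cohort()].
#' @export
cross <- function(cohortA, cohortB, n, seed = 1, category = "cross",
                  prefix = "X") {
  if (n_ind(cohortA$gm) == 0 || n_ind(cohortB$gm) == 0) {
    stop("empty parent cohort")
  }
  if (!identical(cohortA$gm$loci$id, cohortB$gm$loci$id)) {
    stop("parent cohorts must share the same loci")
  }
  L <- n_loci(cohortA$gm)
  out <- withr::with_seed(seed, {
    ia <- sample.int(n_ind(cohortA$gm), n, replace = TRUE)
    ib <- sample.int(n_ind(cohortB$gm), n, replace = TRUE)
    ga <- cohortA$gm$calls[ia, , drop = FALSE]
    gb <- cohortB$gm$calls[ib, , drop = FALSE]
    # a parent with dosage g transmits an alt allele with probability g/2
    ta <- matrix(stats::rbinom(n * L, 1, ga / 2), n, L)
    tb <- matrix(stats::rbinom(n * L, 1, gb / 2), n, L)
    list(calls = ta + tb, ia = ia, ib = ib)
  })
  calls <- out$calls
  rownames(calls) <- sim_ids(prefix, n)
  eq <- NULL
  if (!is.null(cohortA$expected_q) && !is.null(cohortB$expected_q)) {
    eq <- (cohortA$expected_q[out$ia, , drop = FALSE] +
             cohortB$expected_q[out$ib, , drop = FALSE]) / 2
    rownames(eq) <- rownames(calls)
  }
  sim_cohort(genotype_matrix(calls, cohortA$gm$loci), rep(category, n), eq)
}

# internal: pool cohorts
rbind_cohorts <- function(cohorts) {
  gm <- genotype_matrix(
    do.call(rbind, lapply(cohorts, function(x) x$gm$calls)),
    cohorts[[1]]$gm$loci
  )
  eq <- do.call(rbind, lapply(cohorts, function(x) x$expected_q))
  sim_cohort(gm, unlist(lapply(cohorts, `[[`, "category")), eq)
}

#' Default simulation design
#'
#' The standard evaluation design: 100 individuals per pure lineage, 50 per
#' pairwise F1, 150 per pairwise pooled F2-F4 (equal thirds), 200 per
#' pairwise backcross (both directions pooled), and 300 triple hybrids
#' (half F1-by-third-lineage crosses, half backcrosses of those triples to
#' a random pure lineage) — 1800 genotypes in total.
#'
#' @param n_pure,n_f1,n_f2f4,n_bx,n_triple Category sizes.
#' @param triple_backcross_frac Fraction of triple hybrids produced as
#'   triple-by-pure backcrosses.
#' @return A `data.frame` design understood by [simulate_design()].
#' @export
default_sim_design <- function(n_pure = 100, n_f1 = 50, n_f2f4 = 150,
                               n_bx = 200, n_triple = 300,
                               triple_backcross_frac = 0.5) {
  data.frame(
    what = c("pure", "f1", "f2f4", "bx", "triple"),
    n = c(n_pure, n_f1, n_f2f4, n_bx, n_triple),
    extra = c(NA, NA, NA, NA, triple_backcross_frac),
    stringsAsFactors = FALSE
  )
}

#' Simulate the full evaluation cohort
#'
#' Builds pure pools by frequency draws, then crosses individuals
#' Mendelian-style: F1 = pure x pure; F2 = F1 x F1, F3 = F2 x F2,
#' F4 = F3 x F3 (pooled and labelled `F2:F4`); BX = F1 x pure in both
#' directions; triple hybrids as F1(i,j) x pure(k) over the three lineage
#' combinations plus backcrosses of those triples to a pure lineage drawn
#' uniformly at random. An optional per-call genotyping error rate flips
#' dosages for robustness experiments.
#'
#' @param design A [default_sim_design()]-style `data.frame`.
#' @param ref A [build_ref_panel()] with three lineages (typically
#'   restricted to panel loci).
#' @param seed Random seed.
#' @param error_rate Per-genotype probability of re-drawing the call
#'   uniformly from \{0, 1, 2\} (0 = error-free).
#' @return A [sim_cohort()] with labels like `"DLB"`, `"DLB-FLB F1"`,
#'   `"DLB-FLB F2:F4"`, `"DLB-FLB BX"`, `"Triple Hybrid"`.
#' @export
simulate_design <- function(design = default_sim_design(), ref, seed = 1,
                            error_rate = 0) {
  lineages <- rownames(ref$freq)
  if (length(lineages) != 3) stop("reference panel must have three lineages")
  getn <- function(w) {
    n <- design$n[design$what == w]
    if (!length(n)) stop("design is missing component: ", w)
    n
  }
  tb_frac <- design$extra[design$what == "triple"]
  if (!length(tb_frac) || is.na(tb_frac)) tb_frac <- 0.5
  # deterministic sub-seeds for every stochastic step
  sub_seed <- local({
    counter <- 0L
    base <- seed %% 100000L
    function() {
      counter <<- counter + 1L
      base * 10000L + counter
    }
  })
  pairs <- utils::combn(3, 2)
  pair_label <- function(i, j) paste(lineages[i], lineages[j], sep = "-")
  pure <- lapply(lineages, function(k) {
    draw_pure(ref, k, getn("pure"), seed = sub_seed(), prefix = k)
  })
  names(pure) <- lineages
  cohorts <- pure
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    lab <- pair_label(i, j)
    f1 <- cross(pure[[i]], pure[[j]], getn("f1"), seed = sub_seed(),
                category = paste(lab, "F1"), prefix = paste0(lab, ".F1"))
    n3 <- getn("f2f4")
    third <- round(n3 / 3)
    f2 <- cross(f1, f1, third, seed = sub_seed(),
                category = paste(lab, "F2:F4"), prefix = paste0(lab, ".F2"))
    f3 <- cross(f2, f2, third, seed = sub_seed(),
                category = paste(lab, "F2:F4"), prefix = paste0(lab, ".F3"))
    f4 <- cross(f3, f3, n3 - 2 * third, seed = sub_seed(),
                category = paste(lab, "F2:F4"), prefix = paste0(lab, ".F4"))
    nbx <- getn("bx")
    half <- floor(nbx / 2)
    bx1 <- cross(f1, pure[[i]], half, seed = sub_seed(),
                 category = paste(lab, "BX"), prefix = paste0(lab, ".BXa"))
    bx2 <- cross(f1, pure[[j]], nbx - half, seed = sub_seed(),
                 category = paste(lab, "BX"), prefix = paste0(lab, ".BXb"))
    cohorts <- c(cohorts, list(f1, f2, f3, f4, bx1, bx2))
  }
  # triple hybrids: for each (i, j | k) combination, F1(i,j) x pure(k),
  # plus backcrosses of those triples to a uniformly chosen pure lineage
  n_tri <- getn("triple")
  n_bx_tri <- round(n_tri * tb_frac)
  n_f1_tri <- n_tri - n_bx_tri
  combos <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  per_combo <- diff(round(seq(0, n_f1_tri, length.out = 4)))
  per_combo_bx <- diff(round(seq(0, n_bx_tri, length.out = 4)))
  for (ci in seq_along(combos)) {
    i <- combos[[ci]][1]; j <- combos[[ci]][2]; k <- combos[[ci]][3]
    f1 <- cross(pure[[i]], pure[[j]], 50, seed = sub_seed(),
                category = "f1.tmp", prefix = paste0("T", ci, ".F1"))
    tri <- cross(f1, pure[[k]], per_combo[ci], seed = sub_seed(),
                 category = "Triple Hybrid", prefix = paste0("TRI", ci))
    cohorts <- c(cohorts, list(tri))
    if (per_combo_bx[ci] > 0) {
      back_lineage <- withr::with_seed(sub_seed(), {
        sample(lineages, per_combo_bx[ci], replace = TRUE)
      })
      for (m in lineages) {
        nm <- sum(back_lineage == m)
        if (nm == 0) next
        tb <- cross(tri, pure[[m]], nm, seed = sub_seed(),
                    category = "Triple Hybrid",
                    prefix = paste0("TRB", ci, m))
        cohorts <- c(cohorts, list(tb))
      }
    }
  }
  out <- rbind_cohorts(cohorts)
  if (error_rate > 0) {
    out$gm <- withr::with_seed(sub_seed(), {
      calls <- out$gm$calls
      flip <- matrix(stats::runif(length(calls)) < error_rate,
                     nrow(calls), ncol(calls)) & !is.na(calls)
      calls[flip] <- sample(0:2, sum(flip), replace = TRUE)
      genotype_matrix(calls, out$gm$loci)
    })
  }
  out
}
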