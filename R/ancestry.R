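#' Ancestry (Q) matrix
#'
#' Individuals-by-K matrix of ancestry proportions on the unit simplex, the
#' point-estimate analogue of STRUCTURE-style membership coefficients.
#'
#' @param m Numeric matrix with row names (individuals) and column names
#'   (ancestry components); each row must sum to 1 within 1e-8.
#' @param loglik Optional total log-likelihood of the fit.
#' @param converged Logical convergence flag.
#' @param n_iter Iterations used.
#' @return An object of class `q_matrix`.
#' @export
q_matrix <- function(m, loglik = NA_real_, converged = NA, n_iter = NA_integer_) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("q_matrix needs individual row names")
  ok <- stats::complete.cases(m)
  if (any(m[ok, ] < -1e-12)) stop("ancestry proportions must be >= 0")
  rs <- rowSums(m[ok, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-8)) stop("Q rows must sum to 1 (within 1e-8)")
  structure(m, class = c("q_matrix", "matrix"),
            loglik = loglik, converged = converged, n_iter = n_iter)
}

unclass_q <- function(q) {
  m <- unclass(q)
  attr(m, "loglik") <- NULL
  attr(m, "converged") <- NULL
  attr(m, "n_iter") <- NULL
  m
}

#' @export
print.q_matrix <- function(x, ...) {
  cat(sprintf("q_matrix: %d individuals x %d ancestry components\n",
              nrow(x), ncol(x)))
  if (!is.na(attr(x, "loglik"))) {
    cat(sprintf("  log-likelihood %.3f (%s, %d iterations)\n",
                attr(x, "loglik"),
                if (isTRUE(attr(x, "converged"))) "converged" else "not converged",
                attr(x, "n_iter")))
  }
  utils::head(round(unclass_q(x), 3)) |> print()
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Build a reference allele-frequency panel
#'
#' Per-lineage alternate-allele frequencies estimated from the flagged
#' reference individuals only, clamped away from 0 and 1 so the admixture
#' likelihood stays finite at fixed loci. Reference frequencies are never
#' updated from test individuals.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Population map; `is_reference` flags the panel anchors.
#' @param lineages Lineage order of the panel.
#' @param eps Clamp width.
#' @return A `ref_panel`: list with `freq` (lineages x loci), `loci`,
#'   `n_ref` (reference individuals per lineage).
#' @export
build_ref_panel <- function(gm, popmap, lineages = LINEAGES, eps = 1e-6) {
  pm <- align_popmap(gm, popmap)
  freq <- matrix(NA_real_, length(lineages), n_loci(gm),
                 dimnames = list(lineages, gm$loci$id))
  n_ref <- integer(length(lineages))
  names(n_ref) <- lineages
  n_undef <- 0L
  for (k in lineages) {
    ref <- pm$is_reference & pm$group == k
    if (!any(ref)) stop("no reference individuals for lineage ", k)
    n_ref[k] <- sum(ref)
    sub <- gm$calls[ref, , drop = FALSE]
    called <- 2 * colSums(!is.na(sub))
    p <- ifelse(called > 0, colSums(sub, na.rm = TRUE) / called, 0.5)
    n_undef <- n_undef + sum(called == 0)
    freq[k, ] <- pmin(pmax(p, eps), 1 - eps)
  }
  if (n_undef > 0) {
    message("build_ref_panel: ", n_undef,
            " lineage-locus cells had no called reference alleles (set to 0.5)")
  }
  structure(list(freq = freq, loci = gm$loci, n_ref = n_ref),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("ref_panel: %d lineages (%s) x %d loci; references: %s\n",
              nrow(x$freq), paste(rownames(x$freq), collapse = ", "),
              ncol(x$freq), paste(x$n_ref, collapse = "/")))
  invisible(x)
}

# internal: total log-likelihood of dosages G (N x L, NA allowed) under
# mixture frequencies pi (N x L)
# internal: precompute alt/ref copy-count matrices with missing calls
# zeroed, so every EM quantity is a dense matrix product
admix_counts <- function(G) {
  G0 <- G
  G0[is.na(G)] <- 0
  G2 <- 2 - G
  G2[is.na(G)] <- 0
  list(alt = G0, ref = G2)
}

admix_loglik_counts <- function(cnt, pi) {
  # guard against float drift pushing pi marginally outside (0, 1)
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  sum(cnt$alt * log(pi)) + sum(cnt$ref * log1p(-pi))
}

admix_loglik <- function(G, pi) {
  admix_loglik_counts(admix_counts(G), pi)
}

# internal: one EM sweep for Q given fixed P. The per-copy cluster
# responsibilities collapse to two N x K matrix products; rows are
# renormalized (EM weights can reach ~1/eps at clamped loci, so the exact
# row-sum identity only holds to ~1e-6 in floats).
em_update_q <- function(cnt, P, Q) {
  pi <- pmin(pmax(Q %*% P, 1e-12), 1 - 1e-12)
  U <- Q * ((cnt$alt / pi) %*% t(P) + (cnt$ref / (1 - pi)) %*% t(1 - P))
  rs <- rowSums(U)
  zero <- rs <= 0
  if (any(zero)) {
    U[zero, ] <- 1 / ncol(Q)
    rs[zero] <- 1
  }
  U / rs
}

#' Supervised maximum-likelihood ancestry estimation
#'
#' Estimates each individual's ancestry proportions `q` under the admixture
#' likelihood `sum_l [ g_l log(pi_l) + (2 - g_l) log(1 - pi_l) ]` with
#' `pi_l = sum_k q_k p_kl`, holding the reference panel frequencies `p`
#' fixed. Optimized by EM; the log-likelihood is non-decreasing, and since
#' it factorizes over individuals each individual's estimate is frozen once
#' its own log-likelihood gain per sweep drops below `tol`. Missing
#' genotypes contribute nothing.
#'
#' @param gm A [genotype_matrix()] whose loci are present in `ref`.
#' @param ref A [build_ref_panel()].
#' @param tol Per-individual convergence tolerance on the log-likelihood
#'   gain.
#' @param max_iter Maximum EM iterations (a warning flags non-convergence).
#' @return A [q_matrix()] with lineages in the panel's order. Individuals
#'   with no called panel genotypes get uniform rows and are flagged via a
#'   warning.
#' @export
estimate_q_supervised <- function(gm, ref, tol = 1e-6, max_iter = 2000) {
  idx <- match(gm$loci$id, ref$loci$id)
  if (anyNA(idx)) stop("genotype loci missing from reference panel")
  P <- ref$freq[, idx, drop = FALSE]
  G <- gm$calls
  storage.mode(G) <- "double"
  K <- nrow(P)
  N <- nrow(G)
  none <- rowSums(!is.na(G)) == 0
  if (any(none)) {
    warning(sum(none), " individual(s) with no called genotypes; Q left uniform")
  }
  cnt <- admix_counts(G)
  Q <- matrix(1 / K, N, K, dimnames = list(rownames(G), rownames(P)))
  # individuals are independent given fixed P, so each row can be frozen as
  # soon as its own log-likelihood gain drops below its share of `tol`
  row_ll <- function(cnta, cntr, pi) {
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
    rowSums(cnta * log(pi)) + rowSums(cntr * log1p(-pi))
  }
  ll_ind <- row_ll(cnt$alt, cnt$ref, Q %*% P)
  tol_i <- tol
  active <- which(!none)
  it <- 0L
  while (it < max_iter && length(active)) {
    it <- it + 1L
    ca <- cnt$alt[active, , drop = FALSE]
    cr <- cnt$ref[active, , drop = FALSE]
    Qa <- em_update_q(list(alt = ca, ref = cr), P,
                      Q[active, , drop = FALSE])
    Q[active, ] <- Qa
    ll_new <- row_ll(ca, cr, Qa %*% P)
    gain <- ll_new - ll_ind[active]
    ll_ind[active] <- ll_new
    active <- active[gain >= tol_i]
  }
  converged <- length(active) == 0
  if (!converged) warning("supervised EM did not converge in ", max_iter,
                          " iterations")
  Q <- Q / rowSums(Q)
  dimnames(Q) <- list(rownames(G), rownames(P))
  q_matrix(Q, loglik = sum(ll_ind), converged = converged, n_iter = it)
}

#' Unsupervised maximum-likelihood clustering (joint Q and P)
#'
#' Block EM on the same admixture likelihood, alternating updates of
#' individual ancestries `Q` and cluster allele frequencies `P`. The best of
#' `n_init` random restarts (by log-likelihood) is returned. Cluster labels
#' are arbitrary; when `ref` is supplied the clusters are matched to its
#' lineages by minimal total squared frequency distance, otherwise they are
#' ordered by the first individual's memberships.
#'
#' @param gm A [genotype_matrix()].
#' @param K Number of clusters (>= 1).
#' @param seed Random seed for the restarts.
#' @param n_init Number of random restarts.
#' @param ref Optional [build_ref_panel()] used only to order cluster labels.
#' @param tol,max_iter EM stopping rule.
#' @return A [q_matrix()]; the fitted cluster frequencies are attached as
#'   attribute `P`.
#' @export
estimate_q_unsupervised <- function(gm, K, seed = 1, n_init = 5, ref = NULL,
                                    tol = 1e-6, max_iter = 2000) {
  if (K < 1) stop("K must be >= 1")
  if (K > n_ind(gm)) stop("K exceeds the number of individuals")
  G <- gm$calls
  storage.mode(G) <- "double"
  N <- nrow(G)
  L <- ncol(G)
  cnt <- admix_counts(G)
  eps <- 1e-6
  if (K == 1) {
    p <- colSums(G, na.rm = TRUE) / pmax(2 * colSums(!is.na(G)), 1)
    p <- pmin(pmax(p, eps), 1 - eps)
    Q <- matrix(1, N, 1, dimnames = list(rownames(G), "K1"))
    return(q_matrix(Q, loglik = admix_loglik(G, Q %*% matrix(p, 1, L)),
                    converged = TRUE, n_iter = 0L))
  }
  run_one <- function() {
    # seed P from randomly chosen individuals' genotypes plus jitter
    pick <- sample.int(N, K)
    P <- (G[pick, , drop = FALSE] / 2)
    P[is.na(P)] <- 0.5
    P <- pmin(pmax(P + stats::runif(K * L, -0.05, 0.05), eps), 1 - eps)
    Q <- matrix(stats::rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    ll_old <- admix_loglik_counts(cnt, Q %*% P)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      pi <- pmin(pmax(Q %*% P, 1e-12), 1 - 1e-12)
      # P update: expected alt / total gene copies attributed to each cluster
      Anum <- t(t(cnt$alt / pi) %*% Q) * P
      Bnum <- t(t(cnt$ref / (1 - pi)) %*% Q) * (1 - P)
      den <- Anum + Bnum
      Pnew <- ifelse(den > 0, Anum / den, P)
      Pnew <- pmin(pmax(Pnew, eps), 1 - eps)
      Q <- em_update_q(cnt, Pnew, Q)
      P <- Pnew
      ll <- admix_loglik_counts(cnt, Q %*% P)
      if (abs(ll - ll_old) < tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(Q = Q, P = P, ll = ll_old, converged = converged, it = it)
  }
  fits <- withr::with_seed(seed, lapply(seq_len(n_init), function(i) run_one()))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  perm <- order_clusters(best$P, best$Q, gm, ref)
  Q <- best$Q[, perm, drop = FALSE]
  P <- best$P[perm, , drop = FALSE]
  labels <- if (!is.null(ref)) rownames(ref$freq)[seq_len(min(K, nrow(ref$freq)))] else NULL
  colnames(Q) <- if (!is.null(labels) && length(labels) == K) labels else paste0("K", seq_len(K))
  rownames(Q) <- rownames(G)
  out <- q_matrix(Q, loglik = best$ll, converged = best$converged,
                  n_iter = best$it)
  attr(out, "P") <- P
  out
}

# internal: resolve label switching; greedy match of cluster frequency
# vectors to reference lineages on L2 distance, else order by the first
# individual's memberships
order_clusters <- function(P, Q, gm, ref) {
  K <- nrow(P)
  if (!is.null(ref)) {
    idx <- match(gm$loci$id, ref$loci$id)
    if (!anyNA(idx) && nrow(ref$freq) >= K) {
      Pref <- ref$freq[, idx, drop = FALSE]
      d <- as.matrix(stats::dist(rbind(Pref, P)))[seq_len(nrow(Pref)),
                                                  nrow(Pref) + seq_len(K),
                                                  drop = FALSE]
      perm <- integer(K)
      taken <- rep(FALSE, K)
      for (r in seq_len(min(nrow(Pref), K))) {
        j <- which.min(ifelse(taken, Inf, d[r, ]))
        perm[r] <- j
        taken[j] <- TRUE
      }
      if (any(perm == 0)) perm[perm == 0] <- which(!taken)
      return(perm)
    }
  }
  order(Q[1, ], decreasing = TRUE)
}

#' Evanno delta-K model choice
#'
#' Given replicate log-likelihoods across consecutive K values, computes
#' `deltaK(K) = mean(|LL(K+1) - 2 LL(K) + LL(K-1)|) / sd(LL(K))` (mean of
#' per-replicate absolute second differences over the replicate-wise sd) and
#' returns the K maximizing it, ties broken toward the smallest K.
#'
#' @param runs `data.frame` with columns `K`, `rep`, `LL`; at least three
#'   consecutive K values with at least two replicates each.
#' @return List with `K` (the chosen value) and `table` of delta-K values.
#' @export
delta_k <- function(runs) {
  if (!all(c("K", "rep", "LL") %in% names(runs))) {
    stop("runs must have columns K, rep, LL")
  }
  ks <- sort(unique(runs$K))
  if (length(ks) < 3 || any(diff(ks) != 1)) {
    stop("need at least three consecutive K values")
  }
  reps <- sort(unique(runs$rep))
  if (length(reps) < 2) stop("need at least two replicates per K")
  LL <- matrix(NA_real_, length(reps), length(ks),
               dimnames = list(reps, ks))
  for (i in seq_len(nrow(runs))) {
    LL[as.character(runs$rep[i]), as.character(runs$K[i])] <- runs$LL[i]
  }
  if (anyNA(LL)) stop("missing LL for some (K, replicate) combinations")
  sds <- apply(LL, 2, stats::sd)
  interior <- seq(2, length(ks) - 1)
  if (any(sds[interior] == 0)) {
    stop("zero LL standard deviation at K = ",
         paste(ks[interior][sds[interior] == 0], collapse = ", "))
  }
  dk <- vapply(interior, function(j) {
    mean(abs(LL[, j + 1] - 2 * LL[, j] + LL[, j - 1])) / sds[j]
  }, numeric(1))
  tab <- data.frame(K = ks[interior], delta_k = dk)
  list(K = tab$K[which.max(tab$delta_k)], table = tab)
}

#' Impute missing genotypes from group allele frequencies
#'
#' Each missing call is replaced by a Binomial(2, p) draw where p is the
#' alternate-allele frequency of the individual's group; if that group has
#' no called alleles at the locus, the overall frequency is used (with a
#' message). Non-missing calls are untouched.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Population map defining groups.
#' @param seed Random seed.
#' @return A [genotype_matrix()] with no missing calls.
#' @export
impute_by_group_freq <- function(gm, popmap, seed = 1) {
  pm <- align_popmap(gm, popmap)
  freqs <- allele_freqs(gm, pm$group)
  overall <- colSums(gm$calls, na.rm = TRUE) /
    pmax(2 * colSums(!is.na(gm$calls)), 1)
  calls <- gm$calls
  miss <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(miss) == 0) return(gm)
  p <- freqs$p[cbind(match(pm$group[miss[, 1]], rownames(freqs$p)), miss[, 2])]
  undef <- is.na(p)
  if (any(undef)) {
    message("impute_by_group_freq: ", sum(undef),
            " cell(s) fell back to the overall allele frequency")
    p[undef] <- overall[miss[undef, 2]]
  }
  draws <- withr::with_seed(seed, stats::rbinom(length(p), 2, p))
  calls[miss] <- as.integer(draws)
  genotype_matrix(calls, gm$loci)
}

#' Principal component analysis of a dosage matrix
#'
#' Column-centered (optionally unit-variance scaled) PCA of the
#' individuals-by-loci dosage matrix. Constant loci get zero loadings
#' (reported via a message) rather than breaking the scaling.
#'
#' @param gm A [genotype_matrix()] with no missing calls (impute first).
#' @param scale Scale loci to unit variance.
#' @return List of class `pca_result` with `scores` (individuals x PC),
#'   `loadings` (loci x PC) and `var_frac` (variance fractions).
#' @export
pca <- function(gm, scale = FALSE) {
  X <- gm$calls
  if (anyNA(X)) stop("missing calls present; run impute_by_group_freq() first")
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    message("pca: ", sum(const), " constant locus/loci get zero loadings")
  }
  if (scale) {
    Xs <- sweep(X, 2, colMeans(X), `-`)
    Xs[, !const] <- sweep(Xs[, !const, drop = FALSE], 2, sds[!const], `/`)
    pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  } else {
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  }
  loadings <- pr$rotation
  rownames(loadings) <- gm$loci$id
  structure(list(scores = pr$x, loadings = loadings,
                 var_frac = pr$sdev^2 / sum(pr$sdev^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d x %d; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$var_frac[1],
              if (length(x$var_frac) > 1) 100 * x$var_frac[2] else NA))
  invisible(x)
}
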