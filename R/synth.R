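#' Three-lineage allele-frequency model
#'
#' Describes how synthetic lineage allele frequencies are generated:
#' ancestral frequencies uniform on `anc_range`, per-lineage drift under the
#' Balding-Nichols model (`p_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`),
#' and exact planted fixed differences (frequency 1 vs 0) for a configured
#' number of loci per lineage pair. Defaults plant 46 DLB-NLB, 1275
#' DLB-FLB and 1807 NLB-FLB fixed differences at 8582 loci (scaled
#' proportionally at other sizes).
#'
#' @param n_loci Number of loci.
#' @param F Named drift parameters `c(DLB=, NLB=, FLB=)` in (0, 1); `NULL`
#'   means calibrate with [calibrate_drift()] so realized pairwise
#'   Weir-Cockerham theta hits `fst_targets`.
#' @param fixed_counts Planted fixed-difference counts per pair at
#'   `fixed_ref_loci` loci; scaled to `n_loci`.
#' @param fixed_ref_loci Locus count at which `fixed_counts` is quoted.
#' @param fst_targets Pairwise theta targets used when calibrating.
#' @param anc_range Ancestral frequency range.
#' @param missing_rate Per-call missing probability used by
#'   [generate_study()].
#' @param calibration_seed Seed for the calibration pilot.
#' @return A `lineage_model` list.
#' @export
lineage_model <- function(n_loci = 8582, F = NULL,
                          fixed_counts = c(DLB.NLB = 46, DLB.FLB = 1275,
                                           NLB.FLB = 1807),
                          fixed_ref_loci = 8582,
                          fst_targets = c(DLB.NLB = 0.459, DLB.FLB = 0.677,
                                          NLB.FLB = 0.749),
                          anc_range = c(0.05, 0.95), missing_rate = 0.03,
                          calibration_seed = 20210) {
  scaled <- round(fixed_counts * n_loci / fixed_ref_loci)
  if (sum(scaled) > n_loci) stop("planted fixed counts exceed n_loci")
  if (is.null(F)) {
    F <- calibrate_drift(fst_targets = fst_targets,
                         fixed_frac = fixed_counts / fixed_ref_loci,
                         anc_range = anc_range, seed = calibration_seed)
  }
  if (any(F <= 0 | F >= 1)) stop("drift parameters must lie in (0, 1)")
  structure(list(n_loci = n_loci, F = F, fixed_counts = scaled,
                 anc_range = anc_range, missing_rate = missing_rate),
            class = "lineage_model")
}

#' @export
print.lineage_model <- function(x, ...) {
  cat(sprintf("lineage_model: %d loci; F = %s; planted fixed = %s; %.0f%% missing\n",
              x$n_loci,
              paste(sprintf("%s %.3f", names(x$F), x$F), collapse = ", "),
              paste(sprintf("%s %d", names(x$fixed_counts), x$fixed_counts),
                    collapse = ", "),
              100 * x$missing_rate))
  invisible(x)
}

# internal: raw frequency simulation used by both the generator and the
# calibration pilot. The planted fixed-difference sets are nested, not
# disjoint: every locus fixed between DLB and FLB is also fixed between NLB
# and FLB (an FLB-specific pattern such as 0/0/1), and the remaining
# NLB-FLB fixed loci leave DLB free to drift. This mirrors the observed
# overlap in real three-lineage data, where most DLB-FLB fixed sites are a
# subset of the NLB-FLB fixed sites.
simulate_freq_matrix <- function(n_loci, F, fixed_frac, anc_range) {
  n_fixed <- round(fixed_frac[c("DLB.NLB", "DLB.FLB", "NLB.FLB")] * n_loci)
  n_shared <- min(n_fixed["DLB.FLB"], n_fixed["NLB.FLB"])
  n_nf_only <- n_fixed["NLB.FLB"] - n_shared
  n_df_only <- n_fixed["DLB.FLB"] - n_shared
  n_dn <- n_fixed["DLB.NLB"]
  freq <- matrix(NA_real_, 3, n_loci, dimnames = list(LINEAGES, NULL))
  fixed_pair <- rep(NA_character_, n_loci)
  anc <- stats::runif(n_loci, anc_range[1], anc_range[2])
  bn_draw <- function(k, idx) {
    f <- F[k]
    stats::rbeta(length(idx), anc[idx] * (1 - f) / f,
                 (1 - anc[idx]) * (1 - f) / f)
  }
  at <- 0
  take <- function(n) {
    idx <- at + seq_len(n)
    at <<- at + n
    idx
  }
  plant <- function(idx, hi, lo_set, free, tag) {
    hi_first <- stats::runif(length(idx)) < 0.5
    freq[hi, idx] <<- ifelse(hi_first, 1, 0)
    for (l in lo_set) freq[l, idx] <<- ifelse(hi_first, 0, 1)
    if (length(free)) freq[free, idx] <<- bn_draw(free, idx)
    fixed_pair[idx] <<- tag
  }
  if (n_shared > 0) {
    plant(take(n_shared), "FLB", c("DLB", "NLB"), character(0), "DLB.FLB+NLB.FLB")
  }
  if (n_nf_only > 0) plant(take(n_nf_only), "NLB", "FLB", "DLB", "NLB.FLB")
  if (n_df_only > 0) plant(take(n_df_only), "DLB", "FLB", "NLB", "DLB.FLB")
  if (n_dn > 0) plant(take(n_dn), "DLB", "NLB", "FLB", "DLB.NLB")
  rest <- which(is.na(fixed_pair))
  for (k in LINEAGES) freq[k, rest] <- bn_draw(k, rest)
  list(freq = freq, fixed_pair = fixed_pair)
}

# internal: sample diploid genotypes (rows: n per lineage stacked) from a
# lineage frequency matrix
sample_lineage_calls <- function(freq, n_per_lineage) {
  L <- ncol(freq)
  calls <- lapply(rownames(freq), function(k) {
    matrix(stats::rbinom(n_per_lineage * L, 2, rep(freq[k, ], each = n_per_lineage)),
           n_per_lineage, L)
  })
  grouping <- rep(rownames(freq), each = n_per_lineage)
  list(calls = do.call(rbind, calls), grouping = grouping)
}

#' Calibrate Balding-Nichols drift to pairwise F_ST targets
#'
#' Tunes the three per-lineage drift parameters so that multi-locus
#' Weir-Cockerham theta between samples of `n_dip` diploids per lineage
#' matches the pairwise targets. Uses a damped multiplicative fixed-point
#' iteration on a pilot of `pilot_loci` loci (theta is monotone in each
#' drift parameter); the pilot is regenerated with a fixed seed each round
#' so the objective is deterministic.
#'
#' @param fst_targets Pairwise targets `c(DLB.NLB=, DLB.FLB=, NLB.FLB=)`.
#' @param fixed_frac Planted fixed-difference fractions per pair.
#' @param pilot_loci Pilot size.
#' @param n_dip Diploids per lineage in the pilot samples.
#' @param anc_range Ancestral frequency range.
#' @param tol Maximum absolute pilot error to accept.
#' @param max_rounds Iteration cap; failure to reach `tol` is an error
#'   reporting the achieved values.
#' @param seed Pilot seed.
#' @return Named drift parameters `c(DLB=, NLB=, FLB=)`.
#' @export
calibrate_drift <- function(fst_targets = c(DLB.NLB = 0.459, DLB.FLB = 0.677,
                                            NLB.FLB = 0.749),
                            fixed_frac = c(DLB.NLB = 46, DLB.FLB = 1275,
                                           NLB.FLB = 1807) / 8582,
                            pilot_loci = 2000, n_dip = 30,
                            anc_range = c(0.05, 0.95), tol = 0.02,
                            max_rounds = 30, seed = 20210) {
  F <- c(DLB = 0.3, NLB = 0.3, FLB = 0.4)
  pair_members <- list(DLB.NLB = c("DLB", "NLB"), DLB.FLB = c("DLB", "FLB"),
                       NLB.FLB = c("NLB", "FLB"))
  realized <- function(F) {
    withr::with_seed(seed, {
      sim <- simulate_freq_matrix(pilot_loci, F, fixed_frac, anc_range)
      smp <- sample_lineage_calls(sim$freq, n_dip)
      loci <- data.frame(chrom = paste0("s", seq_len(pilot_loci)),
                         pos = 1L, ref = "A", alt = "C",
                         id = paste0("l", seq_len(pilot_loci)))
      gm <- genotype_matrix(smp$calls, loci,
                            paste0("i", seq_along(smp$grouping)))
      fst <- wc_fst(gm, smp$grouping)
      vapply(pair_members, function(m) fst$pairwise[m[1], m[2]], numeric(1))
    })
  }
  for (round in seq_len(max_rounds)) {
    theta <- realized(F)
    err <- theta - fst_targets[names(theta)]
    if (max(abs(err)) < tol) {
      attr(F, "pilot_theta") <- theta
      return(F)
    }
    for (k in names(F)) {
      in_pair <- vapply(pair_members, function(m) k %in% m, logical(1))
      ratio <- mean(fst_targets[in_pair] / theta[in_pair])
      F[k] <- min(max(F[k] * ratio^0.6, 0.01), 0.95)
    }
  }
  stop("calibration failed; achieved pairwise theta: ",
       paste(sprintf("%s=%.3f", names(theta), theta), collapse = ", "))
}

# package-local cache so the default model is calibrated once per session
.trihybrid_cache <- new.env(parent = emptyenv())

#' Default calibrated lineage model
#'
#' A [lineage_model()] at 8582 loci with drift parameters calibrated to the
#' default pairwise theta targets; the calibration is run once per session
#' and cached.
#'
#' @param n_loci Number of loci for the returned model.
#' @return A `lineage_model`.
#' @export
default_lineage_model <- function(n_loci = 8582) {
  key <- "default_F"
  if (is.null(.trihybrid_cache[[key]])) {
    .trihybrid_cache[[key]] <- calibrate_drift()
  }
  lineage_model(n_loci = n_loci, F = .trihybrid_cache[[key]])
}

#' Generate lineage allele frequencies
#'
#' Draws the per-lineage frequency table from a [lineage_model()]: planted
#' fixed differences at exactly 1 vs 0 for their designated pair, all other
#' loci by Balding-Nichols drift from a shared ancestral frequency. Each
#' locus is placed on its own scaffold (short-scaffold reference
#' convention).
#'
#' @param model A [lineage_model()].
#' @param seed Random seed.
#' @return A `lineage_freqs`: list with `freq` (3 x loci), `loci` metadata,
#'   and `fixed_pair` (which pair each planted locus separates, `NA`
#'   otherwise).
#' @export
generate_lineage_freqs <- function(model = default_lineage_model(), seed = 1) {
  out <- withr::with_seed(seed, {
    sim <- simulate_freq_matrix(model$n_loci,
                                model$F,
                                model$fixed_counts / model$n_loci,
                                model$anc_range)
    ord <- sample.int(model$n_loci)  # shuffle so planted loci are interleaved
    sim$freq <- sim$freq[, ord, drop = FALSE]
    sim$fixed_pair <- sim$fixed_pair[ord]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, model$n_loci, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    loci <- data.frame(
      chrom = sprintf("scaffold_%06d", seq_len(model$n_loci)),
      pos = sample.int(10000, model$n_loci, replace = TRUE),
      ref = ref, alt = alt,
      id = sprintf("snp_%06d", seq_len(model$n_loci)),
      stringsAsFactors = FALSE
    )
    list(freq = sim$freq, loci = loci, fixed_pair = sim$fixed_pair)
  })
  colnames(out$freq) <- out$loci$id
  structure(out, class = "lineage_freqs")
}

#' @export
print.lineage_freqs <- function(x, ...) {
  cat(sprintf("lineage_freqs: 3 lineages x %d loci (%d planted fixed)\n",
              ncol(x$freq), sum(!is.na(x$fixed_pair))))
  invisible(x)
}

#' Sample pure-lineage genotype matrices
#'
#' Draws `n_per_lineage` diploids per lineage from a [generate_lineage_freqs()]
#' table (Binomial(2, p) dosages), optionally masking calls at a missing
#' rate.
#'
#' @param freqs A `lineage_freqs` object.
#' @param n_per_lineage Diploids per lineage.
#' @param seed Random seed.
#' @param missing_rate Per-call missing probability.
#' @return List with `gm` ([genotype_matrix()]) and `grouping` (lineage per
#'   individual).
#' @export
sample_lineages <- function(freqs, n_per_lineage = 30, seed = 1,
                            missing_rate = 0) {
  out <- withr::with_seed(seed, {
    smp <- sample_lineage_calls(freqs$freq, n_per_lineage)
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(smp$calls)) < missing_rate,
                     nrow(smp$calls), ncol(smp$calls))
      smp$calls[mask] <- NA_integer_
    }
    smp
  })
  ids <- paste0(out$grouping, "_", sequence(rep(n_per_lineage, 3)))
  list(gm = genotype_matrix(out$calls, freqs$loci, ids),
       grouping = out$grouping)
}

#' Default synthetic study configuration
#'
#' A compact field-survey layout: three pure reference collections (24 DLB
#' in the Mobile-Tensaw Delta analogue, 24 NLB from a northern lake, 14 FLB
#' from the reference Florida river) plus nine admixed sites of 12
#' individuals along the south-eastern seaboard. Focal (FLB) ancestry at
#' admixed sites follows a logistic cline in great-circle distance from the
#' FLB reference site, with an intercept shift for stocked reservoirs; the
#' remaining ancestry is split between DLB and NLB by a per-site weight.
#'
#' @param cline Numeric length 4: logit intercept, distance slope (per km),
#'   reservoir intercept shift, reservoir slope shift.
#' @return A `study_config` list with elements `sites` (data.frame),
#'   `ref_site`, `cline`.
#' @export
default_study_config <- function(cline = c(2.5, -0.004, 1.2, 0)) {
  sites <- data.frame(
    site = c("StJohnsRiver", "MobileDelta", "SugarLake",
             "LakeSeminole", "WestPointRes", "LakeEufaula", "Guntersville",
             "SipseyRiver", "Atchafalaya", "HatchieRiver", "SuttonLake",
             "LakeMattoon"),
    lat = c(29.90, 30.69, 45.42, 30.75, 32.90, 31.95, 34.40,
            33.40, 30.30, 35.50, 34.28, 39.40),
    lon = c(-81.60, -87.99, -93.95, -84.86, -85.18, -85.12, -86.30,
            -87.80, -91.40, -89.20, -78.00, -88.40),
    stocking = c("River", "River", "River", "Reservoir", "Reservoir",
                 "Reservoir", "Reservoir", "River", "River", "River",
                 "Reservoir", "River"),
    n = c(14, 24, 24, 12, 12, 12, 12, 12, 12, 12, 12, 12),
    pure = c("FLB", "DLB", "NLB", NA, NA, NA, NA, NA, NA, NA, NA, NA),
    dlb_weight = c(0, 1, 0, 0.3, 0.25, 0.45, 0.35, 0.85, 0.6, 0.25, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, ref_site = "StJohnsRiver", cline = cline),
            class = "study_config")
}

#' Generate a complete synthetic study
#'
#' Produces everything the analysis pipeline consumes: a genotype matrix
#' (with missing calls at the model's rate), a population map (pure-site
#' individuals flagged as references, admixed-site individuals labelled
#' intergrade), the site table, and the true per-individual ancestry. Each
#' individual's dosages are Binomial(2, sum_k q_k p_kl) draws.
#'
#' @param config A [default_study_config()].
#' @param model A [lineage_model()].
#' @param seed Random seed.
#' @return List with `gm`, `popmap`, `sites`, `truth` (`data.frame` of true
#'   Q), and `freqs` (the underlying lineage frequencies).
#' @export
generate_study <- function(config = default_study_config(),
                           model = default_lineage_model(), seed = 1) {
  freqs <- generate_lineage_freqs(model, seed = seed)
  sites <- config$sites
  ref <- sites[sites$site == config$ref_site, ]
  dist_km <- haversine_km(sites$lat, sites$lon, ref$lat, ref$lon)
  res <- as.integer(sites$stocking == "Reservoir")
  b <- config$cline
  q_flb <- stats::plogis(b[1] + b[2] * dist_km + b[3] * res +
                           b[4] * dist_km * res)
  site_q <- matrix(0, nrow(sites), 3, dimnames = list(sites$site, LINEAGES))
  for (s in seq_len(nrow(sites))) {
    if (!is.na(sites$pure[s])) {
      site_q[s, sites$pure[s]] <- 1
    } else {
      site_q[s, "FLB"] <- q_flb[s]
      site_q[s, "DLB"] <- sites$dlb_weight[s] * (1 - q_flb[s])
      site_q[s, "NLB"] <- (1 - sites$dlb_weight[s]) * (1 - q_flb[s])
    }
  }
  n_tot <- sum(sites$n)
  site_of <- rep(seq_len(nrow(sites)), sites$n)
  ids <- paste0(sites$site[site_of], "_",
                sequence(sites$n))
  mix_p <- site_q[site_of, , drop = FALSE] %*% freqs$freq  # ind x loci
  calls <- withr::with_seed(seed + 7L, {
    m <- matrix(stats::rbinom(length(mix_p), 2, mix_p), n_tot, ncol(mix_p))
    if (model$missing_rate > 0) {
      mask <- matrix(stats::runif(length(m)) < model$missing_rate,
                     nrow(m), ncol(m))
      m[mask] <- NA_integer_
    }
    m
  })
  rownames(calls) <- ids
  gm <- genotype_matrix(calls, freqs$loci, ids)
  popmap <- data.frame(
    individual = ids,
    site = sites$site[site_of],
    group = ifelse(is.na(sites$pure[site_of]), "ILB", sites$pure[site_of]),
    is_reference = !is.na(sites$pure[site_of]),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(individual = ids, site = sites$site[site_of],
                      site_q[site_of, , drop = FALSE],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(gm = gm, popmap = validate_popmap(popmap),
       sites = sites[, c("site", "lat", "lon", "stocking")],
       truth = truth, freqs = freqs)
}
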