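#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius). Vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088) # radius already in km
}

#' Assemble a cline dataset
#'
#' Attaches each individual's site distance (km from the reference site)
#' and stocking stratum to its focal-lineage ancestry proportion.
#'
#' @param q A [q_matrix()] with a column for `lineage`.
#' @param popmap Population map (site per individual).
#' @param sites Site table (see [read_sites()]).
#' @param ref_site Name of the reference site (distance 0).
#' @param lineage Focal ancestry component.
#' @return `data.frame` of class `cline_dataset` with columns `individual`,
#'   `q`, `distance_km`, `stocking`.
#' @export
build_cline_data <- function(q, popmap, sites, ref_site, lineage = "FLB") {
  sites <- validate_sites(sites)
  popmap <- validate_popmap(popmap)
  if (!ref_site %in% sites$site) stop("reference site not in site table: ", ref_site)
  if (!lineage %in% colnames(q)) stop("lineage column not in Q matrix")
  r <- sites[sites$site == ref_site, ]
  sites$distance_km <- haversine_km(sites$lat, sites$lon, r$lat, r$lon)
  idx <- match(rownames(q), popmap$individual)
  if (anyNA(idx)) stop("popmap does not cover all Q individuals")
  sidx <- match(popmap$site[idx], sites$site)
  if (anyNA(sidx)) stop("site table does not cover all sampled sites")
  out <- data.frame(
    individual = rownames(q),
    q = as.numeric(unclass_q(q)[, lineage]),
    distance_km = sites$distance_km[sidx],
    stocking = factor(sites$stocking[sidx], levels = c("River", "Reservoir")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cline_dataset", "data.frame")
  out
}

#' Fractional logistic regression of ancestry on distance and stocking
#'
#' Quasi-binomial GLM with logit link for a proportion response in [0, 1]:
#' either `q ~ distance_km * stocking` (full) or `q ~ distance_km`
#' (reduced). The dispersion is estimated as Pearson chi-squared over the
#' residual degrees of freedom.
#'
#' @param data A [build_cline_data()] data.frame (columns `q`,
#'   `distance_km` and, for the full model, `stocking`).
#' @param formula `"full"` or `"distance_only"`.
#' @return A `cline_fit`: list with the underlying `glm`, `coefficients`,
#'   `dispersion`, `deviance`, `df_residual` and the formula used.
#' @export
fit_fractional_logit <- function(data, formula = c("full", "distance_only")) {
  formula <- match.arg(formula)
  if (any(data$q < 0 | data$q > 1)) stop("responses must lie in [0, 1]")
  if (formula == "full") {
    if (length(unique(data$stocking)) < 2) {
      stop("full model needs both stocking levels")
    }
    fml <- q ~ distance_km * stocking
  } else {
    fml <- q ~ distance_km
  }
  fit <- stats::glm(fml, family = stats::quasibinomial(), data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  structure(list(
    glm = fit,
    coefficients = stats::coef(fit),
    dispersion = pearson / fit$df.residual,
    deviance = fit$deviance,
    df_residual = fit$df.residual,
    formula = formula
  ), class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat("cline_fit (quasi-binomial fractional logit, ", x$formula, " model)\n",
      sep = "")
  print(round(x$coefficients, 6))
  cat(sprintf("dispersion %.4f, residual deviance %.2f on %d df\n",
              x$dispersion, x$deviance, x$df_residual))
  invisible(x)
}

#' @export
coef.cline_fit <- function(object, ...) object$coefficients

#' @export
predict.cline_fit <- function(object, newdata, type = "response", ...) {
  stats::predict(object$glm, newdata = newdata, type = type, ...)
}

#' Chi-squared deviance test between nested cline models
#'
#' Tests the reduction in deviance from the reduced to the full model,
#' scaled by the full model's dispersion, against a chi-squared
#' distribution with the difference in residual degrees of freedom.
#'
#' @param full,reduced Two [fit_fractional_logit()] fits on the same data
#'   with the reduced model nested in the full one.
#' @return The p-value.
#' @export
deviance_test <- function(full, reduced) {
  full_terms <- attr(stats::terms(full$glm), "term.labels")
  red_terms <- attr(stats::terms(reduced$glm), "term.labels")
  if (!all(red_terms %in% full_terms) ||
      stats::nobs(full$glm) != stats::nobs(reduced$glm)) {
    stop("models are not nested fits of the same data")
  }
  df <- reduced$df_residual - full$df_residual
  stat <- (reduced$deviance - full$deviance) / full$dispersion
  if (df == 0) return(1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Geographic extent shift between stocking strata
#'
#' Distance difference at which the fitted ancestry curve of each stratum
#' falls to `ancestry_cut` (Reservoir minus River), found by root-finding
#' on the fitted logit to 0.1 km.
#'
#' @param fit A full-model [fit_fractional_logit()].
#' @param ancestry_cut Ancestry level defining the intergrade boundary.
#' @param max_km Search limit.
#' @return Shift in km (positive when stocking extends the cline).
#' @export
extent_shift <- function(fit, ancestry_cut = 0.06, max_km = 5000) {
  if (fit$formula != "full") stop("extent_shift needs the full model")
  crossing <- function(stock) {
    f <- function(d) {
      stats::predict(fit$glm,
                     newdata = data.frame(
                       distance_km = d,
                       stocking = factor(stock, levels = c("River", "Reservoir"))),
                     type = "response") - ancestry_cut
    }
    if (f(0) < 0 || f(max_km) > 0) {
      stop("fitted ", stock, " curve does not cross ", ancestry_cut,
           " within [0, ", max_km, "] km")
    }
    stats::uniroot(f, c(0, max_km), tol = 0.1)$root
  }
  crossing("Reservoir") - crossing("River")
}

#' Simulate a synthetic ancestry cline
#'
#' Individuals get distances uniform on `[0, max_km]` and a random stocking
#' stratum; their ancestry proportion is a Beta draw around the logistic
#' mean `plogis(b0 + b1 d + b2 s + b3 d s)` with precision `phi`. Used for
#' parameter-recovery and null-calibration experiments.
#'
#' @param n Number of individuals.
#' @param coefs Named or positional numeric of length 4: intercept,
#'   distance slope, stocking shift, distance-by-stocking interaction.
#' @param phi Beta precision (larger = less noise).
#' @param max_km Distance range.
#' @param seed Random seed.
#' @return A `cline_dataset` data.frame with a `truth` attribute.
#' @export
simulate_cline <- function(n = 880, coefs = c(2.5, -0.004, 1.5, 0),
                           phi = 10, max_km = 2500, seed = 1) {
  out <- withr::with_seed(seed, {
    d <- stats::runif(n, 0, max_km)
    s <- stats::rbinom(n, 1, 0.5)
    eta <- coefs[1] + coefs[2] * d + coefs[3] * s + coefs[4] * d * s
    mu <- stats::plogis(eta)
    q <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
    data.frame(
      individual = sprintf("sim_%04d", seq_len(n)),
      q = q,
      distance_km = d,
      stocking = factor(ifelse(s == 1, "Reservoir", "River"),
                        levels = c("River", "Reservoir")),
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("cline_dataset", "data.frame")
  attr(out, "truth") <- coefs
  out
}
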