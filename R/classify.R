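#' Q-threshold category rule
#'
#' An individual is called pure in lineage k when `q_k >= pure_threshold`;
#' otherwise a triple hybrid when every component is at least
#' `minor_threshold`; otherwise a two-lineage hybrid of its two largest
#' components. The rule partitions the simplex.
#'
#' @param pure_threshold Purity threshold (in (0.5, 1)).
#' @param minor_threshold Minimum minor ancestry for a triple hybrid
#'   (in (0, 1 - pure_threshold]).
#' @return A `category_rule` list.
#' @export
category_rule <- function(pure_threshold = 0.94, minor_threshold = 0.06) {
  if (pure_threshold <= 0.5 || pure_threshold >= 1) {
    stop("pure_threshold must be in (0.5, 1)")
  }
  if (minor_threshold <= 0 || minor_threshold > 1 - pure_threshold) {
    stop("minor_threshold must be in (0, 1 - pure_threshold]")
  }
  structure(list(pure_threshold = pure_threshold,
                 minor_threshold = minor_threshold),
            class = "category_rule")
}

#' Assign individuals to pure/hybrid categories from Q-values
#'
#' @param q A [q_matrix()] (or numeric matrix of simplex rows) with lineage
#'   column names.
#' @param rule A [category_rule()].
#' @return Character vector of categories: a lineage name, `"A-B"` for a
#'   two-lineage hybrid (canonical lineage order), or `"Triple Hybrid"`.
#' @export
assign_category <- function(q, rule = category_rule()) {
  m <- unclass_q(q)
  lineages <- colnames(m)
  canon <- c(intersect(LINEAGES, lineages), setdiff(lineages, LINEAGES))
  apply(m, 1, function(qi) {
    if (max(qi) >= rule$pure_threshold) {
      lineages[which.max(qi)]
    } else if (min(qi) >= rule$minor_threshold) {
      "Triple Hybrid"
    } else {
      top2 <- lineages[order(qi, decreasing = TRUE)[1:2]]
      paste(canon[canon %in% top2], collapse = "-")
    }
  })
}

#' Confusion matrix from truth labels and assignments
#'
#' Rows are simulated (truth) categories, columns assigned categories.
#'
#' @param truth Character vector of simulated categories (may carry
#'   generation suffixes such as `" F1"`).
#' @param assigned Character vector of assigned categories.
#' @return Integer matrix.
#' @export
confusion_matrix <- function(truth, assigned) {
  col_levels <- unique(c(truth_target(unique(truth)), assigned))
  tab <- table(factor(truth, levels = unique(truth)),
               factor(assigned, levels = col_levels))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

# internal: map a simulated category label (possibly with generation
# suffix) to its assigned-category target
truth_target <- function(labels) {
  sub("\\s+(F1|F2:F4|F[0-9]+|BX[0-9]*)$", "", labels)
}

#' Efficiency, accuracy and performance of category assignment
#'
#' For each assigned category c: efficiency = correctly assigned /
#' simulated in c (simulated rows pooled across generations, e.g. all
#' `DLB-FLB` F1/F2:F4/BX rows count toward `DLB-FLB`); accuracy =
#' correctly assigned / total assigned to c; performance = efficiency x
#' accuracy. Metrics are kept at full precision; rounding happens only in
#' the print method.
#'
#' @param confusion A [confusion_matrix()] (simulated x assigned counts).
#' @return An `assignment_report`: list with the confusion matrix and a
#'   `metrics` data.frame (`category`, `simulated`, `assigned`, `correct`,
#'   `efficiency`, `accuracy`, `performance`). Categories with zero
#'   assigned counts get `NA` accuracy.
#' @export
evaluate <- function(confusion) {
  confusion <- as.matrix(confusion)
  targets <- truth_target(rownames(confusion))
  cats <- colnames(confusion)
  metrics <- lapply(cats, function(cc) {
    rows <- which(targets == cc)
    simulated <- sum(confusion[rows, , drop = FALSE])
    correct <- sum(confusion[rows, cc, drop = FALSE])
    assigned <- sum(confusion[, cc])
    eff <- if (simulated > 0) correct / simulated else NA_real_
    acc <- if (assigned > 0) correct / assigned else NA_real_
    data.frame(category = cc, simulated = simulated, assigned = assigned,
               correct = correct, efficiency = eff, accuracy = acc,
               performance = eff * acc, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, metrics)
  if (any(metrics$assigned == 0)) {
    warning("category with zero assigned individuals; accuracy undefined")
  }
  structure(list(confusion = confusion, metrics = metrics),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat("assignment_report\n")
  m <- x$metrics
  m$efficiency <- sprintf("%.2f%%", 100 * m$efficiency)
  m$accuracy <- sprintf("%.2f%%", 100 * m$accuracy)
  m$performance <- sprintf("%.2f%%", 100 * m$performance)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Scan purity thresholds for optimal assignment performance
#'
#' Assigns the simulated cohort at each candidate purity threshold and
#' reports the mean per-category performance; the optimum is the argmax,
#' ties broken toward the larger threshold.
#'
#' @param q A [q_matrix()] for simulated individuals.
#' @param truth Truth category labels.
#' @param thresholds Numeric grid of purity thresholds.
#' @param minor_threshold Minor-ancestry threshold held fixed.
#' @return List with `table` (`threshold`, `mean_performance`) and
#'   `optimum`.
#' @export
threshold_scan <- function(q, truth, thresholds, minor_threshold = 0.06) {
  if (!length(thresholds)) stop("empty threshold grid")
  perf <- vapply(thresholds, function(th) {
    rule <- category_rule(th, min(minor_threshold, 1 - th))
    rep <- evaluate(confusion_matrix(truth, assign_category(q, rule)))
    mean(rep$metrics$performance, na.rm = TRUE)
  }, numeric(1))
  best <- max(which(perf == max(perf)))
  list(table = data.frame(threshold = thresholds, mean_performance = perf),
       optimum = thresholds[best])
}
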