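#' Genotype matrix of biallelic SNP dosages
#'
#' The central container of the package: an individuals-by-loci matrix of
#' alternate-allele dosages (0, 1, 2; `NA` = missing call) together with locus
#' metadata. All downstream statistics, filters and ancestry estimators
#' operate on this object.
#'
#' @param calls Integer matrix, individuals in rows, loci in columns. Values
#'   must be 0, 1, 2 or `NA`. Row names are taken as individual ids when
#'   `individuals` is not supplied.
#' @param loci `data.frame` with one row per locus and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt` (single bases) and `id`.
#' @param individuals Character vector of unique individual ids.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` and `loci`.
#' @export
genotype_matrix <- function(calls, loci, individuals = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individuals)) {
    if (nrow(calls) > 0) {
      stop("individual ids are required (row names of `calls` or `individuals`)")
    }
    individuals <- character(0)
  }
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) {
    stop("individual ids must be unique")
  }
  if (length(individuals) != nrow(calls)) {
    stop("length of `individuals` does not match nrow(calls)")
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(req %in% names(loci))) {
    stop("`loci` must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loci) != ncol(calls)) {
    stop("nrow(loci) does not match ncol(calls)")
  }
  if (nrow(loci) > 0) {
    if (any(loci$pos < 1)) stop("locus positions must be >= 1")
    bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
    if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
    if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  }
  rownames(calls) <- individuals
  colnames(calls) <- loci$id
  structure(list(calls = calls, loci = loci), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of individuals / loci
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_ind <- function(gm) nrow(gm$calls)

#' @rdname n_ind
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' Individual ids of a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Character vector.
#' @export
individuals <- function(gm) rownames(gm$calls)

#' Subset a genotype matrix
#'
#' `i` selects individuals, `j` loci; either may be logical, integer, or
#' character (ids). Metadata stays aligned with the calls.
#'
#' @param x A [genotype_matrix()].
#' @param i,j Individual / locus selectors.
#' @param ... Unused.
#' @return A `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) {
    j <- match(j, x$loci$id)
    if (anyNA(j)) stop("unknown locus id(s) in subset")
  }
  calls <- x$calls[i, j, drop = FALSE]
  genotype_matrix(calls, x$loci[j, , drop = FALSE], rownames(calls))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$calls))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d biallelic SNPs (%.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls),
    if (length(x$calls)) 100 * nmiss / length(x$calls) else 0
  ))
  invisible(x)
}

# canonical lineage codes used throughout; ILB = intergrade (admixed) group
LINEAGES <- c("DLB", "NLB", "FLB")
GROUPS <- c(LINEAGES, "ILB")

# internal: check a popmap data.frame and align it to a genotype matrix
align_popmap <- function(gm, popmap) {
  popmap <- validate_popmap(popmap)
  idx <- match(individuals(gm), popmap$individual)
  if (anyNA(idx)) {
    stop(
      "popmap does not cover individuals: ",
      paste(utils::head(individuals(gm)[is.na(idx)], 5), collapse = ", ")
    )
  }
  popmap[idx, , drop = FALSE]
}

#' Validate a population map
#'
#' A population map assigns each individual a sampling site, a lineage group
#' (`DLB`, `NLB`, `FLB` or intergrade `ILB`) and a logical reference-purity
#' flag marking individuals used to anchor supervised ancestry estimation.
#'
#' @param popmap `data.frame` with columns `individual`, `site`, `group`,
#'   `is_reference`.
#' @return The validated `data.frame` (with `is_reference` coerced to
#'   logical), invisibly usable anywhere a popmap is expected.
#' @export
validate_popmap <- function(popmap) {
  req <- c("individual", "site", "group", "is_reference")
  if (!all(req %in% names(popmap))) {
    stop("popmap must have columns: ", paste(req, collapse = ", "))
  }
  popmap$individual <- as.character(popmap$individual)
  popmap$site <- as.character(popmap$site)
  popmap$group <- as.character(popmap$group)
  if (anyDuplicated(popmap$individual)) {
    stop("duplicate individual id(s) in popmap: ",
         paste(unique(popmap$individual[duplicated(popmap$individual)]), collapse = ", "))
  }
  bad <- setdiff(unique(popmap$group), GROUPS)
  if (length(bad)) {
    stop("unknown group token(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(GROUPS, collapse = ", "))
  }
  if (any(!nzchar(popmap$site))) stop("site names must be nonempty")
  popmap$is_reference <- as.logical(popmap$is_reference)
  if (anyNA(popmap$is_reference)) stop("is_reference must be TRUE/FALSE")
  if (any(popmap$is_reference & popmap$group == "ILB")) {
    stop("reference individuals cannot be in the intergrade (ILB) group")
  }
  popmap
}
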