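#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns the biallelic-SNP
#' dosage matrix. Multi-allelic records and indels are skipped and counted;
#' phase separators are ignored; half calls (`./1`) and `./.` become missing.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @param verbose Report the number of skipped records.
#' @return A [genotype_matrix()]. The number of skipped (non-biallelic-SNP)
#'   records is attached as attribute `n_skipped`.
#' @export
read_vcf <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF header/body in ", path, ": ",
                             conditionMessage(e))
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    samples <- colnames(vcf@gt)[-1]
    gm <- genotype_matrix(
      matrix(integer(0), nrow = length(samples), ncol = 0,
             dimnames = list(samples, NULL)),
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), id = character(0))
    )
    attr(gm, "n_skipped") <- 0L
    return(gm)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (verbose && n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s) in ", basename(path))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dosage[gt == "0/0"] <- 0L
  dosage[gt %in% c("0/1", "1/0")] <- 1L
  dosage[gt == "1/1"] <- 2L
  ids <- fix[snp, "ID"]
  chrom <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(chrom[no_id], "_", pos[no_id])
  loci <- data.frame(chrom = chrom, pos = pos, ref = ref[snp], alt = alt[snp],
                     id = ids, stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(dosage), loci, colnames(gt))
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one record per locus with a GT-only FORMAT; missing dosages become
#' `./.`. Loci are written sorted by chromosome and position.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  loci <- gm$loci
  key <- paste(loci$chrom, loci$pos)
  if (anyDuplicated(key)) {
    stop("cannot write VCF: duplicate chrom+pos at ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  ord <- order(loci$chrom, loci$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=trihybrid",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals(gm)), collapse = "\t")
  )
  if (nrow(loci) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(loci), ncol = n_ind(gm))
  calls <- t(gm$calls)  # loci x individuals
  ok <- !is.na(calls)
  gt[ok] <- code[calls[ok] + 1L]
  gt <- gt[ord, , drop = FALSE]
  loci <- loci[ord, , drop = FALSE]
  body <- paste(
    loci$chrom, loci$pos, loci$id, loci$ref, loci$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population map
#'
#' Tab-separated with header columns `individual`, `site`, `group`,
#' `is_reference`. Group tokens outside DLB/NLB/FLB/ILB and duplicate
#' individual ids are errors.
#'
#' @param path Path to a TSV file.
#' @return A validated popmap `data.frame` (see [validate_popmap()]).
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_popmap(pm)
}

#' Write a population map
#' @param popmap A popmap `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(validate_popmap(popmap), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site coordinate/stocking table
#'
#' Tab-separated with header columns `site`, `lat`, `lon`, `stocking`
#' (`River` or `Reservoir`).
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with one row per site.
#' @export
read_sites <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sites(st)
}

#' @rdname read_sites
#' @param sites Site table to validate.
#' @export
validate_sites <- function(sites) {
  req <- c("site", "lat", "lon", "stocking")
  if (!all(req %in% names(sites))) {
    stop("site table must have columns: ", paste(req, collapse = ", "))
  }
  sites$site <- as.character(sites$site)
  if (anyDuplicated(sites$site)) stop("duplicate site name(s) in site table")
  if (any(sites$lat < -90 | sites$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(sites$lon < -180 | sites$lon > 180)) stop("longitude outside [-180, 180]")
  bad <- setdiff(unique(sites$stocking), c("River", "Reservoir"))
  if (length(bad)) {
    stop("unknown stocking token(s) ", paste(bad, collapse = ", "),
         "; allowed: River, Reservoir")
  }
  sites
}

#' Write / read an ancestry (Q) matrix as TSV
#'
#' Columns are `individual` then `Q_<lineage>` for each ancestry component.
#' On reading, rows off the unit simplex by less than 1e-6 are renormalized;
#' larger deviations are an error.
#'
#' @param q A [q_matrix()] or numeric matrix with individuals in rows.
#' @param path File path.
#' @return `write_q` returns `path` invisibly; `read_q` returns a
#'   [q_matrix()].
#' @export
write_q <- function(q, path) {
  m <- unclass_q(q)
  df <- data.frame(individual = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- paste0("Q_", colnames(m))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_q
#' @export
read_q <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "individual") stop("Q table must start with `individual`")
  if (anyDuplicated(df$individual)) stop("duplicate individual id(s) in Q table")
  qcols <- grep("^Q_", names(df), value = TRUE)
  if (!length(qcols)) stop("no Q_<lineage> columns found")
  m <- as.matrix(df[, qcols, drop = FALSE])
  colnames(m) <- sub("^Q_", "", qcols)
  rownames(m) <- df$individual
  rs <- rowSums(m)
  off <- abs(rs - 1)
  if (any(off >= 1e-6)) {
    stop("Q rows off the simplex by >= 1e-6: ",
         paste(utils::head(df$individual[off >= 1e-6], 5), collapse = ", "))
  }
  q_matrix(m / rs)
}
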