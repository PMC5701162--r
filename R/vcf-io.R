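#' Read a diploid VCF into a genotype matrix
#'
#' Loads biallelic SNP records from a VCF (v4.x, plain or gzipped) and encodes
#' genotypes as alternate-allele dosages. Multi-allelic records and records
#' whose REF or ALT is not a single base are skipped, with a message giving
#' the count. Missing genotypes (`./.` or `.`) become `NA`. Phase separators
#' are accepted and ignored (genotypes are treated as unphased).
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0L || ncol(vcf@gt) < 2L) {
    stop("VCF has no genotype columns")
  }
  if (!any(grepl("(^|:)GT(:|$)", vcf@gt[, 1L]))) {
    stop("VCF has no GT field in FORMAT")
  }
  fix <- vcf@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0L) {
    message(n_skip, " non-SNP or multi-allelic record(s) skipped")
  }
  if (!any(snp)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- matrix(code[gt], nrow = nrow(gt), ncol = ncol(gt))
  dos <- t(dos)  # individuals x sites
  rownames(dos) <- colnames(gt)
  geno_matrix(
    dos,
    chrom = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp]
  )
}

#' Write a genotype matrix as VCF v4.2
#'
#' Records are emitted in deterministic (region, position) order so that the
#' same matrix always produces byte-identical output. Missing dosages are
#' written as `./.`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  ord <- order(gm$sites$chrom, gm$sites$pos, method = "radix")
  sites <- gm$sites[ord, , drop = FALSE]
  dos <- gm$dosages[, ord, drop = FALSE]
  gt_str <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_str[dos[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eruptpop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS", ".", "GT",
    sep = "\t"
  )
  if (ncol(dos) > 0L) {
    body <- paste(body, apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  } else {
    body <- character(0)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read the per-sample metadata table
#'
#' A tab-separated file with header columns `sample`, `population`, `period`,
#' `sex`, `age`, `burrow`. Unrecognised or empty `sex`/`age`/`burrow` tokens
#' map to `"unknown"`; `period` must be `pre` or `post` for every sample used
#' in a temporal comparison.
#'
#' @param path Path to the TSV (plain or gzipped).
#' @param samples Optional character vector of sample ids that must all be
#'   present (e.g. the samples of a genotype matrix); any that are missing
#'   trigger an error listing them.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, colClasses = "character", na.strings = c("NA", ""))
  required <- c("sample", "population", "period", "sex", "age", "burrow")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(md$sample)) {
    stop("duplicated sample row(s): ",
         paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
  }
  md$period <- tolower(md$period)
  bad_period <- !md$period %in% c("pre", "post") & !is.na(md$period)
  if (any(bad_period)) {
    stop("period must be 'pre' or 'post'; offending sample(s): ",
         paste(md$sample[bad_period], collapse = ", "))
  }
  md$sex <- ifelse(toupper(md$sex) %in% c("M", "F"), toupper(md$sex), "unknown")
  md$age <- ifelse(md$age %in% c("juvenile", "adult"), md$age, "unknown")
  md$burrow[is.na(md$burrow)] <- "unknown"
  md$sex[is.na(md$sex)] <- "unknown"
  md$age[is.na(md$age)] <- "unknown"
  if (!is.null(samples)) {
    absent <- setdiff(samples, md$sample)
    if (length(absent)) {
      stop("sample(s) in genotype data absent from metadata: ",
           paste(absent, collapse = ", "))
    }
  }
  md
}

#' Write a metadata table
#' @param md Data.frame as returned by [read_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
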