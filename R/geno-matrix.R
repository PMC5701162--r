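#' Construct a genotype matrix
#'
#' The central container of the package: a diploid dosage matrix (individuals
#' in rows, biallelic SNP sites in columns) together with site coordinates.
#' Dosages count copies of the alternate allele: 0 (hom ref), 1 (het),
#' 2 (hom alt), `NA` (missing call). Site coordinates are a target-region
#' identifier plus a 1-based position within that region, and must be unique.
#'
#' @param dosages Integer matrix, individuals x sites, entries in
#'   `{0, 1, 2, NA}`. Row names are the sample identifiers.
#' @param chrom Character vector of region identifiers, one per site.
#' @param pos Integer vector of 1-based positions within region, one per site.
#' @param ref,alt Single bases per site (recycled); carried so VCF round trips
#'   are lossless. Defaults are placeholders for simulated data.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (the matrix, with site ids `region:pos` as column names), `sites`
#'   (data.frame with `chrom`, `pos`, `ref`, `alt`, `id`) and `samples`.
#' @export
geno_matrix <- function(dosages, chrom, pos, ref = "A", alt = "G") {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found other values")
  }
  if (is.null(rownames(dosages))) {
    stop("dosage matrix must have sample identifiers as row names")
  }
  if (anyDuplicated(rownames(dosages))) stop("duplicated sample identifiers")
  n_sites <- ncol(dosages)
  if (length(chrom) != n_sites || length(pos) != n_sites) {
    stop("chrom/pos length must equal the number of sites")
  }
  sites <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n_sites),
    alt = rep_len(as.character(alt), n_sites),
    stringsAsFactors = FALSE
  )
  sites$id <- paste0(sites$chrom, ":", sites$pos)
  if (anyDuplicated(sites$id)) stop("site coordinates must be unique")
  colnames(dosages) <- sites$id
  structure(
    list(dosages = dosages, sites = sites, samples = rownames(dosages)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d individuals x %d biallelic sites (%.1f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by individuals and/or sites
#'
#' Order-preserving: selectors given as character vectors keep the order in
#' which they are supplied; logical or `NULL` selectors keep matrix order.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample identifiers (character), indices, or logical mask;
#'   `NULL` keeps all.
#' @param sites Site identifiers (`"region:pos"`), indices, or logical mask;
#'   `NULL` keeps all.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_matrix <- function(gm, samples = NULL, sites = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- resolve_selector(samples, gm$samples, "sample")
  ci <- resolve_selector(sites, gm$sites$id, "site")
  if (length(si) == 0L) stop("empty sample selection")
  if (length(ci) == 0L) stop("empty site selection")
  geno_matrix(
    gm$dosages[si, ci, drop = FALSE],
    chrom = gm$sites$chrom[ci], pos = gm$sites$pos[ci],
    ref = gm$sites$ref[ci], alt = gm$sites$alt[ci]
  )
}

resolve_selector <- function(sel, labels, what) {
  if (is.null(sel)) return(seq_along(labels))
  if (is.logical(sel)) {
    if (length(sel) != length(labels)) stop("logical ", what, " selector has wrong length")
    return(which(sel))
  }
  if (is.character(sel)) {
    idx <- match(sel, labels)
    if (anyNA(idx)) {
      stop("unknown ", what, " label(s): ", paste(sel[is.na(idx)], collapse = ", "))
    }
    return(idx)
  }
  idx <- as.integer(sel)
  if (any(idx < 1L | idx > length(labels))) stop(what, " index out of range")
  idx
}

#' Per-site alternate-allele frequencies
#'
#' Complete-case per site: missing genotypes are dropped from both numerator
#' and denominator.
#'
#' @param gm A [geno_matrix()].
#' @return Numeric vector of alt-allele frequencies, `NaN` where no calls.
#' @export
allele_freqs <- function(gm) {
  n_called <- colSums(!is.na(gm$dosages))
  colSums(gm$dosages, na.rm = TRUE) / (2 * n_called)
}

# non-missing allele count per site (2 x called genotypes)
allele_counts_n <- function(gm) 2L * colSums(!is.na(gm$dosages))

# alt allele count per site among called genotypes
allele_counts_alt <- function(gm) colSums(gm$dosages, na.rm = TRUE)

#' Identify segregating sites
#'
#' A site is segregating if both alleles are observed among the non-missing
#' genotypes.
#' @param gm A [geno_matrix()].
#' @return Logical vector over sites.
#' @export
is_segregating <- function(gm) {
  ac <- allele_counts_alt(gm)
  an <- allele_counts_n(gm)
  ac > 0L & ac < an
}
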