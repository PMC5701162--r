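#' Mean observed heterozygosity
#'
#' Mean over individuals of the fraction of sites at which the individual is
#' heterozygous. The denominator is explicit because it changes the scale by
#' orders of magnitude: `"snp_sites"` divides by the individual's non-missing
#' SNP calls (a per-SNP rate), `"all_callable_sites"` divides by a fixed
#' callable sequence length in bp (a per-bp rate, the scale on which
#' capture-panel studies usually report heterozygosity).
#'
#' @param gm A [geno_matrix()] with >= 1 individual.
#' @param denominator `"snp_sites"` or `"all_callable_sites"`.
#' @param callable_length Callable length in bp (required for
#'   `"all_callable_sites"`).
#' @return The mean heterozygosity (a rate).
#' @export
mean_heterozygosity <- function(gm,
                                denominator = c("snp_sites", "all_callable_sites"),
                                callable_length = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  denominator <- match.arg(denominator)
  per_ind <- per_individual_het(gm, denominator, callable_length)
  mean(per_ind)
}

# per-individual heterozygosity under either denominator mode
per_individual_het <- function(gm, denominator = "snp_sites",
                               callable_length = NULL) {
  het_counts <- rowSums(gm$dosages == 1L, na.rm = TRUE)
  if (denominator == "snp_sites") {
    denom <- rowSums(!is.na(gm$dosages))
    if (any(denom == 0)) stop("individual(s) with zero called sites")
  } else {
    if (is.null(callable_length)) {
      stop("callable_length is required for denominator = 'all_callable_sites'")
    }
    if (callable_length <= 0) stop("callable_length must be positive")
    denom <- callable_length
  }
  het_counts / denom
}

#' Per-site Watterson's theta and nucleotide diversity
#'
#' For a site with `n` non-missing alleles and alternate-allele count `c`:
#' `pi = c (n - c) / choose(n, 2)` (the unbiased mean pairwise difference)
#' and `theta_W = S / a_{n-1}` with `S` the 0/1 segregation indicator and
#' `a_{n-1} = sum_{i=1}^{n-1} 1/i`. Sites with fewer than two non-missing
#' alleles are excluded with a message.
#'
#' @param gm A [geno_matrix()].
#' @return A `per_site_diversity` data.frame: `site`, `theta_w`, `pi`,
#'   `n_alleles_used`.
#' @export
per_site_diversity <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- allele_counts_n(gm)
  c_alt <- allele_counts_alt(gm)
  keep <- n >= 2L
  if (any(!keep)) {
    message(sum(!keep), " site(s) with < 2 non-missing alleles excluded")
  }
  n <- n[keep]
  c_alt <- c_alt[keep]
  seg <- c_alt > 0L & c_alt < n
  a_n1 <- vapply(n, function(k) sum(1 / seq_len(k - 1L)), numeric(1))
  out <- data.frame(
    site = gm$sites$id[keep],
    theta_w = as.numeric(seg) / a_n1,
    pi = c_alt * (n - c_alt) / choose(n, 2),
    n_alleles_used = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("per_site_diversity", "data.frame")
  out
}

# Tajima (1989) constants for sample size n (number of sequences)
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in sliding windows
#'
#' Windows are half-open intervals `[start, start + window_bp)` on 1-based
#' positions within each target region, advanced by `step_bp` (tiling by
#' default). Within a window, D is computed from the segregating-site count
#' and the summed per-site mean pairwise differences, with the Tajima (1989)
#' normalizing constants evaluated at the minimum non-missing allele count
#' across the window's sites. Windows with no segregating site are undefined
#' and omitted.
#'
#' @param gm A [geno_matrix()].
#' @param window_bp Window width in bp (>= 1).
#' @param step_bp Step in bp; defaults to `window_bp`.
#' @return A `windowed_statistic` data.frame: `chrom`, `start`, `end`
#'   (half-open), `n_sites`, `S`, `value` (D).
#' @export
tajimas_d_windows <- function(gm, window_bp = 100L, step_bp = window_bp) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (window_bp < 1L) stop("window_bp must be >= 1")
  n_all <- allele_counts_n(gm)
  c_alt <- allele_counts_alt(gm)
  rows <- list()
  for (chr in unique(gm$sites$chrom)) {
    in_chr <- which(gm$sites$chrom == chr)
    pos <- gm$sites$pos[in_chr]
    starts <- seq(1L, max(pos), by = step_bp)
    for (st in starts) {
      idx <- in_chr[pos >= st & pos < st + window_bp]
      if (length(idx) == 0L) next
      d <- tajima_d_core(n_all[idx], c_alt[idx])
      if (is.na(d$D)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start = st, end = st + window_bp,
        n_sites = length(idx), S = d$S, value = d$D,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_sites = integer(0), S = integer(0), value = numeric(0))
  class(out) <- c("windowed_statistic", "data.frame")
  out
}

tajima_d_core <- function(n_vec, c_vec) {
  usable <- n_vec >= 2L
  n_vec <- n_vec[usable]
  c_vec <- c_vec[usable]
  if (length(n_vec) == 0L) return(list(D = NA_real_, S = 0L))
  n <- min(n_vec)
  if (n < 4L) return(list(D = NA_real_, S = 0L))
  seg <- c_vec > 0L & c_vec < n_vec
  S <- sum(seg)
  if (S == 0L) return(list(D = NA_real_, S = 0L))
  k_hat <- sum(c_vec * (n_vec - c_vec) / choose(n_vec, 2))
  cst <- tajima_constants(n)
  D <- (k_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  list(D = D, S = S)
}

#' Folded site frequency spectrum with equalized subsampling
#'
#' To compare spectra between samples of unequal size, `subsample_n`
#' individuals are drawn without replacement `reps` times; in each draw the
#' minor-allele count of every segregating site is tabulated and the class
#' counts are averaged across draws.
#'
#' @param gm A [geno_matrix()].
#' @param subsample_n Individuals per draw (2..n available).
#' @param reps Number of subsampling iterations.
#' @param seed Integer seed.
#' @return A `folded_sfs` list: `class_counts` (mean sites per minor-allele
#'   count class `1..floor(n_hap/2)`), `per_rep` (reps x classes matrix),
#'   `n_haplotypes`, `reps`, `subsample_n`.
#' @export
folded_sfs <- function(gm, subsample_n, reps = 20L, seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (subsample_n < 2L) stop("subsample_n must be >= 2")
  if (subsample_n > nrow(gm$dosages)) {
    stop("subsample_n exceeds the available individuals")
  }
  n_hap <- 2L * subsample_n
  n_classes <- n_hap %/% 2L
  withr::with_seed(as.integer(seed), {
    per_rep <- matrix(0, nrow = reps, ncol = n_classes)
    for (r in seq_len(reps)) {
      rows <- sample.int(nrow(gm$dosages), subsample_n)
      sub <- gm$dosages[rows, , drop = FALSE]
      ac <- colSums(sub, na.rm = TRUE)
      an <- 2L * colSums(!is.na(sub))
      minor <- pmin(ac, an - ac)
      minor <- minor[minor >= 1L]
      tab <- tabulate(minor, nbins = n_classes)
      per_rep[r, ] <- tab
    }
    structure(
      list(
        class_counts = colMeans(per_rep),
        per_rep = per_rep,
        n_haplotypes = n_hap,
        reps = reps,
        subsample_n = subsample_n
      ),
      class = "folded_sfs"
    )
  })
}

#' Method-of-moments inbreeding coefficients
#'
#' Per individual, `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the
#' observed homozygous-site count over the individual's non-missing sites,
#' `E_hom = sum_sites [1 - 2 p q * 2n/(2n - 1)]` is the expected count under
#' Hardy-Weinberg at the sample allele frequencies (small-sample corrected),
#' and `L` the number of sites used. Individuals with a degenerate
#' denominator return `NA` with a message.
#'
#' @param gm A [geno_matrix()] with >= 2 individuals.
#' @return Named numeric vector of per-individual F.
#' @export
inbreeding_f <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(gm$dosages) < 2L) stop("inbreeding F requires >= 2 individuals")
  p <- allele_freqs(gm)
  an <- allele_counts_n(gm)
  e_site <- 1 - 2 * p * (1 - p) * an / (an - 1)
  f <- vapply(seq_len(nrow(gm$dosages)), function(i) {
    ok <- !is.na(gm$dosages[i, ]) & an >= 2L
    L <- sum(ok)
    e_hom <- sum(e_site[ok])
    o_hom <- sum(gm$dosages[i, ok] != 1L)
    if (abs(L - e_hom) < 1e-12) return(NA_real_)
    (o_hom - e_hom) / (L - e_hom)
  }, numeric(1))
  names(f) <- gm$samples
  if (anyNA(f)) message(sum(is.na(f)), " individual(s) with degenerate F denominator")
  f
}

# allele presence per site (ref, alt) for a dosage matrix
allele_presence <- function(dos) {
  list(
    ref = colSums(dos < 2L, na.rm = TRUE) > 0L,
    alt = colSums(dos > 0L, na.rm = TRUE) > 0L
  )
}

#' Private alleles with equalized subsampling
#'
#' An allele (reference or alternate) is private to a population if it is
#' observed there and in no other population. To remove sample-size bias,
#' `equalize_n` individuals are drawn per population without replacement in
#' each of `reps` iterations; counts are averaged and their spread reported
#' as the SD across iterations (the "mean +/- SE" of a resampling design).
#'
#' @param pop_matrices Named list of [geno_matrix()] objects over the same
#'   sites (>= 2 populations).
#' @param equalize_n Individuals drawn per population (<= smallest
#'   population).
#' @param reps Iterations.
#' @param seed Integer seed.
#' @return Data.frame: `population`, `mean`, `se`, plus attribute
#'   `"per_rep"` (reps x populations matrix).
#' @export
private_alleles <- function(pop_matrices, equalize_n, reps = 100L, seed = 1L) {
  if (length(pop_matrices) < 2L) stop("private alleles require >= 2 populations")
  check_same_sites(pop_matrices)
  sizes <- vapply(pop_matrices, function(g) nrow(g$dosages), numeric(1))
  if (equalize_n > min(sizes)) {
    stop("equalize_n exceeds the smallest population (", min(sizes), ")")
  }
  withr::with_seed(as.integer(seed), {
    per_rep <- matrix(0, reps, length(pop_matrices))
    for (r in seq_len(reps)) {
      pres <- lapply(pop_matrices, function(g) {
        rows <- sample.int(nrow(g$dosages), equalize_n)
        allele_presence(g$dosages[rows, , drop = FALSE])
      })
      for (i in seq_along(pres)) {
        others_ref <- Reduce(`|`, lapply(pres[-i], `[[`, "ref"))
        others_alt <- Reduce(`|`, lapply(pres[-i], `[[`, "alt"))
        per_rep[r, i] <- sum(pres[[i]]$ref & !others_ref) +
          sum(pres[[i]]$alt & !others_alt)
      }
    }
    out <- data.frame(
      population = names(pop_matrices),
      mean = colMeans(per_rep),
      se = apply(per_rep, 2L, stats::sd),
      stringsAsFactors = FALSE
    )
    attr(out, "per_rep") <- per_rep
    out
  })
}

#' Alleles shared by exactly two of three populations
#'
#' For each pair of populations, counts alleles present in both members of
#' the pair and absent from the third, under the same equalized subsampling
#' design as [private_alleles()].
#'
#' @param pop_matrices Named list of exactly 3 [geno_matrix()] objects over
#'   the same sites.
#' @inheritParams private_alleles
#' @return Data.frame: `pair`, `mean`, `se`, with attribute `"per_rep"`.
#' @export
shared_alleles_pairwise <- function(pop_matrices, equalize_n, reps = 100L,
                                    seed = 1L) {
  if (length(pop_matrices) != 3L) stop("exactly 3 populations required")
  check_same_sites(pop_matrices)
  sizes <- vapply(pop_matrices, function(g) nrow(g$dosages), numeric(1))
  if (equalize_n > min(sizes)) {
    stop("equalize_n exceeds the smallest population (", min(sizes), ")")
  }
  pairs <- utils::combn(3L, 2L)
  pair_names <- apply(pairs, 2L, function(ix) {
    paste(names(pop_matrices)[ix], collapse = "|")
  })
  withr::with_seed(as.integer(seed), {
    per_rep <- matrix(0, reps, ncol(pairs))
    for (r in seq_len(reps)) {
      pres <- lapply(pop_matrices, function(g) {
        rows <- sample.int(nrow(g$dosages), equalize_n)
        allele_presence(g$dosages[rows, , drop = FALSE])
      })
      for (j in seq_len(ncol(pairs))) {
        i1 <- pairs[1L, j]; i2 <- pairs[2L, j]; i3 <- setdiff(1:3, pairs[, j])
        per_rep[r, j] <-
          sum(pres[[i1]]$ref & pres[[i2]]$ref & !pres[[i3]]$ref) +
          sum(pres[[i1]]$alt & pres[[i2]]$alt & !pres[[i3]]$alt)
      }
    }
    out <- data.frame(pair = pair_names, mean = colMeans(per_rep),
                      se = apply(per_rep, 2L, stats::sd),
                      stringsAsFactors = FALSE)
    attr(out, "per_rep") <- per_rep
    out
  })
}

check_same_sites <- function(pop_matrices) {
  ids <- lapply(pop_matrices, function(g) g$sites$id)
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("all population matrices must share the same sites in the same order")
  }
  invisible(TRUE)
}
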