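#' Resample a statistic under the study's subsampling designs
#'
#' Draws `reps` subsamples under one of the designs used to compare unequal
#' samples and evaluates a statistic on each draw:
#' * `"individuals"`: `n` individuals without replacement;
#' * `"loci"`: `n` sites, without replacement while `n` does not exceed the
#'   panel and with replacement (with a warning) beyond it;
#' * `"one_per_group"`: one randomly chosen individual per burrow system
#'   (`n` ignored);
#' * `"sex_partition"`: `n` individuals of the sex given by `sex`.
#'
#' Iterations are seeded as `seed + iteration`, so any single iteration is
#' reproducible in isolation. Draws on which the statistic is undefined
#' (`NA`) are redrawn up to 10 times and then recorded as `NA` with a
#' warning.
#'
#' @param gm A [geno_matrix()].
#' @param metadata Metadata data.frame (needed for `one_per_group` and
#'   `sex_partition`).
#' @param scheme One of `"individuals"`, `"loci"`, `"one_per_group"`,
#'   `"sex_partition"`.
#' @param n Subsample size (individuals or loci, per scheme).
#' @param reps Iterations.
#' @param statistic Function of a `geno_matrix` returning one number;
#'   defaults to SNP-site mean heterozygosity.
#' @param seed Integer seed.
#' @param sex `"M"` or `"F"` for `sex_partition`.
#' @return A `resampling_result` list: `scheme`, `n`, `reps`, `values`,
#'   `mean`, `sd`, `seed`.
#' @export
resample_statistic <- function(gm, metadata = NULL,
                               scheme = c("individuals", "loci",
                                          "one_per_group", "sex_partition"),
                               n = NULL, reps = 100L,
                               statistic = function(g) mean_heterozygosity(g),
                               seed = 1L, sex = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  scheme <- match.arg(scheme)
  md <- NULL
  if (scheme %in% c("one_per_group", "sex_partition")) {
    if (is.null(metadata)) stop("scheme '", scheme, "' requires metadata")
    md <- metadata[match(gm$samples, metadata$sample), ]
  }
  n_ind <- nrow(gm$dosages)
  n_sites <- ncol(gm$dosages)
  if (scheme == "individuals") {
    if (is.null(n) || n < 1L || n > n_ind) stop("infeasible n for individuals scheme")
  } else if (scheme == "loci") {
    if (is.null(n) || n < 1L) stop("infeasible n for loci scheme")
    if (n > n_sites) {
      warning("n (", n, ") exceeds the ", n_sites,
              "-site panel; subsampling loci with replacement")
    }
  } else if (scheme == "sex_partition") {
    if (is.null(sex) || !sex %in% c("M", "F")) stop("sex_partition needs sex 'M' or 'F'")
    avail <- sum(md$sex == sex)
    if (is.null(n) || n < 1L || n > avail) {
      stop("infeasible n: ", avail, " individuals of sex ", sex)
    }
  }
  draw_once <- function() {
    switch(scheme,
      individuals = subset_matrix(gm, samples = sample.int(n_ind, n)),
      loci = {
        idx <- if (n <= n_sites) sample.int(n_sites, n) else
          sample.int(n_sites, n, replace = TRUE)
        # with-replacement draws repeat columns; rebuild a matrix directly
        if (n <= n_sites) subset_matrix(gm, sites = idx) else
          geno_matrix(gm$dosages[, idx, drop = FALSE],
                      chrom = paste0("dup", seq_len(n)), pos = gm$sites$pos[idx])
      },
      one_per_group = {
        picks <- vapply(split(seq_len(n_ind), md$burrow), function(ix) {
          if (length(ix) == 1L) ix else sample(ix, 1L)
        }, numeric(1))
        subset_matrix(gm, samples = sort(picks))
      },
      sex_partition = {
        ix <- which(md$sex == sex)
        subset_matrix(gm, samples = sample(ix, n))
      }
    )
  }
  values <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(as.integer(seed) + r)
    val <- NA_real_
    for (attempt in 1:10) {
      val <- tryCatch(statistic(draw_once()), error = function(e) NA_real_)
      if (!is.na(val)) break
    }
    if (is.na(val)) warning("statistic undefined after 10 redraws at iteration ", r)
    values[r] <- val
  }
  structure(
    list(scheme = scheme, n = n, reps = reps, values = values,
         mean = mean(values, na.rm = TRUE), sd = stats::sd(values, na.rm = TRUE),
         seed = as.integer(seed)),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("resampling (%s, n=%s, reps=%d): mean=%.6g sd=%.6g\n",
              x$scheme, ifelse(is.null(x$n), "-", x$n), x$reps, x$mean, x$sd))
  invisible(x)
}

#' Standard deviation of mean heterozygosity versus number of loci
#'
#' For each panel size in `grid`, draws `reps` random locus subsets
#' (without replacement up to the panel size, with replacement beyond it)
#' and records the mean and SD of mean heterozygosity across draws. The
#' default grid is 50..1,000 in steps of 50, then 1,500..10,000 in steps of
#' 500.
#'
#' @param gm A [geno_matrix()].
#' @param grid Integer vector of locus counts (all >= 2).
#' @param reps Iterations per grid point.
#' @param seed Integer seed.
#' @param statistic Statistic evaluated per draw (default SNP-site mean
#'   heterozygosity).
#' @return Data.frame: `n`, `mean`, `sd`.
#' @export
loci_sd_curve <- function(gm, grid = default_loci_grid(), reps = 100L,
                          seed = 1L,
                          statistic = function(g) mean_heterozygosity(g)) {
  if (length(grid) == 0L) stop("empty grid")
  if (any(grid < 2L)) stop("grid values must be >= 2")
  rows <- lapply(seq_along(grid), function(i) {
    rs <- resample_statistic(gm, scheme = "loci", n = grid[i], reps = reps,
                             statistic = statistic,
                             seed = as.integer(seed) + 100000L * i)
    data.frame(n = grid[i], mean = rs$mean, sd = rs$sd)
  })
  do.call(rbind, rows)
}

#' @rdname loci_sd_curve
#' @export
default_loci_grid <- function() {
  unique(c(seq(50L, 1000L, by = 50L), seq(1000L, 10000L, by = 500L)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the exact small-sample distribution where
#' available and the asymptotic Kolmogorov distribution otherwise
#' (delegating to [stats::ks.test()]).
#'
#' @param x,y Non-empty numeric samples.
#' @return List: `D`, `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Welch's two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided
#' p-value (delegating to [stats::t.test()]). When both samples have zero
#' variance the test is degenerate: identical means return `t = 0, p = 1`,
#' otherwise `NA` with a warning.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return List: `t`, `p`, `df`.
#' @export
welch_t_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(list(t = 0, p = 1, df = NA_real_))
    warning("both samples have zero variance with different means; t undefined")
    return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  }
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
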