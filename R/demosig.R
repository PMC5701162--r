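#' Pairwise mismatch distribution
#'
#' For every pair of individuals, the genetic difference is the L1 distance
#' between dosage vectors over the sites non-missing in both (the number of
#' allele differences between unphased diploid genotypes); an
#' identity-by-state alternative counts sites with differing genotypes.
#' Differences are tabulated as relative frequencies over all
#' `choose(n, 2)` pairs.
#'
#' @param gm A [geno_matrix()] with >= 2 individuals.
#' @param metric `"dosage_l1"` (default) or `"ibs_mismatch"`.
#' @return A `mismatch_dist` list: `diff_classes` (integer classes `0..K`),
#'   `rel_freq`, `pair_diffs` (raw per-pair values), `n_pairs`, `metric`.
#' @export
mismatch_distribution <- function(gm, metric = c("dosage_l1", "ibs_mismatch")) {
  stopifnot(inherits(gm, "geno_matrix"))
  metric <- match.arg(metric)
  n <- nrow(gm$dosages)
  if (n < 2L) stop("mismatch distribution requires >= 2 individuals")
  d <- gm$dosages
  diffs <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(d[i, ]) & !is.na(d[j, ])
      k <- k + 1L
      diffs[k] <- if (metric == "dosage_l1") {
        sum(abs(d[i, both] - d[j, both]))
      } else {
        sum(d[i, both] != d[j, both])
      }
    }
  }
  classes <- 0:max(diffs)
  counts <- tabulate(diffs + 1L, nbins = length(classes))
  structure(
    list(diff_classes = classes, rel_freq = counts / length(diffs),
         pair_diffs = diffs, n_pairs = length(diffs), metric = metric),
    class = "mismatch_dist"
  )
}

#' Harpending's raggedness index
#'
#' Quantifies the spikiness of a mismatch distribution as the sum of squared
#' differences between adjacent class frequencies. Convention used here
#' (fixed by the tests): classes run contiguously from 0 to one past the
#' largest observed difference, absent classes carry frequency 0, and
#' `r = sum_{i=1}^{K+1} (x_i - x_{i-1})^2` over that padded axis — so a
#' distribution has a trailing "fall" term but no leading boundary term.
#'
#' @param dist A `mismatch_dist` from [mismatch_distribution()].
#' @return The raggedness index.
#' @export
raggedness <- function(dist) {
  stopifnot(inherits(dist, "mismatch_dist"))
  if (length(dist$rel_freq) == 0L) stop("empty mismatch distribution")
  x <- c(dist$rel_freq, 0)  # pad one class past the largest difference
  sum(diff(x)^2)
}

#' Compare two mismatch distributions after centering and re-scaling
#'
#' Each distribution's per-pair difference values are centered by their mean
#' and scaled by their SD, removing location (mean divergence) and scale so
#' that only shape is compared; the standardized samples then go through the
#' two-sample KS test.
#'
#' @param d1,d2 `mismatch_dist` objects.
#' @return List: `D`, `p`.
#' @export
compare_mismatch <- function(d1, d2) {
  stopifnot(inherits(d1, "mismatch_dist"), inherits(d2, "mismatch_dist"))
  s1 <- stats::sd(d1$pair_diffs)
  s2 <- stats::sd(d2$pair_diffs)
  if (s1 == 0 || s2 == 0) stop("zero-variance mismatch distribution cannot be re-scaled")
  z1 <- (d1$pair_diffs - mean(d1$pair_diffs)) / s1
  z2 <- (d2$pair_diffs - mean(d2$pair_diffs)) / s2
  ks_two_sample(z1, z2)
}

#' Random-survivorship drift simulation
#'
#' Emulates the immediate genetic effect of a die-off with no subsequent
#' drift: per iteration, `floor(fraction * N)` individuals are designated
#' survivors uniformly at random and the mean heterozygosity of the
#' survivors is recorded. Because survivors are a uniform subsample, the
#' expected survivor heterozygosity equals the full-sample value; the test
#' quantifies how far the observed runs sit from that null. Welch's t
#' compares the per-individual heterozygosities of the full sample with
#' those of the pooled survivors.
#'
#' @param gm A [geno_matrix()] with >= 4 individuals.
#' @param fraction Surviving fraction (default 0.5).
#' @param reps Iterations.
#' @param seed Integer seed.
#' @param denominator,callable_length Passed to the heterozygosity
#'   calculation.
#' @return List: `pre_mean`, `post_mean`, `post_sd` (across iteration
#'   means), `t`, `p`, `reps`, `n_survivors`.
#' @export
survivor_drift_sim <- function(gm, fraction = 0.5, reps = 100L, seed = 1L,
                               denominator = "snp_sites",
                               callable_length = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- nrow(gm$dosages)
  if (n < 4L) stop("survivor simulation requires >= 4 individuals")
  n_surv <- floor(fraction * n)
  if (n_surv < 2L) stop("survivor count < 2; increase fraction or sample size")
  het_full <- per_individual_het(gm, denominator, callable_length)
  if (n_surv == n) {
    return(list(pre_mean = mean(het_full), post_mean = mean(het_full),
                post_sd = 0, t = 0, p = 1, reps = reps, n_survivors = n_surv))
  }
  withr::with_seed(as.integer(seed), {
    rep_means <- numeric(reps)
    surv_het <- vector("list", reps)
    for (r in seq_len(reps)) {
      rows <- sample.int(n, n_surv)
      surv_het[[r]] <- het_full[rows]
      rep_means[r] <- mean(het_full[rows])
    }
    tt <- welch_t_two_sample(het_full, unlist(surv_het))
    list(pre_mean = mean(het_full), post_mean = mean(rep_means),
         post_sd = stats::sd(rep_means), t = tt$t, p = tt$p,
         reps = reps, n_survivors = n_surv)
  })
}
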