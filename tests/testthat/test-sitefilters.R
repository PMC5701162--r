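test_that("HWE exact p-values match full enumeration for n <= 6", {
  expect_equal(hwe_exact_pvalue(2, 0, 0), 1)        # monomorphic convention
  expect_equal(hwe_exact_pvalue(1, 0, 1), 1 / 3)    # Levene by hand
  for (n_AA in 0:3) for (n_Aa in 0:4) for (n_aa in 0:3) {
    n <- n_AA + n_Aa + n_aa
    if (n < 1 || n > 6) next
    expect_equal(
      hwe_exact_pvalue(n_AA, n_Aa, n_aa),
      oracle_hwe_enum(n_AA, n_Aa, n_aa),
      tolerance = 1e-12,
      label = sprintf("counts (%d,%d,%d)", n_AA, n_Aa, n_aa)
    )
  }
  expect_error(hwe_exact_pvalue(-1, 0, 1), ">= 0")
})

test_that("HWE p-values are valid and conservative under the null", {
  # the exact conditional test is discrete, so its null p-values are
  # stochastically larger than uniform: rejection rates must never exceed
  # the nominal level (within binomial noise) at any threshold
  withr::with_seed(77, {
    pvals <- replicate(2000, {
      p <- runif(1, 0.1, 0.9)
      g <- rbinom(30, 2, p)
      hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
    })
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 2000),
               label = sprintf("rejection rate at alpha = %.2f", alpha))
  }
  expect_true(all(pvals >= 0 & pvals <= 1 + 1e-12))
  # and it is not degenerate: small p-values do occur under the null
  expect_gt(mean(pvals <= 0.1), 0.01)
})

test_that("outlier scan refuses coarse envelopes and single populations", {
  gm <- gm_random_hw(20, runif(30, 0.2, 0.8), seed = 1)
  labs <- rep(c("a", "b"), each = 10)
  expect_error(fst_outlier_scan(gm, labs, n_sims = 500), "too coarse")
  expect_error(fst_outlier_scan(gm, rep("a", 20), n_sims = 2000), ">= 2 populations")
})

test_that("outlier scan controls the flagged fraction on neutral data", {
  frac <- vapply(1:20, function(rep_i) {
    cfg <- sim_config(200, 60, 0, generations_pre = 12, generations_post = 0,
                      migration_rate = 0.05, n_demes = 2,
                      initial_freq_spec = "uniform", seed = 100 + rep_i)
    h <- simulate_populations(cfg)
    plan <- sampling_plan(data.frame(
      deme = c(1, 2), generation = 12, n = c(20, 20), n_burrows = c(20, 20),
      label = c("d1", "d2"), population = c("d1", "d2"),
      period = c("pre", "pre")))
    ds <- draw_samples(h, plan, seed = 200 + rep_i)
    seg <- is_segregating(ds$genotypes)
    gm <- subset_matrix(ds$genotypes, sites = which(seg))
    scan <- fst_outlier_scan(gm, ds$metadata$population, n_sims = 4000,
                             fdr = 0.1, seed = 300 + rep_i)
    length(scan$outliers) / ncol(gm$dosages)
  }, numeric(1))
  n_sites_mean <- 150
  bound <- 0.1 + 3 * sqrt(0.1 * 0.9 / (20 * n_sites_mean))
  expect_lt(mean(frac), bound)
})

test_that("a fixed between-deme difference is flagged among neutral sites", {
  hits <- vapply(1:20, function(rep_i) {
    withr::with_seed(1000 + rep_i, {
      p <- runif(500, 0.1, 0.9)
      # two demes at FST ~ 0.01 around shared frequencies
      f <- 0.01
      pa <- rbeta(500, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      pb <- rbeta(500, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      da <- sapply(pa, function(q) rbinom(25, 2, q))
      db <- sapply(pb, function(q) rbinom(25, 2, q))
      dos <- rbind(da, db)
      dos[1:25, 1] <- 0L   # injected fixed difference at site 1
      dos[26:50, 1] <- 2L
      rownames(dos) <- sprintf("i%02d", 1:50)
      gm <- gm_from(dos)
    })
    scan <- fst_outlier_scan(gm, rep(c("a", "b"), each = 25), n_sims = 50000,
                             fdr = 0.1, seed = 2000 + rep_i)
    gm$sites$id[1] %in% scan$outliers
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("identical populations produce flags within the FDR bound", {
  gm0 <- gm_random_hw(15, runif(300, 0.1, 0.9), seed = 5)
  dos <- rbind(gm0$dosages, gm0$dosages)
  rownames(dos) <- sprintf("i%03d", seq_len(nrow(dos)))
  gm <- gm_from(dos)
  scan <- fst_outlier_scan(gm, rep(c("a", "b"), each = 15), n_sims = 5000,
                           fdr = 0.1, seed = 6)
  expect_lte(length(scan$outliers) / 300, 0.1 + 3 * sqrt(0.1 * 0.9 / 300))
})

test_that("filter application reconciles counts and is idempotent", {
  withr::with_seed(8, {
    dos <- sapply(runif(40, 0.2, 0.8), function(p) rbinom(24, 2, p))
    # force two sites far out of HW: all heterozygous
    dos[, 3] <- 1L
    dos[, 17] <- 1L
    rownames(dos) <- sprintf("i%02d", 1:24)
    gm <- gm_from(dos)
  })
  out <- apply_site_filters(gm, hwe_alpha = 0.05,
                            outliers = gm$sites$id[c(5, 9)])
  rep <- out$report
  expect_true(all(c("r1:3", "r1:17") %in% rep$hwe_removed$site))
  n_removed <- length(union(unique(rep$hwe_removed$site), rep$outlier_removed))
  expect_equal(rep$kept + n_removed, rep$n_input)
  expect_equal(ncol(out$genotypes$dosages), rep$kept)
  expect_false(any(out$genotypes$sites$id %in%
                     c(rep$hwe_removed$site, rep$outlier_removed)))
  # idempotent: filtering the filtered panel removes nothing
  again <- apply_site_filters(out$genotypes, hwe_alpha = 0.05)
  expect_identical(again$genotypes$dosages, out$genotypes$dosages)
  # no failures -> identity
  clean <- apply_site_filters(out$genotypes, hwe_alpha = 1e-12)
  expect_identical(clean$genotypes$dosages, out$genotypes$dosages)
  expect_error(apply_site_filters(gm, outliers = gm$sites$id, hwe_alpha = 0),
               "all sites removed")
})
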