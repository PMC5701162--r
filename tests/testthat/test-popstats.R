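test_that("mean heterozygosity honours both denominator modes", {
  gm <- gm_from(matrix(c(0L, 1L), 2, 1, dimnames = list(c("a", "b"), NULL)))
  expect_equal(mean_heterozygosity(gm), 0.5)
  hom <- gm_from(matrix(c(0L, 2L, 2L, 0L), 2, 2,
                        dimnames = list(c("a", "b"), NULL)))
  expect_equal(mean_heterozygosity(hom), 0)
  expect_equal(mean_heterozygosity(hom, "all_callable_sites",
                                   callable_length = 6000), 0)
  # 10 het genotypes per individual over 6 kb callable
  d <- matrix(1L, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  gm10 <- gm_from(d)
  expect_equal(
    mean_heterozygosity(gm10, "all_callable_sites", callable_length = 6000),
    10 / 6000
  )
  expect_error(mean_heterozygosity(gm10, "all_callable_sites"), "callable_length")
  # missing genotypes leave numerator and snp denominator
  dm <- matrix(c(1L, NA, 1L, 1L), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(mean_heterozygosity(gm_from(dm)), mean(c(1, 1)))
})

test_that("per-site pi and thetaW follow their closed forms", {
  # n = 4 alleles, alt count 2: pi = 4/6
  gm <- gm_from(matrix(c(1L, 1L, 1L, 0L, 2L, 2L), 2, 3,
                       dimnames = list(c("a", "b"), NULL)))
  ps <- per_site_diversity(gm)
  expect_equal(ps$pi[1], 2 * (4 - 2) / choose(4, 2))
  expect_equal(ps$theta_w[1], 1 / (1 + 1/2 + 1/3))   # segregating, a3 = 11/6
  expect_equal(ps$pi[2], 1 * 3 / choose(4, 2))
  expect_equal(ps$theta_w[3], 0)                      # monomorphic site
  expect_equal(ps$pi[3], 0)
  # n = 2 segregating: thetaW = 1
  gm2 <- gm_from(matrix(1L, 1, 1, dimnames = list("a", NULL)))
  expect_equal(per_site_diversity(gm2)$theta_w, 1)
  # pairwise enumeration oracle at one site: alleles {0,0,1,1}
  alleles <- c(0, 0, 1, 1)
  pairs <- combn(4, 2)
  pi_oracle <- mean(apply(pairs, 2, function(ix) alleles[ix[1]] != alleles[ix[2]]))
  expect_equal(ps$pi[1], pi_oracle)
})

test_that("pi and thetaW are unbiased on coalescent-law sites", {
  theta <- 0.05
  gm <- coalescent_sites(n_dip = 15, n_sites = 2000, theta = theta, seed = 31)
  ps <- per_site_diversity(gm)
  for (est in list(ps$pi, ps$theta_w)) {
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - theta), 3 * se)
  }
})

test_that("windowed Tajima's D matches the independent textbook evaluation", {
  # fewer than 4 haplotypes: D undefined, window omitted
  gm0 <- gm_from(matrix(1L, 1, 1, dimnames = list("a", NULL)))
  expect_equal(nrow(tajimas_d_windows(gm0)), 0L)
  # exact zero numerator: with n = 4 haplotypes, 8 singletons + 3 doubletons
  # give sum(pi) = 8/2 + 3*(2/3) = 6 = S/a1 = 11/(11/6)
  dz <- cbind(matrix(rep(c(1L, 0L), 8), 2, 8),
              matrix(rep(c(0L, 2L), 3), 2, 3))
  rownames(dz) <- c("a", "b")
  gmz <- gm_from(dz)
  wz <- tajimas_d_windows(gmz, window_bp = 100)
  expect_equal(wz$value, 0)
  # singleton-only window is negative and equals the oracle
  dos <- matrix(0L, 2, 6, dimnames = list(c("a", "b"), NULL))
  dos[1, ] <- 1L  # every site a singleton (n = 4, c = 1)
  gm1 <- gm_from(dos, chrom = rep("r1", 6), pos = 1:6)
  w <- tajimas_d_windows(gm1, window_bp = 100)
  expect_equal(nrow(w), 1L)
  expect_lt(w$value, 0)
  expect_equal(w$value, oracle_tajima_d(gm1), tolerance = 1e-12)
  # whole-matrix windows equal the oracle over 50 simulated datasets
  for (i in 1:50) {
    gm <- coalescent_sites(n_dip = 8, n_sites = 60, theta = 0.05, seed = 500 + i)
    seg <- is_segregating(gm)
    if (!any(seg)) next
    w <- tajimas_d_windows(gm, window_bp = 1000)
    expect_equal(w$value, oracle_tajima_d(gm), tolerance = 1e-6,
                 label = paste("dataset", i))
  }
})

test_that("Tajima's D is near zero under neutrality, negative after expansion", {
  d_vals <- vapply(1:50, function(i) {
    gm <- coalescent_sites(n_dip = 12, n_sites = 400, theta = 0.08,
                           seed = 900 + i)
    tajimas_d_windows(gm, window_bp = 1000)$value[1]
  }, numeric(1))
  expect_lt(abs(mean(d_vals)), 0.3)
  # singleton excess (expansion-like spectrum) drives D negative
  withr::with_seed(41, {
    dos <- matrix(0L, 12, 400, dimnames = list(sprintf("i%02d", 1:12), NULL))
    for (j in 1:400) dos[sample.int(12, 1), j] <- 1L
    gme <- gm_from(dos)
  })
  expect_lt(tajimas_d_windows(gme, window_bp = 1000)$value[1], -1)
})

test_that("folded SFS folds correctly and matches the neutral 1/i law", {
  # 4 haplotypes, minor counts {1,1,2} -> classes {1:2, 2:1}
  dos <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L))
  rownames(dos) <- c("a", "b")
  gm <- gm_from(dos)
  sfs <- folded_sfs(gm, subsample_n = 2, reps = 3, seed = 1)
  expect_equal(sfs$class_counts, c(2, 1))
  expect_equal(sfs$n_haplotypes, 4L)
  # subsampling everyone: zero SD across reps
  expect_equal(apply(sfs$per_rep, 2, sd), c(0, 0))
  expect_error(folded_sfs(gm, subsample_n = 1), ">= 2")
  expect_error(folded_sfs(gm, subsample_n = 5), "exceeds")
  # neutral spectrum: folded class proportions follow (1/i + 1/(n-i)) / a_n
  gmn <- coalescent_sites(n_dip = 10, n_sites = 2000, theta = 0.05, seed = 61)
  sfsn <- folded_sfs(gmn, subsample_n = 10, reps = 1, seed = 2)
  n_hap <- 20
  i_cls <- seq_len(n_hap %/% 2)
  expected_w <- 1 / i_cls + ifelse(i_cls < n_hap - i_cls, 1 / (n_hap - i_cls), 0)
  expected_p <- expected_w / sum(expected_w)
  counts <- sfsn$class_counts
  total <- sum(counts)
  se <- sqrt(expected_p * (1 - expected_p) * total)
  expect_true(all(abs(counts - expected_p * total) < 3 * se + 2))
})

test_that("inbreeding F matches its oracle and limiting behaviour", {
  gm <- gm_random_hw(20, runif(80, 0.2, 0.8), seed = 71)
  f <- inbreeding_f(gm)
  expect_equal(unname(f), oracle_inbreeding_f(gm), tolerance = 1e-6)
  # an individual homozygous everywhere in a polymorphic panel has F > 0
  dos <- gm$dosages
  dos[1, ] <- ifelse(runif(80) < 0.5, 0L, 2L)
  f2 <- inbreeding_f(gm_from(dos))
  expect_gt(f2[1], 0.5)
  expect_error(inbreeding_f(gm_from(matrix(0L, 1, 3,
                                           dimnames = list("a", NULL)))),
               ">= 2 individuals")
})

test_that("private and shared allele counts equal brute-force enumeration", {
  withr::with_seed(81, {
    dos_list <- lapply(1:3, function(i) {
      d <- sapply(runif(10, 0.05, 0.95), function(p) rbinom(6, 2, p))
      rownames(d) <- sprintf("p%d_i%d", i, 1:6)
      d
    })
  })
  gms <- lapply(dos_list, gm_from)
  names(gms) <- c("A", "B", "C")
  # equalize_n = all individuals, one rep: deterministic, equals set algebra
  priv <- private_alleles(gms, equalize_n = 6, reps = 1, seed = 1)
  oracle <- oracle_allele_classes(dos_list)
  expect_equal(priv$mean, as.numeric(oracle$private))
  sh <- shared_alleles_pairwise(gms, equalize_n = 6, reps = 1, seed = 1)
  for (j in seq_len(nrow(sh))) {
    key <- c("A|B" = "1|2", "A|C" = "1|3", "B|C" = "2|3")[sh$pair[j]]
    expect_equal(sh$mean[j], oracle$shared[[key]] %||% 0)
  }
  # private + shared-by-two + universal partition all observed alleles
  pres_total <- sum(sapply(dos_list, function(d) {
    sum(apply(d, 2, function(g) any(g < 2))) + sum(apply(d, 2, function(g) any(g > 0)))
  }))
  n_obs_alleles <- sum(oracle$private) +
    2 * sum(unlist(oracle$shared)) + 3 * oracle$universal
  expect_equal(pres_total, n_obs_alleles)
  # trivial cases
  a <- gm_from(matrix(1L, 1, 1, dimnames = list("x", NULL)))
  b <- gm_from(matrix(0L, 1, 1, dimnames = list("y", NULL)))
  pv <- private_alleles(list(A = a, B = b), equalize_n = 1, reps = 1, seed = 1)
  expect_equal(pv$mean, c(1, 0))  # alt private to A only
  same <- private_alleles(list(A = a, B = a), equalize_n = 1, reps = 1, seed = 1)
  expect_equal(same$mean, c(0, 0))
  expect_error(shared_alleles_pairwise(list(A = a, B = b), 1), "exactly 3")
  expect_error(private_alleles(list(A = a, B = b), equalize_n = 5), "smallest")
})
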