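test_that("invalid configurations are rejected naming the violated bound", {
  expect_error(sim_config(0, 50, 0.5), "n_loci")
  expect_error(sim_config(10, 1, 0.5), "ne_pre")
  expect_error(sim_config(10, 50, 1.0), "decline_fraction")
  expect_error(sim_config(10, 50, -0.1), "decline_fraction")
  expect_error(sim_config(10, 50, 0.5, migration_rate = 0.7), "migration_rate")
})

test_that("the event is instantaneous size bookkeeping", {
  cfg <- sim_config(5, 50, 0.5, generations_pre = 10, generations_post = 10,
                    seed = 1)
  h <- simulate_populations(cfg)
  expect_equal(h$deme_sizes[1:10], rep(50L, 10))       # generations 0..9
  expect_equal(h$deme_sizes[11:21], rep(25L, 11))      # generations 10..20
  expect_true(all(h$freqs >= 0 & h$freqs <= 1))
})

test_that("drift is a martingale: mean final frequency matches the initial", {
  cfg <- sim_config(1000, 50, 0, generations_pre = 10, generations_post = 0,
                    initial_freq_spec = "uniform", seed = 11)
  h <- simulate_populations(cfg)
  p0 <- h$freqs[, 1, 1]
  pT <- h$freqs[, 1, 11]
  # E[pT - p0] = 0; MC error of the mean difference
  se <- sd(pT - p0) / sqrt(length(p0))
  expect_lt(abs(mean(pT - p0)), 3 * se)
})

test_that("heterozygosity decays as H0 (1 - 1/(2N))^t after the event", {
  t_post <- 8
  N <- 25
  cfg <- sim_config(2000, 50, 0.5, generations_pre = 2, generations_post = t_post,
                    initial_freq_spec = "uniform", seed = 5)
  h <- simulate_populations(cfg)
  g_event <- 2
  p_event <- h$freqs[, 1, g_event + 1]
  p_final <- h$freqs[, 1, dim(h$freqs)[3]]
  h0 <- mean(2 * p_event * (1 - p_event))
  h_final <- mean(2 * p_final * (1 - p_final))
  expected <- h0 * (1 - 1 / (2 * N))^t_post
  se <- sd(2 * p_final * (1 - p_final)) / sqrt(length(p_final))
  expect_lt(abs(h_final - expected), 3 * se)
})

test_that("sampled genotypes obey the true frequencies", {
  cfg <- sim_config(1000, 200, 0, generations_pre = 2, generations_post = 0,
                    initial_freq_spec = "uniform", seed = 9)
  h <- simulate_populations(cfg)
  plan <- sampling_plan(data.frame(
    deme = 1, generation = 2, n = 30, n_burrows = 30, label = "X",
    population = "P", period = "pre"), sibship_rate = 0)
  ds <- draw_samples(h, plan, seed = 10)
  expect_equal(nrow(ds$genotypes$dosages), 30L)
  # chi-square goodness of fit of genotype classes to HW at the true
  # frequency, pooled over loci: under the null the z-scores of the het
  # count are standard normal
  p_true <- h$freqs[, 1, 3]
  het_obs <- colSums(ds$genotypes$dosages == 1L)
  mu <- 30 * 2 * p_true * (1 - p_true)
  v <- 30 * 2 * p_true * (1 - p_true) * (1 - 2 * p_true * (1 - p_true))
  z <- (het_obs - mu) / sqrt(pmax(v, 1e-12))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 1.5)
  expect_lt(abs(sd(z) - 1), 0.1)
})

test_that("a fixed locus yields only homozygous-alternate genotypes", {
  cfg <- sim_config(3, 10, 0, generations_pre = 1, generations_post = 0, seed = 2)
  h <- simulate_populations(cfg)
  h$freqs[1, 1, ] <- 1  # pin a locus at fixation
  plan <- sampling_plan(data.frame(
    deme = 1, generation = 1, n = 6, n_burrows = 6, label = "X",
    population = "P", period = "pre"))
  ds <- draw_samples(h, plan, seed = 3)
  expect_true(all(ds$genotypes$dosages[, 1] == 2L))
})

test_that("cohorts larger than the deme census are rejected", {
  cfg <- sim_config(5, 10, 0.5, generations_pre = 2, generations_post = 1, seed = 4)
  h <- simulate_populations(cfg)
  plan <- sampling_plan(data.frame(
    deme = 1, generation = 3, n = 9, n_burrows = 9, label = "X",
    population = "P", period = "post"))
  expect_error(draw_samples(h, plan, seed = 1), "exceeds deme census")
})

test_that("study presets reproduce the sampling design and are deterministic", {
  ds <- emulate_study("speciesA", seed = 7)
  expect_equal(nrow(ds$genotypes$dosages), 57L)
  expect_equal(ncol(ds$genotypes$dosages), 531L)
  expect_equal(sum(ds$metadata$period == "pre"), 17L)
  expect_equal(sum(ds$metadata$period == "post" &
                     ds$metadata$population == "RinconGrande"), 31L)
  expect_equal(sum(ds$metadata$population == "LaLonja"), 9L)
  expect_equal(length(unique(ds$metadata$burrow[ds$metadata$period == "pre"])), 13L)
  dsB <- emulate_study("speciesB", seed = 7)
  expect_equal(nrow(dsB$genotypes$dosages), 29L)
  expect_equal(ncol(dsB$genotypes$dosages), 449L)
  expect_error(emulate_study("speciesC", seed = 1), "unknown preset")

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  emulate_study("speciesB", seed = 13, out_dir = dir1)
  emulate_study("speciesB", seed = 13, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "speciesB.vcf")),
                   readLines(file.path(dir2, "speciesB.vcf")))
  expect_identical(readLines(file.path(dir1, "speciesB_metadata.tsv")),
                   readLines(file.path(dir2, "speciesB_metadata.tsv")))
})

test_that("equilibrium FST between two demes decreases with migration", {
  fst_at <- function(m) {
    cfg <- sim_config(500, 50, 0, generations_pre = 40, generations_post = 0,
                      migration_rate = m, n_demes = 2,
                      initial_freq_spec = "uniform", seed = 21)
    h <- simulate_populations(cfg)
    plan <- sampling_plan(data.frame(
      deme = c(1, 2), generation = 40, n = c(20, 20), n_burrows = c(20, 20),
      label = c("d1", "d2"), population = c("d1", "d2"),
      period = c("pre", "pre")))
    ds <- draw_samples(h, plan, seed = 22)
    weir_cockerham_fst(ds$genotypes, ds$metadata$population)$fst
  }
  fsts <- vapply(c(0.002, 0.02, 0.2), fst_at, numeric(1))
  expect_true(fsts[1] > fsts[2] && fsts[2] > fsts[3])
})
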