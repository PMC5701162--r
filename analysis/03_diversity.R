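#!/usr/bin/env Rscript
# Stage 3: within-population diversity.
#
# Mean observed heterozygosity per population x period with the study's
# equalizing designs (100x bootstrap over individuals, 100x subsamples of
# 100 loci, one-per-burrow, sex partitions), per-site thetaW and pi
# distributions, 20x-equalized folded SFS, inbreeding F, and private /
# pairwise-shared alleles under 100x equalized subsampling.

library(eruptpop)

seed <- 20110604
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

for (preset in c("speciesA", "speciesB")) {
  gm <- read_vcf(file.path("results/filtered", paste0(preset, ".filtered.vcf")))
  md <- read_metadata(file.path("results/data", paste0(preset, "_metadata.tsv")),
                      samples = gm$samples)
  md <- md[match(gm$samples, md$sample), ]
  group <- paste(md$population, md$period, sep = ".")
  groups <- split(seq_along(group), group)
  sub <- lapply(groups, function(ix) subset_matrix(gm, samples = ix))
  eq_n <- min(lengths(groups))

  rows <- lapply(names(sub), function(g) {
    boot_i <- resample_statistic(sub[[g]], scheme = "individuals", n = eq_n,
                                 reps = 100, seed = seed + 11)
    boot_l <- resample_statistic(sub[[g]], scheme = "loci",
                                 n = min(100, ncol(gm$dosages)),
                                 reps = 100, seed = seed + 12)
    ps <- suppressMessages(per_site_diversity(sub[[g]]))
    f <- suppressMessages(inbreeding_f(sub[[g]]))
    data.frame(
      group = g, n = length(groups[[g]]),
      mean_het = mean_heterozygosity(sub[[g]]),
      het_boot_ind = boot_i$mean, het_boot_ind_sd = boot_i$sd,
      het_boot_loci = boot_l$mean, het_boot_loci_sd = boot_l$sd,
      mean_theta_w = mean(ps$theta_w), mean_pi = mean(ps$pi),
      mean_F = mean(f, na.rm = TRUE)
    )
  })
  tab <- do.call(rbind, rows)
  write.table(tab, file.path("results/tables", paste0(preset, "_diversity.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(preset, "diversity by group:\n")
  print(tab, digits = 4)

  # one-per-burrow control for the colonial species' kin structure
  if (preset == "speciesA") {
    for (g in c("RinconGrande.pre", "RinconGrande.post")) {
      opb <- resample_statistic(sub[[g]], md[groups[[g]], ],
                                scheme = "one_per_group", reps = 100,
                                seed = seed + 13)
      cat(sprintf("  one-per-burrow het %s: %.4f (sd %.4f)\n",
                  g, opb$mean, opb$sd))
    }
  }

  # equalized folded SFS, pre vs post of the focal population
  pre_ix <- which(md$period == "pre")
  post_ix <- which(md$period == "post" &
                     md$population %in% md$population[pre_ix])
  n_eq <- min(length(pre_ix), length(post_ix))
  sfs_pre <- folded_sfs(subset_matrix(gm, samples = pre_ix), n_eq,
                        reps = 20, seed = seed + 14)
  sfs_post <- folded_sfs(subset_matrix(gm, samples = post_ix), n_eq,
                         reps = 20, seed = seed + 15)
  sfs_tab <- data.frame(minor_count = seq_along(sfs_pre$class_counts),
                        pre = sfs_pre$class_counts,
                        post = sfs_post$class_counts)
  write.table(sfs_tab, file.path("results/tables", paste0(preset, "_sfs.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  SFS (n = %d individuals, 20 reps): singleton class pre %.1f / post %.1f\n",
              n_eq, sfs_tab$pre[1], sfs_tab$post[1]))

  # private and shared alleles under equalized subsampling
  priv <- private_alleles(sub, equalize_n = eq_n, reps = 100, seed = seed + 16)
  write.table(priv, file.path("results/tables", paste0(preset, "_private.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(priv, digits = 4)
  if (length(sub) == 3) {
    sh <- shared_alleles_pairwise(sub, equalize_n = eq_n, reps = 100,
                                  seed = seed + 17)
    write.table(sh, file.path("results/tables", paste0(preset, "_shared.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    print(sh, digits = 4)
  }
}
cat("diversity tables written under results/tables/\n")
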