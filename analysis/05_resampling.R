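#!/usr/bin/env Rscript
# Stage 5: effect of the number of loci examined, and the pre/post
# significance tests.
#
# For each focal population, the SD of mean heterozygosity across 100
# random locus subsamples over the study grid (50..1,000 by 50, then
# 1,500..10,000 by 500; draws beyond the panel are with replacement).
# Pre/post per-site heterozygosity distributions are compared by the
# two-sample KS test and Welch's t.

library(eruptpop)

seed <- 20110604
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

for (preset in c("speciesA", "speciesB")) {
  gm <- read_vcf(file.path("results/filtered", paste0(preset, ".filtered.vcf")))
  md <- read_metadata(file.path("results/data", paste0(preset, "_metadata.tsv")),
                      samples = gm$samples)
  md <- md[match(gm$samples, md$sample), ]
  group <- paste(md$population, md$period, sep = ".")

  for (g in unique(group)) {
    sub <- subset_matrix(gm, samples = which(group == g))
    curve <- suppressWarnings(
      loci_sd_curve(sub, reps = 100, seed = seed + 30)
    )
    write.table(curve,
                file.path("results/tables",
                          sprintf("%s_%s_loci_curve.tsv", preset, g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%s %s: sd(het) falls %.4f -> %.4f over n = 50..10,000\n",
                preset, g, curve$sd[1], curve$sd[nrow(curve)]))
  }

  pre <- subset_matrix(gm, samples = which(md$period == "pre"))
  post <- subset_matrix(gm, samples = which(md$period == "post" &
                          md$population %in% md$population[md$period == "pre"]))
  het_pre <- colMeans(pre$dosages == 1L, na.rm = TRUE)
  het_post <- colMeans(post$dosages == 1L, na.rm = TRUE)
  ks <- ks_two_sample(het_pre, het_post)
  tt <- welch_t_two_sample(het_pre, het_post)
  cat(sprintf("%s pre vs post per-site het: KS D = %.4f (p = %.3g), Welch t = %.3f (p = %.3g)\n",
              preset, ks$D, ks$p, tt$t, tt$p))
}
cat("loci curves written under results/tables/\n")
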