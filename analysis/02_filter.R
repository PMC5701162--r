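#!/usr/bin/env Rscript
# Stage 2: neutrality site filters.
#
# Per-population exact Hardy-Weinberg test (alpha 0.05) plus an FDIST-style
# FST-outlier scan (50,000 neutral simulations, FDR 0.1) over the
# population x period groups, so that downstream comparisons reflect
# neutral, genome-wide processes. Filtered VCFs and a filter report go to
# results/filtered/.

library(eruptpop)

seed <- 20110604
dir.create("results/filtered", showWarnings = FALSE, recursive = TRUE)

for (preset in c("speciesA", "speciesB")) {
  gm <- read_vcf(file.path("results/data", paste0(preset, ".vcf")))
  md <- read_metadata(file.path("results/data", paste0(preset, "_metadata.tsv")),
                      samples = gm$samples)
  md <- md[match(gm$samples, md$sample), ]
  group <- paste(md$population, md$period, sep = ".")
  scan <- fst_outlier_scan(gm, group, n_sims = 50000, fdr = 0.1,
                           seed = seed + 1)
  filt <- apply_site_filters(gm, metadata = md, hwe_alpha = 0.05,
                             outliers = scan$outliers)
  print(filt$report)
  write_vcf(filt$genotypes,
            file.path("results/filtered", paste0(preset, ".filtered.vcf")))
  report <- list(
    n_input = filt$report$n_input, kept = filt$report$kept,
    hwe_removed = unique(filt$report$hwe_removed$site),
    outlier_removed = filt$report$outlier_removed,
    envelope_mean_fst = scan$mean_fst
  )
  jsonlite::write_json(report,
                       file.path("results/filtered", paste0(preset, "_filter.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
cat("filtered panels written under results/filtered/\n")
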