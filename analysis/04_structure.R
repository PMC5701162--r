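#!/usr/bin/env Rscript
# Stage 4: differentiation among populations.
#
# Pairwise Weir-Cockerham FST for all conspecific population x period
# groups, genotype PCA (Patterson normalization), and EM admixture at
# K = 2..3 (the study's a priori hypotheses) plus an exploratory K sweep.

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

  pairs <- combn(names(groups), 2)
  fst_tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    ix <- c(groups[[pairs[1, j]]], groups[[pairs[2, j]]])
    est <- weir_cockerham_fst(subset_matrix(gm, samples = ix), group[ix])
    data.frame(pop1 = pairs[1, j], pop2 = pairs[2, j], fst = est$fst,
               n_sites = est$n_sites_used)
  }))
  write.table(fst_tab, file.path("results/tables", paste0(preset, "_fst.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(preset, "pairwise FST:\n")
  print(fst_tab, digits = 4)

  pc <- pca_genotypes(gm)
  pc_tab <- data.frame(sample = rownames(pc$coords), group = group,
                       round(pc$coords[, 1:4], 6))
  write.table(pc_tab, file.path("results/tables", paste0(preset, "_pca.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * pc$explained[1], 100 * pc$explained[2]))

  k_values <- if (preset == "speciesA") 2:3 else 2
  for (K in c(k_values, 6)) {
    fit <- admixture_em(gm, K = K, seed = seed + 20 + K, n_starts = 10)
    q_tab <- data.frame(sample = rownames(fit$Q), group = group,
                        round(fit$Q, 6))
    write.table(q_tab,
                file.path("results/tables", sprintf("%s_admixture_K%d.tsv",
                                                    preset, K)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("  admixture K=%d: loglik %.1f, converged %s\n",
                K, fit$loglik, fit$converged))
  }
}
cat("structure tables written under results/tables/\n")
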