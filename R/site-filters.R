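#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test of Hardy-Weinberg genotype proportions from the
#' conditional (Levene/Haldane) distribution of the heterozygote count given
#' the observed allele counts. The p-value sums the probabilities of every
#' heterozygote count whose conditional probability does not exceed that of
#' the observed count (probability-mass two-sided convention).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return The exact p-value. Monomorphic sites return 1 by convention.
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  hs <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  # log P(het = h | n, nA) up to the shared normalising constant
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Scan for FST outlier sites against a neutral island-model envelope
#'
#' An FDIST-style test for loci under putative directional selection. For
#' each site the expected heterozygosity (He, from the pooled allele
#' frequency) and the Weir-Cockerham FST are computed. A neutral envelope is
#' then simulated at the multi-locus mean FST: per simulated site an
#' ancestral frequency is resampled from the observed pooled frequencies,
#' deme frequencies are drawn from the matching beta distribution
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)`, the island-model stationary
#' approximation with mean `p` and variance `F p (1-p)`), and genotypes are
#' sampled at the observed per-population sample sizes. Each observed site
#' receives an empirical upper-tail p-value against the simulated sites
#' nearest to it in He (a fraction `envelope_frac` of the envelope, so the
#' p-value resolution `1/(k+1)` stays fine enough for Benjamini-Hochberg
#' control at `fdr` across hundreds of sites). Only the upper
#' (directional-selection) tail is tested.
#'
#' @param gm A [geno_matrix()].
#' @param pop_labels Population label per individual (>= 2 populations).
#' @param n_sims Simulated neutral sites for the envelope (>= 1,000).
#' @param fdr False discovery rate for Benjamini-Hochberg control.
#' @param seed Integer seed.
#' @param envelope_frac Fraction of the simulated sites, nearest in He,
#'   conditioning each observed site's p-value.
#' @return List: `outliers` (site ids flagged), `table` (per-site He, FST,
#'   empirical p, BH-adjusted p), `mean_fst` (envelope parameter).
#' @export
fst_outlier_scan <- function(gm, pop_labels, n_sims = 50000L, fdr = 0.1,
                             seed = 1L, envelope_frac = 0.25) {
  stopifnot(inherits(gm, "geno_matrix"))
  pops <- unique(pop_labels)
  if (length(pops) < 2L) stop("outlier scan requires >= 2 populations")
  if (n_sims < 1000L) stop("n_sims < 1,000 gives too coarse an envelope; refused")
  if (length(pop_labels) != nrow(gm$dosages)) {
    stop("pop_labels must have one entry per individual")
  }
  withr::with_seed(as.integer(seed), {
    comp <- wc_components(gm$dosages, pop_labels)
    usable <- comp$usable
    fst_obs <- comp$a / (comp$a + comp$b + comp$c)
    p_pool <- allele_freqs(gm)
    he_obs <- 2 * p_pool * (1 - p_pool)
    mean_fst <- sum(comp$a[usable]) / sum((comp$a + comp$b + comp$c)[usable])
    f_env <- min(max(mean_fst, 1e-3), 0.99)
    n_per_pop <- vapply(
      pops,
      function(p) stats::median(rowSums(!is.na(t(gm$dosages[pop_labels == p, , drop = FALSE])))),
      numeric(1)
    )
    n_per_pop <- pmax(2L, as.integer(round(n_per_pop)))
    sim <- simulate_neutral_envelope(p_pool[usable], n_per_pop, f_env, n_sims)
    # condition the tail probability on He: sliding window of the k
    # simulated sites nearest in He
    k <- min(n_sims, max(1000L, as.integer(floor(n_sims * envelope_frac))))
    ord <- order(sim$he)
    he_s <- sim$he[ord]
    fst_s <- sim$fst[ord]
    pvals <- rep(NA_real_, ncol(gm$dosages))
    for (s in which(usable)) {
      ctr <- findInterval(he_obs[s], he_s)
      lo <- max(1L, min(ctr - k %/% 2L, n_sims - k + 1L))
      win <- lo:(lo + k - 1L)
      pvals[s] <- (1 + sum(fst_s[win] >= fst_obs[s], na.rm = TRUE)) /
        (1 + sum(!is.na(fst_s[win])))
    }
    padj <- rep(NA_real_, length(pvals))
    padj[usable] <- stats::p.adjust(pvals[usable], method = "BH")
    flagged <- which(usable & !is.na(padj) & padj <= fdr)
    list(
      outliers = gm$sites$id[flagged],
      table = data.frame(
        site = gm$sites$id, he = he_obs, fst = fst_obs,
        p = pvals, p_bh = padj, stringsAsFactors = FALSE
      ),
      mean_fst = mean_fst
    )
  })
}

# Neutral He/FST envelope: beta-distributed deme frequencies around ancestral
# frequencies resampled from the observed pool, genotypes drawn at the
# observed sample sizes, WC FST recomputed per simulated site.
simulate_neutral_envelope <- function(p_pool, n_per_pop, f_env, n_sims) {
  p_pool <- p_pool[p_pool > 0 & p_pool < 1]
  p_anc <- sample(p_pool, n_sims, replace = TRUE)
  r <- length(n_per_pop)
  shape_scale <- (1 - f_env) / f_env
  dos_list <- vector("list", r)
  p_demes <- matrix(0, n_sims, r)
  het_demes <- matrix(0, n_sims, r)
  for (i in seq_len(r)) {
    pd <- stats::rbeta(n_sims, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    n <- n_per_pop[i]
    # exact HW multinomial via sequential binomials
    nAA <- stats::rbinom(n_sims, n, pd^2)
    pr_het <- ifelse(pd^2 >= 1, 0, 2 * pd * (1 - pd) / (1 - pd^2))
    nAa <- stats::rbinom(n_sims, n - nAA, pmin(pr_het, 1))
    p_demes[, i] <- (2 * nAA + nAa) / (2 * n)
    het_demes[, i] <- nAa / n
  }
  comp <- wc_components_freq(p_demes, het_demes, n_per_pop)
  denom <- comp$a + comp$b + comp$c
  fst <- ifelse(denom > 0, comp$a / denom, NA_real_)
  p_bar <- sweep(p_demes, 2, n_per_pop, `*`)
  p_bar <- rowSums(p_bar) / sum(n_per_pop)
  list(he = 2 * p_bar * (1 - p_bar), fst = fst)
}

#' Apply the neutrality site filters
#'
#' Removes sites failing the exact Hardy-Weinberg test at `hwe_alpha` in any
#' population (testing within populations avoids Wahlund-effect artifacts
#' masking genotyping error), together with any sites named in `outliers`
#' (typically from [fst_outlier_scan()]).
#'
#' @param gm A [geno_matrix()].
#' @param metadata Optional metadata data.frame; when given, HWE is tested
#'   per `population`, otherwise on the pooled sample.
#' @param hwe_alpha Per-site significance threshold (uncorrected by default).
#' @param outliers Character vector of site ids to remove.
#' @param bonferroni Apply a Bonferroni correction to `hwe_alpha` across
#'   sites.
#' @return List: `genotypes` (filtered matrix) and `report`
#'   (`site_filter_report`: `hwe_removed` data.frame with p-values,
#'   `outlier_removed`, `kept`, `n_input`).
#' @export
apply_site_filters <- function(gm, metadata = NULL, hwe_alpha = 0.05,
                               outliers = character(0), bonferroni = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  alpha <- if (bonferroni) hwe_alpha / ncol(gm$dosages) else hwe_alpha
  groups <- if (is.null(metadata)) {
    list(pooled = gm$samples)
  } else {
    md <- metadata[match(gm$samples, metadata$sample), ]
    split(md$sample, md$population)
  }
  hwe_rows <- list()
  for (gname in names(groups)) {
    dos <- gm$dosages[gm$samples %in% groups[[gname]], , drop = FALSE]
    for (j in seq_len(ncol(dos))) {
      g <- dos[, j]
      g <- g[!is.na(g)]
      if (length(g) == 0L) next
      p <- hwe_exact_pvalue(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      if (p < alpha) {
        hwe_rows[[length(hwe_rows) + 1L]] <-
          data.frame(site = gm$sites$id[j], population = gname, p = p,
                     stringsAsFactors = FALSE)
      }
    }
  }
  hwe_removed <- if (length(hwe_rows)) do.call(rbind, hwe_rows) else
    data.frame(site = character(0), population = character(0), p = numeric(0))
  drop_ids <- union(unique(hwe_removed$site), intersect(outliers, gm$sites$id))
  keep <- setdiff(gm$sites$id, drop_ids)
  if (length(keep) == 0L) stop("all sites removed by the filters")
  report <- structure(
    list(
      hwe_removed = hwe_removed,
      outlier_removed = intersect(outliers, gm$sites$id),
      kept = length(keep),
      n_input = ncol(gm$dosages),
      hwe_alpha = alpha,
      test = "Levene-Haldane exact, two-sided by probability mass, per population"
    ),
    class = "site_filter_report"
  )
  list(genotypes = subset_matrix(gm, sites = keep), report = report)
}

#' @export
print.site_filter_report <- function(x, ...) {
  cat(sprintf(
    "site filter report: %d input sites, %d kept (%d HWE-removed, %d outlier-removed)\n",
    x$n_input, x$kept, length(unique(x$hwe_removed$site)), length(x$outlier_removed)
  ))
  invisible(x)
}
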