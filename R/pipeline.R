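#' Default end-to-end run configuration
#'
#' Stage parameters default to the study design: 100 bootstrap iterations,
#' 20 SFS subsampling iterations, 50,000 outlier-scan simulations at FDR
#' 0.1, HWE alpha 0.05, 100-bp Tajima's D windows, admixture at K = 2 and 3,
#' and a 50% survivor fraction.
#'
#' @param vcf,metadata Input paths (a VCF and the metadata TSV); may be
#'   omitted when `preset` is given.
#' @param preset Optional [emulate_study()] preset generating the inputs.
#' @param out_dir Output directory for the report and derived files.
#' @param seed Integer seed governing every stochastic stage.
#' @param ... Overrides for any stage parameter (see the function body for
#'   the full list: `reps`, `sfs_reps`, `outlier_sims`, `fdr`, `hwe_alpha`,
#'   `window_bp`, `K`, `drift_fraction`, `loci_grid`, `equalize_n`,
#'   `admix_starts`).
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, metadata = NULL, preset = NULL,
                       out_dir = tempfile("eruptpop_run_"), seed = 1L, ...) {
  cfg <- list(
    vcf = vcf, metadata = metadata, preset = preset, out_dir = out_dir,
    seed = as.integer(seed),
    reps = 100L, sfs_reps = 20L, outlier_sims = 50000L, fdr = 0.1,
    hwe_alpha = 0.05, window_bp = 100L, K = c(2L, 3L), drift_fraction = 0.5,
    loci_grid = NULL, equalize_n = NULL, admix_starts = 10L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$preset) && (is.null(cfg$vcf) || is.null(cfg$metadata))) {
    stop("either a preset or both vcf and metadata paths are required")
  }
  structure(cfg, class = "run_config")
}

#' Run the full pre/post comparison
#'
#' Executes the pipeline on one dataset: site filtering (per-population HWE
#' exact test, FST-outlier scan over the period groups), then on the
#' filtered panel: mean heterozygosity per group (per-SNP denominator, plus
#' equalized-individual and 100-locus bootstrap designs), per-site theta_W
#' and pi, Tajima's D windows, equalized folded SFS, inbreeding F, private
#' (and, with three groups, pairwise-shared) alleles, pairwise
#' Weir-Cockerham FST, PCA, admixture over the configured K values, the
#' loci/SD curve, mismatch distributions with raggedness, the
#' centered/re-scaled mismatch comparison, and the random-survivorship
#' simulation on the pre-event group. KS and Welch tests compare pre versus
#' post per-site heterozygosity; raw p-values are reported alongside
#' Benjamini-Hochberg-adjusted values across the report's tests.
#'
#' Rerunning the same configuration (including seed) is bit-identical.
#'
#' @param config A [run_config()].
#' @return The report (a nested list), invisibly also written to
#'   `out_dir/report.json` together with `filtered.vcf`, `curve.tsv` and
#'   per-K admixture `Q_K*.tsv` files.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- input ---------------------------------------------------------------
  if (!is.null(config$preset)) {
    logf("input: preset %s, seed %d", config$preset, config$seed)
    ds <- stage("simulate", emulate_study(config$preset, seed = config$seed))
    gm <- ds$genotypes
    md <- ds$metadata
  } else {
    logf("input: %s + %s", config$vcf, config$metadata)
    gm <- stage("read", read_vcf(config$vcf))
    md <- stage("read", read_metadata(config$metadata, samples = gm$samples))
  }
  md <- md[match(gm$samples, md$sample), ]
  group <- paste(md$population, md$period, sep = ".")

  # --- site filters --------------------------------------------------------
  scan <- stage("filter", fst_outlier_scan(
    gm, pop_labels = group, n_sims = config$outlier_sims,
    fdr = config$fdr, seed = config$seed + 1L
  ))
  filt <- stage("filter", apply_site_filters(
    gm, metadata = md, hwe_alpha = config$hwe_alpha, outliers = scan$outliers
  ))
  gmf <- filt$genotypes
  logf("filter: %d -> %d sites (%d HWE, %d outlier)",
       ncol(gm$dosages), ncol(gmf$dosages),
       length(unique(filt$report$hwe_removed$site)),
       length(filt$report$outlier_removed))

  groups <- split(seq_along(group), group)
  sub_gm <- lapply(groups, function(ix) subset_matrix(gmf, samples = ix))
  eq_n <- if (is.null(config$equalize_n)) min(lengths(groups)) else config$equalize_n
  pre_ix <- which(md$period == "pre")
  post_ix <- which(md$period == "post" & md$population %in% md$population[pre_ix])
  gm_pre <- subset_matrix(gmf, samples = pre_ix)
  gm_post <- subset_matrix(gmf, samples = post_ix)

  # --- diversity -----------------------------------------------------------
  het <- lapply(sub_gm, mean_heterozygosity)
  boot_ind <- lapply(seq_along(sub_gm), function(i) {
    rs <- resample_statistic(sub_gm[[i]], scheme = "individuals", n = eq_n,
                             reps = config$reps, seed = config$seed + 10L + i)
    list(mean = rs$mean, sd = rs$sd)
  })
  names(boot_ind) <- names(sub_gm)
  boot_loci <- lapply(seq_along(sub_gm), function(i) {
    n_loci <- min(100L, ncol(gmf$dosages))
    rs <- resample_statistic(sub_gm[[i]], scheme = "loci", n = n_loci,
                             reps = config$reps, seed = config$seed + 20L + i)
    list(mean = rs$mean, sd = rs$sd)
  })
  names(boot_loci) <- names(sub_gm)
  div <- lapply(sub_gm, function(g) {
    ps <- suppressMessages(per_site_diversity(g))
    list(mean_theta_w = mean(ps$theta_w), mean_pi = mean(ps$pi))
  })
  taj <- lapply(sub_gm, function(g) {
    w <- tajimas_d_windows(g, window_bp = config$window_bp)
    list(n_windows = nrow(w), mean_d = if (nrow(w)) mean(w$value) else NA_real_)
  })
  sfs_n <- min(length(pre_ix), length(post_ix))
  sfs <- list(
    pre = folded_sfs(gm_pre, subsample_n = sfs_n, reps = config$sfs_reps,
                     seed = config$seed + 30L),
    post = folded_sfs(gm_post, subsample_n = sfs_n, reps = config$sfs_reps,
                      seed = config$seed + 31L)
  )
  fvals <- suppressMessages(inbreeding_f(gmf))
  f_by_group <- vapply(groups, function(ix) mean(fvals[ix], na.rm = TRUE), numeric(1))
  priv <- private_alleles(sub_gm, equalize_n = eq_n, reps = config$reps,
                          seed = config$seed + 40L)
  shared <- if (length(sub_gm) == 3L) {
    shared_alleles_pairwise(sub_gm, equalize_n = eq_n, reps = config$reps,
                            seed = config$seed + 41L)
  } else NULL

  # --- differentiation -----------------------------------------------------
  pair_idx <- utils::combn(names(sub_gm), 2L)
  fst_pairs <- lapply(seq_len(ncol(pair_idx)), function(j) {
    g1 <- pair_idx[1L, j]; g2 <- pair_idx[2L, j]
    ix <- c(groups[[g1]], groups[[g2]])
    est <- weir_cockerham_fst(subset_matrix(gmf, samples = ix),
                              pop_labels = group[ix])
    list(pair = paste(g1, g2, sep = "|"), fst = est$fst)
  })
  pca <- pca_genotypes(gmf)
  admix <- lapply(config$K, function(k) {
    admixture_em(gmf, K = k, seed = config$seed + 50L + k,
                 n_starts = config$admix_starts)
  })
  names(admix) <- paste0("K", config$K)

  # --- resampling curve ----------------------------------------------------
  grid <- if (is.null(config$loci_grid)) default_loci_grid() else config$loci_grid
  curve <- loci_sd_curve(gmf, grid = grid, reps = config$reps,
                         seed = config$seed + 60L)

  # --- demographic signals -------------------------------------------------
  mism <- lapply(sub_gm, mismatch_distribution)
  ragg <- vapply(mism, raggedness, numeric(1))
  pre_name <- names(sub_gm)[vapply(names(sub_gm), function(nm)
    grepl("\\.pre$", nm), logical(1))][1]
  post_name <- sub("\\.pre$", ".post", pre_name)
  mism_cmp <- if (post_name %in% names(mism)) {
    compare_mismatch(mism[[pre_name]], mism[[post_name]])
  } else NULL
  drift <- survivor_drift_sim(gm_pre, fraction = config$drift_fraction,
                              reps = config$reps, seed = config$seed + 70L)

  # --- pre vs post tests ---------------------------------------------------
  ps_pre <- suppressMessages(per_site_diversity(gm_pre))
  ps_post <- suppressMessages(per_site_diversity(gm_post))
  het_site_pre <- colMeans(gm_pre$dosages == 1L, na.rm = TRUE)
  het_site_post <- colMeans(gm_post$dosages == 1L, na.rm = TRUE)
  ks_het <- ks_two_sample(het_site_pre, het_site_post)
  t_het <- welch_t_two_sample(het_site_pre, het_site_post)
  ks_pi <- ks_two_sample(ps_pre$pi, ps_post$pi)
  raw_p <- c(ks_het = ks_het$p, t_het = t_het$p, ks_pi = ks_pi$p,
             mismatch = if (is.null(mism_cmp)) NA else mism_cmp$p,
             drift = drift$p)
  adj_p <- stats::p.adjust(raw_p[!is.na(raw_p)], method = "BH")

  report <- list(
    config = unclass(config)[c("preset", "seed", "reps", "sfs_reps",
                               "outlier_sims", "fdr", "hwe_alpha", "window_bp",
                               "K", "drift_fraction")],
    filter = list(
      n_input = filt$report$n_input, n_kept = filt$report$kept,
      hwe_removed = unique(filt$report$hwe_removed$site),
      outlier_removed = filt$report$outlier_removed,
      mean_fst_envelope = scan$mean_fst
    ),
    heterozygosity = list(
      mean = het, bootstrap_individuals = boot_ind, bootstrap_100_loci = boot_loci
    ),
    diversity = div,
    tajima_d = taj,
    sfs = list(
      subsample_n = sfs_n,
      pre = as.list(stats::setNames(sfs$pre$class_counts,
                                    seq_along(sfs$pre$class_counts))),
      post = as.list(stats::setNames(sfs$post$class_counts,
                                     seq_along(sfs$post$class_counts)))
    ),
    inbreeding_f = as.list(f_by_group),
    private_alleles = priv,
    shared_alleles = shared,
    fst = fst_pairs,
    pca = list(explained = pca$explained[1:min(5, length(pca$explained))]),
    admixture = lapply(admix, function(a)
      list(K = a$K, loglik = a$loglik, converged = a$converged,
           max_ancestry = unname(apply(a$Q, 1L, max)))),
    loci_sd_curve = curve,
    mismatch = list(raggedness = as.list(ragg),
                    compare_pre_post = mism_cmp),
    survivor_sim = drift,
    tests = list(raw_p = as.list(raw_p), bh_adjusted = as.list(adj_p)),
    seeds = list(root = config$seed)
  )

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  write_vcf(gmf, file.path(config$out_dir, "filtered.vcf"))
  utils::write.table(curve, file.path(config$out_dir, "curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(admix)) {
    q <- data.frame(sample = rownames(admix[[nm]]$Q), admix[[nm]]$Q)
    utils::write.table(q, file.path(config$out_dir, paste0("Q_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logf("done: report.json written")
  invisible(report)
}
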