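#' Configure a forward Wright-Fisher simulation
#'
#' Parameters of a neutral, discrete-generation, forward-time simulation of
#' biallelic loci in one or more demes, with a single instantaneous decline
#' ("the event") after a stated number of pre-event generations. Time is
#' measured in generations 0..(`generations_pre` + `generations_post`); the
#' census size from generation `generations_pre` onward is
#' `floor(ne_pre * (1 - decline_fraction))`.
#'
#' @param n_loci Number of independent biallelic loci (>= 1).
#' @param ne_pre Diploid effective size per deme before the event (>= 2).
#' @param decline_fraction Fraction of the population removed at the event,
#'   in `[0, 1)`.
#' @param generations_pre Generations simulated before the event (>= 1).
#' @param generations_post Generations simulated after the event (>= 0).
#' @param migration_rate Per-generation probability that a gamete is an
#'   immigrant from another deme, in `[0, 0.5]`.
#' @param n_demes Number of demes (>= 1); all demes share founding
#'   frequencies and the decline.
#' @param initial_freq_spec `"neutral"` draws founding minor-allele
#'   frequencies with density proportional to 1/x truncated to
#'   `[1/(2 ne_pre), 0.5]` (the standing neutral spectrum); `"uniform"` draws
#'   uniformly on the same interval (for calibration).
#' @param seed Integer seed owning every stochastic draw of the run, or
#'   `NULL` to continue from the caller's RNG stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci, ne_pre, decline_fraction,
                       generations_pre = 10L, generations_post = 2L,
                       migration_rate = 0, n_demes = 1L,
                       initial_freq_spec = c("neutral", "uniform"),
                       seed = NULL) {
  initial_freq_spec <- match.arg(initial_freq_spec)
  if (n_loci < 1) stop("n_loci must be >= 1 (got ", n_loci, ")")
  if (ne_pre < 2) stop("ne_pre must be >= 2 (got ", ne_pre, ")")
  if (decline_fraction < 0 || decline_fraction >= 1) {
    stop("decline_fraction must satisfy 0 <= decline_fraction < 1 (got ",
         decline_fraction, ")")
  }
  if (migration_rate < 0 || migration_rate > 0.5) {
    stop("migration_rate must lie in [0, 0.5] (got ", migration_rate, ")")
  }
  if (n_demes < 1) stop("n_demes must be >= 1")
  if (generations_pre < 1 || generations_post < 0) {
    stop("generations_pre must be >= 1 and generations_post >= 0")
  }
  structure(
    list(
      n_loci = as.integer(n_loci), ne_pre = as.integer(ne_pre),
      decline_fraction = decline_fraction,
      generations_pre = as.integer(generations_pre),
      generations_post = as.integer(generations_post),
      migration_rate = migration_rate, n_demes = as.integer(n_demes),
      initial_freq_spec = initial_freq_spec,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

draw_initial_freqs <- function(config) {
  xmin <- 1 / (2 * config$ne_pre)
  u <- stats::runif(config$n_loci)
  if (config$initial_freq_spec == "neutral") {
    # inverse-CDF sample of density 1/x on [xmin, 0.5]
    xmin * (0.5 / xmin)^u
  } else {
    xmin + u * (0.5 - xmin)
  }
}

#' Run the forward Wright-Fisher simulation
#'
#' Each generation, deme allele frequencies are mixed by symmetric migration
#' (a fraction `migration_rate` of gametes drawn from the mean of the other
#' demes) and then resampled binomially with `2N` trials, `N` being the
#' census of the receiving generation. The event is an instantaneous size
#' change: no allele-frequency jump beyond the binomial draw at the reduced
#' size. No mutation, selection or recombination.
#'
#' @param config A [sim_config()].
#' @return A `true_history` list: `freqs` (array loci x demes x generations,
#'   generation 0 first), `deme_sizes` (census per generation), `config`.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  g_total <- config$generations_pre + config$generations_post
  n_post <- max(2L, as.integer(floor(config$ne_pre * (1 - config$decline_fraction))))
  sizes <- c(rep(config$ne_pre, config$generations_pre),
             rep(n_post, g_total - config$generations_pre + 1L))
  freqs <- array(NA_real_, dim = c(config$n_loci, config$n_demes, g_total + 1L))
  p0 <- draw_initial_freqs(config)
  for (d in seq_len(config$n_demes)) freqs[, d, 1L] <- p0
  m <- config$migration_rate
  for (g in seq_len(g_total)) {
    p_now <- freqs[, , g, drop = FALSE]
    dim(p_now) <- c(config$n_loci, config$n_demes)
    if (config$n_demes > 1L && m > 0) {
      other_mean <- (rowSums(p_now) - p_now) / (config$n_demes - 1L)
      p_mig <- (1 - m) * p_now + m * other_mean
    } else {
      p_mig <- p_now
    }
    n_gam <- 2L * sizes[g + 1L]
    counts <- stats::rbinom(length(p_mig), size = n_gam, prob = as.vector(p_mig))
    freqs[, , g + 1L] <- counts / n_gam
  }
  structure(
    list(freqs = freqs, deme_sizes = sizes, config = config),
    class = "true_history"
  )
}

#' Define a sampling plan over a simulated history
#'
#' @param cohorts Data.frame with one row per sampled cohort and columns
#'   `deme`, `generation` (0-based generation index into the history), `n`
#'   (individuals), `n_burrows` (burrow systems the cohort spans,
#'   `<= n`), `label`, `population`, `period` (`"pre"`/`"post"`).
#' @param sex_ratio Fraction of sampled individuals that are female.
#' @param sibship_rate Probability that a multiply-sampled burrow system is a
#'   full-sib family sharing two parents (colonial kin structure); 0 gives
#'   fully independent Hardy-Weinberg draws.
#' @param juvenile_rate Fraction of samples labelled juvenile.
#' @return A `sampling_plan` list.
#' @export
sampling_plan <- function(cohorts, sex_ratio = 0.5, sibship_rate = 0,
                          juvenile_rate = 0.25) {
  req <- c("deme", "generation", "n", "n_burrows", "label", "population", "period")
  missing_cols <- setdiff(req, names(cohorts))
  if (length(missing_cols)) {
    stop("cohorts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(cohorts$n < 1)) stop("every cohort needs n >= 1")
  if (any(cohorts$n_burrows > cohorts$n)) stop("n_burrows cannot exceed n")
  if (any(cohorts$n_burrows < 1)) stop("every cohort needs n_burrows >= 1")
  structure(
    list(cohorts = cohorts, sex_ratio = sex_ratio,
         sibship_rate = sibship_rate, juvenile_rate = juvenile_rate),
    class = "sampling_plan"
  )
}

# Assign individuals of the plan to burrows, sexes, ages and sib families.
# Every burrow gets at least one individual; remaining individuals are placed
# uniformly. A multiply-occupied burrow becomes a full-sib family with
# probability sibship_rate.
build_sample_frame <- function(plan) {
  frames <- lapply(seq_len(nrow(plan$cohorts)), function(ci) {
    co <- plan$cohorts[ci, ]
    burrow_idx <- c(seq_len(co$n_burrows),
                    if (co$n > co$n_burrows)
                      sample.int(co$n_burrows, co$n - co$n_burrows, replace = TRUE))
    burrow_idx <- sample(burrow_idx)  # shuffle assignment order
    sib_burrow <- vapply(seq_len(co$n_burrows), function(b) {
      sum(burrow_idx == b) >= 2L && stats::runif(1) < plan$sibship_rate
    }, logical(1))
    data.frame(
      sample = sprintf("%s_%02d", co$label, seq_len(co$n)),
      population = co$population,
      period = co$period,
      sex = ifelse(stats::runif(co$n) < plan$sex_ratio, "F", "M"),
      age = ifelse(stats::runif(co$n) < plan$juvenile_rate, "juvenile", "adult"),
      burrow = sprintf("%s_B%02d", co$label, burrow_idx),
      deme = co$deme,
      generation = co$generation,
      sib_family = ifelse(sib_burrow[burrow_idx],
                          sprintf("%s_B%02d", co$label, burrow_idx), NA_character_),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, frames)
}

# Diploid genotype draws for a prepared sample frame against a history.
# Independent individuals: dosage ~ Binomial(2, p). Full-sib families: two
# parental genotypes are drawn from the deme frequency and each sib receives
# one allele from each parent.
draw_genotypes_frame <- function(history, frame) {
  n_loci <- dim(history$freqs)[1]
  dos <- matrix(NA_integer_, nrow = nrow(frame), ncol = n_loci,
                dimnames = list(frame$sample, NULL))
  for (key in unique(paste(frame$deme, frame$generation))) {
    rows <- which(paste(frame$deme, frame$generation) == key)
    d <- frame$deme[rows[1]]
    g <- frame$generation[rows[1]]
    if (g < 0 || g > dim(history$freqs)[3] - 1L) {
      stop("cohort generation ", g, " not present in history")
    }
    if (length(rows) > history$deme_sizes[g + 1L]) {
      stop("cohort size ", length(rows), " exceeds deme census ",
           history$deme_sizes[g + 1L], " at generation ", g)
    }
    p <- history$freqs[, d, g + 1L]
    fams <- frame$sib_family[rows]
    indep <- rows[is.na(fams)]
    if (length(indep)) {
      draws <- stats::rbinom(length(indep) * n_loci, 2L, rep(p, each = length(indep)))
      dos[indep, ] <- matrix(draws, nrow = length(indep))
    }
    for (fam in unique(fams[!is.na(fams)])) {
      sibs <- rows[!is.na(fams) & fams == fam]
      par1 <- stats::rbinom(n_loci, 2L, p)
      par2 <- stats::rbinom(n_loci, 2L, p)
      for (s in sibs) {
        dos[s, ] <- stats::rbinom(n_loci, 1L, par1 / 2) +
          stats::rbinom(n_loci, 1L, par2 / 2)
      }
    }
  }
  dos
}

#' Sample diploid genotypes from a simulated history
#'
#' @param history A `true_history` from [simulate_populations()].
#' @param plan A [sampling_plan()].
#' @param seed Optional integer seed; `NULL` continues the caller's stream.
#' @return A list with `genotypes` (a [geno_matrix()], loci placed on
#'   synthetic target regions) and `metadata` (data.frame in the package's
#'   metadata layout).
#' @export
draw_samples <- function(history, plan, seed = NULL) {
  stopifnot(inherits(history, "true_history"), inherits(plan, "sampling_plan"))
  if (!is.null(seed)) set.seed(seed)
  frame <- build_sample_frame(plan)
  dos <- draw_genotypes_frame(history, frame)
  coords <- place_on_regions(ncol(dos))
  gm <- geno_matrix(dos, chrom = coords$chrom, pos = coords$pos)
  md <- frame[, c("sample", "population", "period", "sex", "age", "burrow")]
  list(genotypes = gm, metadata = md)
}

# Scatter loci over synthetic 1,200-bp target regions (unique coordinates).
place_on_regions <- function(n_sites, n_regions = 2000L, region_bp = 1200L) {
  if (n_sites > n_regions * region_bp) stop("too many sites for the region grid")
  cells <- sample.int(n_regions * region_bp, n_sites)
  list(
    chrom = sprintf("tr%04d", (cells - 1L) %/% region_bp + 1L),
    pos = (cells - 1L) %% region_bp + 1L
  )
}

study_presets <- function() {
  list(
    speciesA = list(
      # colonial species: restricted range, kin-structured burrows, ~40% decline
      config = list(ne_pre = 300L, decline_fraction = 0.40,
                    generations_pre = 8L, generations_post = 2L,
                    migration_rate = 0.005, n_demes = 2L),
      cohorts = data.frame(
        deme = c(1L, 1L, 2L), generation = c(7L, 10L, 10L),
        n = c(17L, 31L, 9L), n_burrows = c(13L, 9L, 9L),
        label = c("RGpre", "RGpost", "LLpost"),
        population = c("RinconGrande", "RinconGrande", "LaLonja"),
        period = c("pre", "post", "post"),
        stringsAsFactors = FALSE
      ),
      sex_ratio = 0.5, sibship_rate = 0.3,
      target_snps = 531L
    ),
    speciesB = list(
      # solitary species: single population, ~25% decline, no kin structure
      config = list(ne_pre = 500L, decline_fraction = 0.25,
                    generations_pre = 8L, generations_post = 2L,
                    migration_rate = 0, n_demes = 1L),
      cohorts = data.frame(
        deme = c(1L, 1L), generation = c(7L, 10L),
        n = c(12L, 17L), n_burrows = c(12L, 17L),
        label = c("SRpre", "SRpost"),
        population = c("SanRamon", "SanRamon"),
        period = c("pre", "post"),
        stringsAsFactors = FALSE
      ),
      sex_ratio = 0.5, sibship_rate = 0,
      target_snps = 449L
    )
  )
}

#' Generate a study-structured synthetic dataset
#'
#' Emulates the sampling design of the two-species eruption study: preset
#' `"speciesA"` gives 57 samples in three cohorts (17 pre-event and 31
#' post-event from the focal deme, 9 post-event from a second deme) and a
#' panel of exactly 531 SNPs segregating in the sample; `"speciesB"` gives
#' 12 pre + 17 post samples and 449 SNPs. Loci that are monomorphic in the
#' drawn sample are discarded and fresh loci simulated until the target
#' panel size is reached.
#'
#' @param species_preset `"speciesA"` or `"speciesB"`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param out_dir Optional directory; when given, `<preset>.vcf` and
#'   `<preset>_metadata.tsv` are written there.
#' @param keep_monomorphic Retain sampled monomorphic loci instead of
#'   re-drawing (panel then has a random segregating count; used to study
#'   denominator questions).
#' @param batch_loci Loci simulated per batch while filling the panel.
#' @return List with `genotypes`, `metadata`, `history` (last batch), and
#'   file `paths` when `out_dir` was given.
#' @export
emulate_study <- function(species_preset, seed, out_dir = NULL,
                          keep_monomorphic = FALSE, batch_loci = 1500L) {
  presets <- study_presets()
  if (!species_preset %in% names(presets)) {
    stop("unknown preset '", species_preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  ps <- presets[[species_preset]]
  set.seed(as.integer(seed))
  plan <- sampling_plan(ps$cohorts, sex_ratio = ps$sex_ratio,
                        sibship_rate = ps$sibship_rate)
  frame <- build_sample_frame(plan)
  target <- ps$target_snps
  dos_all <- NULL
  history <- NULL
  for (batch in 1:40) {
    cfg <- do.call(sim_config, c(list(n_loci = batch_loci, seed = NULL), ps$config))
    history <- simulate_populations(cfg)
    dos <- draw_genotypes_frame(history, frame)
    if (!keep_monomorphic) {
      ac <- colSums(dos)
      seg <- ac > 0L & ac < 2L * nrow(dos)
      dos <- dos[, seg, drop = FALSE]
    }
    dos_all <- if (is.null(dos_all)) dos else cbind(dos_all, dos)
    if (ncol(dos_all) >= target) break
  }
  if (ncol(dos_all) < target) {
    stop("could not reach ", target, " segregating sites; increase batch_loci")
  }
  if (!keep_monomorphic) dos_all <- dos_all[, seq_len(target), drop = FALSE]
  coords <- place_on_regions(ncol(dos_all))
  gm <- geno_matrix(dos_all, chrom = coords$chrom, pos = coords$pos)
  md <- frame[, c("sample", "population", "period", "sex", "age", "burrow")]
  out <- list(genotypes = gm, metadata = md, history = history)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    vcf_path <- file.path(out_dir, paste0(species_preset, ".vcf"))
    md_path <- file.path(out_dir, paste0(species_preset, "_metadata.tsv"))
    write_vcf(gm, vcf_path)
    write_metadata(md, md_path)
    out$paths <- c(vcf = vcf_path, metadata = md_path)
  }
  out
}
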