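# Shared fixtures and independent oracle implementations used across the
# suite. Oracles deliberately use different code paths (loops, enumeration,
# base-R reference routines) from the package internals they check.

# quick geno_matrix from a plain dosage matrix
gm_from <- function(dos, chrom = NULL, pos = NULL) {
  dos <- as.matrix(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("ind%02d", seq_len(nrow(dos)))
  if (is.null(chrom)) chrom <- rep("r1", ncol(dos))
  if (is.null(pos)) pos <- seq_len(ncol(dos))
  geno_matrix(dos, chrom = chrom, pos = pos)
}

# random HW genotype matrix at given allele freqs
gm_random_hw <- function(n_ind, freqs, seed = 1) {
  withr::with_seed(seed, {
    dos <- sapply(freqs, function(p) rbinom(n_ind, 2, p))
    gm_from(matrix(dos, nrow = n_ind))
  })
}

# sites drawn from the neutral coalescent site-frequency law: a segregating
# site carries derived count i (of n haplotypes) with probability
# proportional to 1/i; haplotypes are paired into diploids. E[pi per site]
# and E[thetaW per site] both equal theta.
coalescent_sites <- function(n_dip, n_sites, theta, seed = 1) {
  withr::with_seed(seed, {
    n_hap <- 2L * n_dip
    a_n1 <- sum(1 / seq_len(n_hap - 1L))
    p_seg <- theta * a_n1
    stopifnot(p_seg < 1)
    dos <- matrix(0L, n_dip, n_sites)
    seg <- runif(n_sites) < p_seg
    counts <- sample(seq_len(n_hap - 1L), n_sites, replace = TRUE,
                     prob = 1 / seq_len(n_hap - 1L))
    for (j in which(seg)) {
      hap <- integer(n_hap)
      hap[sample.int(n_hap, counts[j])] <- 1L
      dos[, j] <- hap[seq(1, n_hap, by = 2)] + hap[seq(2, n_hap, by = 2)]
    }
    gm_from(dos)
  })
}

# Levene conditional distribution by direct enumeration of genotype
# configurations (weight = multinomial arrangements x 2^het)
oracle_hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  cfgs <- list()
  for (h in 0:n) {
    aa_ <- (nA - h) / 2
    if (aa_ < 0 || aa_ != floor(aa_)) next
    bb_ <- n - h - aa_
    if (bb_ < 0 || 2 * bb_ + h != 2 * n - nA) next
    w <- factorial(n) / (factorial(aa_) * factorial(h) * factorial(bb_)) * 2^h
    cfgs[[length(cfgs) + 1]] <- c(h = h, w = w)
  }
  tab <- do.call(rbind, cfgs)
  prob <- tab[, "w"] / sum(tab[, "w"])
  p_obs <- prob[tab[, "h"] == n_Aa]
  sum(prob[prob <= p_obs + 1e-12])
}

# Tajima (1989) D, independent textbook evaluation over a whole matrix.
# Mean pairwise differences computed by explicit pair enumeration over
# individuals' allele counts; constants written out separately.
oracle_tajima_d <- function(gm) {
  dos <- gm$dosages
  an <- 2 * colSums(!is.na(dos))
  n <- min(an[an >= 2])
  ac <- colSums(dos, na.rm = TRUE)
  seg <- ac > 0 & ac < an
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  khat <- 0
  for (j in seq_len(ncol(dos))) {
    cj <- ac[j]; nj <- an[j]
    if (nj < 2) next
    khat <- khat + cj * (nj - cj) / (nj * (nj - 1) / 2)
  }
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  unname((khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# Weir & Cockerham (1984) variance components, coded independently with
# explicit scalar loops over populations and sites.
oracle_wc_fst <- function(gm, labels) {
  dos <- gm$dosages
  pops <- unique(labels)
  r <- length(pops)
  A <- B <- C <- 0
  for (j in seq_len(ncol(dos))) {
    ni <- pi_ <- hi <- numeric(r)
    ok <- TRUE
    for (k in seq_len(r)) {
      g <- dos[labels == pops[k], j]
      g <- g[!is.na(g)]
      if (length(g) < 2) { ok <- FALSE; break }
      ni[k] <- length(g)
      pi_[k] <- sum(g) / (2 * length(g))
      hi[k] <- mean(g == 1)
    }
    if (!ok) next
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi_) / sum(ni)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# method-of-moments F, independent scalar re-derivation
oracle_inbreeding_f <- function(gm) {
  dos <- gm$dosages
  nind <- nrow(dos)
  sapply(seq_len(nind), function(i) {
    O <- 0; E <- 0; L <- 0
    for (j in seq_len(ncol(dos))) {
      if (is.na(dos[i, j])) next
      g <- dos[, j][!is.na(dos[, j])]
      two_n <- 2 * length(g)
      if (two_n < 2) next
      p <- sum(g) / two_n
      L <- L + 1
      E <- E + (1 - 2 * p * (1 - p) * two_n / (two_n - 1))
      O <- O + as.numeric(dos[i, j] != 1)
    }
    if (abs(L - E) < 1e-12) return(NA_real_)
    (O - E) / (L - E)
  })
}

# exact two-sample KS p by full permutation enumeration (small n, m)
oracle_ks_perm_p <- function(x, y) {
  ks_d <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
  }
  d_obs <- ks_d(x, y)
  pool <- c(x, y)
  n <- length(x)
  splits <- combn(length(pool), n)
  ds <- apply(splits, 2, function(ix) ks_d(pool[ix], pool[-ix]))
  mean(ds >= d_obs - 1e-12)
}

# brute-force private/shared allele counts from presence sets
oracle_allele_classes <- function(dos_list) {
  pres <- lapply(dos_list, function(d) {
    list(ref = apply(d, 2, function(g) any(g[!is.na(g)] < 2)),
         alt = apply(d, 2, function(g) any(g[!is.na(g)] > 0)))
  })
  K <- length(pres)
  n_sites <- ncol(dos_list[[1]])
  private <- integer(K)
  shared_pairs <- list()
  universal <- 0
  for (allele in c("ref", "alt")) {
    inpop <- sapply(pres, `[[`, allele)  # sites x K
    for (j in seq_len(n_sites)) {
      v <- inpop[j, ]
      if (sum(v) == 1) private[which(v)] <- private[which(v)] + 1
      if (sum(v) == K) universal <- universal + 1
      if (K == 3 && sum(v) == 2) {
        key <- paste(which(v), collapse = "|")
        shared_pairs[[key]] <- (shared_pairs[[key]] %||% 0) + 1
      }
    }
  }
  list(private = private, shared = shared_pairs, universal = universal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
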