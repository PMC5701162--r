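# Weir & Cockerham (1984) per-site variance components a (among populations),
# b (among individuals within populations), c (within individuals), computed
# from per-population sample sizes, allele frequencies and observed
# heterozygote frequencies. n may be a vector (constant over sites) or a
# sites x r matrix (complete-case sizes varying by site).
wc_components_freq <- function(p_mat, h_mat, n) {
  r <- ncol(p_mat)
  if (is.matrix(n)) n_mat <- n else n_mat <- matrix(n, nrow(p_mat), r, byrow = TRUE)
  n_sum <- rowSums(n_mat)
  n_bar <- n_sum / r
  n_c <- (n_sum - rowSums(n_mat^2) / n_sum) / (r - 1)
  p_bar <- rowSums(n_mat * p_mat) / n_sum
  s2 <- rowSums(n_mat * (p_mat - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_mat * h_mat) / n_sum
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_ <- h_bar / 2
  list(a = a, b = b, c = c_)
}

# Per-site WC components from a dosage matrix and population labels, with
# per-site complete-case sample sizes. Sites where any population has < 2
# genotyped individuals are marked unusable.
wc_components <- function(dosages, pop_labels) {
  pops <- unique(pop_labels)
  r <- length(pops)
  n_sites <- ncol(dosages)
  n_mat <- p_mat <- h_mat <- matrix(0, n_sites, r)
  for (i in seq_len(r)) {
    d <- dosages[pop_labels == pops[i], , drop = FALSE]
    n_mat[, i] <- colSums(!is.na(d))
    p_mat[, i] <- ifelse(n_mat[, i] > 0, colSums(d, na.rm = TRUE) / (2 * n_mat[, i]), 0)
    h_mat[, i] <- ifelse(n_mat[, i] > 0, colSums(d == 1L, na.rm = TRUE) / n_mat[, i], 0)
  }
  usable <- rowSums(n_mat >= 2) == r
  comp <- wc_components_freq(p_mat, h_mat, n_mat)
  comp$a[!usable] <- NA_real_
  comp$b[!usable] <- NA_real_
  comp$c[!usable] <- NA_real_
  comp$usable <- usable
  comp
}

#' Weir-Cockerham FST
#'
#' Multi-locus FST as the ratio of sums of the Weir & Cockerham (1984)
#' variance components, `sum(a) / sum(a + b + c)`, with per-site components
#' returned for inspection. Negative estimates are admissible (sampling noise
#' around zero differentiation). Sites at which any population has fewer
#' than two genotyped individuals are excluded.
#'
#' @param gm A [geno_matrix()].
#' @param pop_labels Population label per individual (>= 2 populations).
#' @return List: `fst` (multi-locus ratio-of-sums), `per_site` (data.frame
#'   with components `a`, `b`, `c` and per-site `fst`), `n_sites_used`.
#' @export
weir_cockerham_fst <- function(gm, pop_labels) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (length(unique(pop_labels)) < 2L) stop("FST requires >= 2 populations")
  if (length(pop_labels) != nrow(gm$dosages)) {
    stop("pop_labels must have one entry per individual")
  }
  comp <- wc_components(gm$dosages, pop_labels)
  if (!any(comp$usable)) stop("no analyzable site (need >= 2 genotyped individuals per population)")
  denom <- comp$a + comp$b + comp$c
  list(
    fst = sum(comp$a[comp$usable]) / sum(denom[comp$usable]),
    per_site = data.frame(
      site = gm$sites$id, a = comp$a, b = comp$b, c = comp$c,
      fst = ifelse(denom != 0, comp$a / denom, NA_real_),
      stringsAsFactors = FALSE
    ),
    n_sites_used = sum(comp$usable)
  )
}

#' Genotype PCA with Patterson normalization
#'
#' Centers each site's dosages by twice the pooled allele frequency and
#' scales by the binomial standard deviation `sqrt(2 p (1-p))`; missing
#' dosages are mean-imputed (zero after centering). Coordinates are the
#' eigenvectors of the individual-by-individual covariance scaled by the
#' square roots of their eigenvalues; axis signs are fixed by making the
#' largest-magnitude loading positive.
#'
#' @param gm A [geno_matrix()] with >= 3 individuals and >= 2 polymorphic
#'   sites.
#' @return List: `coords` (individuals x axes), `explained` (fraction of
#'   variance per axis), `eigenvalues`.
#' @export
pca_genotypes <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(gm$dosages) < 3L) stop("PCA requires >= 3 individuals")
  p <- allele_freqs(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("PCA requires >= 2 polymorphic sites")
  d <- gm$dosages[, poly, drop = FALSE]
  p <- p[poly]
  m <- sweep(d, 2L, 2 * p, `-`)
  m <- sweep(m, 2L, sqrt(2 * p * (1 - p)), `/`)
  m[is.na(m)] <- 0
  cov_ii <- tcrossprod(m) / ncol(m)
  eig <- eigen(cov_ii, symmetric = TRUE)
  n_axes <- min(nrow(m) - 1L, ncol(m))
  vals <- pmax(eig$values[seq_len(n_axes)], 0)
  vecs <- eig$vectors[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(n_axes)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  coords <- sweep(vecs, 2L, sqrt(vals), `*`)
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  list(coords = coords, explained = vals / sum(eig$values[eig$values > 0]),
       eigenvalues = vals)
}

#' Maximum-likelihood admixture by EM
#'
#' Fits the standard admixture model: individual `i`'s dosage at site `j` is
#' `Binomial(2, sum_k q_ik p_jk)` with ancestry fractions `Q` on the simplex
#' and ancestral allele frequencies `P` in `[0,1]`. Block EM updates of `Q`
#' and `P` from several random starts; the best final likelihood is kept.
#' Missing genotypes contribute nothing to the likelihood or the updates.
#'
#' @param gm A [geno_matrix()].
#' @param K Number of ancestral populations (1..n individuals).
#' @param seed Integer seed for the random starts.
#' @param tol Convergence threshold on the log-likelihood gain.
#' @param max_iter Iteration cap per start.
#' @param n_starts Random restarts (best kept).
#' @return An `admixture_fit` list: `Q`, `P`, `loglik`, `loglik_trace` (of
#'   the best start), `converged`, `K`.
#' @export
admixture_em <- function(gm, K, seed = 1L, tol = 1e-6, max_iter = 500L,
                         n_starts = 10L) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- nrow(gm$dosages)
  L <- ncol(gm$dosages)
  if (K < 1L || K > n) stop("K must lie in 1..number of individuals")
  g <- gm$dosages
  obs <- !is.na(g)
  g0 <- ifelse(obs, g, 0)          # alt-allele counts
  g2 <- ifelse(obs, 2L - g, 0)     # ref-allele counts
  eps <- 1e-9
  p_hat <- pmin(pmax(allele_freqs(gm), eps), 1 - eps)
  loglik_of <- function(Q, P) {
    mu <- pmin(pmax(Q %*% t(P), eps), 1 - eps)
    sum(g0 * log(mu) + g2 * log(1 - mu)) + sum(lchoose(2, g[obs]))
  }
  withr::with_seed(as.integer(seed), {
    best <- NULL
    for (s in seq_len(n_starts)) {
      Q <- matrix(stats::rexp(n * K), n, K)
      Q <- Q / rowSums(Q)
      P <- matrix(pmin(pmax(
        rep(p_hat, each = K) + stats::rnorm(L * K, 0, 0.05), eps), 1 - eps),
        nrow = L, ncol = K, byrow = TRUE)
      if (K == 1L) { Q[] <- 1; P[, 1] <- p_hat }
      trace <- numeric(0)
      ll_prev <- -Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        mu <- pmin(pmax(Q %*% t(P), eps), 1 - eps)
        # expected ancestry-specific allele counts (alt and ref channels)
        alt_w <- g0 / mu          # n x L
        ref_w <- g2 / (1 - mu)
        A_num <- matrix(0, L, K)  # expected alt alleles from ancestry k at site j
        R_num <- matrix(0, L, K)
        Q_new <- matrix(0, n, K)
        for (k in seq_len(K)) {
          ak <- alt_w * tcrossprod(Q[, k], P[, k])   # q_ik p_jk g / mu
          rk <- ref_w * tcrossprod(Q[, k], 1 - P[, k])
          A_num[, k] <- colSums(ak)
          R_num[, k] <- colSums(rk)
          Q_new[, k] <- rowSums(ak) + rowSums(rk)
        }
        P <- pmin(pmax(A_num / pmax(A_num + R_num, eps), eps), 1 - eps)
        Q <- Q_new / pmax(rowSums(Q_new), eps)
        if (K == 1L) Q[] <- 1
        ll <- loglik_of(Q, P)
        trace <- c(trace, ll)
        if (is.finite(ll_prev) && ll - ll_prev < tol) {
          converged <- TRUE
          break
        }
        ll_prev <- ll
      }
      if (is.null(best) || trace[length(trace)] > best$loglik) {
        best <- list(Q = Q, P = P, loglik = trace[length(trace)],
                     loglik_trace = trace, converged = converged, K = K)
      }
    }
    rownames(best$Q) <- gm$samples
    rownames(best$P) <- gm$sites$id
    class(best) <- "admixture_fit"
    best
  })
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture fit: K=%d, loglik=%.3f, converged=%s\n",
              x$K, x$loglik, x$converged))
  invisible(x)
}
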