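#' Admixture-model log-likelihood
#'
#' Binomial likelihood of dosages under the admixture model: with ancestry
#' proportions Q (samples x K) and ancestral allele frequencies F
#' (K x SNPs), the alternate-allele probability for sample i at SNP j is
#' `p_ij = sum_k q_ik f_kj` and the contribution of a dosage g is
#' `g log p + (2 - g) log(1 - p)`. Missing dosages contribute nothing.
#'
#' @param G genotype matrix (samples x SNPs, values 0/1/2/NA).
#' @param Q samples x K ancestry proportions.
#' @param F_mat K x SNPs allele frequencies.
#' @param eps clamp for p into [eps, 1-eps] (default 1e-9).
#' @return scalar log-likelihood.
#' @export
admix_loglik <- function(G, Q, F_mat, eps = 1e-9) {
  stopifnot(nrow(G) == nrow(Q), ncol(Q) == nrow(F_mat),
            ncol(G) == ncol(F_mat))
  P <- Q %*% F_mat
  if (any(P < -1e-8 | P > 1 + 1e-8)) stop("allele probability outside [0,1]")
  P <- pmin(pmax(P, eps), 1 - eps)
  ll <- G * log(P) + (2 - G) * log1p(-P)
  sum(ll, na.rm = TRUE)
}

#' Fit the admixture model by EM
#'
#' Plain expectation–maximization for the admixture likelihood (the model
#' maximized by the ADMIXTURE program; EM replaces its block-relaxation
#' accelerator, which is irrelevant at desk scale). Q is initialized from a
#' flat Dirichlet and F from jittered per-SNP sample frequencies, both
#' seeded, so runs are reproducible random restarts. The log-likelihood
#' trace is non-decreasing; non-convergence within `max_iter` returns the
#' fit with `converged = FALSE` and a warning.
#'
#' @param G genotype matrix (values 0/1/2/NA).
#' @param K number of ancestral groups (1 <= K <= n samples).
#' @param seed integer seed (required).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-4).
#' @param max_iter iteration cap (default 2000).
#' @param eps frequency clamp into [eps, 1-eps] (default 1e-6).
#' @return an `admixture_fit` list: `Q`, `F` (K x SNPs), `loglik` (trace),
#'   `seed`, `iterations`, `converged`.
#' @export
admix_em <- function(G, K, seed, tol = 1e-4, max_iter = 2000, eps = 1e-6) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  n <- nrow(G); m <- ncol(G)
  if (K < 1 || K > n) stop("need 1 <= K <= n_samples")
  set.seed(seed)
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0L
  G0 <- matrix(as.numeric(G0), n, m)
  H0 <- (2 - G0) * obs                      # reference-allele counts, masked
  n_obs2 <- 2 * rowSums(obs)                # total allele observations per sample

  # init: Q ~ Dirichlet(1,..,1); F = sample frequency jittered by +-0.05,
  # one offset per ancestral group (not per SNP) so the whole fit is
  # exactly equivariant under SNP-column permutation
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  pbar <- colSums(G0) / pmax(2 * colSums(obs), 1)
  F_mat <- matrix(rep(pbar, each = K), K, m) +
    stats::runif(K, -0.05, 0.05)
  F_mat <- pmin(pmax(F_mat, eps), 1 - eps)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- Q %*% F_mat
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    A <- G0 / P                              # alt-allele responsibility scale
    B <- H0 / (1 - P)                        # ref-allele responsibility scale
    # E[alleles from k] factorizes: Q update needs row sums of
    # A * (q_k f_k^T), i.e. Q * (A F^T); F update needs column sums,
    # i.e. F * (A^T Q)^T. Four BLAS products per iteration.
    Qn <- Q * (A %*% t(F_mat) + B %*% t(1 - F_mat))
    Fn <- F_mat * t(crossprod(A, Q))
    Fd <- Fn + (1 - F_mat) * t(crossprod(B, Q))
    Q <- Qn / pmax(n_obs2, 1)
    Q <- Q / rowSums(Q)                      # guard rounding drift
    F_mat <- Fn / pmax(Fd, 1e-12)
    F_mat <- pmin(pmax(F_mat, eps), 1 - eps)
    ll <- admix_loglik(G, Q, F_mat)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  rownames(Q) <- rownames(G)
  structure(list(Q = Q, F = F_mat, loglik = trace, seed = seed,
                 iterations = iter, converged = converged),
            class = "admixture_fit")
}

#' Multiple seeded EM restarts
#'
#' Runs one EM fit per seed and returns the fits sorted by final
#' log-likelihood (best first), emulating an ensemble of independent
#' admixture runs.
#'
#' @param G genotype matrix.
#' @param K number of ancestral groups.
#' @param seeds integer vector, one seed per start.
#' @param ... passed to [admix_em()].
#' @return list of `admixture_fit` objects, best log-likelihood first.
#' @export
admix_multistart <- function(G, K, seeds, ...) {
  if (anyDuplicated(seeds)) warning("duplicate seeds among restarts")
  fits <- lapply(seeds, function(s) admix_em(G, K, seed = s, ...))
  ord <- order(vapply(fits, function(f) utils::tail(f$loglik, 1), numeric(1)),
               decreasing = TRUE)
  fits[ord]
}
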