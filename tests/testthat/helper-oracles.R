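# Shared fixtures and independent oracles for the test suite.

# random simplex matrix (rows sum to 1)
rand_q <- function(n, K, seed) {
  set.seed(seed)
  x <- matrix(rgamma(n * K, 1), n, K)
  q_matrix(x / rowSums(x), sample_ids = sprintf("S%02d", seq_len(n)))
}

# all permutations of 1..n (for brute-force alignment, n <= 6)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

# brute-force optimal column alignment: exhaustive over K! permutations
brute_align <- function(q_ref, q_other) {
  K <- ncol(q_ref)
  best <- NULL
  best_cost <- Inf
  for (p in all_perms(K)) {
    cost <- sum((q_ref - q_other[, p, drop = FALSE])^2)
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  list(perm = unlist(best), cost = best_cost)
}

# per-basepair boolean-mask oracle for interval coverage (single contig)
mask_total_bp <- function(starts, ends, genome_len) {
  mask <- logical(genome_len)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  sum(mask)
}

# brute-force IBS distance by per-SNP enumeration
brute_ibs <- function(g) {
  n <- nrow(g)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- !is.na(g[i, ]) & !is.na(g[j, ])
    sim <- (2 - abs(g[i, shared] - g[j, shared])) / 2
    d[i, j] <- 1 - mean(sim)
  }
  d
}

# brute-force admixture loglik by scalar double loop
brute_loglik <- function(G, Q, F_mat) {
  total <- 0
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    g <- G[i, j]
    if (is.na(g)) next
    p <- sum(Q[i, ] * F_mat[, j])
    total <- total + g * log(p) + (2 - g) * log(1 - p)
  }
  total
}

# a small panel with clean 3-population structure for EM tests
small_panel <- function(seed = 42, n_per = 20, m = 300, fst = 0.25) {
  model <- pop_model(3, m, fst = fst, pure_sizes = rep(n_per, 3))
  simulate_genotypes(model, seed = seed)
}
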