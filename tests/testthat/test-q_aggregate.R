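test_that("column alignment undoes planted permutations exactly", {
  q <- rand_q(25, 5, seed = 10)
  rev_q <- q[, 5:1]
  al <- align_columns(q, rev_q)
  expect_equal(al$perm, 5:1)
  expect_equal(unname(al$aligned), unname(q))
  al_id <- align_columns(q, q)
  expect_equal(al_id$perm, 1:5)
  expect_error(align_columns(q, q[, 1:3]), "K mismatch")
})

test_that("assignment alignment equals exhaustive search over all K! permutations", {
  for (K in 2:6) {
    for (rep in 1:3) {
      qa <- rand_q(12, K, seed = 100 * K + rep)
      qb <- rand_q(12, K, seed = 200 * K + rep)
      al <- align_columns(qa, qb)
      bf <- brute_align(qa, qb)
      expect_equal(sum((qa - al$aligned)^2), bf$cost, tolerance = 1e-12)
    }
  }
})

test_that("run distance is a normalized, label-switching-proof metric", {
  q <- rand_q(30, 4, seed = 3)
  expect_equal(run_distance(q, q), 0)
  perm <- q[, c(2, 4, 1, 3)]
  expect_equal(run_distance(q, perm), 0)
  set.seed(44)
  for (rep in 1:5) {
    a <- rand_q(15, 3, seed = rep)
    b <- rand_q(15, 3, seed = rep + 50)
    expect_equal(run_distance(a, b), run_distance(b, a), tolerance = 1e-12)
    expect_gte(run_distance(a, b), 0)
    expect_lte(run_distance(a, b), 1)
  }
})

test_that("hierarchical clustering of runs recovers planted modes", {
  tq <- rand_q(40, 4, seed = 6)
  # all runs identical -> one cluster
  same <- simulate_run_ensemble(tq, 5, noise_sd = 0, permute = TRUE, seed = 2)
  expect_length(cluster_runs(same, 0.1), 1)
  # planted 6/4 two-mode ensemble -> exactly the planted partition
  ens <- simulate_run_ensemble(tq, 10, noise_sd = 0.02, permute = TRUE,
                               modes = 2, seed = 21, mode_sizes = c(6, 4))
  cl <- cluster_runs(ens, 0.1)
  expect_length(cl, 2)
  expect_equal(cl[[1]], which(ens$info$mode == 1))
  expect_equal(cl[[2]], which(ens$info$mode == 2))
  # zero cut on distinct noisy runs -> all singletons
  noisy <- simulate_run_ensemble(tq, 4, noise_sd = 0.05, permute = FALSE, seed = 3)
  expect_length(cluster_runs(noisy, 0), 4)
})

test_that("mode aggregation discards singleton outlier runs and averages the rest", {
  tq <- rand_q(30, 4, seed = 8)
  # single cluster of identical permuted runs: average equals the truth
  same <- simulate_run_ensemble(tq, 5, noise_sd = 0, permute = TRUE, seed = 12)
  agg <- aggregate_modes(same, 0.1)
  expect_length(agg, 1)
  expect_equal(run_distance(agg[[1]]$Q, tq), 0, tolerance = 1e-9)
  # averaging reduces noise roughly as 1/sqrt(n_runs)
  noise_sd <- 0.03; n_runs <- 12
  noisy <- simulate_run_ensemble(tq, n_runs, noise_sd = noise_sd,
                                 permute = TRUE, seed = 13)
  aggn <- aggregate_modes(noisy, 0.1)
  expect_length(aggn, 1)
  err <- max(abs(aggn[[1]]$Q - align_columns(aggn[[1]]$Q, tq)$aligned))
  expect_lt(err, 5 * noise_sd / sqrt(n_runs))
  # 9 coherent runs + 1 flat outlier: outlier discarded, one mode survives
  coherent <- simulate_run_ensemble(tq, 9, noise_sd = 0.01, permute = TRUE,
                                    seed = 14)
  flat <- q_matrix(matrix(1 / 4, 30, 4, dimnames = list(rownames(tq), NULL)))
  agg2 <- aggregate_modes(c(coherent$runs, list(flat)), 0.1, K_label = 4)
  expect_length(agg2, 1)
  expect_equal(agg2[[1]]$discarded, 10L)
  expect_setequal(agg2[[1]]$members, 1:9)
  # all-singleton ensembles are an error
  spread <- lapply(1:3, function(s) rand_q(30, 4, seed = 300 + s))
  expect_error(aggregate_modes(spread, 0.01), "no stable mode")
})

test_that("mode labels follow cluster size order (K then K.1)", {
  tq <- rand_q(30, 4, seed = 16)
  ens <- simulate_run_ensemble(tq, 10, noise_sd = 0.02, permute = TRUE,
                               modes = 2, seed = 17, mode_sizes = c(6, 4))
  agg <- aggregate_modes(ens, 0.1)
  expect_equal(vapply(agg, function(x) x$mode_label, character(1)),
               c("4", "4.1"))
  expect_length(agg[[1]]$members, 6)
  expect_length(agg[[2]]$members, 4)
})

test_that("aggregation is invariant to independent per-run column permutations", {
  tq <- rand_q(25, 5, seed = 19)
  base <- simulate_run_ensemble(tq, 6, noise_sd = 0.02, permute = FALSE,
                                seed = 23)
  agg_a <- aggregate_modes(base, 0.1)
  set.seed(31)
  shuffled <- lapply(base$runs, function(q) {
    out <- q[, sample(ncol(q))]
    rownames(out) <- rownames(q)
    out
  })
  agg_b <- aggregate_modes(shuffled, 0.1)
  expect_equal(run_distance(agg_a[[1]]$Q, agg_b[[1]]$Q), 0, tolerance = 1e-9)
  # averaged rows stay on the simplex
  expect_lt(max(abs(rowSums(agg_b[[1]]$Q) - 1)), 1e-9)
})

test_that("the K-ladder names splits and recovers a planted hierarchy", {
  set.seed(50)
  n <- 60
  grp3 <- rep(1:3, each = 20)
  q3 <- matrix(0, n, 3); q3[cbind(1:n, grp3)] <- 1
  grp4 <- ifelse(grp3 == 3, 3 + (seq_len(n) %% 2), grp3)
  q4 <- matrix(0, n, 4); q4[cbind(1:n, grp4)] <- 1
  grp5 <- ifelse(grp3 == 1, ifelse(seq_len(n) %% 2 == 0, 1, 5), grp4)
  q5 <- matrix(0, n, 5); q5[cbind(1:n, grp5)] <- 1
  soft <- function(q) { q <- q + 0.01; q / rowSums(q) }
  rownames(q3) <- rownames(q4) <- rownames(q5) <- sprintf("S%02d", 1:n)
  lad <- ladder_match(list(`3` = soft(q3), `4` = soft(q4), `5` = soft(q5)),
                      base_names = c("cA", "XI", "GJ"))
  expect_equal(sum(lad$edges$split[lad$edges$K_child == 4]), 2)  # one split: 2 child edges
  expect_setequal(lad$names_per_K[["4"]], c("cA", "XI", "GJ1", "GJ2"))
  # the K=5 level splits cA; GJ1/GJ2 persist
  expect_true(all(c("GJ1", "GJ2", "cA1", "cA2", "XI") %in%
                  lad$names_per_K[["5"]]))
  expect_error(ladder_match(list(`3` = soft(q3), `5` = soft(q5))), "missing K")

  # correlation matching agrees with optimal assignment on this
  # unambiguous fixture: each parent's assigned child maps back to it
  cors <- cor(soft(q4), soft(q3))
  greedy_parent <- apply(cors, 1, which.max)
  lsap <- clue::solve_LSAP(t(1 - cors))    # parents (3) -> distinct children (4)
  for (p in 1:3)
    expect_equal(unname(greedy_parent[as.integer(lsap)[p]]), p)
})
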