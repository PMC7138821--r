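#' Align the columns of one Q matrix onto another
#'
#' Independent admixture runs label ancestral groups arbitrarily (label
#' switching). The permutation of `q_other`'s columns minimizing the total
#' squared difference to `q_ref` is found exactly by optimal assignment on
#' the K x K column-distance cost matrix (the least-squares objective
#' underlying CLUMPP's G' statistic, solved exactly instead of
#' heuristically).
#'
#' @param q_ref,q_other Q matrices over the same samples with the same K.
#' @return list with `perm` (integer: `aligned = q_other[, perm]`) and
#'   `aligned` (the permuted `q_other`).
#' @export
align_columns <- function(q_ref, q_other) {
  if (ncol(q_ref) != ncol(q_other)) stop("K mismatch between runs")
  if (nrow(q_ref) != nrow(q_other)) stop("sample-set mismatch between runs")
  K <- ncol(q_ref)
  # cost[r, c] = squared distance between ref column r and other column c
  cost <- matrix(0, K, K)
  for (r in seq_len(K))
    for (cc in seq_len(K))
      cost[r, cc] <- sum((q_ref[, r] - q_other[, cc])^2)
  sol <- clue::solve_LSAP(cost)
  perm <- as.integer(sol)
  list(perm = perm, aligned = q_other[, perm, drop = FALSE])
}

#' Distance between two admixture runs
#'
#' Per-cell root-mean-square difference after optimal column alignment,
#' normalized so the value lies in [0, 1]: the squared cell differences are
#' summed, divided by `2 * n_samples` (the largest possible sum for rows on
#' the simplex), and square-rooted. Identical runs — including runs equal up
#' to column permutation — have distance 0.
#'
#' @param q_a,q_b Q matrices over the same samples with the same K.
#' @return scalar in [0, 1].
#' @export
run_distance <- function(q_a, q_b) {
  al <- align_columns(q_a, q_b)
  sqrt(sum((q_a - al$aligned)^2) / (2 * nrow(q_a)))
}

#' All pairwise distances between runs of an ensemble
#'
#' @param ensemble a `run_ensemble` (see [simulate_run_ensemble()]) or a
#'   plain list of Q matrices.
#' @return a `dist` object over runs.
#' @export
run_distance_matrix <- function(ensemble) {
  runs <- if (inherits(ensemble, "run_ensemble")) ensemble$runs else ensemble
  n <- length(runs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- run_distance(runs[[i]], runs[[j]])
  stats::as.dist(d)
}

#' Cluster admixture runs by Q-matrix similarity
#'
#' Average-linkage hierarchical clustering on the [run_distance_matrix()],
#' cut at a fixed height. Runs that converged to the same solution mode fall
#' in one cluster; outlier runs become singletons.
#'
#' @param ensemble a `run_ensemble` or list of Q matrices.
#' @param cut_threshold tree-cut height on the per-cell RMS scale
#'   (default 0.1).
#' @return list of integer vectors of run indices, largest cluster first
#'   (size ties broken by smallest member index).
#' @export
cluster_runs <- function(ensemble, cut_threshold = 0.1) {
  runs <- if (inherits(ensemble, "run_ensemble")) ensemble$runs else ensemble
  if (length(runs) < 2) stop("need at least 2 runs")
  d <- run_distance_matrix(runs)
  if (max(d) == 0) return(list(seq_along(runs)))
  hc <- stats::hclust(d, method = "average")
  memb <- stats::cutree(hc, h = cut_threshold)
  cl <- split(seq_along(runs), memb)
  ord <- order(-lengths(cl), vapply(cl, min, integer(1)))
  unname(cl[ord])
}

#' Aggregate an ensemble of runs into solution modes
#'
#' The aggregation rule applied per K: cluster the runs, discard one-element
#' clusters as outlier runs, and average the Q matrices within each
#' remaining cluster after aligning every member onto the cluster medoid
#' (the member with the smallest summed distance to the others, so the
#' result does not depend on run order). The largest cluster is the primary
#' mode, labelled `"K"`; further modes are labelled `"K.1"`, `"K.2"`, ... in
#' decreasing size order.
#'
#' @param ensemble a `run_ensemble` or list of Q matrices.
#' @param cut_threshold passed to [cluster_runs()].
#' @param K_label integer or string used to build mode labels (defaults to
#'   the ensemble's K).
#' @return list of `mode_summary` objects: `mode_label`, `Q` (averaged),
#'   `members` (run indices), `discarded` (outlier run indices, shared by
#'   all summaries).
#' @export
aggregate_modes <- function(ensemble, cut_threshold = 0.1, K_label = NULL) {
  runs <- if (inherits(ensemble, "run_ensemble")) ensemble$runs else ensemble
  if (is.null(K_label))
    K_label <- if (inherits(ensemble, "run_ensemble")) ensemble$K
               else ncol(runs[[1]])
  cl <- cluster_runs(runs, cut_threshold)
  keep <- cl[lengths(cl) >= 2]
  discarded <- sort(unlist(cl[lengths(cl) == 1]))
  if (!length(keep))
    stop("no stable mode: every run cluster is a singleton")
  out <- vector("list", length(keep))
  for (ci in seq_along(keep)) {
    idx <- keep[[ci]]
    sub <- runs[idx]
    dm <- as.matrix(run_distance_matrix(sub))
    medoid <- which.min(rowSums(dm))
    acc <- matrix(0, nrow(sub[[1]]), ncol(sub[[1]]))
    for (r in seq_along(sub))
      acc <- acc + align_columns(sub[[medoid]], sub[[r]])$aligned
    avg <- acc / length(sub)
    avg <- avg / rowSums(avg)
    rownames(avg) <- rownames(sub[[1]])
    label <- if (ci == 1) as.character(K_label)
             else paste0(K_label, ".", ci - 1L)
    out[[ci]] <- structure(list(mode_label = label, Q = q_matrix(avg),
                                members = idx, discarded = discarded),
                           class = "mode_summary")
  }
  out
}

#' Link subpopulation columns across consecutive K levels
#'
#' Builds the refinement ladder that names the final grouping: each column
#' of the averaged Q at K+1 is matched to the column at K with which it is
#' best correlated across samples (ties broken toward the K+1 column with
#' the larger mean proportion). A K-level group matched by two or more K+1
#' columns is a split; its children extend the parent name with 1, 2, ...
#' in decreasing mean-proportion order, while a sole child inherits the
#' parent name.
#'
#' @param mode_summaries named list: one primary `mode_summary` (or plain Q
#'   matrix) per K, names = K values; K values must be consecutive.
#' @param base_names optional names for the columns at the lowest K
#'   (default `G1..GK`).
#' @return list with `names_per_K` (named list of column-name vectors) and
#'   `edges` (data.frame: K_parent, parent_col, K_child, child_col, split
#'   flag).
#' @export
ladder_match <- function(mode_summaries, base_names = NULL) {
  Ks <- as.integer(names(mode_summaries))
  if (any(is.na(Ks))) stop("mode_summaries must be named by K value")
  ord <- order(Ks)
  Ks <- Ks[ord]
  mode_summaries <- mode_summaries[ord]
  if (length(Ks) < 2) stop("need at least two consecutive K levels")
  if (any(diff(Ks) != 1))
    stop("missing K level: have ", paste(Ks, collapse = ", "))
  getQ <- function(x) if (inherits(x, "mode_summary")) x$Q else x
  q0 <- getQ(mode_summaries[[1]])
  if (is.null(base_names)) base_names <- paste0("G", seq_len(ncol(q0)))
  names_per_K <- stats::setNames(vector("list", length(Ks)), Ks)
  names_per_K[[1]] <- base_names
  edges <- NULL
  for (li in seq_len(length(Ks) - 1)) {
    qa <- getQ(mode_summaries[[li]])
    qb <- getQ(mode_summaries[[li + 1]])
    cors <- stats::cor(qb, qa)              # (K+1 cols) x (K cols)
    parent <- apply(cors, 1, which.max)
    child_names <- character(ncol(qb))
    for (p in sort(unique(parent))) {
      kids <- which(parent == p)
      pname <- names_per_K[[li]][p]
      if (length(kids) == 1) {
        child_names[kids] <- pname
      } else {
        kids <- kids[order(-colMeans(qb)[kids])]
        child_names[kids] <- paste0(pname, seq_along(kids))
      }
      edges <- rbind(edges, data.frame(
        K_parent = Ks[li], parent_col = p, parent_name = pname,
        K_child = Ks[li + 1], child_col = kids,
        child_name = child_names[kids],
        split = length(kids) > 1, stringsAsFactors = FALSE))
    }
    names_per_K[[li + 1]] <- child_names
  }
  rownames(edges) <- NULL
  list(names_per_K = names_per_K, edges = edges)
}
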