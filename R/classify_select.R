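#' Map subpopulation groups to major variety groups
#'
#' @param groups character vector of subpopulation names, one per Q column.
#' @param major character vector over \{"cA","XI","GJ","other"\} giving the
#'   major variety group of each subpopulation.
#' @return a `group_scheme` list.
#' @export
group_scheme <- function(groups, major) {
  if (length(groups) != length(major)) stop("groups and major differ in length")
  if (anyDuplicated(groups)) stop("duplicate group names")
  if (!all(major %in% c("cA", "XI", "GJ", "other")))
    stop("major labels must be cA, XI, GJ or other")
  structure(list(groups = as.character(groups), major = as.character(major)),
            class = "group_scheme")
}

#' Classify samples from admixture proportions
#'
#' The membership rule: a sample whose largest admixture component reaches
#' the threshold (default 0.65) belongs to that subpopulation. Otherwise,
#' if the summed components of the subpopulations within a single major
#' group (cA, XI or GJ, evaluated in that fixed order with the maximal sum
#' winning ties) reach the threshold, the sample is admixed within that
#' major group (`cA-adm` / `XI-adm` / `GJ-adm`). Remaining samples are
#' fully `admixed`. The published protocol states the threshold both as
#' "exceeding 0.65" and ">= 0.65"; `>=` is applied uniformly. For a threshold above 0.5 at
#' most one component can reach it (rows are on the simplex); this is
#' asserted.
#'
#' @param q Q matrix (samples x K).
#' @param scheme a [group_scheme()] covering all K columns.
#' @param threshold membership threshold (default 0.65).
#' @return data.frame: `sample_id`, `label`, `max_component`,
#'   `max_group`, and one `<major>_sum` column per major group present.
#' @export
classify <- function(q, scheme, threshold = 0.65) {
  stopifnot(inherits(scheme, "group_scheme"))
  if (ncol(q) != length(scheme$groups))
    stop("scheme does not cover the ", ncol(q), " Q columns")
  majors <- c("cA", "XI", "GJ")
  sums <- sapply(majors, function(mg) {
    cols <- which(scheme$major == mg)
    if (!length(cols)) return(rep(0, nrow(q)))
    rowSums(q[, cols, drop = FALSE])
  })
  if (is.null(dim(sums))) sums <- matrix(sums, nrow = 1,
                                         dimnames = list(NULL, majors))
  imax <- max.col(q, ties.method = "first")
  vmax <- q[cbind(seq_len(nrow(q)), imax)]
  if (threshold > 0.5 && any(rowSums(q >= threshold) > 1))
    stop("internal error: multiple components reach a threshold > 0.5")
  label <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    if (vmax[i] >= threshold) {
      label[i] <- scheme$groups[imax[i]]
    } else {
      hit <- which(sums[i, ] >= threshold)
      if (length(hit)) {
        best <- hit[which.max(sums[i, hit])]   # maximal sum wins ties
        label[i] <- paste0(majors[best], "-adm")
      } else {
        label[i] <- "admixed"
      }
    }
  }
  out <- data.frame(sample_id = rownames(q), label = label,
                    max_component = vmax,
                    max_group = scheme$groups[imax],
                    stringsAsFactors = FALSE)
  colnames(sums) <- paste0(majors, "_sum")
  cbind(out, as.data.frame(sums))
}

#' Identity-by-state distance matrix
#'
#' For dosages g in \{0,1,2\}, the IBS similarity of two samples at one SNP
#' is `(2 - |g_i - g_j|) / 2`; the distance is one minus the average
#' similarity over the SNPs genotyped in both samples (pairwise complete
#' observations).
#'
#' @param g genotype matrix (see [genotype_matrix()]).
#' @return symmetric n x n matrix with zero diagonal, dimnames = sample ids.
#' @export
ibs_distance <- function(g) {
  n <- nrow(g)
  obs <- !is.na(g)
  M <- matrix(as.numeric(obs), n)
  m_ij <- tcrossprod(M)
  if (any(m_ij == 0)) {
    bad <- which(m_ij == 0, arr.ind = TRUE)[1, ]
    stop("samples '", rownames(g)[bad[1]], "' and '", rownames(g)[bad[2]],
         "' share no genotyped SNPs")
  }
  # |g_i - g_j| summed over shared SNPs from dosage-class indicators
  A0 <- matrix(as.numeric(obs & g == 0L), n)
  A1 <- matrix(as.numeric(obs & g == 1L), n)
  A2 <- matrix(as.numeric(obs & g == 2L), n)
  absdiff <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0)) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  d <- absdiff / (2 * m_ij)
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Principal axes of a distance matrix
#'
#' Classical multidimensional scaling (principal coordinates): the squared
#' distances are double-centered and the top eigenvectors, scaled by the
#' square roots of their eigenvalues, give the coordinate axes — the
#' principled reading of "a PCA of an IBS distance matrix". Axis signs are
#' fixed so each axis's largest-magnitude loading is positive. If fewer
#' than `n_axes` positive eigenvalues exist, the available axes are
#' returned with a warning.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes requested (default 5).
#' @return n x n_axes (or fewer) coordinate matrix, rownames preserved.
#' @export
principal_axes <- function(D, n_axes = 5) {
  D <- as.matrix(D)
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix diagonal is not zero")
  mds <- stats::cmdscale(D, k = min(n_axes, nrow(D) - 1), eig = TRUE)
  pos <- sum(mds$eig > 1e-8 * max(abs(mds$eig)))
  k_avail <- min(n_axes, pos)
  if (k_avail < n_axes)
    warning("only ", k_avail, " positive eigenvalues; returning ",
            k_avail, " axes")
  coords <- mds$points[, seq_len(k_avail), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  rownames(coords) <- rownames(D)
  coords
}

#' Select the representative sample of a group
#'
#' The representative of a subpopulation is the member closest (Euclidean,
#' over the principal axes) to the group centroid — the mean coordinate of
#' all its members — among the members whose seed is available. Ties are
#' broken lexicographically by sample id.
#'
#' @param coords coordinate matrix from [principal_axes()], rownames =
#'   sample ids.
#' @param labels character vector of group labels, parallel to the rows of
#'   `coords` (e.g. the `label` column of [classify()]).
#' @param target_group group to represent.
#' @param available logical vector parallel to `coords` rows; samples with
#'   `FALSE` cannot be chosen but still contribute to the centroid.
#' @return the selected sample id (length-1 character).
#' @export
select_representative <- function(coords, labels, target_group,
                                  available = rep(TRUE, nrow(coords))) {
  stopifnot(length(labels) == nrow(coords),
            length(available) == nrow(coords))
  members <- which(labels == target_group)
  if (!length(members)) stop("no members in group '", target_group, "'")
  avail <- members[available[members]]
  if (!length(avail))
    stop("no available member in group '", target_group, "'")
  centroid <- colMeans(coords[members, , drop = FALSE])
  dd <- sqrt(colSums((t(coords[avail, , drop = FALSE]) - centroid)^2))
  ids <- rownames(coords)[avail]
  ids[order(dd, ids)][1]
}
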