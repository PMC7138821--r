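#' Specify a structured population model for genotype simulation
#'
#' Describes a panel of K_true differentiated subpopulations plus optional
#' admixed individuals, standing in for the 3K-class rice diversity panel:
#' pure samples belong to a single subpopulation; admixed samples carry a
#' stated mixing vector over subpopulations. Each subpopulation maps to a
#' major variety group (cA, XI, GJ or other) for downstream classification.
#'
#' @param K_true number of subpopulations (>= 1).
#' @param n_snps number of SNPs.
#' @param fst differentiation of each subpopulation from the ancestral pool,
#'   scalar or length-K vector, each in (0, 1).
#' @param pure_sizes integer vector (length K_true) of pure samples per
#'   subpopulation.
#' @param admixed list of numeric mixing vectors (each length K_true, summing
#'   to 1), one per admixed sample; may be empty.
#' @param major_groups character vector (length K_true) over
#'   \{"cA","XI","GJ","other"\}; defaults spread groups across the three
#'   major rice groups.
#' @return a `pop_model` list.
#' @export
pop_model <- function(K_true, n_snps, fst = 0.15,
                      pure_sizes = rep(30L, K_true),
                      admixed = list(),
                      major_groups = NULL) {
  stopifnot(K_true >= 1, n_snps >= 1, length(pure_sizes) == K_true)
  fst <- rep_len(fst, K_true)
  if (any(fst <= 0 | fst >= 1)) stop("fst must be in (0, 1)")
  for (w in admixed) {
    if (length(w) != K_true || abs(sum(w) - 1) > 1e-6)
      stop("each admixed mixing vector must have length K_true and sum to 1")
  }
  if (is.null(major_groups)) {
    pool <- c("cA", "XI", "GJ")
    major_groups <- pool[(seq_len(K_true) - 1L) %% 3L + 1L]
  }
  if (length(major_groups) != K_true ||
      !all(major_groups %in% c("cA", "XI", "GJ", "other")))
    stop("major_groups must map every subpopulation to cA/XI/GJ/other")
  structure(list(K_true = K_true, n_snps = as.integer(n_snps), fst = fst,
                 pure_sizes = as.integer(pure_sizes), admixed = admixed,
                 major_groups = major_groups),
            class = "pop_model")
}

#' Simulate genotypes under the admixture model
#'
#' Ancestral allele frequencies are drawn uniformly on (0.05, 0.95);
#' per-subpopulation frequencies follow the Balding–Nichols distribution,
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral frequency p
#' and whose variance is `F p (1-p)`. Each sample's dosage at each SNP is
#' Binomial(2, sum_k q_k f_kj) given its ancestry vector q.
#'
#' @param model a [pop_model()].
#' @param seed integer seed (required; the generator refuses to run
#'   unseeded).
#' @param missing_rate fraction of dosage cells set to NA (default 0).
#' @return list with `genotypes` (see [genotype_matrix()]), `true_q`
#'   (samples x K_true), `pop_freqs` (K_true x n_snps), `ancestral_freqs`,
#'   and `truth` (data.frame of sample id, planted label, major group).
#' @export
simulate_genotypes <- function(model, seed, missing_rate = 0) {
  stopifnot(inherits(model, "pop_model"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  K <- model$K_true
  m <- model$n_snps
  p0 <- stats::runif(m, 0.05, 0.95)
  Fst <- model$fst
  pf <- matrix(0, K, m)
  for (k in seq_len(K)) {
    a <- p0 * (1 - Fst[k]) / Fst[k]
    b <- (1 - p0) * (1 - Fst[k]) / Fst[k]
    pf[k, ] <- stats::rbeta(m, a, b)
  }
  n_pure <- sum(model$pure_sizes)
  n_adm <- length(model$admixed)
  n <- n_pure + n_adm
  Q <- matrix(0, n, K)
  label <- character(n)
  row <- 1L
  pop_names <- paste0("pop", seq_len(K))
  for (k in seq_len(K)) {
    for (i in seq_len(model$pure_sizes[k])) {
      Q[row, k] <- 1
      label[row] <- pop_names[k]
      row <- row + 1L
    }
  }
  for (w in model$admixed) {
    Q[row, ] <- w
    label[row] <- "admixed_planted"
    row <- row + 1L
  }
  P <- Q %*% pf                      # n x m expected allele frequency
  G <- matrix(stats::rbinom(n * m, 2L, as.vector(P)), n, m)
  if (missing_rate > 0) {
    drop <- stats::runif(n * m) < missing_rate
    G[drop] <- NA_integer_
  }
  ids <- sprintf("S%03d", seq_len(n))
  g <- genotype_matrix(G, sample_ids = ids)
  tq <- if (K >= 2) q_matrix(Q, sample_ids = ids) else
    matrix(1, n, 1, dimnames = list(ids, NULL))
  truth <- data.frame(sample_id = ids, label = label,
                      stringsAsFactors = FALSE)
  list(genotypes = g, true_q = tq, pop_freqs = pf, ancestral_freqs = p0,
       truth = truth, major_groups = model$major_groups)
}

#' Simulate an ensemble of noisy, label-switched Q-matrix replicates
#'
#' Emulates repeated admixture runs: each replicate resamples every row of
#' the underlying Q from a Dirichlet centred on the true row (concentration
#' `1/noise_sd^2`, so rows stay on the simplex by construction), then
#' optionally permutes the columns to plant label switching. With
#' `modes = 2` a second solution mode is constructed by merging the two
#' closest groups and re-splitting the largest remaining group, mimicking
#' alternative refinements seen across real runs.
#'
#' @param true_q samples x K Q matrix.
#' @param n_runs number of replicates (>= 2).
#' @param noise_sd Dirichlet noise scale (>= 0; 0 = exact copies).
#' @param permute plant a random column permutation per run?
#' @param modes 1 or 2 solution modes.
#' @param seed integer seed (required).
#' @param mode_sizes runs per mode when `modes = 2` (default 60/40 split).
#' @return a `run_ensemble`: list with `K`, `runs` (list of Q matrices) and
#'   `info` (data.frame: run id, mode, permutation string, seed).
#' @export
simulate_run_ensemble <- function(true_q, n_runs, noise_sd = 0.02,
                                  permute = TRUE, modes = 1, seed,
                                  mode_sizes = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(modes %in% c(1, 2))
  set.seed(seed)
  K <- ncol(true_q)
  bases <- list(true_q)
  if (modes == 2) bases[[2]] <- .second_mode(true_q)
  if (is.null(mode_sizes)) {
    n1 <- ceiling(0.6 * n_runs)
    mode_sizes <- c(n1, n_runs - n1)
  }
  if (modes == 1) mode_sizes <- n_runs
  if (sum(mode_sizes) != n_runs) stop("mode_sizes must sum to n_runs")
  mode_of <- rep(seq_along(mode_sizes), mode_sizes)
  runs <- vector("list", n_runs)
  perms <- character(n_runs)
  for (r in seq_len(n_runs)) {
    base <- bases[[mode_of[r]]]
    Qr <- if (noise_sd == 0) base else {
      conc <- 1 / noise_sd^2
      t(apply(base, 1, function(q) {
        a <- pmax(q, 1e-9) * conc
        x <- stats::rgamma(K, shape = a)
        x / sum(x)
      }))
    }
    perm <- if (permute) sample(K) else seq_len(K)
    Qr <- Qr[, perm, drop = FALSE]
    rownames(Qr) <- rownames(true_q)
    runs[[r]] <- q_matrix(Qr, tol = 1e-6)
    perms[r] <- paste(perm, collapse = ",")
  }
  info <- data.frame(run = seq_len(n_runs), mode = mode_of,
                     permutation = perms, seed = seed,
                     stringsAsFactors = FALSE)
  structure(list(K = K, runs = runs, info = info), class = "run_ensemble")
}

# Alternative-mode Q: merge the two closest columns, re-split the largest.
.second_mode <- function(q) {
  K <- ncol(q)
  if (K < 3) stop("modes = 2 needs K >= 3")
  d <- as.matrix(stats::dist(t(q)))
  diag(d) <- Inf
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  i <- min(ij); j <- max(ij)
  merged <- q[, i] + q[, j]
  rest <- q[, -c(i, j), drop = FALSE]
  big <- which.max(colSums(rest))
  out <- cbind(rest[, -big, drop = FALSE],
               merged, rest[, big] / 2, rest[, big] / 2)
  colnames(out) <- NULL
  out
}

#' Simulate a toy genome pair with planted structural variants
#'
#' Builds a random base genome, then applies a set of non-overlapping
#' insertion / deletion / tandem-duplication events left-to-right to obtain
#' the alternate genome. A transposable-element track covering a configured
#' fraction of the planted events is emitted alongside, so TE-overlap
#' accounting can be checked against ground truth.
#'
#' @param base_len reference length in bp (>= 10000).
#' @param sv_spec data.frame with columns `svtype` (INS/DEL/DUP_TANDEM),
#'   `pos` (0-based reference position) and `length` (bp); events must not
#'   overlap on the reference. May have zero rows.
#' @param seed integer seed (required).
#' @param te_cover fraction of planted events covered by the TE track
#'   (default 0.7).
#' @return list with `ref`, `alt` (single-contig named character vectors),
#'   `svs` (truth `sv_set` on the reference), `te` ([interval_set()]),
#'   and `ins_te_flags` (logical per INS record, TE-derived or not).
#' @export
simulate_toy_genome_pair <- function(base_len, sv_spec = NULL, seed,
                                     te_cover = 0.7) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (base_len < 10000) stop("base_len must be >= 10 kb")
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), base_len, replace = TRUE),
               collapse = "")
  if (is.null(sv_spec) || nrow(sv_spec) == 0) {
    empty <- sv_records()
    return(list(ref = c(chr1 = ref), alt = c(chr1 = ref), svs = empty,
                te = interval_set(), ins_te_flags = logical(0)))
  }
  spec <- sv_spec[order(sv_spec$pos), , drop = FALSE]
  if (!all(spec$svtype %in% SV_TYPES)) stop("unknown svtype in sv_spec")
  if (any(spec$length <= 0)) stop("event lengths must be positive")
  # reference footprint: INS occupies 1 bp, DEL/DUP their interval
  foot_end <- spec$pos + ifelse(spec$svtype == "INS", 1L, spec$length)
  if (any(spec$pos[-1] < foot_end[-nrow(spec)]))
    stop("planted events overlap on the base genome")
  if (max(foot_end) > base_len) stop("event extends past the genome end")

  pieces <- character(0)
  cursor <- 0L   # 0-based position on ref consumed so far
  rn <- character(0); st <- integer(0); en <- integer(0)
  ty <- character(0); ln <- integer(0)
  for (r in seq_len(nrow(spec))) {
    type <- spec$svtype[r]; pos <- spec$pos[r]; len <- spec$length[r]
    pieces <- c(pieces, substr(ref, cursor + 1L, pos))
    if (type == "DEL") {
      cursor <- pos + len
      st <- c(st, pos); en <- c(en, pos + len)
    } else if (type == "DUP_TANDEM") {
      seg <- substr(ref, pos + 1L, pos + len)
      pieces <- c(pieces, seg, seg)
      cursor <- pos + len
      st <- c(st, pos); en <- c(en, pos + len)
    } else { # INS
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      pieces <- c(pieces, substr(ref, pos + 1L, pos + 1L), ins)
      cursor <- pos + 1L
      st <- c(st, pos); en <- c(en, pos + 1L)
    }
    rn <- c(rn, "chr1"); ty <- c(ty, type); ln <- c(ln, len)
  }
  pieces <- c(pieces, substr(ref, cursor + 1L, base_len))
  alt <- paste(pieces, collapse = "")
  svs <- sv_records(rn, st, en, ty, ln)

  # TE track: cover a te_cover fraction of events (chosen at random),
  # extending each covered event's reference footprint slightly.
  n_ev <- nrow(svs)
  covered <- sort(sample(n_ev, round(te_cover * n_ev)))
  te_start <- pmax(0L, svs$start[covered] - 10L)
  te_end <- pmin(base_len, svs$end[covered] + 10L)
  te <- interval_set(rep("chr1", length(covered)), te_start, te_end)
  ins_idx <- which(svs$svtype == "INS")
  ins_te_flags <- ins_idx %in% covered
  list(ref = c(chr1 = ref), alt = c(chr1 = alt), svs = svs, te = te,
       ins_te_flags = ins_te_flags, te_covered_events = covered)
}

#' Draw a random non-overlapping SV specification
#'
#' Convenience generator for [simulate_toy_genome_pair()]: event positions
#' are spaced at least `min_gap` apart, lengths uniform in
#' `[min_len, max_len]`, types drawn uniformly from the three SV classes.
#'
#' @param n_events number of events.
#' @param base_len genome length the events must fit in.
#' @param min_len,max_len event length range in bp.
#' @param min_gap minimum distance between consecutive event footprints.
#' @param seed integer seed (required).
#' @return data.frame with `svtype`, `pos`, `length`.
#' @export
random_sv_spec <- function(n_events, base_len, min_len = 200, max_len = 2000,
                           min_gap = 2000, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  lens <- as.integer(round(stats::runif(n_events, min_len, max_len)))
  types <- sample(SV_TYPES, n_events, replace = TRUE)
  foot <- ifelse(types == "INS", 1L, lens)
  slack <- base_len - sum(foot) - (n_events + 1L) * min_gap
  if (slack < 0) stop("events do not fit: increase base_len or reduce events")
  extra <- stats::runif(n_events + 1L)
  extra <- floor(extra / sum(extra) * slack)
  pos <- integer(n_events)
  cursor <- 0L
  for (i in seq_len(n_events)) {
    cursor <- cursor + min_gap + extra[i]
    pos[i] <- cursor
    cursor <- cursor + foot[i]
  }
  data.frame(svtype = types, pos = pos, length = lens,
             stringsAsFactors = FALSE)
}

#' Simulate shotgun reads from a genome
#'
#' Reads of fixed length are placed uniformly at random on the forward
#' strand until the requested coverage is reached; sequencing errors are
#' independent substitutions at the stated rate.
#'
#' @param genome named character vector of contig sequences.
#' @param coverage target mean depth (> 0).
#' @param read_len read length in bp (<= shortest contig).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer seed (required).
#' @return named character vector of reads.
#' @export
simulate_reads <- function(genome, coverage, read_len, error_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (coverage <= 0) stop("coverage must be > 0")
  lens <- nchar(genome)
  if (read_len > min(lens)) stop("read_len exceeds a contig length")
  set.seed(seed)
  out <- character(0)
  for (ci in seq_along(genome)) {
    L <- lens[ci]
    n_reads <- max(1L, as.integer(round(coverage * L / read_len)))
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    reads <- substring(genome[[ci]], starts, starts + read_len - 1L)
    if (error_rate > 0) {
      reads <- vapply(reads, function(rd) {
        hit <- which(stats::runif(read_len) < error_rate)
        if (!length(hit)) return(rd)
        ch <- strsplit(rd, "", fixed = TRUE)[[1]]
        for (h in hit)
          ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    names(reads) <- sprintf("%s_read%06d", names(genome)[ci], seq_len(n_reads))
    out <- c(out, reads)
  }
  out
}
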