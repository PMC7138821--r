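#' Fragment an assembly into redundant pseudo-reads
#'
#' Emulates cutting an assembly into fixed-length pseudo-reads at a stated
#' redundancy: for each phase p in 0..redundancy-1, the contig is tiled by
#' non-overlapping windows of `read_len` starting at offset
#' `p * read_len / redundancy`, so every interior base is covered
#' `redundancy` (or `redundancy - 1`) times. Terminal partial windows are
#' kept when at least `read_len / 10`; a contig shorter than that is
#' emitted whole with a warning.
#'
#' @param seqs named character vector of contig sequences, or a named
#'   integer vector of contig lengths (sequences are not needed for the
#'   coordinate bookkeeping).
#' @param read_len pseudo-read length in bp (default 50000, >= 1000).
#' @param redundancy number of phase-shifted tilings (default 10, >= 1).
#' @return data.frame of class `pseudo_read_set`: `read_id`, `contig`,
#'   `start` (0-based), `length`, `phase`.
#' @export
fragment <- function(seqs, read_len = 50000, redundancy = 10) {
  if (read_len < 1000) stop("read_len must be >= 1000")
  if (redundancy < 1) stop("redundancy must be >= 1")
  lens <- if (is.numeric(seqs)) stats::setNames(as.integer(seqs), names(seqs))
          else nchar(seqs)
  if (is.null(names(lens))) stop("contigs must be named")
  offset_step <- read_len / redundancy
  min_keep <- read_len / 10
  out <- vector("list", 0)
  for (ci in seq_along(lens)) {
    L <- lens[ci]
    nm <- names(lens)[ci]
    if (L < min_keep) {
      warning("contig '", nm, "' (", L, " bp) shorter than read_len/10; ",
              "emitted whole")
      out[[length(out) + 1]] <- data.frame(
        contig = nm, start = 0L, length = L, phase = 0L,
        stringsAsFactors = FALSE)
      next
    }
    for (p in seq_len(redundancy) - 1L) {
      off <- as.integer(round(p * offset_step))
      starts <- seq.int(off, L - 1L, by = read_len)
      ends <- pmin(starts + read_len, L)
      keep <- (ends - starts) >= min_keep
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        contig = nm, start = starts[keep],
        length = (ends - starts)[keep], phase = p,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$phase, df$start), , drop = FALSE]
  df$read_id <- sprintf("%s_p%d_%d", df$contig, df$phase, df$start)
  rownames(df) <- NULL
  df <- df[, c("read_id", "contig", "start", "length", "phase")]
  class(df) <- c("pseudo_read_set", "data.frame")
  df
}

#' Filter structural variants by type and length
#'
#' Keeps insertions, deletions and tandem duplications up to a maximum
#' length of 25 kb (inclusive: "up to" reads as <=). Dropped records are
#' tallied by reason in the `dropped` attribute.
#'
#' @param svs an `sv_set` (see [sv_records()]).
#' @param max_len length cap in bp (default 25000).
#' @return filtered `sv_set` with attribute `dropped` =
#'   `c(type = ..., length = ...)`.
#' @export
filter_svs <- function(svs, max_len = 25000) {
  ok_type <- svs$svtype %in% SV_TYPES
  ok_len <- svs$length <= max_len
  keep <- ok_type & ok_len
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_set", "data.frame")
  attr(out, "dropped") <- c(type = sum(!ok_type),
                            length = sum(ok_type & !ok_len))
  out
}

#' Reference bases affected by structural variation
#'
#' Deletions and tandem duplications contribute their reference intervals,
#' merged so overlapping records are counted once; insertions contribute
#' their inserted lengths (their reference footprint is a single anchor
#' base).
#'
#' @param svs a filtered `sv_set`.
#' @return total affected bp (numeric).
#' @export
affected_bp <- function(svs) {
  if (!nrow(svs)) return(0)
  span <- svs$svtype %in% c("DEL", "DUP_TANDEM")
  iv <- interval_set(svs$ref_name[span], svs$start[span], svs$end[span])
  total_bp(iv) + sum(svs$length[!span])
}

#' Merged reference intervals of the spanning SV records
#'
#' @param svs an `sv_set`.
#' @return an [interval_set()] over the DEL / DUP_TANDEM records.
#' @export
sv_intervals <- function(svs) {
  span <- svs$svtype %in% c("DEL", "DUP_TANDEM")
  interval_set(svs$ref_name[span], svs$start[span], svs$end[span])
}

#' Bundle one pairwise comparison
#'
#' @param query,reference assembly names.
#' @param svs filtered `sv_set` of the query called against the reference.
#' @param ins_te_flags optional logical per INS record: inserted sequence
#'   classified as TE-derived.
#' @return a `pairwise_sv_summary` list with `affected_bp` precomputed.
#' @export
pairwise_sv_summary <- function(query, reference, svs, ins_te_flags = NULL) {
  n_ins <- sum(svs$svtype == "INS")
  if (!is.null(ins_te_flags) && length(ins_te_flags) != n_ins)
    stop("ins_te_flags must have one entry per INS record")
  structure(list(query = query, reference = reference, svs = svs,
                 ins_te_flags = ins_te_flags,
                 affected_bp = affected_bp(svs)),
            class = "pairwise_sv_summary")
}

#' Fraction of structurally variable sequence that is TE-related
#'
#' Over a set of pairwise comparisons: reference bp of deletion/duplication
#' intervals overlapping the reference's TE track, plus inserted bp of
#' insertions flagged TE-derived, divided by total affected bp.
#' Insertions without flags count as non-TE (classifying inserted sequence
#' against a TE library is external); this conservative default is noted
#' via message once per call.
#'
#' @param summaries list of [pairwise_sv_summary()] objects.
#' @param te_tracks named list of [interval_set()], one per reference
#'   assembly name.
#' @return fraction in [0, 1].
#' @export
te_fraction <- function(summaries, te_tracks) {
  tot <- 0
  te <- 0
  unflagged <- FALSE
  for (s in summaries) {
    if (!s$reference %in% names(te_tracks))
      stop("no TE track for reference '", s$reference, "'")
    track <- te_tracks[[s$reference]]
    iv <- sv_intervals(s$svs)
    te <- te + interval_intersect_bp(iv, track)
    ins_len <- s$svs$length[s$svs$svtype == "INS"]
    if (length(ins_len)) {
      if (is.null(s$ins_te_flags)) unflagged <- TRUE
      else te <- te + sum(ins_len[s$ins_te_flags])
    }
    tot <- tot + s$affected_bp
  }
  if (unflagged)
    message("te_fraction: unflagged insertions counted as non-TE")
  if (tot == 0) return(0)
  te / tot
}

#' Naive pairwise structural-variant detection for toy genomes
#'
#' A desk-scale stand-in for long-read mapping plus SV calling, usable on
#' genomes up to about 1 Mb: k-mers unique in both genomes are anchored,
#' the collinear chain is extracted (longest increasing subsequence on the
#' query side), and each gap between adjacent anchors is classified — a
#' reference-only gap is a deletion, a query-only gap an insertion, and a
#' query gap whose extra sequence duplicates the adjacent reference window
#' a tandem duplication.
#'
#' @param ref,alt single-contig named character vectors (reference and
#'   query genome).
#' @param anchor_k anchor k-mer size (default 21).
#' @param slack bp of gap tolerated as alignment noise (default 10).
#' @param stride keep one anchor per `stride` bp of reference (default 10).
#'   Thinning speeds up chaining without changing gap classification —
#'   both gap sides grow by the same amount — at the cost of up to
#'   `stride` bp of breakpoint blur, which stays below `anchor_k`.
#' @return an `sv_set` on the reference.
#' @export
naive_pair_sv <- function(ref, alt, anchor_k = 21, slack = 10, stride = 10) {
  ref_seq <- unname(ref[[1]])
  alt_seq <- unname(alt[[1]])
  ref_name <- if (!is.null(names(ref))) names(ref)[1] else "ref"
  rk <- .kmer_positions(ref_seq, anchor_k)
  ak <- .kmer_positions(alt_seq, anchor_k)
  shared <- intersect(names(rk), names(ak))
  if (!length(shared)) stop("sequences unrelated at k = ", anchor_k)
  rp <- rk[shared]
  ap <- ak[shared]
  ord <- order(rp)
  rp <- rp[ord]; ap <- ap[ord]
  if (stride > 1) {
    keep <- !duplicated(rp %/% stride)
    rp <- rp[keep]; ap <- ap[keep]
  }
  # collinear chain: longest increasing subsequence of query positions
  lis <- .longest_increasing(ap)
  rp <- rp[lis]; ap <- ap[lis]
  if (length(rp) < 2) stop("anchor chain too short at k = ", anchor_k)

  rn <- character(0); st <- integer(0); en <- integer(0)
  ty <- character(0); ln <- integer(0)
  for (i in seq_len(length(rp) - 1)) {
    gr <- rp[i + 1] - (rp[i] + anchor_k)   # unanchored ref bp
    ga <- ap[i + 1] - (ap[i] + anchor_k)   # unanchored query bp
    if (gr <= slack && ga <= slack) next
    if (ga <= slack) {                     # reference-only gap: deletion
      s0 <- rp[i] + anchor_k - 1L          # 0-based
      rn <- c(rn, ref_name); st <- c(st, s0); en <- c(en, s0 + gr)
      ty <- c(ty, "DEL"); ln <- c(ln, gr)
    } else if (gr <= slack) {              # query-only gap: INS or tandem dup
      s0 <- rp[i] + anchor_k - 1L
      extra <- ga - gr
      gap_seq <- substr(alt_seq, ap[i] + anchor_k, ap[i + 1] - 1L)
      left_win <- substr(ref_seq, max(1L, rp[i] + anchor_k - extra),
                         rp[i] + anchor_k - 1L)
      right_win <- substr(ref_seq, rp[i] + anchor_k,
                          min(nchar(ref_seq), rp[i] + anchor_k + extra - 1L))
      if (.approx_match(gap_seq, left_win) || .approx_match(gap_seq, right_win)) {
        # duplicated copy of the adjacent reference window
        dup_ref_start <- if (.approx_match(gap_seq, right_win)) s0
                         else s0 - extra
        rn <- c(rn, ref_name); st <- c(st, dup_ref_start)
        en <- c(en, dup_ref_start + extra)
        ty <- c(ty, "DUP_TANDEM"); ln <- c(ln, extra)
      } else {
        rn <- c(rn, ref_name); st <- c(st, s0); en <- c(en, s0 + 1L)
        ty <- c(ty, "INS"); ln <- c(ln, extra)
      }
    } else {                               # both gapped: substitution block
      extra <- ga - gr
      s0 <- rp[i] + anchor_k - 1L
      if (extra > slack) {
        gap_seq <- substr(alt_seq, ap[i] + anchor_k, ap[i + 1] - 1L)
        half <- substr(gap_seq, 1L, extra)
        ref_gap <- substr(ref_seq, rp[i] + anchor_k, rp[i + 1] - 1L)
        if (.approx_match(half, substr(ref_gap, 1L, extra))) {
          rn <- c(rn, ref_name); st <- c(st, s0); en <- c(en, s0 + extra)
          ty <- c(ty, "DUP_TANDEM"); ln <- c(ln, extra)
        } else {
          rn <- c(rn, ref_name); st <- c(st, s0); en <- c(en, s0 + 1L)
          ty <- c(ty, "INS"); ln <- c(ln, extra)
        }
      } else if (-extra > slack) {
        rn <- c(rn, ref_name); st <- c(st, s0); en <- c(en, s0 - extra)
        ty <- c(ty, "DEL"); ln <- c(ln, -extra)
      }
    }
  }
  sv_records(rn, st, en, ty, ln)
}

# 1-based start positions of k-mers occurring exactly once in seq
.kmer_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k")
  km <- substring(seq, 1:(L - k + 1), k:L)
  dt <- data.table::data.table(km = km, pos = seq_along(km))
  dt[, "n" := .N, by = "km"]
  dt <- dt[dt$n == 1L]
  stats::setNames(dt$pos, dt$km)
}

.longest_increasing <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- integer(0)      # indices into x of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {       # binary search: first tail with x >= x[i]
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(0)
  i <- tails[length(tails)]
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

# crude identity check tolerant of a few edge mismatches
.approx_match <- function(a, b, max_frac = 0.1) {
  if (nchar(a) == 0 || nchar(b) == 0) return(FALSE)
  L <- min(nchar(a), nchar(b))
  if (abs(nchar(a) - nchar(b)) > max(5, 0.2 * L)) return(FALSE)
  ca <- strsplit(substr(a, 1, L), "")[[1]]
  cb <- strsplit(substr(b, 1, L), "")[[1]]
  mean(ca != cb) <= max_frac
}

#' Pairwise affected-bp matrix over a set of assemblies
#'
#' Runs the naive detector plus the length filter for every ordered pair
#' (query fragmented onto reference is directional; both directions are
#' reported, no symmetrization) and records the affected reference bp.
#'
#' @param assemblies named list of single-contig genomes (named character
#'   vectors as from [simulate_toy_genome_pair()]).
#' @param max_len SV length cap passed to [filter_svs()].
#' @param anchor_k passed to [naive_pair_sv()].
#' @param group_map optional named character vector assembly -> group for
#'   group-mean summaries.
#' @return list with `matrix` (query rows x reference columns, diagonal 0)
#'   and, when `group_map` is given, `group_means` (data.frame).
#' @export
pairwise_matrix <- function(assemblies, max_len = 25000, anchor_k = 21,
                            group_map = NULL) {
  n <- length(assemblies)
  if (n < 2) stop("need at least 2 assemblies")
  nms <- names(assemblies)
  if (is.null(nms)) stop("assemblies must be named")
  M <- matrix(0, n, n, dimnames = list(query = nms, reference = nms))
  for (qi in seq_len(n)) for (ri in seq_len(n)) {
    if (qi == ri) next
    svs <- filter_svs(naive_pair_sv(assemblies[[ri]], assemblies[[qi]],
                                    anchor_k = anchor_k), max_len)
    M[qi, ri] <- affected_bp(svs)
  }
  out <- list(matrix = M)
  if (!is.null(group_map)) {
    gq <- group_map[nms]
    rows <- list()
    for (ga in unique(gq)) for (gb in unique(gq)) {
      sel <- outer(gq == ga, gq == gb) & !diag(n)
      if (!any(sel)) next
      rows[[length(rows) + 1]] <- data.frame(
        query_group = ga, reference_group = gb,
        mean_affected_bp = mean(M[sel]), n_pairs = sum(sel),
        stringsAsFactors = FALSE)
    }
    out$group_means <- do.call(rbind, rows)
  }
  out
}
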