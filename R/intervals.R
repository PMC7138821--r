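#' Normalized genomic interval set
#'
#' Stores 0-based half-open intervals per reference sequence, normalized so
#' that intervals are sorted and disjoint (overlapping or bookended intervals
#' are merged). All interval arithmetic in the package goes through this
#' representation, so affected-bp sums never double-count overlap.
#'
#' @param ref_name character vector of reference sequence names.
#' @param start,end integer vectors, 0-based half-open (`end > start` unless
#'   the interval is empty, which is dropped).
#' @return A data.frame of class `interval_set` with columns
#'   `ref_name`, `start`, `end`, sorted and disjoint within each reference.
#' @export
interval_set <- function(ref_name = character(), start = integer(), end = integer()) {
  stopifnot(length(ref_name) == length(start), length(start) == length(end))
  if (length(start) && any(end < start)) {
    bad <- which(end < start)[1]
    stop("interval ", bad, " on '", ref_name[bad], "' has end < start (",
         start[bad], " > ", end[bad], ")")
  }
  keep <- end > start
  ref_name <- as.character(ref_name)[keep]
  start <- as.integer(start)[keep]
  end <- as.integer(end)[keep]
  out <- list()
  for (rn in sort(unique(ref_name))) {
    i <- ref_name == rn
    # IRanges is 1-based closed; shift on the way in and out
    ir <- IRanges::reduce(IRanges::IRanges(start = start[i] + 1L, end = end[i]))
    out[[rn]] <- data.frame(ref_name = rn,
                            start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir),
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ref_name = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("interval_set", "data.frame")
  res
}

#' Total bases covered by an interval set
#'
#' @param x an `interval_set`.
#' @return integer, the sum of interval widths (each base counted once).
#' @export
total_bp <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  if (!nrow(x)) return(0L)
  sum(x$end - x$start)
}

#' Bases shared between two interval sets
#'
#' @param a,b `interval_set` objects.
#' @return integer, the number of bases covered by both sets.
#' @export
interval_intersect_bp <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  refs <- intersect(unique(a$ref_name), unique(b$ref_name))
  tot <- 0L
  for (rn in refs) {
    ia <- a[a$ref_name == rn, ]
    ib <- b[b$ref_name == rn, ]
    ra <- IRanges::IRanges(start = ia$start + 1L, end = ia$end)
    rb <- IRanges::IRanges(start = ib$start + 1L, end = ib$end)
    tot <- tot + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  tot
}
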