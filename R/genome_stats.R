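#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (as the printed assembly tables
#' do), rather than R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Contig N50
#'
#' The smallest contig length L such that contigs of length >= L together
#' cover at least half of the assembly.
#'
#' @param lengths positive contig lengths in bp.
#' @return N50 in bp.
#' @export
contig_n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Count assembly gaps
#'
#' A gap is a maximal run of N characters (case-insensitive).
#'
#' @param sequence nucleotide sequence string (or vector; counts are summed).
#' @return integer number of gap runs.
#' @export
gap_count <- function(sequence) {
  hits <- stringi::stri_count_regex(toupper(sequence), "N+")
  sum(hits)
}

#' Adjusted BUSCO completeness
#'
#' Rescales a raw BUSCO completeness percentage from the full benchmark set
#' to the set excluding genes absent from the whole lineage (13 of 1,440
#' benchmark genes are absent from all tested cereal genomes, so they
#' artificially depress every raw score): `raw * total / (total -
#' excluded)`, rounded half-up to 2 decimals. A result above 100 is capped
#' with a warning.
#'
#' @param raw_pct raw completeness in percent (0..100), vectorized.
#' @param total benchmark set size (default 1440).
#' @param excluded lineage-absent genes removed (default 13).
#' @return adjusted percentage(s), 2 decimals.
#' @export
adjusted_busco <- function(raw_pct, total = 1440, excluded = 13) {
  if (any(raw_pct < 0 | raw_pct > 100)) stop("raw_pct must be in [0, 100]")
  if (excluded >= total) stop("excluded must be < total")
  adj <- round_half_up(raw_pct * total / (total - excluded), 2)
  if (any(adj > 100)) {
    warning("adjusted completeness above 100% capped")
    adj <- pmin(adj, 100)
  }
  adj
}

#' Build a BUSCO missing-gene panel
#'
#' @param missing_sets named list: per assembly, the character ids of
#'   benchmark genes reported missing.
#' @param outgroup_presence logical matrix genes x outgroup genomes (TRUE =
#'   found in that outgroup); rownames are gene ids. Genes not listed are
#'   treated as absent from the outgroups.
#' @param universe character vector of all benchmark gene ids.
#' @return a `busco_panel` list.
#' @export
busco_panel <- function(missing_sets, outgroup_presence = NULL,
                        universe = NULL) {
  if (!length(missing_sets)) stop("empty panel")
  if (is.null(universe)) universe <- unique(unlist(missing_sets))
  for (nm in names(missing_sets))
    if (!all(missing_sets[[nm]] %in% universe))
      stop("assembly '", nm, "' lists genes outside the universe")
  if (!length(universe)) stop("empty gene universe")
  structure(list(missing_sets = missing_sets,
                 outgroup_presence = outgroup_presence,
                 universe = universe),
            class = "busco_panel")
}

#' Genes missing from every assembly, and from the whole lineage
#'
#' `missing_in_all` is the intersection of the per-assembly missing sets —
#' benchmark genes absent from every assembly under evaluation.
#' `lineage_absent` is its subset also absent from every outgroup genome in
#' the presence table; these are the genes excluded by the adjusted
#' completeness correction.
#'
#' @param panel a [busco_panel()].
#' @return list with character vectors `missing_in_all` and
#'   `lineage_absent`.
#' @export
universal_missing <- function(panel) {
  stopifnot(inherits(panel, "busco_panel"))
  mia <- Reduce(intersect, panel$missing_sets)
  op <- panel$outgroup_presence
  la <- if (is.null(op)) mia else {
    present_somewhere <- rownames(op)[rowSums(op) > 0]
    setdiff(mia, present_somewhere)
  }
  list(missing_in_all = sort(mia), lineage_absent = sort(la))
}

#' Estimate genome size from a k-mer spectrum
#'
#' Counts canonical k-mers across the reads, builds the depth histogram,
#' locates the coverage peak (the histogram mode at depth >= `min_depth`,
#' after excluding the low-depth error limb up to the first local minimum),
#' and estimates genome size as total counted k-mers divided by the peak
#' depth. The integer mode is refined by parabolic interpolation through
#' its two neighbours, removing the bias from the effective per-base k-mer
#' coverage falling between integers.
#'
#' @param reads named character vector of reads (or a FASTA path).
#' @param k k-mer size, 13..31 (default 17).
#' @param min_depth smallest depth eligible as the coverage peak
#'   (default 2; use 1 for error-free single-copy input).
#' @return list with `genome_size` (bp estimate), `peak_depth`
#'   (interpolated), `total_kmers`, and `histogram` (data.frame depth,
#'   count).
#' @export
kmer_genome_size <- function(reads, k = 17, min_depth = 2) {
  if (k < 13 || k > 31) stop("k must be in 13..31")
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fasta(reads)
  counts <- .canonical_kmer_counts(reads, k)
  total <- sum(counts)
  h <- table(counts)
  depth <- as.integer(names(h))
  cnt <- as.integer(h)
  hist_df <- data.frame(depth = depth, count = cnt)
  # dense vector over 1..max depth for peak finding
  dense <- integer(max(depth))
  dense[depth] <- cnt
  lo <- as.integer(min_depth)
  if (lo > length(dense)) stop("no k-mer reaches min_depth")
  region <- dense[lo:length(dense)]
  if (length(region) == 1) {
    cut_i <- 1L
  } else if (region[1] <= region[2]) {
    # no error limb at the start of the eligible range
    cut_i <- 1L
  } else {
    # descending error limb: find first local minimum, search beyond it
    dmin <- which(diff(region) >= 0)[1]
    if (is.na(dmin))
      stop("no local minimum separating the error peak; ",
           "coverage too low for a depth peak — use deeper sequencing")
    cut_i <- dmin + 1L
  }
  cut_d <- lo + cut_i - 1L
  # The coverage component is near-symmetric around its peak, while bin
  # counts are overdispersed (adjacent k-mers share reads), so the
  # count-weighted mean depth over the component estimates the fractional
  # peak far more stably than the integer histogram mode. Error-limb
  # k-mers (below the cut) are excluded from both the peak and the total.
  dd <- cut_d:length(dense)
  cc <- dense[dd]
  if (sum(cc) == 0) stop("no k-mers beyond the error limb")
  peak <- sum(as.numeric(dd) * cc) / sum(cc)
  total_main <- sum(as.numeric(dd) * cc)
  list(genome_size = total_main / peak, peak_depth = peak,
       mode_depth = dd[which.max(cc)], total_kmers = total,
       histogram = hist_df)
}

# Canonical (strand-collapsed) k-mer multiplicities, k-mers with N dropped.
.canonical_kmer_counts <- function(reads, k) {
  reads <- toupper(reads)
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) stop("no read is as long as k")
  kmers <- unlist(lapply(reads, function(rd) {
    L <- nchar(rd)
    substring(rd, 1:(L - k + 1), k:L)
  }), use.names = FALSE)
  kmers <- kmers[!stringi::stri_detect_fixed(kmers, "N")]
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", kmers))
  canon <- ifelse(kmers <= rc, kmers, rc)
  dt <- data.table::data.table(km = canon)
  dt[, .N, by = "km"]$N
}

#' Summarize the numeric columns of a statistics table
#'
#' Arithmetic mean (half-up, 2 decimals), minimum and maximum with their
#' row labels, for each numeric column of an assembly/TE statistics table.
#'
#' @param stats data.frame, or path to a CSV read with headers.
#' @param label_col column holding row labels (name or index, default 1).
#' @return data.frame: `column`, `mean`, `min`, `min_label`, `max`,
#'   `max_label`, `n`.
#' @export
table_summaries <- function(stats, label_col = 1) {
  if (is.character(stats) && length(stats) == 1)
    stats <- utils::read.csv(stats, check.names = FALSE,
                             stringsAsFactors = FALSE)
  labels <- as.character(stats[[label_col]])
  if (is.numeric(label_col)) stats <- stats[, -label_col, drop = FALSE]
  else stats <- stats[, setdiff(names(stats), label_col), drop = FALSE]
  rows <- lapply(names(stats), function(cn) {
    x <- stats[[cn]]
    if (!is.numeric(x)) {
      conv <- suppressWarnings(as.numeric(x))
      if (anyNA(conv) && !all(is.na(conv) == is.na(x)))
        stop("non-numeric cell in column '", cn, "': ",
             x[which(is.na(conv) & !is.na(x))[1]])
      x <- conv
    }
    data.frame(column = cn, mean = round_half_up(mean(x), 2),
               min = min(x), min_label = labels[which.min(x)],
               max = max(x), max_label = labels[which.max(x)],
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count rows passing a comparison
#'
#' @param x numeric vector.
#' @param op one of `"<"`, `"<="`, `">"`, `">="`.
#' @param value threshold.
#' @return integer count.
#' @export
count_passing <- function(x, op, value) {
  f <- match.fun(op)
  sum(f(x, value))
}

#' Printed assembly statistics of the 12 new rice genomes
#'
#' The published per-assembly table bundled as plain CSV: genome size,
#' contig count, contig N50, gap count, scaffold N50, raw and adjusted
#' BUSCO completeness. These printed values are inputs for the summary
#' arithmetic and the BUSCO-adjustment verification.
#'
#' @return data.frame, one row per assembly.
#' @export
assembly_stats_table <- function() {
  path <- system.file("extdata", "assembly_stats.csv", package = "panstruct",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Printed transposable-element content of the 16 rice genomes
#'
#' Percent of each genome annotated as TE, by class (Total, LTR-RT, LINEs,
#' SINEs, DNA-TEs, Unclassified), bundled as plain CSV.
#'
#' @return data.frame, one row per genome.
#' @export
te_content_table <- function() {
  path <- system.file("extdata", "te_content.csv", package = "panstruct",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
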