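#' Validate a Q matrix of admixture proportions
#'
#' A Q matrix holds one row per sample and one column per ancestral group;
#' rows are points on the simplex (entries in [0,1], summing to 1).
#'
#' @param proportions numeric matrix, samples x K.
#' @param sample_ids optional character vector of unique sample ids; taken
#'   from rownames if absent, generated (`S1..Sn`) otherwise.
#' @param tol allowed deviation of each row sum from 1 (default 1e-6).
#' @return the validated matrix with sample ids as rownames.
#' @export
q_matrix <- function(proportions, sample_ids = NULL, tol = 1e-6) {
  proportions <- as.matrix(proportions)
  if (ncol(proportions) < 2)
    stop("a Q matrix needs K >= 2 columns, got ", ncol(proportions))
  if (is.null(sample_ids)) sample_ids <- rownames(proportions)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(proportions)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(sample_ids) != nrow(proportions))
    stop("sample_ids length does not match row count")
  if (any(proportions < -tol | proportions > 1 + tol))
    stop("admixture proportions outside [0,1]")
  rs <- rowSums(proportions)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop("row ", bad[1], " (", sample_ids[bad[1]], ") sums to ",
         format(rs[bad[1]]), ", not 1")
  proportions[proportions < 0] <- 0
  proportions[proportions > 1] <- 1
  rownames(proportions) <- sample_ids
  colnames(proportions) <- NULL
  proportions
}

#' Read a whitespace-delimited .Q file of admixture proportions
#'
#' The interchange format written by ADMIXTURE and consumed by CLUMPP-style
#' aggregation: one row per sample, K whitespace-separated proportions, no
#' header. K is inferred from the column count. Rows whose sum is within
#' 1e-3 of 1 are renormalized to sum exactly 1; larger deviations are an
#' error naming the offending row.
#'
#' @param path file path.
#' @param sample_ids optional sample ids (the format itself carries none).
#' @return a validated Q matrix (see [q_matrix()]).
#' @export
read_q_file <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path)
  nf <- nf[!is.na(nf)]
  if (!length(nf)) stop("empty .Q file: ", path)
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nf), collapse = ", "))
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-3)
  if (length(bad))
    stop("row ", bad[1], " of ", path, " sums to ", format(rs[bad[1]]),
         " (deviation > 1e-3)")
  m <- m / rs
  q_matrix(m, sample_ids = sample_ids)
}

#' Write a Q matrix in .Q interchange format
#'
#' @param q a Q matrix.
#' @param path output path.
#' @param digits significant digits written (default 10, round-trips to 1e-6).
#' @return `path`, invisibly.
#' @export
write_q_file <- function(q, path, digits = 10) {
  txt <- apply(q, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                       collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Dosages count copies of the alternate allele (0, 1 or 2); missing calls
#' are NA. Two plain-text dialects are supported:
#' \describe{
#'   \item{simple_matrix}{header row of SNP ids; one row per sample with the
#'     sample id in the first column; missing written as `NA`.}
#'   \item{plink_raw_like}{a PLINK `--recode A` style table with columns
#'     FID IID PAT MAT SEX PHENOTYPE followed by per-SNP dosages; IID is
#'     used as the sample id.}
#' }
#'
#' @param path file path.
#' @param dialect one of `"simple_matrix"`, `"plink_raw_like"`.
#' @return integer matrix samples x SNPs, dimnames set, values in
#'   \{0,1,2,NA\}.
#' @export
read_genotypes <- function(path, dialect = c("simple_matrix", "plink_raw_like")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (dialect == "simple_matrix") {
    ids <- as.character(df[[1]])
    g <- as.matrix(df[, -1, drop = FALSE])
  } else {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(df)[seq_len(6)]))
      stop("plink_raw_like file must start with columns ",
           paste(need, collapse = " "))
    ids <- as.character(df[["IID"]])
    g <- as.matrix(df[, -(1:6), drop = FALSE])
  }
  storage.mode(g) <- "integer"
  ok <- is.na(g) | g %in% 0:2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("dosage out of range at sample '", ids[bad[1]], "', SNP '",
         colnames(g)[bad[2]], "': ", g[bad[1], bad[2]])
  }
  genotype_matrix(g, sample_ids = ids, snp_ids = colnames(g))
}

#' Validate a genotype dosage matrix
#'
#' @param dosages integer matrix samples x SNPs with values in \{0,1,2,NA\}.
#' @param sample_ids,snp_ids optional unique ids (taken from dimnames).
#' @return the validated integer matrix with dimnames set.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(sample_ids)) sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  if (!all(is.na(dosages) | dosages %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(sample_ids, snp_ids)
  dosages
}

#' Write a genotype matrix
#'
#' @param g genotype matrix (see [genotype_matrix()]).
#' @param path output path.
#' @param dialect as in [read_genotypes()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("simple_matrix", "plink_raw_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple_matrix") {
    df <- data.frame(sample = rownames(g), g, check.names = FALSE)
  } else {
    df <- data.frame(FID = rownames(g), IID = rownames(g), PAT = 0, MAT = 0,
                     SEX = 0, PHENOTYPE = -9, g, check.names = FALSE)
  }
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- structural variant records ------------------------------------------

SV_TYPES <- c("INS", "DEL", "DUP_TANDEM")

#' Construct a table of structural-variant records
#'
#' Coordinates are 0-based half-open on the reference. For DEL and
#' DUP_TANDEM the record spans the affected reference interval and
#' `length = end - start`; an INS occupies the single anchor base
#' `[start, start + 1)` and carries its inserted length separately.
#'
#' @param ref_name,start,end,svtype,length parallel vectors.
#' @return data.frame of class `sv_set`.
#' @export
sv_records <- function(ref_name = character(), start = integer(),
                       end = integer(), svtype = character(),
                       length = integer()) {
  df <- data.frame(ref_name = as.character(ref_name),
                   start = as.integer(start), end = as.integer(end),
                   svtype = as.character(svtype), length = as.integer(length),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$svtype %in% SV_TYPES))
      stop("unknown svtype: ", paste(setdiff(df$svtype, SV_TYPES), collapse = ", "))
    if (any(df$end < df$start)) stop("SV record with end < start")
    if (any(df$length <= 0)) stop("SV record with non-positive length")
    span <- df$svtype %in% c("DEL", "DUP_TANDEM")
    if (any(df$length[span] != (df$end - df$start)[span]))
      stop("DEL/DUP_TANDEM records must have length == end - start")
    if (any(df$end[!span] != df$start[!span] + 1L))
      stop("INS records must span the single anchor base [start, start+1)")
  }
  class(df) <- c("sv_set", "data.frame")
  df
}

#' Read structural variants from a VCF
#'
#' Parses a VCF carrying SVTYPE (and SVLEN and/or END) INFO keys, the
#' convention of long-read SV callers. Only insertions (`INS`), deletions
#' (`DEL`) and tandem duplications (`DUP:TANDEM`, normalized to
#' `DUP_TANDEM`) are retained; other SVTYPEs are dropped and counted.
#' Records with neither SVLEN nor END are skipped and counted. VCF POS
#' (1-based) is converted to the internal 0-based half-open convention: a
#' deletion POS=101, END=200 becomes the interval [100, 200), length 100.
#'
#' @param path VCF path (plain text).
#' @return an `sv_set` (see [sv_records()]) with attributes
#'   `dropped_svtype` and `skipped_no_length` giving drop counts.
#' @export
read_sv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  info <- VariantAnnotation::info(vcf)
  n <- nrow(vcf)
  if (n == 0) {
    out <- sv_records()
    attr(out, "dropped_svtype") <- 0L
    attr(out, "skipped_no_length") <- 0L
    return(out)
  }
  svtype <- as.character(info$SVTYPE)
  svtype[svtype == "DUP:TANDEM"] <- "DUP_TANDEM"
  pos <- BiocGenerics::start(vcf)
  chrom <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf)))
  svlen <- if ("SVLEN" %in% names(info)) info$SVLEN else rep(NA, n)
  if (is(svlen, "List") || is.list(svlen))
    svlen <- vapply(svlen, function(x) if (length(x)) as.numeric(x[1]) else NA_real_,
                    numeric(1))
  svlen <- as.numeric(svlen)
  endv <- if ("END" %in% names(info)) suppressWarnings(as.numeric(info$END)) else rep(NA_real_, n)

  keep_type <- svtype %in% SV_TYPES
  dropped_svtype <- sum(!keep_type)

  have_len <- !is.na(svlen) | !is.na(endv)
  skipped <- sum(keep_type & !have_len)
  keep <- keep_type & have_len

  rn <- character(0); st <- integer(0); en <- integer(0)
  ty <- character(0); ln <- integer(0)
  for (i in which(keep)) {
    type <- svtype[i]
    start0 <- pos[i] - 1L
    if (type == "INS") {
      len <- if (!is.na(svlen[i])) abs(svlen[i]) else endv[i] - pos[i] + 1
      end0 <- start0 + 1L
    } else {
      if (!is.na(endv[i])) {
        end0 <- as.integer(endv[i])
        len <- end0 - start0
      } else {
        len <- abs(svlen[i])
        end0 <- start0 + as.integer(len)
      }
    }
    if (is.na(len) || len <= 0) { skipped <- skipped + 1L; next }
    rn <- c(rn, chrom[i]); st <- c(st, start0); en <- c(en, as.integer(end0))
    ty <- c(ty, type); ln <- c(ln, as.integer(len))
  }
  out <- sv_records(rn, st, en, ty, ln)
  attr(out, "dropped_svtype") <- as.integer(dropped_svtype)
  attr(out, "skipped_no_length") <- as.integer(skipped)
  if (dropped_svtype > 0)
    message("read_sv_vcf: dropped ", dropped_svtype,
            " record(s) with SVTYPE outside {INS, DEL, DUP:TANDEM}")
  out
}

#' Write structural variants as a minimal VCF
#'
#' Inverse of [read_sv_vcf()] for fixtures: 0-based half-open records are
#' restored to 1-based POS/END with SVTYPE/SVLEN/END INFO keys.
#'
#' @param svs an `sv_set`.
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">")
  if (is.null(contig_lengths)) {
    refs <- unique(svs$ref_name)
    if (length(refs))
      hdr <- c(hdr, paste0("##contig=<ID=", refs, ">"))
  } else {
    hdr <- c(hdr, paste0("##contig=<ID=", names(contig_lengths),
                         ",length=", contig_lengths, ">"))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(svs)) {
    vcf_type <- ifelse(svs$svtype == "DUP_TANDEM", "DUP:TANDEM", svs$svtype)
    alt <- paste0("<", vcf_type, ">")
    svlen <- ifelse(svs$svtype == "DEL", -svs$length, svs$length)
    rows <- paste(svs$ref_name, svs$start + 1L, ".", "N", alt, ".", "PASS",
                  paste0("SVTYPE=", vcf_type, ";SVLEN=", svlen,
                         ";END=", svs$end),
                  sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## ---- FASTA / BED ----------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Sequences are validated against the nucleotide alphabet
#' (A, C, G, T, N, case-insensitive) and upper-cased.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  # read without an alphabet so foreign symbols reach our validator
  # (DNAStringSet would silently drop them)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  bad <- stringi::stri_detect_regex(seqs, "[^ACGTN]")
  if (any(bad)) {
    sym <- unique(unlist(stringi::stri_extract_all_regex(seqs[bad], "[^ACGTN]")))
    stop("non-nucleotide symbol(s) in '", names(seqs)[bad][1], "': ",
         paste(sym, collapse = ", "))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a BED file as a normalized interval set
#'
#' Standard 0-based half-open BED, 3+ columns; overlapping intervals are
#' merged on read.
#'
#' @param path BED path.
#' @return an [interval_set()].
#' @export
read_bed <- function(path) {
  if (length(readLines(path, warn = FALSE)) == 0) return(interval_set())
  gr <- rtracklayer::import(path, format = "BED")
  interval_set(ref_name = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr))
}

#' Write an interval set as 3-column BED
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  if (!nrow(x)) { writeLines(character(0), path); return(invisible(path)) }
  utils::write.table(x[, c("ref_name", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
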