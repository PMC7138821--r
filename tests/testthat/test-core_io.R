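test_that("read_q_file parses well-formed files and infers K", {
  f <- withr::local_tempfile(fileext = ".Q")
  writeLines(c("0.7 0.3", "0.2 0.8"), f)
  q <- read_q_file(f)
  expect_equal(ncol(q), 2)
  expect_equal(unname(q[1, ]), c(0.7, 0.3))
})

test_that("read_q_file rejects bad rows with informative errors", {
  f <- withr::local_tempfile(fileext = ".Q")
  writeLines(c("0.7 0.3", "0.5 0.6"), f)
  expect_error(read_q_file(f), "row 2")
  writeLines(c("0.7 0.3", "0.2 0.3 0.5"), f)
  expect_error(read_q_file(f), "ragged")
})

test_that("Q files round-trip to 1e-6", {
  q <- rand_q(15, 4, seed = 1)
  f <- withr::local_tempfile(fileext = ".Q")
  write_q_file(q, f)
  back <- read_q_file(f, sample_ids = rownames(q))
  expect_equal(unname(back), unname(q), tolerance = 1e-6)
})

test_that("genotype matrices round-trip in both dialects and reject bad dosages", {
  set.seed(5)
  g <- genotype_matrix(matrix(sample(c(0:2, NA), 30, replace = TRUE), 5, 6))
  for (d in c("simple_matrix", "plink_raw_like")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_genotypes(g, f, d)
    back <- read_genotypes(f, d)
    expect_identical(unname(back), unname(g))
    expect_identical(rownames(back), rownames(g))
  }
  f <- withr::local_tempfile(fileext = ".txt")
  txt <- readLines(write_genotypes(g, f, "simple_matrix"))
  txt[2] <- sub(" (0|1|2|NA)$", " 7", txt[2])
  writeLines(txt, f)
  expect_error(read_genotypes(f, "simple_matrix"), "out of range")
})

test_that("read_sv_vcf applies the coordinate convention and drops other types", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t300\t.\tN\t<BND>\t.\tPASS\tSVTYPE=BND",
    "chr1\t400\t.\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=250"), f)
  svs <- suppressMessages(read_sv_vcf(f))
  expect_equal(nrow(svs), 2)
  del <- svs[svs$svtype == "DEL", ]
  expect_equal(c(del$start, del$end, del$length), c(100, 200, 100))
  ins <- svs[svs$svtype == "INS", ]
  expect_equal(c(ins$start, ins$end, ins$length), c(399, 400, 250))
  expect_equal(attr(svs, "dropped_svtype"), 1L)
})

test_that("a planted SV set survives the VCF round trip", {
  set.seed(9)
  n <- 50
  starts <- sort(sample.int(90000, n)) + seq_len(n) * 400L  # keep separated
  types <- sample(c("INS", "DEL", "DUP_TANDEM"), n, replace = TRUE)
  lens <- sample(50:300, n, replace = TRUE)
  ends <- ifelse(types == "INS", starts + 1L, starts + lens)
  svs <- sv_records(rep("chr1", n), starts, ends, types, lens)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, f, contig_lengths = c(chr1 = max(ends) + 1000L))
  back <- read_sv_vcf(f)
  expect_equal(nrow(back), n)
  expect_equal(back$length, svs$length)
  expect_equal(back$start, svs$start)
  expect_equal(back$svtype, svs$svtype)
})

test_that("FASTA round-trips and rejects foreign symbols", {
  seqs <- c(a = "ACGTNNACGT", b = "TTTTAAACCC")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  writeLines(c(">x", "ACGQ"), f)
  expect_error(read_fasta(f))
})

test_that("BED reading normalizes to disjoint intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t5\t20"), f)
  iv <- read_bed(f)
  expect_equal(nrow(iv), 1)
  expect_equal(total_bp(iv), 20)
  writeLines(character(0), f)
  expect_equal(total_bp(read_bed(f)), 0L)
})

test_that("interval normalization matches the per-basepair mask oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(1:30, 1)
    starts <- sample(0:9000, n, replace = TRUE)
    ends <- starts + sample(1:800, n, replace = TRUE)
    iv <- interval_set(rep("c", n), starts, ends)
    expect_equal(total_bp(iv), mask_total_bp(starts, ends, 10000))
    expect_true(all(iv$start[-1] > iv$end[-nrow(iv)] - 1))  # disjoint, sorted
  }
})

test_that("interval_intersect_bp matches a mask oracle", {
  set.seed(7)
  for (rep in 1:5) {
    a_s <- sample(0:5000, 10); a_e <- a_s + sample(1:500, 10, replace = TRUE)
    b_s <- sample(0:5000, 10); b_e <- b_s + sample(1:500, 10, replace = TRUE)
    a <- interval_set(rep("c", 10), a_s, a_e)
    b <- interval_set(rep("c", 10), b_s, b_e)
    mask_a <- logical(6000); mask_b <- logical(6000)
    for (i in 1:10) { mask_a[(a_s[i] + 1):a_e[i]] <- TRUE
                      mask_b[(b_s[i] + 1):b_e[i]] <- TRUE }
    expect_equal(interval_intersect_bp(a, b), sum(mask_a & mask_b))
  }
})
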