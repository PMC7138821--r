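test_that("contig N50 matches its definition, including a brute-force scan", {
  expect_equal(contig_n50(c(10, 10, 30)), 30)
  expect_equal(contig_n50(50), 50)
  expect_error(contig_n50(numeric(0)), "empty")
  set.seed(2)
  for (rep in 1:10) {
    lens <- sample(1:500, sample(1:20, 1), replace = TRUE)
    # brute force: smallest L among the lengths with sum(lengths >= L) >= half
    cand <- sort(unique(lens))
    ok <- cand[vapply(cand, function(L) sum(lens[lens >= L]) >= sum(lens) / 2,
                      logical(1))]
    expect_equal(contig_n50(lens), max(ok))
  }
})

test_that("gap counting finds maximal N runs", {
  expect_equal(gap_count("ACGT"), 0)
  expect_equal(gap_count("ACNNNGTNNA"), 2)
  expect_equal(gap_count("nnACGTnn"), 2)
  set.seed(4)
  for (rep in 1:5) {
    k <- sample(0:8, 1)
    parts <- replicate(k + 1,
      paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), replace = TRUE),
            collapse = ""))
    gaps <- replicate(k, strrep("N", sample(1:5, 1)))
    seqx <- paste0(paste0(parts[seq_len(k)], gaps, collapse = ""), parts[k + 1])
    expect_equal(gap_count(seqx), k)
  }
})

test_that("the BUSCO adjustment reproduces all published (raw, adjusted) pairs", {
  tbl <- assembly_stats_table()
  expect_equal(nrow(tbl), 12)
  # the correction is raw * 1440/1427, rounded half-up to 2 decimals;
  # it must reproduce the printed adjusted column bit-for-bit
  expect_equal(adjusted_busco(tbl$busco_raw_pct), tbl$busco_adjusted_pct)
  expect_equal(adjusted_busco(97.60), 98.49)
  expect_equal(adjusted_busco(95.70), 96.57)
  expect_equal(adjusted_busco(98.60), 99.50)
  # properties: linear in raw, identity when nothing is excluded
  expect_equal(adjusted_busco(0), 0)
  expect_equal(adjusted_busco(50, excluded = 0), 50)
  expect_equal(adjusted_busco(80) / 2, adjusted_busco(40), tolerance = 0.01)
  expect_warning(capped <- adjusted_busco(99.9), "capped")
  expect_equal(capped, 100)
})

test_that("universal missing-gene logic intersects assemblies then outgroups", {
  p <- busco_panel(list(asm1 = c("a", "b"), asm2 = c("b", "c")),
                   universe = letters[1:5])
  um <- universal_missing(p)
  expect_equal(um$missing_in_all, "b")
  # an outgroup carrying the gene removes it from the lineage-absent set
  op <- matrix(TRUE, 1, 2, dimnames = list("b", c("og1", "og2")))
  p2 <- busco_panel(list(asm1 = c("a", "b"), asm2 = c("b", "c")),
                    outgroup_presence = op, universe = letters[1:5])
  expect_equal(universal_missing(p2)$lineage_absent, character(0))
  # synthetic panel planted with 16 universally missing / 13 outgroup-absent
  universe <- sprintf("GENE%04d", 1:1440)
  core_missing <- universe[1:16]
  in_outgroups <- core_missing[14:16]
  set.seed(8)
  missing_sets <- lapply(1:12, function(i)
    sort(c(core_missing, sample(universe[-(1:16)], 14))))
  names(missing_sets) <- paste0("asm", 1:12)
  op2 <- matrix(FALSE, 16, 3, dimnames = list(core_missing, paste0("maize", 1:3)))
  op2[in_outgroups, ] <- TRUE
  panel <- busco_panel(missing_sets, outgroup_presence = op2,
                       universe = universe)
  um2 <- universal_missing(panel)
  expect_length(um2$missing_in_all, 16)
  expect_length(um2$lineage_absent, 13)
})

test_that("k-mer genome size handles degenerate and error-bearing input", {
  set.seed(14)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 30000,
                                  replace = TRUE), collapse = ""))
  # single copy of the genome, min_depth 1: estimate = k-mer count
  one <- kmer_genome_size(genome, k = 17, min_depth = 1)
  expect_equal(one$genome_size, 30000 - 16)
  # 15x error-free reads: within 2% of truth, invariant to read order
  reads <- simulate_reads(genome, coverage = 15, read_len = 600, seed = 21)
  est <- kmer_genome_size(reads, k = 17, min_depth = 2)
  expect_lt(abs(est$genome_size - 30000) / 30000, 0.02)
  est_rev <- kmer_genome_size(rev(reads), k = 17, min_depth = 2)
  expect_equal(est$genome_size, est_rev$genome_size)
  # substitution errors populate a depth-1 limb that must be excluded
  reads_e <- simulate_reads(genome, coverage = 15, read_len = 600,
                            error_rate = 0.003, seed = 22)
  est_e <- kmer_genome_size(reads_e, k = 17, min_depth = 1)
  expect_lt(abs(est_e$genome_size - 30000) / 30000, 0.03)
  expect_error(kmer_genome_size(reads, k = 9), "k must be")
})

test_that("table summaries reproduce the published TE and assembly means", {
  te <- te_content_table()
  expect_equal(nrow(te), 16)
  s <- table_summaries(te, "variety")
  expect_equal(s$mean[s$column == "LTR-RT"], 25.96)
  expect_equal(s$mean[s$column == "DNA-TEs"], 15.26)
  expect_equal(s$mean[s$column == "LINEs"], 1.43)

  asm <- assembly_stats_table()
  sa <- table_summaries(asm[, c("variety", "contig_n50_bp", "n_gaps")],
                        "variety")
  expect_equal(round(sa$mean[sa$column == "contig_n50_bp"] / 1e6, 2), 23.10)
  expect_equal(sa$max[sa$column == "contig_n50_bp"], 30913760)
  expect_equal(round(sa$mean[sa$column == "n_gaps"]), 18)
  expect_equal(count_passing(asm$n_gaps, "<", 10), 8)

  single <- table_summaries(data.frame(id = "x", v = 3.14159), "id")
  expect_equal(single$mean, 3.14)
  expect_equal(single$min, single$max)
  bad <- data.frame(id = "x", v = "oops")
  expect_error(table_summaries(bad, "id"), "non-numeric")
})
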