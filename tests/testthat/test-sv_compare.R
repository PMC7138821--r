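test_that("fragmentation meets its coverage bookkeeping", {
  fr <- fragment(c(ctg = 100000L), read_len = 50000, redundancy = 10)
  total <- sum(fr$length)
  expect_lt(abs(total - 10 * 100000), 10 * 50000)   # within one window/phase
  fr1 <- fragment(c(ctg = 100000L), read_len = 50000, redundancy = 1)
  expect_equal(fr1$start, c(0, 50000))
  expect_equal(fr1$length, c(50000, 50000))
  expect_warning(fragment(c(tiny = 2000L), read_len = 50000, redundancy = 2),
                 "emitted whole")
})

test_that("interior base coverage is redundancy or redundancy-1 across a parameter grid", {
  for (params in list(c(20000, 5000, 5), c(30000, 6000, 3), c(40000, 8000, 4))) {
    L <- params[1]; rl <- params[2]; red <- params[3]
    fr <- fragment(c(ctg = L), read_len = rl, redundancy = red)
    cov <- integer(L)
    for (i in seq_len(nrow(fr))) {
      idx <- (fr$start[i] + 1):(fr$start[i] + fr$length[i])
      cov[idx] <- cov[idx] + 1L
    }
    interior <- cov[(rl + 1):(L - rl)]
    expect_true(all(interior %in% c(red - 1L, red)),
                label = sprintf("L=%d rl=%d red=%d", L, rl, red))
  }
})

test_that("the SV filter applies the inclusive 25 kb cap by type", {
  svs <- sv_records(rep("c", 4), c(0, 50000, 100000, 150000),
                    c(25000, 75001, 100001, 180000),
                    c("DEL", "DEL", "INS", "DUP_TANDEM"),
                    c(25000, 25001, 25000, 30000))
  f <- filter_svs(svs)
  expect_equal(f$length, c(25000, 25000))   # boundary kept, 25001/30000 dropped
  expect_equal(unname(attr(f, "dropped")["length"]), 2L)
  # mixed fixture: kept count equals hand enumeration
  set.seed(5)
  n <- 100
  types <- sample(c("INS", "DEL", "DUP_TANDEM"), n, replace = TRUE)
  lens <- sample(c(100, 20000, 26000), n, replace = TRUE)
  starts <- seq(0, by = 30000, length.out = n)
  ends <- ifelse(types == "INS", starts + 1, starts + lens)
  svs2 <- sv_records(rep("c", n), starts, ends, types, lens)
  expect_equal(nrow(filter_svs(svs2)), sum(lens <= 25000))
})

test_that("affected bp merges spans and adds insertion lengths", {
  a <- sv_records(c("c", "c"), c(1000, 3000), c(1500, 3001),
                  c("DEL", "INS"), c(500, 300))
  expect_equal(affected_bp(a), 800)
  b <- sv_records(c("c", "c"), c(0, 50), c(100, 150), c("DEL", "DEL"),
                  c(100, 100))
  expect_equal(affected_bp(b), 150)
  # random record sets vs per-bp mask + INS sum oracle
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    types <- sample(c("INS", "DEL", "DUP_TANDEM"), n, replace = TRUE)
    starts <- sample(0:20000, n)
    lens <- sample(50:2000, n, replace = TRUE)
    ends <- ifelse(types == "INS", starts + 1, starts + lens)
    svs <- sv_records(rep("c", n), starts, ends, types, lens)
    span <- types != "INS"
    oracle <- mask_total_bp(starts[span], ends[span], 25000) +
      sum(lens[!span])
    expect_equal(affected_bp(svs), oracle)
  }
})

test_that("TE fractions recover planted ground truth", {
  # all spans inside TE, all INS flagged -> 1; nothing overlapping -> 0
  svs <- sv_records(c("c", "c"), c(100, 500), c(200, 501),
                    c("DEL", "INS"), c(100, 50))
  s_all <- pairwise_sv_summary("q", "c", svs, ins_te_flags = TRUE)
  expect_equal(te_fraction(list(s_all),
                           list(c = interval_set("c", 0, 1000))), 1)
  s_none <- pairwise_sv_summary("q", "c", svs, ins_te_flags = FALSE)
  expect_equal(te_fraction(list(s_none),
                           list(c = interval_set("c", 5000, 6000))), 0)
  expect_error(te_fraction(list(s_all), list(other = interval_set())),
               "no TE track")
  # planted toy pair: the generator covers 70% of events with the TE track
  spec <- random_sv_spec(20, base_len = 150000, min_len = 300,
                         max_len = 1500, seed = 41)
  toy <- simulate_toy_genome_pair(150000, spec, seed = 42, te_cover = 0.7)
  flags <- toy$ins_te_flags
  summ <- pairwise_sv_summary("alt", "chr1", toy$svs, ins_te_flags = flags)
  frac <- te_fraction(list(summ), list(chr1 = toy$te))
  covered_bp <- sum(toy$svs$length[toy$te_covered_events])
  expect_equal(frac, covered_bp / sum(toy$svs$length), tolerance = 0.01)
})

test_that("the naive detector recovers planted events with correct types", {
  spec <- data.frame(svtype = "DEL", pos = 50000L, length = 500L)
  toy <- simulate_toy_genome_pair(100000, spec, seed = 3)
  det <- naive_pair_sv(toy$ref, toy$alt)
  expect_equal(nrow(det), 1)
  expect_equal(det$svtype, "DEL")
  expect_lt(abs(det$start - 50000), 21)
  expect_lt(abs(det$length - 500), 5)
  # identical sequences: no calls
  expect_equal(nrow(naive_pair_sv(toy$ref, toy$ref)), 0)
  # 20 mixed events >= 200 bp, >= 2 kb apart: >= 90% type-correct recovery
  spec2 <- random_sv_spec(20, base_len = 200000, min_len = 200,
                          max_len = 2000, min_gap = 2000, seed = 11)
  toy2 <- simulate_toy_genome_pair(200000, spec2, seed = 12)
  det2 <- naive_pair_sv(toy2$ref, toy2$alt)
  hits <- 0
  for (i in seq_len(nrow(toy2$svs))) {
    p <- toy2$svs[i, ]
    ok <- any(det2$svtype == p$svtype &
              abs(det2$start - p$start) <= 50 &
              abs(det2$length - p$length) <= 20)
    hits <- hits + ok
  }
  expect_gte(hits / nrow(toy2$svs), 0.9)
})

test_that("pairwise matrices are directional with zero diagonal and ordered divergence", {
  set.seed(61)
  base <- simulate_toy_genome_pair(60000, NULL, seed = 71)$ref
  # same base seed -> same reference; only the planted spec differs
  mk_variant <- function(n_events, spec_seed) {
    spec <- random_sv_spec(n_events, base_len = 60000, min_len = 300,
                           max_len = 800, min_gap = 1500, seed = spec_seed)
    simulate_toy_genome_pair(60000, spec, seed = 71)$alt
  }
  a <- mk_variant(2, 81)
  b <- mk_variant(6, 82)
  cc <- mk_variant(12, 83)
  asm <- list(base = base, a = a, b = b, c = cc)
  pm <- pairwise_matrix(asm[c("base", "a", "b", "c")], anchor_k = 21)
  M <- pm$matrix
  expect_true(all(diag(M) == 0))
  expect_lt(M["a", "base"], M["b", "base"])
  expect_lt(M["b", "base"], M["c", "base"])
  # identical pair contributes zeros both ways
  pm2 <- pairwise_matrix(list(x = base, y = base))
  expect_equal(unname(pm2$matrix), matrix(0, 2, 2))
  expect_error(pairwise_matrix(list(x = base)), "at least 2")
})
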