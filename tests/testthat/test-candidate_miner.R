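test_that("intergenic extraction forms regions only between non-overlapping neighbours", {
  idx <- toy_index(list("a", "c1", 0, 100, "+"),
                   list("b", "c1", 150, 300, "+"))
  r <- extract_intergenic(idx)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(100, 150))
  expect_equal(r$orientation, "tandem")

  # overlapping pair: no region
  idx2 <- toy_index(list("a", "c1", 0, 100, "+"),
                    list("b", "c1", 50, 200, "-"))
  expect_equal(nrow(extract_intergenic(idx2)), 0)

  # nested pair: no region (negative gap)
  idx3 <- toy_index(list("a", "c1", 0, 500, "+"),
                    list("b", "c1", 100, 200, "-"))
  expect_equal(nrow(extract_intergenic(idx3)), 0)

  # abutting genes: zero-length region kept pre-filter
  idx4 <- toy_index(list("a", "c1", 0, 100, "-"),
                    list("b", "c1", 100, 200, "+"))
  r4 <- extract_intergenic(idx4)
  expect_equal(r4$length, 0)
})

test_that("a 20-gene chromosome with 3 planted overlaps yields 16 regions", {
  start <- seq(0, by = 2000, length.out = 20)
  end <- start + 1000
  # plant 3 overlaps: shift three genes left into their predecessor
  for (i in c(5, 11, 17)) start[i] <- end[i - 1] - 200
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), seqid = "c1",
                      start = start, end = end,
                      strand = rep(c("+", "-"), 10), fpkm = 1)
  r <- extract_intergenic(genome_index(genes))
  expect_equal(nrow(r), 16)
  # brute-force oracle agrees
  expect_equal(nrow(r), sum(!is.na(bf_call_candidates(genes)$orientation)))
})

test_that("orientation is a pure function of the strand pair and is flip-symmetric", {
  expect_equal(pair_orientation("-", "+"), "divergent")
  expect_equal(pair_orientation("+", "-"), "convergent")
  expect_equal(pair_orientation("+", "+"), "tandem")
  expect_equal(pair_orientation("-", "-"), "tandem")
  # mirroring coordinates and reversing both strands preserves the class
  flip <- function(s) ifelse(s == "+", "-", "+")
  for (l in c("+", "-")) for (r in c("+", "-")) {
    expect_equal(pair_orientation(l, r),
                 pair_orientation(flip(r), flip(l)))
  }
})

test_that("expression threshold is the inclusive top-fraction order statistic", {
  expect_equal(expression_threshold(c(1, 2, 3, 4), 0.5), 3)
  expect_true(all(c(3, 4) >= expression_threshold(c(1, 2, 3, 4), 0.5)))
  expect_equal(expression_threshold(rep(7, 5), 0.5), 7)  # ties: all top
  expect_equal(expression_threshold(c(5, 1, 9), 1.0), 1) # min value
  expect_error(expression_threshold(numeric(0)), "empty")
})

test_that("the core filter applies orientation, fold-change, window and top-set rules", {
  # 6 filler genes fix the top-50% cutoff; values 10 and 20 are in the top set
  filler <- lapply(1:6, function(i) {
    list(sprintf("f%d", i), "c2", i * 10000, i * 10000 + 500, "+",
         c(0.1, 0.2, 0.5, 1, 30, 40)[i])
  })
  mk <- function(s1, s2, f1, f2, gap = 500) {
    rows <- c(list(list("a", "c1", 0, 1000, s1, f1),
                   list("b", "c1", 1000 + gap, 2000 + gap, s2, f2)),
              filler)
    idx <- do.call(toy_index, rows)
    cands <- call_candidates(extract_intergenic(idx), idx)
    cands[cands$seqid == "c1", ]
  }
  # divergent, fc = 2, both in top set: passes
  expect_true(mk("-", "+", 10, 20)$passes_core_filter)
  # convergent with both flanking genes in the top set fails (need exactly one)
  expect_false(mk("+", "-", 10, 20)$passes_core_filter)
  # convergent with exactly one top gene passes
  expect_true(mk("+", "-", 0.5, 20)$passes_core_filter)
  # fc below 1.5 fails
  expect_false(mk("-", "+", 10, 14)$passes_core_filter)
  # tandem never passes
  expect_false(mk("+", "+", 10, 20)$passes_core_filter)
  # gap below the 50-bp floor fails
  expect_false(mk("-", "+", 10, 20, gap = 25)$passes_core_filter)
  # zero lower FPKM: infinite fold change still passes
  r <- mk("-", "+", 0, 20)
  expect_equal(r$fold_change, Inf)
  expect_true(r$passes_core_filter)
  # both zero: undefined fold change, fails
  r0 <- mk("-", "+", 0, 0)
  expect_true(is.na(r0$fold_change))
  expect_false(r0$passes_core_filter)
})

test_that("divergent plus convergent passing counts partition all passing", {
  g <- gen_genome(generator_config(seed = 21))
  cands <- call_candidates(extract_intergenic(g$index), g$index)
  p <- cands[cands$passes_core_filter, ]
  expect_equal(sum(p$orientation == "divergent") +
                 sum(p$orientation == "convergent"), nrow(p))
})

test_that("candidate calling matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    genes <- random_gene_table(sample(6:40, 1), n_seq = sample(1:3, 1))
    idx <- genome_index(genes)
    got <- call_candidates(extract_intergenic(idx), idx)
    want <- bf_call_candidates(genes)
    got <- got[order(got$region_id), ]
    want <- want[order(want$region_id), ]
    expect_equal(got$region_id, want$region_id)
    expect_equal(got$passes_core_filter, want$passes, info = paste("seed", seed))
    expect_equal(got$fold_change, want$fold_change)
  }
})

test_that("tightening thresholds is monotone in the passing count", {
  g <- gen_genome(generator_config(seed = 31))
  regions <- extract_intergenic(g$index)
  n_pass <- function(...) {
    sum(call_candidates(regions, g$index, miner_params(...))$passes_core_filter)
  }
  base <- n_pass()
  expect_lte(n_pass(min_fc = 3), base)          # raising min_fc
  expect_lte(n_pass(min_fc = 10), n_pass(min_fc = 3))
  expect_gte(n_pass(min_len = 1, max_len = 50000), base)  # widening window
  expect_lte(n_pass(min_len = 200, max_len = 5000), base) # narrowing window
})

test_that("short filter is inclusive at the cutoff and reports the retained fraction", {
  filler <- lapply(1:2, function(i) {
    list(sprintf("f%d", i), "c9", i * 100000, i * 100000 + 500, "+", 0.1)
  })
  rows <- c(filler, unlist(lapply(seq_along(c(400, 1000, 1200)), function(i) {
    len <- c(400, 1000, 1200)[i]
    base <- i * 1e6
    list(list(sprintf("L%d", i), "c1", base, base + 1000, "-", 50),
         list(sprintf("R%d", i), "c1", base + 1000 + len, base + 2500 + len,
              "+", 2))
  }), recursive = FALSE))
  idx <- do.call(toy_index, rows)
  cands <- call_candidates(extract_intergenic(idx), idx)
  expect_equal(sum(cands$passes_core_filter), 3)
  short <- filter_short(cands, 1000)
  expect_equal(sort(short$length), c(400, 1000))  # 1000 retained (inclusive)
  expect_equal(attr(short, "retained_fraction"), 2 / 3)
  none <- filter_short(cands, 300)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "retained_fraction"), 0)
})

test_that("the short fraction of planted candidates tracks the generator setting", {
  cfg <- generator_config(seed = 41, n_chrom = 8, units_per_chrom = 50,
                          p_divergent = 0.5, p_convergent = 0.5)
  g <- gen_genome(cfg)
  cands <- call_candidates(extract_intergenic(g$index), g$index)
  short <- filter_short(cands)
  expect_equal(attr(short, "retained_fraction"), 0.427, tolerance = 0.12)
})
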