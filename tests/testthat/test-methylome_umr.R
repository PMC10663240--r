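site <- function(seqid, pos, context, mc, cov, strand = "+") {
  data.frame(seqid = seqid, pos = pos, strand = strand, context = context,
             mc_reads = mc, total_reads = cov, stringsAsFactors = FALSE)
}

test_that("tiling assigns sites by floor(pos/100) and computes exact sums", {
  sites <- site("c1", 150, "CG", 1, 10)
  tiles <- tile_methylome(sites, seqlens = c(c1 = 300))
  expect_equal(nrow(tiles), 3)
  t2 <- tiles[tiles$start == 100, ]
  expect_equal(t2$n_CG, 1)
  expect_equal(t2$level_CG, 0.10)
  expect_equal(tiles$status[tiles$start != 100], c("missing", "missing"))

  # a sequence with no sites still partitions into missing tiles
  empty <- tile_methylome(sites[0, ], seqlens = c(c1 = 1000))
  expect_equal(nrow(empty), 10)
  expect_true(all(empty$status == "missing"))
})

test_that("hand-written sites across 3 tiles reproduce per-context sums", {
  sites <- rbind(
    site("c1", c(10, 20, 30, 40), "CG", c(1, 0, 2, 1), c(10, 8, 10, 12)),
    site("c1", c(110, 130), "CHG", c(5, 3), c(10, 10)),
    site("c1", c(150, 160, 170), "CHH", c(0, 0, 1), c(9, 11, 10)),
    site("c1", c(210, 220, 230), "CG", c(9, 8, 10), c(10, 10, 10))
  )
  tiles <- tile_methylome(sites, seqlens = c(c1 = 300))
  expect_equal(tiles$n_CG, c(4, 0, 3))
  expect_equal(tiles$mc_CG, c(4, 0, 27))
  expect_equal(tiles$cov_CG, c(40, 0, 30))
  expect_equal(tiles$level_CG, c(0.1, NA, 0.9))
  expect_equal(tiles$n_CHG, c(0, 2, 0))
  expect_equal(tiles$mc_CHG[2] / tiles$cov_CHG[2], 0.4)
  expect_equal(tiles$n_all, c(4, 5, 3))
  expect_equal(tiles$mean_coverage, c(10, 10, 10))
  # read conservation: tile sums equal site sums
  expect_equal(sum(tiles$mc_CG + tiles$mc_CHG + tiles$mc_CHH),
               sum(sites$mc_reads))
  expect_equal(sum(tiles$cov_CG + tiles$cov_CHG + tiles$cov_CHH),
               sum(sites$total_reads))
})

test_that("status rules: cytosine floor, coverage floor, strict 10% ceiling", {
  tl <- function(n_cg, mc, cov, mean_cov) {
    data.frame(seqid = "c1", start = 0, end = 100,
               n_CG = n_cg, mc_CG = mc, cov_CG = cov,
               level_CG = ifelse(cov > 0, mc / cov, NA),
               n_CHG = 0, mc_CHG = 0, cov_CHG = 0, level_CHG = NA,
               n_CHH = 0, mc_CHH = 0, cov_CHH = 0, level_CHH = NA,
               n_all = n_cg, mean_coverage = mean_cov)
  }
  # 1 cytosine at huge coverage: missing under the default (or) rule
  expect_equal(call_tile_status(tl(1, 0, 50, 50)), "missing")
  # ... but not under the "and" reading
  expect_equal(call_tile_status(tl(1, 0, 50, 50), missing_rule = "and"),
               "unmethylated")
  # plenty of cytosines but 4x coverage: missing (or) / unmethylated (and)
  expect_equal(call_tile_status(tl(10, 0, 40, 4)), "missing")
  expect_equal(call_tile_status(tl(10, 0, 40, 4), missing_rule = "and"),
               "unmethylated")
  # low levels in all present contexts: unmethylated
  expect_equal(call_tile_status(tl(10, 10, 200, 20)), "unmethylated")
  # level exactly 0.10: methylated (strict <)
  expect_equal(call_tile_status(tl(10, 20, 200, 20)), "methylated")
})

test_that("UMR merging trims missing flanks and applies span and missing-fraction rules", {
  tl <- function(statuses, seqid = "c1") {
    n <- length(statuses)
    data.frame(seqid = seqid, start = (0:(n - 1)) * 100, end = (1:n) * 100,
               status = statuses, stringsAsFactors = FALSE)
  }
  # three unmethylated tiles: one 300-bp UMR
  u <- merge_umrs(tl(c("unmethylated", "unmethylated", "unmethylated")))
  expect_equal(nrow(u), 1)
  expect_equal(c(u$start, u$end, u$missing_fraction), c(0, 300, 0))
  # U, missing, U: kept, missing fraction exactly 1/3
  u2 <- merge_umrs(tl(c("unmethylated", "missing", "unmethylated")))
  expect_equal(nrow(u2), 1)
  expect_equal(u2$missing_fraction, 1 / 3)
  # U, missing, missing, U: 2/4 missing > 1/3, rejected
  expect_equal(nrow(merge_umrs(tl(c("unmethylated", "missing", "missing",
                                    "unmethylated")))), 0)
  # two 200-bp runs split by a methylated tile: both below 300 bp
  expect_equal(nrow(merge_umrs(tl(c("unmethylated", "unmethylated",
                                    "methylated", "unmethylated",
                                    "unmethylated")))), 0)
  # flanking missing tiles are trimmed before the tests
  u3 <- merge_umrs(tl(c("missing", "unmethylated", "unmethylated",
                        "unmethylated", "missing")))
  expect_equal(nrow(u3), 1)
  expect_equal(c(u3$start, u3$end, u3$n_tiles), c(100, 400, 3))
  # an all-missing run yields nothing
  expect_equal(nrow(merge_umrs(tl(rep("missing", 5)))), 0)
})

test_that("UMR output satisfies its invariants and merging is stable", {
  m <- gen_methylome(c(c1 = 30000, c2 = 20000), generator_config(seed = 5))
  tiles <- tile_methylome(m$sites, seqlens = c(c1 = 30000, c2 = 20000))
  u <- merge_umrs(tiles)
  expect_true(all(u$end - u$start >= 300))
  expect_true(all(u$missing_fraction <= 1 / 3))
  for (sq in unique(u$seqid)) {
    x <- u[u$seqid == sq, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] > x$end[-nrow(x)]))
  }
  expect_identical(merge_umrs(tiles), u)
})

test_that("lowering the level ceiling never increases total UMR bp", {
  m <- gen_methylome(c(c1 = 40000), generator_config(seed = 9, umr_level = 0.05))
  total_bp <- vapply(c(0.25, 0.10, 0.05, 0.02), function(th) {
    tiles <- tile_methylome(m$sites, seqlens = c(c1 = 40000), max_level = th)
    u <- merge_umrs(tiles)
    sum(u$end - u$start)
  }, numeric(1))
  expect_false(is.unsorted(rev(total_bp)))
})

test_that("global weighted levels divide read sums per context", {
  s <- rbind(site("c1", 1:3, "CG", c(1, 1, 1), c(10, 10, 10)),
             site("c1", 4:5, "CHG", c(5, 5), c(5, 5)))
  lev <- global_levels(s)
  expect_equal(lev$CG, 0.10)
  expect_equal(lev$CHG, 1.0)
  expect_true(is.na(lev$CHH))  # no CHH sites
  expect_equal(lev$all, 13 / 40)
  # zero-coverage sites are excluded from the ratio
  s2 <- rbind(s, site("c1", 6, "CG", 0, 0))
  expect_equal(global_levels(s2)$CG, 0.10)
  expect_error(global_levels(s[0, ]), "empty")
})

test_that("candidate/UMR overlap respects the half-open convention", {
  umr <- data.frame(seqid = "c1", start = 199, end = 500)
  cand <- data.frame(seqid = "c1", start = 100, end = 200)
  expect_equal(overlap_candidates(cand, umr)$n_overlapping, 1)  # 1 bp shared
  umr2 <- data.frame(seqid = "c1", start = 200, end = 500)
  expect_equal(overlap_candidates(cand, umr2)$n_overlapping, 0) # abutting
  both <- overlap_candidates(rbind(cand, cand), umr)
  expect_equal(both$pct, 100)
  expect_equal(both$mean_candidate_length, 100)
  expect_equal(both$mean_umr_length, 301)
})

test_that("allc records round-trip through write/read with the 1-based boundary", {
  m <- gen_methylome(c(c1 = 5000), generator_config(seed = 3,
                                                    umrs_per_chrom = 1L))
  path <- tempfile(fileext = ".tsv")
  write_allc(m$sites, path)
  expect_no_warning(back <- read_allc(path))
  expect_equal(back, m$sites)
  raw <- read.delim(path, header = FALSE)
  expect_equal(raw[[2]], m$sites$pos + 1)
})
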