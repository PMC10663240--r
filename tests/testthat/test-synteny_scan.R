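# A small query genome and subject copies with hand-planted rearrangements.
syn_fixture <- function() {
  n <- 8
  q <- genome_index(data.frame(
    gene_id = sprintf("q%02d", 1:n), seqid = "qc1",
    start = (1:n) * 2000, end = (1:n) * 2000 + 1000,
    strand = c("+", "-", "+", "+", "-", "+", "-", "-")
  ), genome_id = "query")
  cand <- data.frame(region_id = "r1", left_gene_id = "q04",
                     right_gene_id = "q05", stringsAsFactors = FALSE)
  list(q = q, cand = cand)
}

subject_from <- function(genes, genome_id) {
  genes$start <- seq_len(nrow(genes)) * 3000
  genes$end <- genes$start + 1000
  genome_index(genes, genome_id = genome_id)
}

test_that("an identical subject genome is called high_quality with 0/0 intervening", {
  fx <- syn_fixture()
  sg <- fx$q$genes
  sg$gene_id <- paste0("s.", sg$gene_id)
  s <- subject_from(sg, "s")
  call <- scan_region(fx$cand, fx$q, s, identity_hits(fx$q, s, "s."))
  expect_equal(call$klass, "high_quality")
  expect_equal(call$intervening_query, 0L)
  expect_equal(call$intervening_subject, 0L)
})

test_that("planted rearrangements are classified as indel, inversion or none", {
  fx <- syn_fixture()
  base <- fx$q$genes[, c("gene_id", "seqid", "start", "end", "strand", "fpkm")]
  base$gene_id <- paste0("s.", base$gene_id)
  mk_call <- function(sg) {
    s <- subject_from(sg, "s")
    scan_region(fx$cand, fx$q, s, identity_hits(fx$q, s, "s."))
  }
  insert_between <- function(k) {
    i <- which(base$gene_id == "s.q04")
    ins <- data.frame(gene_id = sprintf("s.x%02d", seq_len(k)), seqid = "qc1",
                      start = 0, end = 1, strand = "+", fpkm = 0)
    rbind(base[1:i, ], ins, base[(i + 1):nrow(base), ])
  }
  # 2 genes inserted between the pair: indel (0 vs 2)
  call <- mk_call(insert_between(2))
  expect_equal(call$klass, "indel")
  expect_equal(call$intervening_subject, 2L)
  # 6 genes inserted: beyond the <=5 ceiling, none
  expect_equal(mk_call(insert_between(6))$klass, "none")
  # right gene strand-flipped in place: inversion
  flipped <- base
  i <- flipped$gene_id == "s.q05"
  flipped$strand[i] <- "+"  # query q05 is "-"
  expect_equal(mk_call(flipped)$klass, "inversion")
  # both genes flipped, counts equal: not extended to inversion -> none
  both <- base
  both$strand[both$gene_id == "s.q04"] <- "-"
  both$strand[both$gene_id == "s.q05"] <- "+"
  expect_equal(mk_call(both)$klass, "none")
  # flanking gene absent from the hit table: none, not an error
  s <- subject_from(base, "s")
  hits <- identity_hits(fx$q, s, "s.")
  hits <- hits[hits$query_gene_id != "q04", ]
  expect_equal(scan_region(fx$cand, fx$q, s, hits)$klass, "none")
})

test_that("reversing an entire subject chromosome changes no call", {
  for (seed in 1:10) {
    set.seed(seed)
    inst <- random_synteny_instance()
    fwd <- scan_region(inst$candidate, inst$query, inst$subject, inst$hits)
    sg <- inst$subject$genes
    L <- max(sg$end) + 1000
    rev_g <- data.frame(gene_id = sg$gene_id, seqid = sg$seqid,
                        start = L - sg$end, end = L - sg$start,
                        strand = ifelse(sg$strand == "+", "-", "+"),
                        fpkm = sg$fpkm)
    rev_idx <- genome_index(rev_g, genome_id = inst$subject$genome_id)
    bwd <- scan_region(inst$candidate, inst$query, rev_idx, inst$hits)
    expect_equal(bwd$klass, fwd$klass, info = paste("seed", seed))
    expect_equal(bwd$intervening_subject, fwd$intervening_subject)
  }
})

test_that("scan_region matches the brute-force oracle on random instances", {
  for (seed in 1:40) {
    set.seed(seed)
    inst <- random_synteny_instance(n_genes = sample(6:20, 1),
                                    n_hits = sample(10:50, 1))
    got <- scan_region(inst$candidate, inst$query, inst$subject, inst$hits)
    want <- bf_scan_region(inst$candidate, inst$query, inst$subject,
                           inst$hits)
    expect_equal(got$klass, want, info = paste("seed", seed))
  }
})

test_that("raising max_between never decreases the syntenic count", {
  cfg <- generator_config(seed = 13, insertion_rate = 0.4, max_inserted = 3,
                          big_insertion_rate = 0.2)
  g <- gen_genome(cfg)
  subs <- gen_subject_genomes(g)
  cands <- call_candidates(extract_intergenic(g$index), g$index)
  p <- cands[cands$passes_core_filter, ]
  n_syn <- vapply(c(0, 2, 5, 8), function(mb) {
    syn <- build_matrix(p, g$index, subs$indexes, subs$hits,
                        max_between = mb)
    sum(syn$matrix != "none")
  }, numeric(1))
  expect_false(is.unsorted(n_syn))
})

test_that("the presence/absence matrix tallies breadth and per-genome totals", {
  g <- gen_genome(generator_config(seed = 17, n_chrom = 1,
                                   units_per_chrom = 10))
  cands <- call_candidates(extract_intergenic(g$index), g$index)
  p <- cands[cands$passes_core_filter, ]
  # no subject genomes: empty matrix, all breadths 0
  syn0 <- build_matrix(p, g$index, list(), list())
  expect_equal(ncol(syn0$matrix), 0)
  expect_true(all(syn0$breadth == 0))
  # identity subject genome: breadth 1 everywhere
  sg <- g$index$genes
  sg$gene_id <- paste0("s.", sg$gene_id)
  s <- genome_index(sg, genome_id = "s01")
  syn1 <- build_matrix(p, g$index, list(s01 = s),
                       list(s01 = identity_hits(g$index, s, "s.")))
  expect_true(all(syn1$breadth == 1))
  expect_equal(unname(syn1$per_genome_syntenic), nrow(p))
  # dropping all hits but those of 2 candidates leaves exactly 2 rows filled
  keep <- unlist(p[1:2, c("left_gene_id", "right_gene_id")])
  hits2 <- identity_hits(g$index, s, "s.")
  hits2 <- hits2[hits2$query_gene_id %in% keep, ]
  syn2 <- build_matrix(p, g$index, list(s01 = s), list(s01 = hits2))
  expect_equal(sum(syn2$breadth > 0), 2)
  expect_true(all(names(which(syn2$breadth > 0)) %in% p$region_id[1:2]))
})

test_that("high-confidence calls need length, strict >10 fold change and a high_quality cell", {
  g <- gen_genome(generator_config(seed = 19, n_chrom = 1,
                                   units_per_chrom = 12))
  cands <- call_candidates(extract_intergenic(g$index), g$index)
  p <- cands[cands$passes_core_filter, ]
  sg <- g$index$genes
  sg$gene_id <- paste0("s.", sg$gene_id)
  s <- genome_index(sg, genome_id = "s01")
  syn <- build_matrix(p, g$index, list(s01 = s),
                      list(s01 = identity_hits(g$index, s, "s.")))
  # force controlled fold changes and lengths
  p$fold_change[] <- 12; p$length[] <- 800
  p$fold_change[1] <- 10  # exactly 10: excluded (strict >)
  p$length[2] <- 1200     # too long: excluded
  hc <- high_confidence(p, syn, fc_min = 10, len_max = 1000)
  expect_false(p$region_id[1] %in% hc$region_ids)
  expect_false(p$region_id[2] %in% hc$region_ids)
  expect_equal(hc$n, nrow(p) - 2)
  expect_equal(hc$pct_of_syntenic, round(100 * hc$n / hc$n_syntenic, 1))
  # high-confidence rows are a subset of rows with a high_quality call
  hq_rows <- rownames(syn$matrix)[rowSums(syn$matrix == "high_quality") > 0]
  expect_true(all(hc$region_ids %in% hq_rows))
})

test_that("validation shortlists rank by fold change and by synteny breadth", {
  mk <- data.frame(
    region_id = c("rA", "rB", "rC", "rD"),
    length = c(500, 300, 300, 900),
    fpkm_left = c(2, 30, 5, 8), fpkm_right = c(1, 1, 1, 1),
    fold_change = c(2, 30, 5, 8),
    stringsAsFactors = FALSE
  )
  syn <- list(matrix = matrix("none", 4, 3,
                              dimnames = list(mk$region_id, c("a", "b", "c"))),
              breadth = setNames(c(0, 3, 3, 1), mk$region_id))
  class(syn) <- "synteny_matrix"
  syn$matrix["rB", ] <- "high_quality"
  syn$matrix["rC", ] <- "indel"
  syn$matrix["rD", "a"] <- "inversion"
  sel1 <- select_for_validation(mk, syn, k = 1)
  expect_equal(sel1$by_fold_change$region_id, "rB")  # highest fc
  sel2 <- select_for_validation(mk, syn, k = 2)
  # breadth ties (rB, rC at 3) broken by length ascending then id
  expect_equal(sel2$by_breadth$region_id, c("rB", "rC"))
  # infinite fold changes rank first, ordered by the high gene's FPKM
  mk2 <- mk
  mk2$fold_change[c(1, 4)] <- Inf
  sel3 <- select_for_validation(mk2, syn, k = 2)
  expect_equal(sel3$by_fold_change$region_id, c("rD", "rA"))  # fpkm 8 > 2
  # k beyond the candidate count returns all with a warning
  expect_warning(sel_all <- select_for_validation(mk, syn, k = 9),
                 "exceeds")
  expect_equal(nrow(sel_all$by_fold_change), 4)
})
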