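# Independent brute-force re-implementations used as oracles. These work
# directly from the rule definitions, per pair, with no code shared with
# the package internals.

# Candidate caller oracle: loops over gene pairs on each sequence sorted by
# (start, end, gene_id); consecutive pairs with a non-negative gap form a
# region; the classification predicate is evaluated literally per pair.
bf_call_candidates <- function(genes, min_len = 50, max_len = 20000,
                               min_fc = 1.5, top_fraction = 0.5) {
  n <- nrow(genes)
  cutoff <- sort(genes$fpkm, decreasing = TRUE)[ceiling(top_fraction * n)]
  out <- list()
  for (sq in sort(unique(genes$seqid))) {
    gg <- genes[genes$seqid == sq, , drop = FALSE]
    gg <- gg[order(gg$start, gg$end, gg$gene_id), , drop = FALSE]
    if (nrow(gg) < 2) next
    for (i in seq_len(nrow(gg) - 1)) {
      a <- gg[i, ]; b <- gg[i + 1, ]
      if (b$start < a$end) next  # overlapping or nested: no region
      len <- b$start - a$end
      orient <- if (a$strand == "-" && b$strand == "+") "divergent"
                else if (a$strand == "+" && b$strand == "-") "convergent"
                else "tandem"
      hi <- max(a$fpkm, b$fpkm); lo <- min(a$fpkm, b$fpkm)
      fc <- if (hi == 0) NA_real_ else if (lo == 0) Inf else hi / lo
      a_top <- a$fpkm >= cutoff; b_top <- b$fpkm >= cutoff
      pass <- len >= min_len && len <= max_len &&
        orient %in% c("divergent", "convergent") &&
        !is.na(fc) && fc >= min_fc &&
        max(a$fpkm, b$fpkm) >= cutoff &&
        (orient != "convergent" || sum(c(a_top, b_top)) == 1)
      out[[length(out) + 1L]] <- data.frame(
        region_id = sprintf("%s:%d-%d", sq, a$end, b$start),
        orientation = orient, fold_change = fc, passes = pass,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Microsynteny oracle: enumerates every hit pair with explicit loops and
# classifies by comparing the subject pair pattern, read either forward or
# reverse-complemented, against the query pattern.
bf_scan_region <- function(candidate, query_index, subject_index, hits,
                           max_between = 5) {
  qg <- query_index$genes
  sg <- subject_index$genes
  ql <- qg[qg$gene_id == candidate$left_gene_id, ]
  qr <- qg[qg$gene_id == candidate$right_gene_id, ]
  iq <- abs(qr$rank - ql$rank) - 1L
  flip <- function(s) ifelse(s == "+", "-", "+")
  best <- NULL
  if (ql$seqid == qr$seqid && iq <= max_between) {
    for (i in which(hits$query_gene_id == candidate$left_gene_id)) {
      for (j in which(hits$query_gene_id == candidate$right_gene_id)) {
        sa <- sg[sg$gene_id == hits$subject_gene_id[i], ]
        sb <- sg[sg$gene_id == hits$subject_gene_id[j], ]
        if (nrow(sa) == 0 || nrow(sb) == 0) next
        if (sa$seqid != sb$seqid || sa$gene_id == sb$gene_id) next
        between <- abs(sb$rank - sa$rank) - 1L
        if (between > max_between) next
        key <- list(between = between,
                    esum = hits$evalue[i] + hits$evalue[j],
                    ids = c(sa$gene_id, sb$gene_id),
                    sa = sa, sb = sb)
        if (is.null(best) ||
            key$between < best$between ||
            (key$between == best$between && key$esum < best$esum) ||
            (key$between == best$between && key$esum == best$esum &&
             (key$ids[1] < best$ids[1] ||
              (key$ids[1] == best$ids[1] && key$ids[2] < best$ids[2])))) {
          best <- key
        }
      }
    }
  }
  if (is.null(best)) return("none")
  # subject pattern with the left-flank ortholog first
  if (best$sb$rank > best$sa$rank) {
    pattern <- c(best$sa$strand, best$sb$strand)
  } else {
    pattern <- flip(c(best$sa$strand, best$sb$strand))
  }
  mismatches <- sum(pattern != c(ql$strand, qr$strand))
  counts_equal <- best$between == iq
  if (mismatches == 0 && counts_equal) "high_quality"
  else if (mismatches == 0) "indel"
  else if (mismatches == 1 && counts_equal) "inversion"
  else "none"
}

# Random miner instance: genes may overlap, tie and carry zero FPKM.
random_gene_table <- function(n, n_seq = 2) {
  seqid <- sort(sample(sprintf("c%d", seq_len(n_seq)), n, replace = TRUE))
  start <- unlist(lapply(split(seq_len(n), seqid), function(i) {
    cumsum(sample(0:4000, length(i), replace = TRUE))
  }), use.names = FALSE)
  len <- sample(100:3000, n, replace = TRUE)
  fpkm <- round(stats::rlnorm(n, 1, 2), 2)
  fpkm[sample(n, size = max(1, n %/% 10))] <- 0
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), seqid = seqid,
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             fpkm = fpkm, stringsAsFactors = FALSE)
}

# Random synteny instance: a small query genome, a shuffled/mutated subject
# genome and a many-to-many hit table.
random_synteny_instance <- function(n_genes = 12, n_hits = 30) {
  q <- genome_index(data.frame(
    gene_id = sprintf("q%02d", seq_len(n_genes)),
    seqid = "qc1",
    start = seq_len(n_genes) * 2000,
    end = seq_len(n_genes) * 2000 + 1000,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  ), genome_id = "q")
  m <- sample(5:25, 1)
  s <- genome_index(data.frame(
    gene_id = sprintf("s%02d", seq_len(m)),
    seqid = sample(c("sc1", "sc2"), m, replace = TRUE),
    start = seq_len(m) * 2000,
    end = seq_len(m) * 2000 + 1000,
    strand = sample(c("+", "-"), m, replace = TRUE)
  ), genome_id = "s")
  hits <- data.frame(
    query_gene_id = sample(q$genes$gene_id, n_hits, replace = TRUE),
    subject_gene_id = sample(s$genes$gene_id, n_hits, replace = TRUE),
    evalue = signif(10^stats::runif(n_hits, -50, -6), 3),
    bitscore = round(stats::runif(n_hits, 50, 500)),
    stringsAsFactors = FALSE
  )
  i <- sample(n_genes - 1, 1)
  candidate <- data.frame(
    region_id = "r1",
    left_gene_id = sprintf("q%02d", i),
    right_gene_id = sprintf("q%02d", i + 1),
    stringsAsFactors = FALSE
  )
  list(query = q, subject = s, hits = hits, candidate = candidate)
}

# Per-bp Jaccard between two interval sets over the given extents.
interval_jaccard <- function(a, b, seqlens) {
  paint <- function(iv, L, sq) {
    v <- logical(L)
    x <- iv[iv$seqid == sq, , drop = FALSE]
    for (i in seq_len(nrow(x))) {
      if (x$end[i] > x$start[i]) v[(x$start[i] + 1):x$end[i]] <- TRUE
    }
    v
  }
  num <- 0; den <- 0
  for (sq in names(seqlens)) {
    va <- paint(a, seqlens[[sq]], sq)
    vb <- paint(b, seqlens[[sq]], sq)
    num <- num + sum(va & vb)
    den <- den + sum(va | vb)
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Minimal genome-index builder for hand-written cases.
toy_index <- function(..., genome_id = "toy") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], seqid = r[[2]],
               start = as.numeric(r[[3]]), end = as.numeric(r[[4]]),
               strand = r[[5]],
               fpkm = if (length(r) > 5) as.numeric(r[[6]]) else 0,
               stringsAsFactors = FALSE)
  }))
  genome_index(df, genome_id = genome_id)
}

# Hit table connecting query genes to same-named subject genes 1:1.
identity_hits <- function(query_index, subject_index, prefix) {
  q <- query_index$genes$gene_id
  data.frame(query_gene_id = q,
             subject_gene_id = paste0(prefix, q),
             evalue = 1e-30, bitscore = 400, stringsAsFactors = FALSE)
}
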