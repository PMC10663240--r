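#!/usr/bin/env Rscript
# Stage 4: tile the simulated methylome in 100-bp windows, call
# unmethylated regions, compare them per-bp with the planted UMRs, and
# intersect them with the mined candidates.

library(insulatr)

fixture <- file.path("results", "fixture")
sites <- read_allc(file.path(fixture, "allc.tsv"))
sl_tab <- read.delim(file.path(fixture, "seqlens.tsv"))
seqlens <- setNames(sl_tab$length, sl_tab$seqid)
planted <- read.delim(file.path(fixture, "truth_umrs.tsv"))
cands <- read.delim(file.path("results", "candidates.tsv"))
passing <- cands[cands$passes_core_filter, ]

tiles <- tile_methylome(sites, seqlens = seqlens)
umrs <- merge_umrs(tiles)
write.table(umrs, file.path("results", "umrs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
bed <- umrs
bed$name <- sprintf("UMR%04d", seq_len(nrow(umrs)))
write_bed(bed, file.path("results", "umrs.bed"))

lev <- global_levels(sites)
cat(sprintf("global weighted levels: mCG %.3f, mCHG %.3f, mCHH %.3f (all %.3f)\n",
            lev$CG, lev$CHG, lev$CHH, lev$all))
cat(sprintf("tiles: %d (%s)\n", nrow(tiles),
            paste(names(table(tiles$status)), table(tiles$status),
                  sep = "=", collapse = ", ")))

paint <- function(iv, sq, L) {
  v <- logical(L)
  x <- iv[iv$seqid == sq, , drop = FALSE]
  for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
  v
}
num <- 0; den <- 0
for (sq in names(seqlens)) {
  a <- paint(planted, sq, seqlens[[sq]])
  b <- paint(umrs, sq, seqlens[[sq]])
  num <- num + sum(a & b); den <- den + sum(a | b)
}
cat(sprintf("%d UMRs called vs %d planted; per-bp Jaccard %.3f\n",
            nrow(umrs), nrow(planted), num / den))

ov <- overlap_candidates(passing, umrs)
cat(sprintf("candidate/UMR overlap: %d of %d (%.1f%%); mean lengths %.0f bp (candidates) vs %.0f bp (UMRs)\n",
            ov$n_overlapping, ov$n_candidates, ov$pct,
            ov$mean_candidate_length, ov$mean_umr_length))
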