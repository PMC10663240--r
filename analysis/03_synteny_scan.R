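#!/usr/bin/env Rscript
# Stage 3: microsynteny of the candidate flanking pairs across the subject
# genomes: presence/absence matrix, rearrangement classes versus planted
# truth, the high-confidence subset, and the two validation shortlists.

library(insulatr)

fixture <- file.path("results", "fixture")
idx <- read_gene_models(file.path(fixture, "genes.gff3"),
                        file.path(fixture, "expression.tsv"))
cands <- read.delim(file.path("results", "candidates.tsv"))
passing <- cands[cands$passes_core_filter, ]
truth <- read.delim(file.path(fixture, "truth_synteny.tsv"))

genomes <- sub("\\.blast\\.tsv$", "",
               list.files(fixture, pattern = "\\.blast\\.tsv$"))
subs <- lapply(genomes, function(g) {
  read_gene_models(file.path(fixture, paste0(g, ".gff3")), genome_id = g)
})
names(subs) <- genomes
hits <- lapply(genomes, function(g) {
  read_ortholog_hits(file.path(fixture, paste0(g, ".blast.tsv")),
                     subject_index = subs[[g]])
})
names(hits) <- genomes

syn <- build_matrix(passing, idx, subs, hits)
write.table(data.frame(region_id = rownames(syn$matrix), syn$matrix,
                       check.names = FALSE),
            file.path("results", "synteny_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(syn$calls, file.path("results", "synteny_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pred <- setNames(syn$calls$klass,
                 paste(syn$calls$region_id, syn$calls$subject_genome_id))
key <- paste(truth$region_id, truth$genome_id)
confusion <- table(planted = truth$klass, called = pred[key])
cat("confusion matrix (planted vs called):\n")
print(confusion)

hc <- high_confidence(passing, syn)
sel <- select_for_validation(passing, syn)
write.table(sel$by_fold_change,
            file.path("results", "shortlist_fold_change.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sel$by_breadth, file.path("results", "shortlist_breadth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("syntenic in >= 1 genome: %d of %d candidates\n",
            hc$n_syntenic, nrow(passing)))
cat(sprintf("high confidence (<= 1 kb, fc > 10, high-quality call): %d (%.1f%% of syntenic)\n",
            hc$n, hc$pct_of_syntenic))
cat(sprintf("shortlists written: %d by fold change, %d by synteny breadth\n",
            nrow(sel$by_fold_change), nrow(sel$by_breadth)))
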