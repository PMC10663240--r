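#!/usr/bin/env Rscript
# Stage 2: mine insulator-like candidates from the simulated annotation.
# Extracts intergenic regions between adjacent gene pairs, classifies them
# by orientation and expression fold change, and checks recovery against
# the planted truth from stage 1.

library(insulatr)

fixture <- file.path("results", "fixture")
idx <- read_gene_models(file.path(fixture, "genes.gff3"),
                        file.path(fixture, "expression.tsv"))
truth <- read.delim(file.path(fixture, "truth_candidates.tsv"))

regions <- extract_intergenic(idx)
cands <- call_candidates(regions, idx, miner_params())
passing <- cands[cands$passes_core_filter, ]
short <- filter_short(cands)

write.table(cands, file.path("results", "candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
bed <- passing
bed$name <- bed$region_id
bed$score <- bed$fold_change
write_bed(bed, file.path("results", "candidates.bed"))

planted <- truth$region_id[truth$planted]
cat(sprintf("%d intergenic regions; %d pass the core filter (%d divergent, %d convergent)\n",
            nrow(regions), nrow(passing),
            sum(passing$orientation == "divergent"),
            sum(passing$orientation == "convergent")))
cat(sprintf("planted recovery: %d/%d, false positives: %d\n",
            sum(passing$region_id %in% planted), length(planted),
            sum(!passing$region_id %in% planted)))
cat(sprintf("short (<= 1 kb) subset: %d candidates, %.1f%% of passing\n",
            nrow(short), 100 * attr(short, "retained_fraction")))
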