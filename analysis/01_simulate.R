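#!/usr/bin/env Rscript
# Stage 1: materialise the synthetic study. One seeded configuration
# generates every input the downstream stages consume — an annotated
# 4-chromosome genome (200 genes, 40 planted insulator-like candidates
# among single-rule negatives), three subject genomes with planted
# rearrangements, a methylome with planted UMRs, and a dual-reporter assay
# whose construct strengths include the two validated insulators.

library(insulatr)

seed <- 20260922L
fixture <- file.path("results", "fixture")
dir.create(fixture, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed,
                        inversion_rate = 0.25, insertion_rate = 0.25,
                        deletion_rate = 0.15, big_insertion_rate = 0.10)

g <- gen_genome(cfg)
write_gene_models(g$index, file.path(fixture, "genes.gff3"),
                  file.path(fixture, "expression.tsv"))
write.table(g$truth, file.path(fixture, "truth_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

subs <- gen_subject_genomes(g)
for (n in names(subs$indexes)) {
  write_gene_models(subs$indexes[[n]], file.path(fixture, paste0(n, ".gff3")))
  write_hit_table(subs$hits[[n]], file.path(fixture, paste0(n, ".blast.tsv")))
}
write.table(subs$truth, file.path(fixture, "truth_synteny.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

seqlens <- tapply(g$index$genes$end, g$index$genes$seqid, max) + 1000
write.table(data.frame(seqid = names(seqlens), length = as.integer(seqlens)),
            file.path(fixture, "seqlens.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
m <- gen_methylome(seqlens, cfg)
write_allc(m$sites, file.path(fixture, "allc.tsv"))
write.table(m$planted, file.path(fixture, "truth_umrs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_assay(gen_assay(cfg), file.path(fixture, "assay.tsv"))

cat(sprintf("genome: %d genes on %d chromosomes; %d planted candidates\n",
            nrow(g$index$genes), length(seqlens), sum(g$truth$planted)))
cat(sprintf("subjects: %d genomes, %d planted synteny calls (%s)\n",
            length(subs$indexes), nrow(subs$truth),
            paste(names(table(subs$truth$klass)),
                  table(subs$truth$klass), sep = "=", collapse = ", ")))
cat(sprintf("methylome: %d sites, %d planted UMRs; assay: %d constructs\n",
            nrow(m$sites), nrow(m$planted), length(cfg$strengths)))
cat("fixture written to", fixture, "\n")
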