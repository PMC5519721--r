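#!/usr/bin/env Rscript
# Stage 3 — selection scan.
#
# Computes per-SNP Weir-Cockerham F_ST, derived allele frequencies, raw and
# standardized iHS (DAF bins of width 0.05) and XP-EHH, windowed XP-CLR with a
# method-of-moments drift scale, and the log composite likelihood over the
# three cross-population metrics. Writes results/scores.tsv.

suppressMessages({ library(sreselscan); library(data.table) })

d <- "results/fixture"
gmap <- read_genetic_map(file.path(d, "genetic_map.tsv"))
truth <- fread(file.path(d, "truth.tsv"))
n_dip <- NULL  # derived from the VCF sample columns
hdr <- grep("^#CHROM", readLines(file.path(d, "panel.vcf"), n = 50), value = TRUE)
samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
pop_map <- stats::setNames(sub("_.*$", "", samples), samples)

pv <- read_vcf_panel(file.path(d, "panel.vcf"), pop_map, genetic_map = gmap)
anc <- read_ancestral(file.path(d, "ancestral.tsv"))
variants <- merge(pv$variants, anc, by = "variant_id", sort = FALSE)

scores <- selection_scan(pv$panels, variants)
fwrite(scores, "results/scores.tsv", sep = "\t")

fst_ml <- wc_fst_multilocus(wc_fst(nrow(pv$panels[[1]]$H), colSums(pv$panels[[1]]$H),
                                   nrow(pv$panels[[2]]$H), colSums(pv$panels[[2]]$H)))
message(sprintf("multi-locus F_ST = %.3f (generating c = 0.15)", fst_ml))
message(sprintf("outliers: %d SNPs with |standardized XP-EHH| > 2, %d with |iHS| > 2",
                sum(abs(scores$xpehh_std) > 2, na.rm = TRUE),
                sum(abs(scores$ihs_std) > 2, na.rm = TRUE)))
message("scores written to results/scores.tsv")
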