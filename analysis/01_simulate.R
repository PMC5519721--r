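#!/usr/bin/env Rscript
# Stage 1 — simulate the study world.
#
# Generates a two-population cohort with Balding-Nichols divergence
# (expected F_ST 0.15), 20 genes of which about half carry a skipped exon,
# and 300 SNPs of which 20% are planted inside ESE/ESS/ISE hexamers with
# known inducing/disrupting alleles. Emits the plain-text fixture (VCF, GFF3,
# FASTA, motif/ancestral/map TSVs, B-value bedGraph, truth table) that every
# later stage consumes.

suppressMessages(library(sreselscan))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

fx <- simulate_fixture(sim_config(n_snps = 300L, seed = seed))
dir.create("results", showWarnings = FALSE)
paths <- write_fixture(fx, "results/fixture")

message(sprintf("seed %d: %d SNPs (%d SRE), %d genes, %d skipped exons",
                seed, nrow(fx$variants), sum(fx$truth$is_sre),
                nrow(fx$models$genes), nrow(fx$models$skipped_exons)))
message("fixture written to results/fixture/")
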