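# Shared fixture builders. Everything is generated in code at test time; the
# default fixture is small enough to regenerate per file.

# Cache one default fixture per session (generation is a few seconds).
.fx_cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 3L, n_snps = 200L) {
  key <- paste0("fx_", seed, "_", n_snps)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- simulate_fixture(sim_config(n_snps = n_snps, seed = seed))
  }
  .fx_cache[[key]]
}

written_fixture <- function(seed = 3L, n_snps = 200L) {
  key <- paste0("dir_", seed, "_", n_snps)
  if (is.null(.fx_cache[[key]])) {
    d <- file.path(tempdir(), paste0("sre_fx_", seed, "_", n_snps))
    write_fixture(default_fixture(seed, n_snps), d)
    .fx_cache[[key]] <- d
  }
  .fx_cache[[key]]
}

fixture_pop_map <- function(fx) {
  pops <- names(fx$panels)
  stats::setNames(
    rep(pops, times = vapply(fx$panels, function(p) nrow(p$H) / 2L, numeric(1))),
    unlist(lapply(pops, function(p)
      sprintf("%s_%03d", p, seq_len(nrow(fx$panels[[p]]$H) / 2L))))
  )
}

# A minimal single-gene fixture for geometry/class unit tests:
# gene G1 on + strand, exons (0-based half-open) E1 [10,19), E2 [30,39),
# E3 [50,59); isoform t1 = E1+E2+E3, t2 = E1+E3 (E2 skipped); CDS = exons.
tiny_gene_models <- function(strand = "+") {
  exons <- data.table::data.table(
    gene_id = "G1",
    tx_id = rep(c("G1.t1", "G1.t2"), c(3L, 2L)),
    chrom = "chr1",
    start = c(10L, 30L, 50L, 10L, 50L),
    end = c(19L, 39L, 59L, 19L, 59L),
    strand = strand
  )
  exons[, exon_id := paste0(chrom, ":", start, "-", end)]
  genes <- exons[, .(chrom = chrom[1L], start = min(start), end = max(end),
                     strand = strand[1L]), by = gene_id]
  cds <- exons[tx_id == "G1.t1"][, .(gene_id, tx_id, chrom, start, end, strand,
                                     phase = 0L)]
  structure(list(genes = genes, exons = exons, cds = cds,
                 skipped_exons = sreselscan:::flag_skipped_exons(exons)),
            class = "gene_models")
}

# Reference built around tiny_gene_models: deterministic sequence with known
# codons in each exon (exon length 9 = 3 codons).
tiny_reference <- function(exon1 = "ATGGAACCT", exon2 = "GAATGGCCT",
                           exon3 = "AAACCCTAA") {
  s <- strrep("T", 70)
  substr(s, 11, 19) <- exon1
  substr(s, 31, 39) <- exon2
  substr(s, 51, 59) <- exon3
  x <- Biostrings::DNAStringSet(s)
  names(x) <- "chr1"
  x
}

# Small random panel for estimator oracles.
random_panel <- function(n_hap, m, seed, pop = "P1") {
  set.seed(seed)
  H <- matrix(rbinom(n_hap * m, 1L, runif(m, 0.1, 0.9)[rep(seq_len(m), each = n_hap)]),
              n_hap, m)
  haplotype_panel(pop, H, "chr1", seq_len(m) * 1000L)
}
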