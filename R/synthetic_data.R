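# synthetic_data: fixture generator with known truth.
#
# The generator emits the statistical structure the analysis assumes:
# two-or-more populations diverged under the Balding-Nichols model (parameter
# c = expected F_ST), haplotype panels with copy-induced local LD and optional
# planted sweeps, gene models containing skipped exons, and SNPs planted
# inside/outside SRE hexamers with known disrupting/inducing alleles.

#' Simulation configuration
#'
#' Defaults describe the stated world the test-suite exercises: two
#' populations at Balding-Nichols c = 0.15 (a typical continental-scale
#' F_ST), 50 diploids (100 haplotypes) per population, 20 multi-exon genes of
#' which half carry a skipped middle exon, and 20% of SNPs planted inside SRE
#' hexamers with a 1:1 disrupt:induce ratio.
#'
#' @param n_populations number of populations (>= 2).
#' @param n_hap haplotypes per population.
#' @param n_snps total SNPs to plant.
#' @param divergence Balding-Nichols c in (0,1); equals the expected F_ST.
#' @param n_genes,exons_per_gene,skip_prob gene-model parameters.
#' @param sre_fraction fraction of SNPs planted inside SRE motifs.
#' @param disrupt_induce_ratio ratio of plants whose reference allele carries
#'   the motif (derived allele disrupts) to plants whose alternate allele
#'   creates it.
#' @param sweep optional list(core_index, favored_allele, carrier_fraction,
#'   window, pop) describing a planted sweep.
#' @param switch_prob per-site template-switch probability of the haplotype
#'   copying process (controls background LD).
#' @param seed master seed; fixes every downstream draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2L, n_hap = 100L, n_snps = 300L,
                       divergence = 0.15, n_genes = 20L, exons_per_gene = 5L,
                       skip_prob = 0.5, sre_fraction = 0.2,
                       disrupt_induce_ratio = 1, sweep = NULL,
                       switch_prob = 0.05, seed = 1L) {
  stopifnot(n_populations >= 2L, n_hap >= 4L, n_snps >= 1L,
            divergence > 0, divergence < 1,
            sre_fraction > 0, sre_fraction <= 1,
            skip_prob > 0, skip_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate ancestral and per-population allele frequencies (Balding-Nichols)
#'
#' The ancestral frequency p0 is Uniform(0.05, 0.95); each population's
#' frequency is Beta(p0(1-c)/c, (1-p0)(1-c)/c), so that the expected
#' Weir-Cockerham F_ST between any two populations equals c.
#'
#' @param n_snps number of SNPs.
#' @param c divergence parameter in (0,1).
#' @param seed RNG seed.
#' @param n_populations number of populations.
#' @return list with `p0` (length n_snps) and `freqs`
#'   (n_snps x n_populations matrix).
#' @export
simulate_frequencies <- function(n_snps, c, seed, n_populations = 2L) {
  if (!(c > 0 && c < 1)) {
    stop_sre("divergence parameter c must lie in (0,1)", "sre_config_error")
  }
  set.seed(seed)
  p0 <- runif(n_snps, 0.05, 0.95)
  shape1 <- p0 * (1 - c) / c
  shape2 <- (1 - p0) * (1 - c) / c
  freqs <- vapply(seq_len(n_populations),
                  function(i) rbeta(n_snps, shape1, shape2),
                  numeric(n_snps))
  list(p0 = p0, freqs = matrix(freqs, nrow = n_snps))
}

#' Simulate a haplotype panel at given allele frequencies
#'
#' Per-site allele counts are exact Binomial(n_hap, freq) draws; background
#' local LD is induced by drawing a pool of founder haplotypes (iid
#' Bernoulli(freq) per site) and building every further haplotype as a mosaic
#' copy of previously built founders with per-site template-switch probability
#' `switch_prob`, then applying frequency-correcting mutations (random flips)
#' until each site's allele count matches its Binomial draw. Realized
#' frequencies are therefore exactly Binomial-distributed around the target
#' while nearby sites share haplotype stretches.
#'
#' @param freqs per-site ALT allele frequencies in \[0,1\].
#' @param n_hap number of haplotypes (>= 4).
#' @param seed RNG seed.
#' @param pos_bp physical positions (default 1 kb spacing).
#' @param chrom contig name.
#' @param pop population label.
#' @param pos_cM genetic positions (default uniform 1 cM/Mb).
#' @param switch_prob per-site template switch probability.
#' @param n_founders size of the founder haplotype pool (default 25).
#' @return a [haplotype_panel()].
#' @export
simulate_panel <- function(freqs, n_hap, seed,
                           pos_bp = seq_along(freqs) * 1000L, chrom = "chr1",
                           pop = "P1", pos_cM = pos_bp * 1e-6,
                           switch_prob = 0.05, n_founders = 25L) {
  if (n_hap < 4L) stop_sre("n_hap must be >= 4", "sre_config_error")
  stopifnot(all(freqs >= 0 & freqs <= 1))
  set.seed(seed)
  m <- length(freqs)
  target <- rbinom(m, n_hap, freqs)

  K <- min(n_founders, n_hap)
  H <- matrix(0L, n_hap, m)
  for (i in seq_len(K)) H[i, ] <- rbinom(m, 1L, freqs)
  for (i in seq_len(n_hap)[-seq_len(K)]) {
    # mosaic copy of the founder haplotypes
    switches <- c(TRUE, runif(m - 1L) < switch_prob)
    templ <- sample.int(K, sum(switches), replace = TRUE)
    seg <- cumsum(switches)
    H[i, ] <- H[cbind(templ[seg], seq_len(m))]
  }
  # frequency-correcting mutations: flip random entries until counts match
  pick <- function(x, k) x[sample.int(length(x), k)]
  for (j in seq_len(m)) {
    d <- sum(H[, j]) - target[j]
    if (d > 0L) {
      H[pick(which(H[, j] == 1L), d), j] <- 0L
    } else if (d < 0L) {
      H[pick(which(H[, j] == 0L), -d), j] <- 1L
    }
  }
  haplotype_panel(pop, H, chrom, pos_bp, pos_cM)
}

#' Plant a selective sweep into a haplotype panel
#'
#' A fraction `f` of the haplotypes carrying `favored_allele` at the core site
#' are replaced by copies of one randomly chosen carrier haplotype over a
#' window of `L` sites either side of the core, producing extended haplotype
#' homozygosity on the favored background.
#'
#' @param panel a [haplotype_panel()].
#' @param core_index column index of the core site.
#' @param favored_allele 0 or 1.
#' @param f carrier fraction replaced, in \[0,1\].
#' @param L half-window in sites (default 100).
#' @param seed RNG seed.
#' @return modified [haplotype_panel()].
#' @export
plant_sweep <- function(panel, core_index, favored_allele, f, L = 100L, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), f >= 0, f <= 1)
  carriers <- which(panel$H[, core_index] == favored_allele)
  if (!length(carriers)) {
    stop_sre("favored allele absent at core site", "sre_config_error")
  }
  if (f == 0) return(panel)
  set.seed(seed)
  template <- carriers[sample.int(length(carriers), 1L)]
  n_rep <- round(f * length(carriers))
  if (n_rep == 0L) return(panel)
  repl <- carriers[sample.int(length(carriers), n_rep)]
  win <- max(1L, core_index - L):min(ncol(panel$H), core_index + L)
  panel$H[repl, win] <- matrix(panel$H[template, win], n_rep, length(win),
                               byrow = TRUE)
  panel
}

# ---------------------------------------------------------------------------
# Gene models + motif planting

# Brute-force motif check used at construction time: does any 6-base window of
# the 11-base transcribed-strand context (allele substituted at center) match
# any motif of any element type?
.matches_any_motif <- function(ctx11, allele, motif_sets) {
  s <- ctx11
  substr(s, 6L, 6L) <- allele
  wins <- vapply(1:6, function(i) substr(s, i, i + 5L), character(1L))
  any(wins %in% unlist(motif_sets))
}

.matched_motifs <- function(ctx11, allele, motifs) {
  s <- ctx11
  substr(s, 6L, 6L) <- allele
  wins <- vapply(1:6, function(i) substr(s, i, i + 5L), character(1L))
  intersect(wins, motifs)
}

# random DNA string
.rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic genome: gene models, motif-planted SNPs, truth table
#'
#' Lays out `n_genes` genes (random strand) on one contig, each with
#' `exons_per_gene` exons of 90 bp separated by 300 bp introns. A fraction
#' `skip_prob` of genes get a second isoform lacking one internal exon (the
#' skipped exon). SRE SNPs are planted so that exactly one allele's 11-base
#' transcribed-strand context contains a motif hexamer: ISE plants fall in the
#' introns flanking skipped exons, ESE/ESS plants inside skipped exons (with
#' functional class following from the codon change); non-SRE SNPs are planted
#' so that neither allele matches any motif.
#'
#' @param config a [sim_config()].
#' @param motif_sets named list of hexamer vectors (ESE/ESS/ISE), e.g. from
#'   [read_motifs()] or [default_motif_sets()].
#' @return list with `fasta` (DNAStringSet), `models` (gene_models),
#'   `variants` (data.table: variant_id, chrom, pos, ref, alt), `truth`
#'   (data.table: one row per planted SNP with is_sre, element_type,
#'   inducing/disrupting allele, func_class, skipped_exon_id), and `gff`
#'   (data.table of GFF3 rows, written by [write_fixture()]).
#' @export
generate_genes_and_motifs <- function(config, motif_sets) {
  set.seed(child_seed(config$seed, 11L))
  exon_len <- 90L; intron_len <- 300L; gap <- 500L
  n_ex <- config$exons_per_gene
  stopifnot(n_ex >= 3L)
  gene_len <- n_ex * exon_len + (n_ex - 1L) * intron_len

  genes <- data.table(
    gene_id = sprintf("G%03d", seq_len(config$n_genes)),
    start = gap + (seq_len(config$n_genes) - 1L) * (gene_len + gap),  # 0-based
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    has_skip = runif(config$n_genes) < config$skip_prob
  )
  if (!any(genes$has_skip)) genes$has_skip[1L] <- TRUE
  genes[, end := start + gene_len]
  contig_len <- max(genes$end) + gap
  seq_chr <- .rand_dna(contig_len)

  # exon coordinates (0-based half-open), genomic order
  exon_tab <- genes[, {
    es <- start + (seq_len(n_ex) - 1L) * (exon_len + intron_len)
    .(exon_idx = seq_len(n_ex), start = es, end = es + exon_len)
  }, by = .(gene_id, strand, has_skip)]
  # skipped exon: a random internal exon of genes with two isoforms
  skip_pick <- exon_tab[has_skip == TRUE & exon_idx > 1L & exon_idx < n_ex,
                        .SD[sample(.N, 1L)], by = gene_id][, .(gene_id, exon_idx)]
  exon_tab[, skipped := FALSE]
  exon_tab[skip_pick, skipped := TRUE, on = c("gene_id", "exon_idx")]

  # --- plant SNPs ------------------------------------------------------
  n_sre <- round(config$sre_fraction * config$n_snps)
  n_non <- config$n_snps - n_sre
  # element-type allocation: half ISE, rest split ESE/ESS
  n_ise <- ceiling(n_sre / 2L)
  n_ese <- ceiling((n_sre - n_ise) / 2L)
  n_ess <- n_sre - n_ise - n_ese
  types <- c(rep("ISE", n_ise), rep("ESE", n_ese), rep("ESS", n_ess))
  # disrupt:induce — TRUE means reference allele carries the motif (the
  # alternate allele disrupts it); FALSE means the alternate allele creates it
  r <- config$disrupt_induce_ratio
  ref_carries <- runif(n_sre) < r / (1 + r)

  skip_genes <- unique(exon_tab[skipped == TRUE, gene_id])
  used <- integer(0)  # genomic positions (1-based) already claimed +/- 11bp

  claim <- function(pos1) {
    if (any(abs(used - pos1) < 12L)) return(FALSE)
    used <<- c(used, pos1); TRUE
  }

  plants <- vector("list", config$n_snps)
  seq_env <- new.env(); assign("s", seq_chr, envir = seq_env)

  get_ctx <- function(pos1, strand) {
    s <- get("s", envir = seq_env)
    ctx <- substr(s, pos1 - 5L, pos1 + 5L)
    if (strand == "-") revcomp(ctx) else ctx
  }
  put_ctx <- function(pos1, strand, ctx11) {
    s <- get("s", envir = seq_env)
    if (strand == "-") ctx11 <- revcomp(ctx11)
    substr(s, pos1 - 5L, pos1 + 5L) <- ctx11
    assign("s", s, envir = seq_env)
  }

  plant_sre <- function(etype, ref_has_motif) {
    motifs <- motif_sets[[etype]]
    for (attempt in seq_len(1000L)) {
      g <- sample(skip_genes, 1L)
      ge <- exon_tab[gene_id == g]
      sk <- ge[skipped == TRUE]
      strand <- ge$strand[1L]
      if (etype == "ISE") {
        # a position in one of the two introns flanking the skipped exon,
        # >= 8 bp from intron boundaries
        side <- sample(c("up", "dn"), 1L)
        intr <- if (side == "up") c(ge[exon_idx == sk$exon_idx - 1L, end], sk$start)
                else c(sk$end, ge[exon_idx == sk$exon_idx + 1L, start])
        pos1 <- sample((intr[1L] + 9L):(intr[2L] - 8L), 1L)  # 1-based
      } else {
        pos1 <- sample((sk$start + 7L):(sk$end - 6L), 1L)    # interior of exon
      }
      if (!any(abs(used - pos1) < 12L)) {
        motif <- sample(motifs, 1L)
        off <- sample(0:5, 1L)           # SNP at motif position off (0-based)
        motif_base <- substr(motif, off + 1L, off + 1L)
        other <- sample(setdiff(DNA_BASES, motif_base), 3L)
        # transcribed-strand context with the motif written in, SNP at center
        ctx <- get_ctx(pos1, strand)
        substr(ctx, 6L - off, 11L - off) <- motif
        ok <- FALSE
        for (alt_t in other) {  # transcribed-strand non-motif allele
          if (.matches_any_motif(ctx, alt_t, motif_sets)) next
          ctx_m <- ctx; substr(ctx_m, 6L, 6L) <- motif_base
          # the motif allele must match only its own element type
          hits <- vapply(names(motif_sets), function(tt)
            length(.matched_motifs(ctx_m, motif_base, motif_sets[[tt]])) > 0L,
            logical(1L))
          if (!identical(names(which(hits)), etype)) next
          ok <- TRUE; break
        }
        if (!ok) next
        ref_t <- if (ref_has_motif) motif_base else alt_t
        alt_t_allele <- if (ref_has_motif) alt_t else motif_base
        ctx_ref <- ctx; substr(ctx_ref, 6L, 6L) <- ref_t
        put_ctx(pos1, strand, ctx_ref)
        claim(pos1)
        # report alleles in reference-strand coordinates
        flip <- function(b) if (strand == "-") revcomp(b) else b
        return(list(pos = pos1, ref = flip(ref_t), alt = flip(alt_t_allele),
                    element_type = etype, gene_id = g, strand = strand,
                    inducing = flip(motif_base), disrupting = flip(if (ref_has_motif) alt_t else ref_t),
                    skipped_exon = sprintf("chr1:%d-%d", sk$start, sk$end)))
      }
    }
    stop_sre("could not place SRE plant after 1000 attempts", "sre_generation_error")
  }

  plant_non_sre <- function() {
    for (attempt in seq_len(1000L)) {
      # mostly intronic, some exonic (constitutive exons), some intergenic
      kind <- sample(c("intron", "exon", "intergenic"), 1L,
                     prob = c(0.6, 0.3, 0.1))
      if (kind == "intergenic") {
        pos1 <- sample(10:(gap - 10L), 1L)
        strand <- "+"
        g <- NA_character_
      } else {
        g <- sample(genes$gene_id, 1L)
        ge <- exon_tab[gene_id == g]
        strand <- ge$strand[1L]
        if (kind == "exon") {
          e <- ge[sample(.N, 1L)]
          pos1 <- sample((e$start + 7L):(e$end - 6L), 1L)
        } else {
          i <- sample(seq_len(n_ex - 1L), 1L)
          pos1 <- sample((ge$end[i] + 9L):(ge$start[i + 1L] - 8L), 1L)
        }
      }
      if (any(abs(used - pos1) < 12L)) next
      ctx <- get_ctx(pos1, strand)
      ref_t <- substr(ctx, 6L, 6L)
      cand <- sample(setdiff(DNA_BASES, ref_t), 3L)
      if (.matches_any_motif(ctx, ref_t, motif_sets)) {
        # rewrite the reference center base if the existing context matches
        repl <- Filter(function(b) !.matches_any_motif(ctx, b, motif_sets),
                       DNA_BASES)
        if (!length(repl)) next
        ref_t <- repl[1L]
        ctx_ref <- ctx; substr(ctx_ref, 6L, 6L) <- ref_t
        put_ctx(pos1, strand, ctx_ref)
        ctx <- ctx_ref
        cand <- sample(setdiff(DNA_BASES, ref_t), 3L)
      }
      alt_t <- NULL
      for (b in cand) {
        if (!.matches_any_motif(ctx, b, motif_sets)) { alt_t <- b; break }
      }
      if (is.null(alt_t)) next
      claim(pos1)
      flip <- function(b) if (strand == "-") revcomp(b) else b
      return(list(pos = pos1, ref = flip(ref_t), alt = flip(alt_t),
                  element_type = NA_character_, gene_id = g, strand = strand,
                  inducing = NA_character_, disrupting = NA_character_,
                  skipped_exon = NA_character_))
    }
    stop_sre("could not place non-SRE plant after 1000 attempts",
             "sre_generation_error")
  }

  k <- 1L
  for (i in seq_len(n_sre)) {
    plants[[k]] <- c(plant_sre(types[i], ref_carries[i]), is_sre = TRUE)
    k <- k + 1L
  }
  for (i in seq_len(n_non)) {
    plants[[k]] <- c(plant_non_sre(), is_sre = FALSE)
    k <- k + 1L
  }

  truth <- rbindlist(lapply(plants, as.data.table))
  data.table::setorder(truth, pos)
  truth[, variant_id := sprintf("snp%04d", .I)]

  fasta <- Biostrings::DNAStringSet(get("s", envir = seq_env))
  names(fasta) <- "chr1"

  models <- .build_gene_models(exon_tab, exon_len)
  # functional class truth by codon arithmetic on the emitted sequence
  truth[, func_class := .truth_func_class(.SD, exon_tab, fasta), by = variant_id]
  variants <- truth[, .(variant_id, chrom = "chr1", pos, ref, alt)]
  list(fasta = fasta, models = models, variants = variants,
       truth = truth[, .(variant_id, chrom = "chr1", pos, ref, alt, is_sre,
                         element_type, inducing_allele = inducing,
                         disrupting_allele = disrupting, func_class,
                         gene_id, strand, skipped_exon_id = skipped_exon)],
       exon_tab = exon_tab)
}

# Assemble a gene_models object from the generator's exon table: one full
# isoform per gene plus a skipping isoform for genes with a skipped exon.
.build_gene_models <- function(exon_tab, exon_len) {
  rows <- list()
  for (g in unique(exon_tab$gene_id)) {
    ge <- exon_tab[gene_id == g]
    rows[[length(rows) + 1L]] <- data.table(
      gene_id = g, tx_id = paste0(g, ".t1"), chrom = "chr1",
      start = ge$start, end = ge$end, strand = ge$strand[1L]
    )
    if (any(ge$skipped)) {
      ke <- ge[skipped == FALSE]
      rows[[length(rows) + 1L]] <- data.table(
        gene_id = g, tx_id = paste0(g, ".t2"), chrom = "chr1",
        start = ke$start, end = ke$end, strand = ke$strand[1L]
      )
    }
  }
  exons <- rbindlist(rows)
  exons[, exon_id := paste0(chrom, ":", start, "-", end)]
  data.table::setorder(exons, gene_id, tx_id, start)
  genes <- exons[, .(chrom = chrom[1L], start = min(start), end = max(end),
                     strand = strand[1L]), by = gene_id]
  # CDS = exons of the full isoform, frame from cumulative exon length
  cds <- exons[grepl("\\.t1$", tx_id)][, {
    o <- if (strand[1L] == "+") order(start) else order(-start)
    len <- (end - start)[o]
    cum_before <- cumsum(c(0L, head(len, -1L)))
    data.table(chrom = chrom[o], start = start[o], end = end[o],
               strand = strand[o], tx_id = tx_id[o],
               phase = as.integer((3L - cum_before %% 3L) %% 3L))
  }, by = gene_id]
  structure(list(genes = genes, exons = exons, cds = cds,
                 skipped_exons = flag_skipped_exons(exons)),
            class = "gene_models")
}

# Truth functional class for one planted SNP via direct codon arithmetic.
.truth_func_class <- function(row, exon_tab, fasta) {
  pos0 <- row$pos - 1L
  if (is.na(row$gene_id)) return("other")
  ge <- exon_tab[gene_id == row$gene_id]
  inside <- ge[start <= pos0 & pos0 < end]
  if (nrow(inside) == 0L) return("intronic")
  strand <- ge$strand[1L]
  # coding offset along the transcription direction over the full isoform
  seqc <- as.character(fasta[[1L]])
  ex <- ge[order(start)]
  cds_seq <- paste(vapply(seq_len(nrow(ex)), function(i)
    substr(seqc, ex$start[i] + 1L, ex$end[i]), character(1L)), collapse = "")
  # offset of pos0 within the concatenated plus-strand exon sequence
  prior <- sum(pmax(0L, pmin(ex$end, pos0) - ex$start))
  if (strand == "-") {
    cds_seq <- revcomp(cds_seq)
    coff <- nchar(cds_seq) - prior - 1L
    ref_t <- revcomp(row$ref); alt_t <- revcomp(row$alt)
  } else {
    coff <- prior
    ref_t <- row$ref; alt_t <- row$alt
  }
  codon_i <- coff %/% 3L
  within <- coff %% 3L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return("other")
  stopifnot(substr(codon, within + 1L, within + 1L) == ref_t)
  codon_alt <- codon
  substr(codon_alt, within + 1L, within + 1L) <- alt_t
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(codon_alt)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*" && aa_ref != "*") "LOF"
  else "non-synonymous"
}

#' Built-in demonstration motif sets
#'
#' Small synthetic hexamer sets (50 per element type) for tests and examples;
#' drawn deterministically so they are disjoint across element types. Real
#' analyses should supply published ESE/ESS/ISE hexamer lists via
#' [read_motifs()].
#'
#' @param n_per_type hexamers per element type.
#' @param seed RNG seed.
#' @return named list of hexamer character vectors, class `motif_set`.
#' @export
default_motif_sets <- function(n_per_type = 50L, seed = 99L) {
  set.seed(seed)
  all_hex <- character(0)
  out <- list()
  for (et in c("ESE", "ESS", "ISE")) {
    hx <- character(0)
    while (length(hx) < n_per_type) {
      cand <- .rand_dna(6L)
      if (!cand %in% all_hex) {
        hx <- c(hx, cand); all_hex <- c(all_hex, cand)
      }
    }
    out[[et]] <- sort(hx)
  }
  structure(out, class = "motif_set")
}

# ---------------------------------------------------------------------------
# Whole-fixture assembly and plain-text emission

#' Generate a complete synthetic fixture in memory
#'
#' Runs the full generator: genome + gene models + planted SNPs, then
#' Balding-Nichols frequencies and LD-structured haplotype panels at the
#' planted positions, ancestral-allele assignment, optional sweep, B-value
#' track and uniform genetic map.
#'
#' @param config a [sim_config()].
#' @param motif_sets hexamer sets (default [default_motif_sets()]).
#' @return list: fasta, models, variants, truth, panels (list of
#'   [haplotype_panel()]), ancestral (data.table), bvals (data.table
#'   chrom/start/end/value), genetic_map, motif_sets, config.
#' @export
simulate_fixture <- function(config = sim_config(), motif_sets = default_motif_sets()) {
  gen <- generate_genes_and_motifs(config, motif_sets)
  n <- nrow(gen$variants)
  fr <- simulate_frequencies(n, config$divergence, child_seed(config$seed, 21L),
                             config$n_populations)
  pops <- paste0("P", seq_len(config$n_populations))
  contig_len <- Biostrings::width(gen$fasta)[1L]
  panels <- list()
  for (i in seq_along(pops)) {
    panels[[pops[i]]] <- simulate_panel(
      fr$freqs[, i], config$n_hap, child_seed(config$seed, 30L + i),
      pos_bp = gen$variants$pos, chrom = "chr1", pop = pops[i],
      switch_prob = config$switch_prob
    )
  }
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    panels[[sw$pop]] <- plant_sweep(panels[[sw$pop]], sw$core_index,
                                    sw$favored_allele, sw$carrier_fraction,
                                    sw$window %||% 100L,
                                    child_seed(config$seed, 41L))
  }
  set.seed(child_seed(config$seed, 51L))
  # ancestral allele: mostly the reference, occasionally alt, 5% unknown
  anc_kind <- sample(c("ref", "alt", "unknown"), n, replace = TRUE,
                     prob = c(0.80, 0.15, 0.05))
  ancestral <- data.table(
    variant_id = gen$variants$variant_id,
    ancestral = ifelse(anc_kind == "ref", gen$variants$ref,
                       ifelse(anc_kind == "alt", gen$variants$alt, NA_character_))
  )
  # B values: piecewise constant on {100,...,1000}, 5 kb segments
  brk <- seq(0L, contig_len + 5000L, by = 5000L)
  bvals <- data.table(chrom = "chr1", start = head(brk, -1L), end = tail(brk, -1L),
                      value = sample(seq(100L, 1000L, by = 100L),
                                     length(brk) - 1L, replace = TRUE))
  genetic_map <- data.table(chrom = "chr1", pos = c(1L, contig_len),
                            cM = c(1L, contig_len) * 1e-6)
  # per-population allele counts on the variants table
  variants <- data.table::copy(gen$variants)
  for (p in names(panels)) {
    variants[, paste0("x_", p) := colSums(panels[[p]]$H)]
    variants[, paste0("n_", p) := nrow(panels[[p]]$H)]
  }
  list(fasta = gen$fasta, models = gen$models, variants = variants,
       truth = gen$truth, panels = panels, ancestral = ancestral,
       bvals = bvals, genetic_map = genetic_map, motif_sets = motif_sets,
       config = config)
}

#' Write a fixture to disk as the plain-text formats the readers consume
#'
#' Emits VCF (phased GT), GFF3, FASTA (+.fai), motif TSV, ancestral TSV,
#' genetic map TSV, B-value bedGraph, truth TSV and a manifest recording the
#' seed and a config hash.
#'
#' @param fx fixture from [simulate_fixture()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, named character vector of file paths.
#' @export
write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "panel.vcf"),
    gff = file.path(out_dir, "genes.gff3"),
    fasta = file.path(out_dir, "ref.fa"),
    motifs = file.path(out_dir, "motifs.tsv"),
    ancestral = file.path(out_dir, "ancestral.tsv"),
    map = file.path(out_dir, "genetic_map.tsv"),
    bvals = file.path(out_dir, "bvalues.bedgraph"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  write_vcf(fx$panels, fx$variants, paths["vcf"])
  write_gff3(fx$models, paths["gff"])
  Biostrings::writeXStringSet(fx$fasta, paths["fasta"])
  Rsamtools::indexFa(paths["fasta"])
  mot <- rbindlist(lapply(names(fx$motif_sets), function(t)
    data.table(hexamer = fx$motif_sets[[t]], element_type = t)))
  fwrite(mot, paths["motifs"], sep = "\t")
  fwrite(fx$ancestral, paths["ancestral"], sep = "\t")
  fwrite(fx$genetic_map, paths["map"], sep = "\t", col.names = FALSE)
  fwrite(fx$bvals, paths["bvals"], sep = "\t", col.names = FALSE)
  fwrite(fx$truth, paths["truth"], sep = "\t")
  writeLines(c(
    sprintf("seed\t%d", fx$config$seed),
    sprintf("config_hash\t%s", config_hash(fx$config)),
    sprintf("n_snps\t%d", nrow(fx$variants)),
    "ld_model\thaplotype mosaic copying, per-site switch prob 0.05, binomial frequency correction"
  ), paths["manifest"])
  invisible(paths)
}

#' Stable hash of a simulation config
#' @param config a [sim_config()].
#' @return character scalar (FNV-1a over the deparsed config).
#' @export
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Minimal VCF 4.2 writer for phased biallelic panels (fixture emission; reading
# goes through VariantAnnotation).
write_vcf <- function(panels, variants, path) {
  pops <- names(panels)
  sample_names <- unlist(lapply(pops, function(p)
    sprintf("%s_%03d", p, seq_len(nrow(panels[[p]]$H) / 2L))))
  gt_cols <- do.call(cbind, lapply(pops, function(p) {
    H <- panels[[p]]$H
    i1 <- seq(1L, nrow(H), 2L)
    matrix(paste0(t(H[i1, , drop = FALSE]), "|", t(H[i1 + 1L, , drop = FALSE])),
           ncol(H), length(i1))
  }))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", ".", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

# Minimal GFF3 writer mirroring what rtracklayer::import reads back.
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in models$genes$gene_id) {
    gr <- models$genes[gene_id == g]
    lines <- c(lines, sprintf("chr1\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              gr$start + 1L, gr$end, gr$strand, g))
    for (t in unique(models$exons[gene_id == g, tx_id])) {
      te <- models$exons[tx_id == t]
      lines <- c(lines, sprintf("chr1\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                min(te$start) + 1L, max(te$end), te$strand[1L], t, g))
      lines <- c(lines, sprintf("chr1\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                te$start + 1L, te$end, te$strand, t))
      tc <- models$cds[tx_id == t]
      if (nrow(tc)) {
        lines <- c(lines, sprintf("chr1\tsynth\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                                  tc$start + 1L, tc$end, tc$strand, tc$phase, t))
      }
    }
  }
  writeLines(lines, path)
}

#' Simulate a background-selection-confounded stratum fixture
#'
#' Generates per-SNP (B stratum, SRE flag, high-F_ST flag) data in which the
#' odds ratio between high F_ST and SRE membership equals `stratum_or` inside
#' every B stratum, but B is correlated with both SRE membership and high
#' F_ST, so the crude (pooled) odds ratio is inflated — the situation the
#' Cochran-Mantel-Haenszel common odds ratio corrects.
#'
#' @param n_snps number of SNPs.
#' @param stratum_or within-stratum odds ratio (default 1.2).
#' @param seed RNG seed.
#' @return data.table with columns b_stratum, is_sre, high_fst.
#' @export
simulate_confounded_strata <- function(n_snps, stratum_or = 1.2, seed = 1L) {
  set.seed(seed)
  # stratum 1: low B (strong background selection) — SRE-rich and high-Fst-rich
  p_sre <- c(0.70, 0.25)
  p_hf_nonsre <- c(0.45, 0.05)
  stratum <- sample(1:2, n_snps, replace = TRUE)
  is_sre <- runif(n_snps) < p_sre[stratum]
  base <- p_hf_nonsre[stratum]
  odds_sre <- stratum_or * base / (1 - base)
  p_hf <- ifelse(is_sre, odds_sre / (1 + odds_sre), base)
  data.table(b_stratum = c(100L, 600L)[stratum], is_sre = is_sre,
             high_fst = runif(n_snps) < p_hf)
}
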