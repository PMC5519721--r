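# io_formats: readers/writers for the standard formats the pipeline touches.
#
# Conventions: VCF positions stay 1-based in the variants table (VCF
# convention); gene models and interval tracks are converted to 0-based
# half-open internally at the read boundary; a 1-based query position q tests
# containment of q-1 in a track.

#' Construct a haplotype panel
#'
#' A haplotype panel is the unit the selection statistics operate on: a binary
#' haplotype-by-site matrix for one population, with physical and genetic
#' positions. Entry 1 codes the ALT allele at that site.
#'
#' @param pop population label.
#' @param H integer/numeric matrix, haplotypes in rows, sites in columns,
#'   entries in \{0,1\}.
#' @param chrom chromosome name (single value; one panel spans one contig).
#' @param pos_bp 1-based physical positions, strictly increasing.
#' @param pos_cM genetic positions in centimorgans, non-decreasing. Defaults
#'   to a uniform 1 cM/Mb map over `pos_bp`.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(pop, H, chrom, pos_bp, pos_cM = pos_bp * 1e-6) {
  H <- as.matrix(H)
  if (ncol(H) != length(pos_bp)) {
    stop_sre("number of sites in H must match pos_bp", "sre_format_error")
  }
  if (anyNA(H) || !all(H %in% c(0L, 1L))) {
    stop_sre("haplotype matrix entries must be 0/1 with no missing values",
             "sre_format_error")
  }
  if (is.unsorted(pos_bp, strictly = TRUE)) {
    stop_sre("physical positions must be strictly increasing", "sre_format_error")
  }
  if (is.unsorted(pos_cM)) {
    stop_sre("genetic positions must be non-decreasing", "sre_format_error")
  }
  structure(
    list(pop = pop, H = matrix(as.integer(H), nrow(H), ncol(H)),
         chrom = chrom, pos_bp = as.integer(pos_bp), pos_cM = as.numeric(pos_cM)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> pop=%s  %d haplotypes x %d sites  (%s:%d-%d)\n",
              x$pop, nrow(x$H), ncol(x$H), x$chrom,
              min(x$pos_bp), max(x$pos_bp)))
  invisible(x)
}

#' Read a phased VCF into per-population haplotype panels
#'
#' Only biallelic, phased SNP records enter the pipeline; indels,
#' multi-allelic and unphased records are skipped and counted.
#'
#' @param path VCF file (4.x, GT field required, phased with `|`).
#' @param pop_assignment named character vector mapping sample name to
#'   population label; every VCF sample must be present.
#' @param genetic_map optional data.frame/data.table with columns
#'   `chrom, pos, cM` used to interpolate genetic positions (default: uniform
#'   1 cM/Mb).
#' @return list with `panels` (named list of [haplotype_panel()]), `variants`
#'   (data.table: variant_id, chrom, pos, ref, alt, plus per-population ALT
#'   counts `x_<pop>` and haplotype totals `n_<pop>`), and `n_skipped`.
#' @export
read_vcf_panel <- function(path, pop_assignment, genetic_map = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% names(VariantAnnotation::geno(vcf))) {
    stop_sre("VCF has no GT field", "sre_format_error")
  }
  samples <- colnames(vcf)
  missing_samples <- setdiff(samples, names(pop_assignment))
  if (length(missing_samples)) {
    stop_sre(paste("samples absent from pop_assignment:",
                   paste(missing_samples, collapse = ", ")),
             "sre_config_error")
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))

  gt <- VariantAnnotation::geno(vcf)$GT
  phased <- apply(gt, 1L, function(g) all(grepl("^[01][|][01]$", g)))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% DNA_BASES & alt1 %in% DNA_BASES & phased
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("read_vcf_panel: skipped %d non-biallelic/indel/unphased records",
                    n_skipped))
  }

  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  if (length(unique(chrom)) > 1L) {
    stop_sre("panels spanning multiple chromosomes are not supported",
             "sre_format_error")
  }
  ord <- order(pos)
  gt <- gt[keep, , drop = FALSE][ord, , drop = FALSE]
  variants <- data.table(
    variant_id = rownames(gt) %||% paste0("var", seq_len(sum(keep))),
    chrom = chrom[ord], pos = pos[ord],
    ref = ref[keep][ord], alt = alt1[keep][ord]
  )

  pos_cM <- interp_genetic_map(genetic_map, variants$chrom[1L], variants$pos)
  pops <- unique(unname(pop_assignment[samples]))
  panels <- list()
  for (p in pops) {
    smp <- samples[pop_assignment[samples] == p]
    gts <- gt[, smp, drop = FALSE]
    h1 <- matrix(as.integer(substr(gts, 1L, 1L)), nrow(gts), ncol(gts))
    h2 <- matrix(as.integer(substr(gts, 3L, 3L)), nrow(gts), ncol(gts))
    # interleave the two haplotypes of each sample, haplotypes in rows
    H <- matrix(0L, 2L * length(smp), nrow(gts))
    H[seq(1L, 2L * length(smp), 2L), ] <- t(h1)
    H[seq(2L, 2L * length(smp), 2L), ] <- t(h2)
    panels[[p]] <- haplotype_panel(p, H, variants$chrom[1L], variants$pos, pos_cM)
    variants[, paste0("x_", p) := colSums(H)]
    variants[, paste0("n_", p) := nrow(H)]
  }
  list(panels = panels, variants = variants, n_skipped = n_skipped)
}

# Interpolate genetic positions (cM) at physical positions from a map table;
# uniform 1 cM/Mb when no map is given. Linear interpolation, constant-slope
# extrapolation at the ends.
interp_genetic_map <- function(map, chrom, pos) {
  if (is.null(map)) return(pos * 1e-6)
  map <- as.data.frame(map)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) < 2L) return(pos * 1e-6)
  stats::approx(m$pos, m$cM, xout = pos, rule = 2L)$y
}

#' Read a genetic map (TSV with columns chrom, pos, cM)
#' @param path tab-separated file.
#' @return data.table with columns chrom, pos, cM.
#' @export
read_genetic_map <- function(path) {
  m <- fread(path, col.names = c("chrom", "pos", "cM"))
  if (any(m$cM < 0)) stop_sre("negative cM in genetic map", "sre_format_error")
  m
}

#' Read gene models from GFF3 or BED12
#'
#' Exons are stored 0-based half-open. An exon is flagged skipped iff it is
#' present in at least one isoform and absent in at least one other isoform of
#' the same gene while both flanking exons are shared by that other isoform.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED12 (`.bed`) file.
#' @return object of class `gene_models`: list with `genes`, `exons`, `cds`
#'   data.tables and `skipped_exons` (gene_id, exon_id, start, end).
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    exons <- rbindlist(lapply(seq_along(gr), function(i) {
      bl <- GenomicRanges::ranges(rtracklayer::blocks(gr[i]))[[1L]]
      data.table(
        gene_id = sub("\\.[^.]*$", "", gr$name[i]), tx_id = gr$name[i],
        chrom = as.character(GenomicRanges::seqnames(gr[i])),
        start = GenomicRanges::start(bl) - 1L, end = GenomicRanges::end(bl),
        strand = as.character(GenomicRanges::strand(gr[i]))
      )
    }))
    cds <- exons[0L]
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    ex <- gr[gr$type == "exon"]
    tx <- gr[gr$type %in% c("mRNA", "transcript")]
    tx_parent <- setNames(as.character(unlist(tx$Parent)), tx$ID)
    exons <- data.table(
      gene_id = unname(tx_parent[as.character(unlist(ex$Parent))]),
      tx_id = as.character(unlist(ex$Parent)),
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex) - 1L, end = GenomicRanges::end(ex),
      strand = as.character(GenomicRanges::strand(ex))
    )
    # exon outside its parent transcript span is a malformed model
    tx_span <- data.table(tx_id = tx$ID,
                          tx_start = GenomicRanges::start(tx) - 1L,
                          tx_end = GenomicRanges::end(tx))
    chk <- merge(exons, tx_span, by = "tx_id")
    if (any(chk$start < chk$tx_start | chk$end > chk$tx_end)) {
      stop_sre("exon outside parent transcript span", "sre_format_error")
    }
    cd <- gr[gr$type == "CDS"]
    cds <- if (length(cd)) data.table(
      gene_id = unname(tx_parent[as.character(unlist(cd$Parent))]),
      tx_id = as.character(unlist(cd$Parent)),
      chrom = as.character(GenomicRanges::seqnames(cd)),
      start = GenomicRanges::start(cd) - 1L, end = GenomicRanges::end(cd),
      strand = as.character(GenomicRanges::strand(cd)),
      phase = as.integer(cd$phase)
    ) else exons[0L]
  }
  if (anyNA(exons$gene_id)) {
    stop_sre("exon with no resolvable gene parent", "sre_format_error")
  }
  exons[, exon_id := paste0(chrom, ":", start, "-", end)]
  data.table::setorder(exons, gene_id, tx_id, start)
  genes <- exons[, .(chrom = chrom[1L], start = min(start), end = max(end),
                     strand = strand[1L]), by = gene_id]
  structure(list(genes = genes, exons = exons, cds = cds,
                 skipped_exons = flag_skipped_exons(exons)),
            class = "gene_models")
}

# Identify skipped exons: internal exon e of isoform t is skipped if another
# isoform of the same gene carries both exons flanking e in t but not e.
flag_skipped_exons <- function(exons) {
  out <- list()
  for (g in unique(exons$gene_id)) {
    ge <- exons[gene_id == g]
    txs <- split(ge$exon_id, ge$tx_id)
    if (length(txs) < 2L) next
    for (t in names(txs)) {
      ids <- txs[[t]]
      if (length(ids) < 3L) next
      for (i in 2L:(length(ids) - 1L)) {
        e <- ids[i]; up <- ids[i - 1L]; dn <- ids[i + 1L]
        hit <- vapply(txs[names(txs) != t], function(o) {
          all(c(up, dn) %in% o) && !(e %in% o)
        }, logical(1L))
        if (any(hit)) out[[length(out) + 1L]] <- ge[exon_id == e][1L,
          .(gene_id, exon_id, chrom, start, end, strand)]
      }
    }
  }
  if (!length(out)) {
    return(data.table(gene_id = character(), exon_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  unique(rbindlist(out))
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d transcripts, %d skipped exons\n",
              nrow(x$genes), length(unique(x$exons$tx_id)),
              nrow(x$skipped_exons)))
  invisible(x)
}

#' Read a hexamer motif set
#'
#' @param path TSV with columns `hexamer`, `element_type` (ESE/ESS/ISE); rows
#'   with invalid length or non-ACGT characters are rejected with their row
#'   numbers reported via warning.
#' @param element_type optional filter to a single type.
#' @return named list of character vectors (deduplicated hexamer sets), one
#'   per element type, class `motif_set`.
#' @export
read_motifs <- function(path, element_type = NULL) {
  m <- fread(path, header = TRUE)
  if (nrow(m) == 0L) stop_sre("empty motif file", "sre_config_error")
  data.table::setnames(m, 1:2, c("hexamer", "element_type"))
  m[, hexamer := toupper(hexamer)]
  bad <- which(nchar(m$hexamer) != 6L | grepl("[^ACGT]", m$hexamer))
  if (length(bad)) {
    warning(sprintf("read_motifs: rejected rows %s (not 6-base ACGT)",
                    paste(bad, collapse = ",")))
    m <- m[-bad]
  }
  if (!is.null(element_type)) m <- m[m$element_type == element_type]
  if (nrow(m) == 0L) stop_sre("no valid motifs", "sre_config_error")
  sets <- lapply(split(m$hexamer, m$element_type), function(x) sort(unique(x)))
  structure(sets, class = "motif_set")
}

#' Read an interval track (bedGraph: chrom, start, end, value)
#'
#' BED semantics: 0-based half-open intervals. Intervals must be
#' non-overlapping within a chromosome.
#'
#' @param path bedGraph file.
#' @return `interval_track`: a GRanges with a `value` column.
#' @export
read_interval_track <- function(path) {
  d <- fread(path, header = FALSE, col.names = c("chrom", "start", "end", "value"))
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start + 1L, d$end),
                               value = d$value)
  gr <- GenomicRanges::sort(gr)
  if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0L) {
    stop_sre("interval track has overlapping intervals", "sre_format_error")
  }
  gr
}

#' Look up the track value covering a 1-based position
#'
#' A 1-based query position q tests containment of the 0-based base q-1, i.e.
#' BED interval \[lo, hi) covers q iff lo < q <= hi.
#'
#' @param track value of [read_interval_track()] (GRanges with `value`).
#' @param chrom chromosome.
#' @param pos 1-based position(s).
#' @return numeric vector; NA where no interval covers the position.
#' @export
lookup_track <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  known <- chrom %in% GenomeInfoDb::seqlevels(track)
  if (!any(known)) return(out)
  q <- GenomicRanges::GRanges(rep(chrom, length.out = length(pos))[known],
                              IRanges::IRanges(pos[known], width = 1L))
  hits <- GenomicRanges::findOverlaps(q, track)
  vals <- rep(NA_real_, sum(known))
  vals[S4Vectors::queryHits(hits)] <- track$value[S4Vectors::subjectHits(hits)]
  out[known] <- vals
  out
}

#' Read an ancestral-allele table (TSV: variant_id, ancestral)
#' @param path tab-separated file with a header.
#' @return data.table with columns variant_id, ancestral (NA when not ACGT).
#' @export
read_ancestral <- function(path) {
  a <- fread(path, header = TRUE)
  data.table::setnames(a, 1:2, c("variant_id", "ancestral"))
  a[, ancestral := toupper(ancestral)]
  a[!ancestral %in% DNA_BASES, ancestral := NA_character_]
  a
}

#' Read reference sequence (FASTA)
#' @param path FASTA file.
#' @return `DNAStringSet` named by contig.
#' @export
read_reference <- function(path) {
  Biostrings::readDNAStringSet(path)
}
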