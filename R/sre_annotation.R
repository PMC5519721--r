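# sre_annotation: annotate variants against SRE hexamer motifs with allelic
# effect and exon-skipping context, and assign SNP functional class.
#
# Motif matching is performed on the transcribed strand of the host gene
# (contexts from minus-strand genes are reverse-complemented before
# windowing), since SRE hexamers are defined on pre-mRNA. Inducing/disrupting
# alleles are reported in reference-strand (VCF) coordinates.

#' Extract the 11-base sequence context centered on a variant
#'
#' @param fasta `DNAStringSet` (from [read_reference()]).
#' @param chrom contig name.
#' @param pos 1-based position; must be at least 6 bases from either contig
#'   edge, otherwise NA is returned (context unavailable).
#' @return upper-case 11-base string with the reference base at the center,
#'   or `NA_character_` when the context is unavailable.
#' @export
extract_context <- function(fasta, chrom, pos) {
  if (!chrom %in% names(fasta)) {
    stop_sre(sprintf("contig %s not in reference", chrom), "sre_format_error")
  }
  len <- Biostrings::width(fasta[names(fasta) == chrom])[1L]
  if (pos < 6L || pos > len - 5L) return(NA_character_)
  toupper(as.character(Biostrings::subseq(fasta[[which(names(fasta) == chrom)]],
                                          pos - 5L, pos + 5L)))
}

#' Enumerate the six hexamer windows containing a variant
#'
#' From the 11-base context with `allele` substituted at the center, takes a
#' 6-base window with the SNP in the last position and successively shifts it
#' until the SNP is in the first position.
#'
#' @param context11 11-base context string.
#' @param allele single base substituted at the center (position 6, 1-based).
#' @return character vector of exactly 6 hexamers, each containing the
#'   substituted base.
#' @export
hexamer_windows <- function(context11, allele) {
  if (is.na(context11) || nchar(context11) != 11L) {
    stop_sre("context must be an 11-base string", "sre_format_error")
  }
  if (!is_base(allele)) stop_sre("allele must be a single ACGT base", "sre_format_error")
  s <- context11
  substr(s, 6L, 6L) <- allele
  vapply(1:6, function(i) substr(s, i, i + 5L), character(1L))
}

#' Match both alleles of a variant against a motif set
#'
#' @param context11 11-base context (reference base at center).
#' @param ref,alt alleles; `ref` must equal the context center.
#' @param motifs character vector of hexamer motifs.
#' @return list with `ref` and `alt`: the motif hexamers matched by each
#'   allele's six windows (exact string match).
#' @export
allelic_motif_match <- function(context11, ref, alt, motifs) {
  if (substr(context11, 6L, 6L) != ref) {
    stop_sre("reference allele does not match context center", "sre_data_error")
  }
  list(ref = intersect(hexamer_windows(context11, ref), motifs),
       alt = intersect(hexamer_windows(context11, alt), motifs))
}

# Host gene of a 1-based position (first gene whose span contains it), or NA.
.host_gene <- function(models, chrom, pos) {
  pos0 <- pos - 1L
  g <- models$genes[models$genes$chrom == chrom &
                      models$genes$start <= pos0 & pos0 < models$genes$end]
  if (nrow(g) == 0L) return(NULL)
  g[1L]
}

#' Exon-skip geometry for a variant
#'
#' ISE candidates require the variant to lie in an intron immediately flanking
#' (either side of) a skipped exon of the host gene; ESE/ESS candidates
#' require it to lie inside a skipped exon. The junction distance is the bp
#' distance to the nearest exon/intron boundary of the host gene, 0 for the
#' first exonic or intronic base past a junction.
#'
#' @param chrom,pos variant location (pos 1-based).
#' @param models a `gene_models` object.
#' @param element_type "ESE", "ESS" or "ISE".
#' @return list: context_ok, skipped_exon_id (or NA), junction_distance
#'   (or NA), gene_id, strand, reason.
#' @export
exon_skip_context <- function(chrom, pos, models, element_type) {
  host <- .host_gene(models, chrom, pos)
  if (is.null(host)) {
    return(list(context_ok = FALSE, skipped_exon_id = NA_character_,
                junction_distance = NA_integer_, gene_id = NA_character_,
                strand = NA_character_, reason = "intergenic"))
  }
  pos0 <- pos - 1L
  ex <- unique(models$exons[models$exons$gene_id == host$gene_id,
                            c("start", "end")])
  ex <- ex[order(ex$start)]
  in_exon <- any(ex$start <= pos0 & pos0 < ex$end)
  # distance to the nearest junction: the first base on either side of an
  # exon boundary has distance 0
  J <- c(ex$start, ex$end)
  junction_distance <- min(ifelse(pos0 >= J, pos0 - J, J - 1L - pos0))
  sk <- models$skipped_exons[models$skipped_exons$gene_id == host$gene_id]
  ok <- FALSE; sk_id <- NA_character_
  if (nrow(sk)) {
    if (element_type %in% c("ESE", "ESS")) {
      hit <- sk[sk$start <= pos0 & pos0 < sk$end]
      if (in_exon && nrow(hit)) { ok <- TRUE; sk_id <- hit$exon_id[1L] }
    } else if (element_type == "ISE") {
      if (!in_exon) {
        # intron containing pos0: between consecutive exon boundaries
        ints <- data.table(start = head(ex$end, -1L), end = tail(ex$start, -1L))
        intr <- ints[ints$start <= pos0 & pos0 < ints$end]
        if (nrow(intr)) {
          adj <- sk[sk$start == intr$end[1L] | sk$end == intr$start[1L]]
          if (nrow(adj)) { ok <- TRUE; sk_id <- adj$exon_id[1L] }
        }
      }
    }
  }
  list(context_ok = ok, skipped_exon_id = sk_id,
       junction_distance = as.integer(junction_distance),
       gene_id = host$gene_id, strand = host$strand,
       reason = if (ok) "ok" else "geometry")
}

#' Functional class of a SNP
#'
#' `intronic` for intron-interior SNPs of a host gene; coding classes by
#' codon comparison on the transcribed strand (stop-gain and canonical
#' splice-dinucleotide disruption give `LOF`); `other` for UTR/intergenic or
#' when no CDS is available.
#'
#' @param chrom,pos,ref,alt variant fields (pos 1-based, reference-strand
#'   alleles).
#' @param models a `gene_models` object with a `cds` table.
#' @param fasta reference `DNAStringSet`.
#' @return one of "intronic", "synonymous", "non-synonymous", "LOF", "other".
#' @export
functional_class <- function(chrom, pos, ref, alt, models, fasta) {
  host <- .host_gene(models, chrom, pos)
  if (is.null(host)) return("other")
  pos0 <- pos - 1L
  ex <- unique(models$exons[models$exons$gene_id == host$gene_id,
                            c("start", "end")])
  ex <- ex[order(ex$start)]
  in_exon <- any(ex$start <= pos0 & pos0 < ex$end)
  if (!in_exon) {
    # splice dinucleotide: first/last two intronic bases flanking an exon
    near <- any(pos0 %in% c(ex$end, ex$end + 1L)) ||
      any(pos0 %in% c(ex$start - 1L, ex$start - 2L))
    return(if (near) "LOF" else "intronic")
  }
  cds <- models$cds[models$cds$gene_id == host$gene_id]
  hitcds <- cds[cds$start <= pos0 & pos0 < cds$end]
  if (nrow(cds) == 0L || nrow(hitcds) == 0L) {
    warning(sprintf("no CDS covering %s:%d; classifying as other", chrom, pos))
    return("other")
  }
  strand <- host$strand
  cds <- cds[order(cds$start)]
  seqc <- as.character(fasta[[which(names(fasta) == chrom)]])
  cds_seq <- paste(vapply(seq_len(nrow(cds)), function(i)
    substr(seqc, cds$start[i] + 1L, cds$end[i]), character(1L)), collapse = "")
  prior <- sum(pmax(0L, pmin(cds$end, pos0) - cds$start))
  if (strand == "-") {
    cds_seq <- revcomp(cds_seq)
    coff <- nchar(cds_seq) - prior - 1L
    ref_t <- revcomp(ref); alt_t <- revcomp(alt)
  } else {
    coff <- prior
    ref_t <- ref; alt_t <- alt
  }
  codon_i <- coff %/% 3L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return("other")
  within <- coff %% 3L
  if (substr(codon, within + 1L, within + 1L) != ref_t) {
    stop_sre(sprintf("reference mismatch at %s:%d", chrom, pos), "sre_data_error")
  }
  codon_alt <- codon
  substr(codon_alt, within + 1L, within + 1L) <- alt_t
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(codon_alt)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*" && aa_ref != "*") "LOF"
  else "non-synonymous"
}

#' Annotate all variants against SRE motif sets
#'
#' A variant is an SRE SNP iff at least one allele's hexamer windows exactly
#' match a motif of some element type AND the element-type-appropriate
#' exon-skip geometry holds (ISE: intron flanking a skipped exon; ESE/ESS:
#' inside a skipped exon). When both alleles match motifs the allelic
#' direction is recorded as "ambiguous".
#'
#' @param variants data.table with variant_id, chrom, pos, ref, alt.
#' @param models a `gene_models` object.
#' @param motif_sets named list of hexamer vectors (names in ESE/ESS/ISE).
#' @param fasta reference `DNAStringSet`.
#' @param transcribed_strand match motifs on the transcribed strand of the
#'   host gene (default TRUE); FALSE matches on the reference strand.
#' @return data.table, one row per variant: func_class, is_sre, element_types
#'   (comma-joined), inducing_allele, disrupting_allele (reference-strand
#'   bases or "ambiguous"), context_ok, skipped_exon_id, junction_distance,
#'   reason.
#' @export
annotate_all <- function(variants, models, motif_sets, fasta,
                         transcribed_strand = TRUE) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i]
    ctx <- extract_context(fasta, v$chrom, v$pos)
    host <- .host_gene(models, v$chrom, v$pos)
    strand <- if (!is.null(host)) host$strand else "+"
    fc <- functional_class(v$chrom, v$pos, v$ref, v$alt, models, fasta)
    base <- data.table(
      variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt, func_class = fc,
      gene_id = if (is.null(host)) NA_character_ else host$gene_id,
      is_sre = FALSE, element_types = NA_character_,
      inducing_allele = NA_character_, disrupting_allele = NA_character_,
      context_ok = FALSE, skipped_exon_id = NA_character_,
      junction_distance = NA_integer_, reason = "no_match"
    )
    if (is.na(ctx)) { base$reason <- "context_unavailable"; return(base) }
    if (transcribed_strand && strand == "-") {
      ctx_t <- revcomp(ctx); ref_t <- revcomp(v$ref); alt_t <- revcomp(v$alt)
    } else {
      ctx_t <- ctx; ref_t <- v$ref; alt_t <- v$alt
    }
    types_hit <- character(0); sk_id <- NA_character_; jd <- NA_integer_
    ref_any <- FALSE; alt_any <- FALSE; any_geom <- FALSE
    for (et in names(motif_sets)) {
      mm <- allelic_motif_match(ctx_t, ref_t, alt_t, motif_sets[[et]])
      if (!length(mm$ref) && !length(mm$alt)) next
      geo <- exon_skip_context(v$chrom, v$pos, models, et)
      jd <- geo$junction_distance
      if (!geo$context_ok) next
      any_geom <- TRUE
      types_hit <- c(types_hit, et)
      sk_id <- geo$skipped_exon_id
      ref_any <- ref_any || length(mm$ref) > 0L
      alt_any <- alt_any || length(mm$alt) > 0L
    }
    if (is.na(jd) && !is.null(host)) {
      jd <- exon_skip_context(v$chrom, v$pos, models, "ESE")$junction_distance
    }
    base$junction_distance <- jd
    if (any_geom) {
      base$is_sre <- TRUE
      base$context_ok <- TRUE
      base$element_types <- paste(types_hit, collapse = ",")
      base$skipped_exon_id <- sk_id
      base$reason <- "ok"
      if (ref_any && alt_any) {
        base$inducing_allele <- "ambiguous"
        base$disrupting_allele <- "ambiguous"
      } else if (ref_any) {
        base$inducing_allele <- v$ref
        base$disrupting_allele <- v$alt
      } else {
        base$inducing_allele <- v$alt
        base$disrupting_allele <- v$ref
      }
    }
    base
  })
  rbindlist(rows)
}
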