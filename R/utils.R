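# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of an ACGT string
#' @param x character vector of DNA strings.
#' @return character vector, reverse-complemented.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a codon (character scalar, ACGT, length 3) to an amino acid
# one-letter code, '*' for stop.
translate_codon <- function(codon) {
  stopifnot(nchar(codon) == 3L)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# Deterministic child seed: derive a stream-specific 31-bit seed from a master
# seed so independent simulation stages do not share RNG streams.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(stream) * 7919L %% 2147483647L
}

# Validate a single upper-case base.
is_base <- function(x) {
  is.character(x) & nchar(x) == 1L & x %in% DNA_BASES
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_sre <- function(msg, class) {
  stop(structure(
    class = c(class, "sreselscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
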