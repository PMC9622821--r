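# Internal genetic-code helpers shared by the ORF caller, MILC and dN/dS.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

# codons -> one-letter amino acids ('*' for stop)
translate_codons <- function(codons) {
  unname(.codon_table()[codons])
}

# nucleotide string (length divisible by 3) -> peptide, stop dropped if final
translate_nt <- function(nt) {
  n <- nchar(nt)
  stopifnot(n %% 3 == 0)
  starts <- seq.int(1L, n, 3L)
  aa <- translate_codons(substring(nt, starts, starts + 2L))
  aa <- aa[!(seq_along(aa) == length(aa) & aa == "*")]
  paste(aa, collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

# sense codons (61) and synonymous-family structure keyed by amino acid
.sense_codons <- function() {
  gc <- .codon_table()
  names(gc)[gc != "*"]
}

.codon_families <- function() {
  gc <- .codon_table()
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}
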