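# Small sequence helpers shared across modules.

#' Reverse complement of a nucleotide string
#' @param s residue string (IUPAC codes allowed; case preserved).
#' @return The reverse complement.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Translate frame 1 of a CDS with the standard genetic code, dropping any
# trailing partial codon. No ORF search: inputs are annotated CDSs.
translate_cds <- function(s) {
  s <- toupper(gsub("\\s", "", s))
  n3 <- (nchar(s) %/% 3L) * 3L
  if (n3 < 3L) stop("sequence shorter than one codon")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n3)),
                                     if.fuzzy.codon = "solve"))
}

# Column-wise statistics of a pairwise alignment given its two gapped strings.
# Substitutions are counted over columns where both sequences have a residue;
# indel events are maximal gap runs in either string.
.aln_columns <- function(a, b) {
  ac <- strsplit(toupper(a), "")[[1L]]
  bc <- strsplit(toupper(b), "")[[1L]]
  both <- ac != "-" & bc != "-"
  gap_events <- function(x) {
    r <- rle(x == "-")
    sum(r$values)
  }
  list(
    columns = length(ac),
    aligned_columns = sum(both),
    substitutions = sum(both & ac != bc),
    matches = sum(both & ac == bc),
    indel_events = gap_events(ac) + gap_events(bc)
  )
}

# Global nucleotide alignment with BLAST-like affine scoring.
.align_nt_global <- function(a, b, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2, type = "global") {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = type, substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(pa = pa,
       a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}
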