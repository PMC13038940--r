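# Core amino-acid alphabet constants shared across encoders.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This is the canonical internal
#' column order of every PSSM profile and feature block in the package;
#' PSI-BLAST file column order (`ARNDCQEGHILKMFPSTWYV`) is remapped to this
#' order at parse time.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order used by PSI-BLAST ASCII PSSM files.
PSIBLAST_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues excluded from the benchmark datasets (ambiguous / non-standard).
DEFAULT_FORBIDDEN <- c("X", "U", "Z", "B")

# Split a sequence string into a character vector of residues.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}
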