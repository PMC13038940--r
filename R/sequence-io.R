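# FASTA I/O and dataset-hygiene filtering.

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a data frame of protein
#' records. Sequence identifiers are the first whitespace-delimited token of
#' each header. Order is preserved and duplicate identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_records` data frame with columns `id` and `sequence`.
#'   Sequences are returned as read (case is normalised later, by
#'   [filter_records()]).
#' @seealso [write_fasta()], [filter_records()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA (sequence data before any '>' header): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA header with empty identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  protein_records(ids, as.character(set))
}

#' Construct a set of protein records
#'
#' @param id Character vector of non-empty identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @return A `protein_records` data frame.
#' @export
protein_records <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  id <- as.character(id)
  sequence <- as.character(sequence)
  if (any(!nzchar(id))) stop("record identifiers must be non-empty")
  if (anyDuplicated(id)) stop("record identifiers must be unique")
  structure(data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE),
            class = c("protein_records", "data.frame"))
}

#' Write protein records to a FASTA file
#'
#' @param records A `protein_records` data frame (or any data frame with
#'   `id` and `sequence` columns).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Filter protein records by length and alphabet
#'
#' Applies the benchmark-dataset hygiene rules used throughout the package:
#' sequences are upper-cased, terminal `*` stop characters are stripped, and
#' a record is rejected when its raw sequence is shorter than `min_len`
#' (reason `SHORT`) or contains any character outside the 20 standard
#' amino-acid letters -- including the ambiguous residues `X`, `U`, `Z`, `B`
#' (reason `NONSTANDARD`). Length is assessed before the alphabet so a
#' too-short sequence is reported as `SHORT` regardless of its content.
#'
#' @param records A `protein_records` data frame.
#' @param min_len Minimum sequence length kept (default 50).
#' @param forbidden Characters that mark a sequence as non-standard, in
#'   addition to anything outside [AA_ALPHABET]. Defaults to `X,U,Z,B`.
#' @return A list of class `pvp_filter` with elements `kept` (a
#'   `protein_records` data frame, upper-cased and validated) and `rejected`
#'   (a data frame with columns `id`, `length`, `reason`).
#' @examples
#' recs <- protein_records(c("a", "b"), c(strrep("A", 60), strrep("A", 30)))
#' filter_records(recs)$rejected
#' @export
filter_records <- function(records, min_len = 50L,
                           forbidden = DEFAULT_FORBIDDEN) {
  seqs <- toupper(records$sequence)
  stripped <- sub("\\*+$", "", seqs)
  n_stripped <- sum(stripped != seqs)
  if (n_stripped > 0) {
    message(n_stripped, " sequence(s) had terminal '*' stop characters stripped")
  }
  seqs <- stripped
  lens <- nchar(seqs)
  bad_alpha <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]*$"), seqs) |
    vapply(seqs, function(s) any(seq_chars(s) %in% toupper(forbidden)),
           logical(1), USE.NAMES = FALSE)
  reason <- rep(NA_character_, length(seqs))
  reason[bad_alpha] <- "NONSTANDARD"
  reason[lens < min_len] <- "SHORT"   # length rule takes precedence
  keep <- is.na(reason) & lens >= 1L
  reason[!keep & is.na(reason)] <- "SHORT"
  kept <- protein_records(records$id[keep], seqs[keep])
  rejected <- data.frame(id = records$id[!keep],
                         length = lens[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  structure(list(kept = kept, rejected = rejected), class = "pvp_filter")
}

#' @export
print.pvp_filter <- function(x, ...) {
  cat("Protein record filter: ", nrow(x$kept), " kept, ",
      nrow(x$rejected), " rejected\n", sep = "")
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

#' Write a rejection report as tab-separated text
#'
#' @param filter_result A `pvp_filter` object from [filter_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(filter_result, path) {
  utils::write.table(filter_result$rejected, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
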