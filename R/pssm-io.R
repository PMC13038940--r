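# PSI-BLAST ASCII PSSM parsing, writing and normalization.
#
# The ASCII dialect (blastpgp/psiblast -out_ascii_pssm): 2-3 header lines, a
# label line with 40 amino-acid letters, then one line per position holding
# <index> <residue> <20 log-odds ints> <20 weighted-percentage ints> <2 reals>,
# followed by footer statistics. Only the log-odds block is retained.

#' Construct a PSSM profile
#'
#' An `L x 20` position-specific scoring matrix together with its residue
#' string. Columns are always stored in the package's canonical alphabetical
#' order ([AA_ALPHABET]); `column_order` records the order found in the
#' source file, if any.
#'
#' @param residues Character vector of length L (one standard amino acid per
#'   position), or a single string of length L.
#' @param scores Numeric `L x 20` matrix of log-odds scores, columns in
#'   alphabetical amino-acid order.
#' @param column_order The 20 letters in source-file column order (defaults
#'   to alphabetical).
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(residues, scores,
                         column_order = AA_ALPHABET) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- seq_chars(residues)
  }
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("PSSM scores must be numeric")
  if (ncol(scores) != 20L) stop("PSSM must have exactly 20 score columns")
  if (nrow(scores) != length(residues)) {
    stop("PSSM row count (", nrow(scores), ") does not match residue count (",
         length(residues), ")")
  }
  if (nrow(scores) == 0L) stop("empty PSSM profile")
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad)) {
    stop("PSSM residues outside the 20-letter alphabet: ",
         paste(bad, collapse = ", "))
  }
  if (!setequal(column_order, AA_ALPHABET)) {
    stop("column_order must be a permutation of the 20 standard amino acids")
  }
  dimnames(scores) <- list(NULL, AA_ALPHABET)
  structure(list(residues = residues, scores = scores,
                 column_order = column_order),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile: L = ", length(x$residues), ", sequence ",
      paste(utils::head(x$residues, 10), collapse = ""),
      if (length(x$residues) > 10) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of positions in a PSSM profile
#' @param profile A `pssm_profile`.
#' @return Integer L.
#' @export
pssm_length <- function(profile) length(profile$residues)

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect. Only the first 20 numeric columns
#' (the log-odds block) are kept; the weighted-percentage block, the two
#' trailing information columns and the footer are discarded. Columns are
#' remapped from file order to alphabetical order at parse time so that all
#' downstream encoders are independent of file column order.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A [pssm_profile()].
#' @export
read_psiblast_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PSSM file: ", path)

  # label line: the first line whose tokens are 40 single letters
  label_idx <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 40L && all(grepl("^[A-Z]$", toks))) {
      label_idx <- i
      break
    }
  }
  if (is.na(label_idx)) stop("no PSSM column-label line found in ", path)
  labels <- strsplit(trimws(lines[label_idx]), "\\s+")[[1]]
  col_order <- labels[1:20]
  if (!setequal(col_order, AA_ALPHABET)) {
    stop("PSSM column labels are not the 20 standard amino acids in ", path)
  }

  if (label_idx >= length(lines)) stop("no PSSM matrix rows found in ", path)
  residues <- character(0)
  rows <- list()
  for (i in seq(label_idx + 1L, length(lines))) {
    line <- lines[i]
    if (!grepl("^\\s*\\d+\\s+[A-Za-z]($|\\s)", line)) {
      if (length(rows) > 0L) break   # footer reached
      next
    }
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    payload <- toks[-(1:2)]
    if (length(payload) != 42L) {
      stop("malformed PSSM row at line ", i, " of ", path, ": expected 42 ",
           "numeric fields after index and residue, found ", length(payload))
    }
    vals <- suppressWarnings(as.numeric(payload))
    if (anyNA(vals)) {
      stop("non-numeric PSSM field at line ", i, " of ", path)
    }
    res <- toupper(toks[2])
    if (!res %in% AA_ALPHABET) {
      stop("PSSM residue '", toks[2], "' at line ", i, " of ", path,
           " is outside the 20-letter alphabet")
    }
    residues <- c(residues, res)
    rows[[length(rows) + 1L]] <- vals[1:20]
  }
  if (!length(rows)) stop("no PSSM matrix rows found in ", path)
  scores_file_order <- do.call(rbind, rows)
  colnames(scores_file_order) <- col_order
  scores <- scores_file_order[, AA_ALPHABET, drop = FALSE]
  pssm_profile(residues, scores, column_order = col_order)
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [read_psiblast_pssm()] parses back to an identical
#' profile. The weighted-percentage block is written as zeros and the two
#' trailing real columns as `0.00`. Scores must be integer-valued (the
#' dialect carries integer log-odds); write before normalising.
#'
#' @param profile A [pssm_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (any(profile$scores != round(profile$scores))) {
    stop("only integer-valued profiles can be written in the ASCII dialect")
  }
  ord <- profile$column_order
  scores <- profile$scores[, ord, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
             con)
  writeLines(paste0("          ", paste(sprintf("%4s", c(ord, ord)), collapse = "")), con)
  for (k in seq_len(nrow(scores))) {
    writeLines(paste0(sprintf("%5d %s ", k, profile$residues[k]),
                      paste(sprintf("%4d", as.integer(scores[k, ])), collapse = ""),
                      " ",
                      paste(sprintf("%4d", integer(20)), collapse = ""),
                      "  0.00 0.00"),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Normalize the scores of a PSSM profile
#'
#' @param profile A [pssm_profile()].
#' @param mode `"raw"` (identity), `"sigmoid"` (elementwise
#'   `1 / (1 + exp(-p))`), or `"row_standard"` (each row rescaled to zero
#'   mean and unit variance across its 20 entries; rows with zero variance
#'   map to all-zeros).
#' @return A [pssm_profile()] with transformed scores.
#' @export
normalize_pssm <- function(profile, mode = c("raw", "sigmoid", "row_standard")) {
  stopifnot(inherits(profile, "pssm_profile"))
  mode <- match.arg(mode)
  s <- profile$scores
  out <- switch(mode,
    raw = s,
    sigmoid = 1 / (1 + exp(-s)),
    row_standard = {
      mu <- rowMeans(s)
      sdv <- apply(s, 1L, stats::sd)
      z <- (s - mu) / ifelse(sdv > 0, sdv, 1)
      z[sdv == 0, ] <- 0
      z
    })
  pssm_profile(profile$residues, out, column_order = profile$column_order)
}

#' Read a directory of per-protein PSSM files
#'
#' Expects one `<id>.pssm` file per requested identifier.
#'
#' @param dir Directory containing `<id>.pssm` files.
#' @param ids Identifiers to read; defaults to every `.pssm` file present.
#' @return Named list of [pssm_profile()] objects.
#' @export
read_pssm_dir <- function(dir, ids = NULL) {
  if (!dir.exists(dir)) stop("PSSM directory not found: ", dir)
  if (is.null(ids)) {
    files <- list.files(dir, pattern = "\\.pssm$")
    ids <- sub("\\.pssm$", "", files)
  }
  paths <- file.path(dir, paste0(ids, ".pssm"))
  missing <- ids[!file.exists(paths)]
  if (length(missing)) {
    stop("missing PSSM file(s) for id(s): ", paste(missing, collapse = ", "))
  }
  profiles <- lapply(paths, read_psiblast_pssm)
  names(profiles) <- ids
  profiles
}
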