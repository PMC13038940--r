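# PSSM-derived evolutionary descriptors: AAC-PSSM (20), DPC-PSSM (400),
# PSSM-COM (400) and Pse-PSSM (40), concatenated to the 860-feature block.
#
# Default per-encoder normalization follows the descriptors' original
# definitions: raw log-odds for AAC-PSSM / DPC-PSSM / PSSM-COM, row-wise
# standardization for Pse-PSSM.

#' AAC-PSSM: per-column mean of the PSSM
#'
#' The composition of each amino-acid type in the profile: the mean over all
#' L positions of that type's log-odds column,
#' `x_j = (1/L) * sum_k p(k, j)`.
#'
#' @param profile A [pssm_profile()].
#' @return Named numeric vector of length 20 (`AACPSSM_A` ... `AACPSSM_Y`).
#' @export
aac_pssm <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  out <- colMeans(profile$scores)
  names(out) <- paste0("AACPSSM_", AA_ALPHABET)
  out
}

#' DPC-PSSM: dipeptide composition of the PSSM
#'
#' Mean product of column i at one position and column j at the next,
#' `y(i, j) = (1/(L-1)) * sum_{k=1}^{L-1} p(k, i) * p(k+1, j)`, flattened
#' row-major over the 20 x 20 ordered pairs.
#'
#' @param profile A [pssm_profile()] with at least 2 positions.
#' @return Named numeric vector of length 400 (`DPCPSSM_A_A`,
#'   `DPCPSSM_A_C`, ...).
#' @export
dpc_pssm <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  s <- profile$scores
  L <- nrow(s)
  if (L < 2L) stop("DPC-PSSM requires a profile of length >= 2")
  m <- crossprod(s[seq_len(L - 1L), , drop = FALSE],
                 s[2:L, , drop = FALSE]) / (L - 1L)
  out <- as.vector(t(m))
  names(out) <- paste0("DPCPSSM_",
                       rep(AA_ALPHABET, each = 20L), "_",
                       rep(AA_ALPHABET, times = 20L))
  out
}

#' PSSM-COM: residue-grouped row sums of the PSSM
#'
#' A 20 x 20 matrix whose i-th row is the vector sum of all PSSM rows at
#' positions where the protein sequence carries the i-th standard amino
#' acid; rows for residues absent from the sequence are zero. With
#' `length_normalize = TRUE` (default) the sums are divided by L, removing
#' the sequence-length confound.
#'
#' @param profile A [pssm_profile()].
#' @param length_normalize Divide the grouped sums by L (default `TRUE`).
#' @return Named numeric vector of length 400 (`PSSMCOM_<residue>_<column>`,
#'   row-major).
#' @export
pssm_composition <- function(profile, length_normalize = TRUE) {
  stopifnot(inherits(profile, "pssm_profile"))
  s <- profile$scores
  L <- nrow(s)
  res <- factor(profile$residues, levels = AA_ALPHABET)
  m <- rowsum(s, res)                 # rows only for residues present
  full <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  full[rownames(m), ] <- m
  if (length_normalize) full <- full / L
  out <- as.vector(t(full))
  names(out) <- paste0("PSSMCOM_",
                       rep(AA_ALPHABET, each = 20L), "_",
                       rep(AA_ALPHABET, times = 20L))
  out
}

#' Pse-PSSM: pseudo position-specific scoring matrix descriptor
#'
#' Captures global composition and local sequence-order effects: 20 column
#' means of the (row-standardized) profile plus, for lag `xi`, 20 mean
#' squared lag-differences
#' `(1/(L-xi)) * sum_k (p(k, j) - p(k+xi, j))^2`.
#'
#' @param profile A [pssm_profile()] with more than `xi` positions.
#' @param xi Sequence-order lag (default 1).
#' @param standardize Row-standardize the profile first (default `TRUE`,
#'   the descriptor's conventional form).
#' @return Named numeric vector of length 40 (`PSEPSSM_1` ... `PSEPSSM_40`).
#' @export
pse_pssm <- function(profile, xi = 1L, standardize = TRUE) {
  stopifnot(inherits(profile, "pssm_profile"))
  xi <- as.integer(xi)
  if (xi < 1L) stop("xi must be a positive integer")
  L <- pssm_length(profile)
  if (L <= xi) stop("Pse-PSSM requires profile length L > xi (L = ", L,
                    ", xi = ", xi, ")")
  if (standardize) profile <- normalize_pssm(profile, "row_standard")
  s <- profile$scores
  means <- colMeans(s)
  d <- s[seq_len(L - xi), , drop = FALSE] - s[(xi + 1L):L, , drop = FALSE]
  lag_terms <- colSums(d^2) / (L - xi)
  out <- c(means, lag_terms)
  names(out) <- paste0("PSEPSSM_", seq_len(40L))
  out
}

#' Encode a PSSM profile as the 860-feature evolutionary vector
#'
#' Fixed concatenation order: AAC-PSSM (20), DPC-PSSM (400), PSSM-COM (400),
#' Pse-PSSM (40).
#'
#' @param profile A [pssm_profile()] with at least 2 positions.
#' @param xi Pse-PSSM lag (default 1).
#' @param length_normalize PSSM-COM length normalization (default `TRUE`).
#' @return Named numeric vector of length 860.
#' @export
encode_evolutionary <- function(profile, xi = 1L, length_normalize = TRUE) {
  c(aac_pssm(profile),
    dpc_pssm(profile),
    pssm_composition(profile, length_normalize = length_normalize),
    pse_pssm(profile, xi = xi))
}

#' Encode a batch of PSSM profiles
#'
#' @param profiles Named list of [pssm_profile()] objects.
#' @param ... Passed to [encode_evolutionary()].
#' @return Numeric matrix, one row per profile, 860 named columns.
#' @export
encode_evolutionary_batch <- function(profiles, ...) {
  rows <- lapply(profiles, encode_evolutionary, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- names(profiles)
  out
}
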