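# Classical sequence descriptors: AAC (20), DPC (400), GAAC (5), GDPC (25),
# CTDC (39), CTDT (39), CTDD (195); concatenated to the 723-feature block.

validate_sequence <- function(sequence, min_len = 1L, what = "descriptor") {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("sequence must be a single character string")
  }
  chars <- seq_chars(toupper(sequence))
  if (length(chars) < min_len) {
    stop(what, " requires sequence length >= ", min_len)
  }
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("sequence contains non-standard residues: ", paste(bad, collapse = ", "))
  }
  chars
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues; sums to 1.
#'
#' @param sequence Amino-acid sequence (single string over the standard
#'   alphabet).
#' @return Named numeric vector of length 20.
#' @export
seq_aac <- function(sequence) {
  chars <- validate_sequence(sequence, 1L, "AAC")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("AAC_", AA_ALPHABET)
  out
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered residue pairs among the L-1
#' overlapping adjacent pairs; sums to 1.
#'
#' @inheritParams seq_aac
#' @return Named numeric vector of length 400.
#' @export
seq_dpc <- function(sequence) {
  chars <- validate_sequence(sequence, 2L, "DPC")
  L <- length(chars)
  pairs <- paste0(chars[-L], "_", chars[-1L])
  lev <- paste0(rep(AA_ALPHABET, each = 20L), "_", rep(AA_ALPHABET, 20L))
  counts <- table(factor(pairs, levels = lev))
  out <- as.numeric(counts) / (L - 1L)
  names(out) <- paste0("DPC_", lev)
  out
}

#' Grouped amino-acid composition (GAAC)
#'
#' AAC after mapping residues to five physicochemical groups (aliphatic,
#' aromatic, positively charged, negatively charged, uncharged).
#'
#' @inheritParams seq_aac
#' @return Named numeric vector of length 5.
#' @export
seq_gaac <- function(sequence) {
  chars <- validate_sequence(sequence, 1L, "GAAC")
  grp <- residue_group(chars)
  counts <- table(factor(grp, levels = names(GAAC_GROUPS)))
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("GAAC_", names(GAAC_GROUPS))
  out
}

#' Grouped dipeptide composition (GDPC)
#'
#' DPC over the five physicochemical groups: 25 ordered group pairs.
#'
#' @inheritParams seq_aac
#' @return Named numeric vector of length 25.
#' @export
seq_gdpc <- function(sequence) {
  chars <- validate_sequence(sequence, 2L, "GDPC")
  grp <- residue_group(chars)
  L <- length(chars)
  pairs <- paste0(grp[-L], "_", grp[-1L])
  gn <- names(GAAC_GROUPS)
  lev <- paste0(rep(gn, each = 5L), "_", rep(gn, 5L))
  counts <- table(factor(pairs, levels = lev))
  out <- as.numeric(counts) / (L - 1L)
  names(out) <- paste0("GDPC_", lev)
  out
}

residue_group <- function(chars) {
  map <- character(0)
  for (g in names(GAAC_GROUPS)) map[GAAC_GROUPS[[g]]] <- g
  unname(map[chars])
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' For each of 13 physicochemical properties partitioning the alphabet into
#' three groups:
#' * CTDC: the three group fractions (sum to 1 per property);
#' * CTDT: the three between-group transition frequencies (unordered pairs
#'   1-2, 1-3, 2-3) among the L-1 adjacent pairs;
#' * CTDD: for each group, the positions (as percent of L, 1-based) of its
#'   first occurrence and of the residues completing 25, 50, 75 and 100
#'   percent of that group's occurrences (fractional counts rounded up);
#'   all five are 0 when the group is absent.
#'
#' @inheritParams seq_aac
#' @return Named numeric vector of length 273 (39 + 39 + 195), blocks in the
#'   order CTDC, CTDT, CTDD.
#' @export
seq_ctd <- function(sequence) {
  chars <- validate_sequence(sequence, 2L, "CTD")
  L <- length(chars)
  aa_idx <- match(chars, AA_ALPHABET)
  ctdc <- numeric(0); ctdt <- numeric(0); ctdd <- numeric(0)
  for (prop in names(CTD_PROPERTIES)) {
    gidx <- ctd_group_index(prop)[aa_idx]
    # composition
    comp <- tabulate(gidx, 3L) / L
    names(comp) <- paste0("CTDC_", prop, "_G", 1:3)
    ctdc <- c(ctdc, comp)
    # transition
    a <- gidx[-L]; b <- gidx[-1L]
    tr <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
            sum((a == 1 & b == 3) | (a == 3 & b == 1)),
            sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (L - 1L)
    names(tr) <- paste0("CTDT_", prop, "_", c("G1G2", "G1G3", "G2G3"))
    ctdt <- c(ctdt, tr)
    # distribution
    for (g in 1:3) {
      pos <- which(gidx == g)
      n <- length(pos)
      if (n == 0L) {
        d <- numeric(5)
      } else {
        cuts <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * n))
        d <- pos[cuts] / L * 100
      }
      names(d) <- paste0("CTDD_", prop, "_G", g, "_",
                         c("first", "p25", "p50", "p75", "p100"))
      ctdd <- c(ctdd, d)
    }
  }
  c(ctdc, ctdt, ctdd)
}

#' Encode a sequence as the 723-feature classical descriptor vector
#'
#' Fixed concatenation order: AAC (20), DPC (400), GAAC (5), GDPC (25),
#' CTDC (39), CTDT (39), CTDD (195).
#'
#' @inheritParams seq_aac
#' @return Named numeric vector of length 723.
#' @export
encode_sequence <- function(sequence) {
  c(seq_aac(sequence), seq_dpc(sequence), seq_gaac(sequence),
    seq_gdpc(sequence), seq_ctd(sequence))
}

#' Encode a batch of protein records
#'
#' @param records A `protein_records` data frame (see [protein_records()]).
#' @return Numeric matrix, one row per record (rownames = ids), 723 named
#'   columns.
#' @export
encode_sequence_batch <- function(records) {
  rows <- lapply(records$sequence, encode_sequence)
  out <- do.call(rbind, rows)
  rownames(out) <- records$id
  out
}
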