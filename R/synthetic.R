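# Synthetic sequences, PSSM profiles and labeled datasets with a
# controllable planted class signal, so every pipeline stage is testable
# without external databases or PSI-BLAST runs.
#
# Profiles emulate random-coil PSI-BLAST output: integer log-odds in
# [-10, 10], roughly centred at zero. The class signal is planted by
# default in a chosen set of PSSM columns (+delta mean shift for the
# positive class), mirroring the working hypothesis that the evolutionary
# profile — not raw composition — carries the virion/non-virion signal; a
# sequence-composition mode exists to exercise the classical 723-feature
# path.

#' Configuration for the synthetic fixture generator
#'
#' @param n_pos,n_neg Positive (PVP) and negative class sizes.
#' @param length_range Inclusive (min, max) sequence length range.
#' @param effect_size Class signal delta >= 0: mean log-odds shift applied
#'   to `signal_columns` of positive-class profiles (PSSM mode), or
#'   log-scale enrichment of `signal_residues` in positive-class sequences
#'   (sequence mode).
#' @param signal_columns Indices (1..20, alphabetical order) of the PSSM
#'   columns carrying the signal.
#' @param signal_residues Residues enriched in positive sequences
#'   (sequence mode).
#' @param signal_mode `"pssm"` (default) or `"sequence"`.
#' @param seed Integer master seed; every record derives its own stream
#'   from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_pos = 100L, n_neg = 100L,
                         length_range = c(60L, 100L), effect_size = 0,
                         signal_columns = 1:5,
                         signal_residues = c("A", "C", "D"),
                         signal_mode = c("pssm", "sequence"), seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(n_pos >= 1L, n_neg >= 1L, effect_size >= 0,
            length(length_range) == 2L, length_range[1] >= 2L,
            length_range[1] <= length_range[2],
            all(signal_columns %in% 1:20))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 effect_size = effect_size,
                 signal_columns = as.integer(signal_columns),
                 signal_residues = signal_residues,
                 signal_mode = signal_mode, seed = as.integer(seed)),
            class = "synth_config")
}

# fixed slightly non-uniform background residue composition
synth_background <- function() {
  w <- c(1.4, 0.6, 1.0, 1.1, 0.8, 1.3, 0.5, 1.0, 1.1, 1.5,
         0.5, 0.9, 0.9, 0.8, 1.0, 1.2, 1.0, 1.2, 0.3, 0.7)
  stats::setNames(w / sum(w), AA_ALPHABET)
}

#' Generate one synthetic PSSM profile
#'
#' Scores are rounded Gaussian draws (sd 2) clamped to the PSI-BLAST
#' log-odds range `[-10, 10]`; positive-class profiles get a `+delta` mean
#' shift on the configured signal columns before rounding. The residue
#' string is drawn from a fixed background composition. Deterministic given
#' `seed`.
#'
#' @param length Profile length L (>= 2).
#' @param positive Logical: is this a positive-class (PVP) profile?
#' @param cfg A [synth_config()].
#' @param seed Seed for this profile (default: the config's master seed).
#' @return A [pssm_profile()].
#' @export
synth_pssm <- function(length, positive, cfg, seed = cfg$seed) {
  length <- as.integer(length)
  if (length < 2L) stop("profile length must be at least 2")
  set.seed(seed)
  mu <- matrix(0, length, 20L)
  if (positive && cfg$signal_mode == "pssm") {
    mu[, cfg$signal_columns] <- cfg$effect_size
  }
  raw <- matrix(stats::rnorm(length * 20L, mean = mu, sd = 2), length, 20L)
  scores <- pmin(pmax(round(raw), -10L), 10L)
  bg <- synth_background()
  residues <- sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
  pssm_profile(residues, scores)
}

#' Generate one synthetic protein sequence
#'
#' @inheritParams synth_pssm
#' @return Character string over the 20-letter alphabet.
#' @export
synth_sequence <- function(length, positive, cfg, seed = cfg$seed) {
  set.seed(seed)
  w <- synth_background()
  if (positive && cfg$signal_mode == "sequence") {
    w[cfg$signal_residues] <- w[cfg$signal_residues] * exp(cfg$effect_size / 2)
    w <- w / sum(w)
  }
  paste(sample(AA_ALPHABET, length, replace = TRUE, prob = w), collapse = "")
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_pos + n_neg` paired sequence/profile records (positives
#' first). When `dir` is given, writes `sequences.fasta`, one
#' `pssm/<id>.pssm` per record, `labels.tsv` and a `manifest.json` snapshot
#' of the generator parameters — all in the exact dialects the package's
#' readers accept.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory (created if needed).
#' @return List of class `synth_dataset`: `records`
#'   ([protein_records()]), `profiles` (named list of [pssm_profile()]),
#'   `labels` (named 0/1 vector), and `paths` when written.
#' @export
synth_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_pos + cfg$n_neg
  labels <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
  ids <- sprintf("%s%03d", ifelse(labels == 1L, "pvp", "neg"),
                 stats::ave(seq_len(n), labels, FUN = seq_along))
  set.seed(cfg$seed)
  lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n,
                 replace = TRUE)
  seeds <- (cfg$seed + 7919L * seq_len(n)) %% .Machine$integer.max
  profiles <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    pos <- labels[i] == 1L
    profiles[[i]] <- synth_pssm(lens[i], pos, cfg, seed = seeds[i])
    # sequence and profile share the residue string so PSSM-COM grouping is
    # consistent between FASTA and profile views of a record
    seqs[i] <- paste(profiles[[i]]$residues, collapse = "")
    if (cfg$signal_mode == "sequence") {
      seqs[i] <- synth_sequence(lens[i], pos, cfg, seed = seeds[i] + 1L)
      profiles[[i]]$residues <- seq_chars(seqs[i])
    }
  }
  names(profiles) <- ids
  records <- protein_records(ids, seqs)
  names(labels) <- ids
  out <- list(records = records, profiles = profiles, labels = labels,
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pssm_dir <- file.path(dir, "pssm")
    dir.create(pssm_dir, showWarnings = FALSE)
    fasta <- file.path(dir, "sequences.fasta")
    write_fasta(records, fasta)
    for (id in ids) {
      write_psiblast_pssm(profiles[[id]], file.path(pssm_dir,
                                                    paste0(id, ".pssm")))
    }
    labels_path <- file.path(dir, "labels.tsv")
    utils::write.table(data.frame(id = ids, label = labels),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(unclass(cfg), manifest, auto_unbox = TRUE)
    out$paths <- list(fasta = fasta, pssm_dir = pssm_dir,
                      labels = labels_path, manifest = manifest)
  }
  class(out) <- "synth_dataset"
  out
}

#' Feature matrix of a synthetic dataset
#'
#' Convenience wrapper: encodes every record with the evolutionary (860) or
#' classical sequence (723) encoder and attaches the labels.
#'
#' @param ds A `synth_dataset`.
#' @param features `"evolutionary"` or `"sequence"`.
#' @return A [feature_matrix()].
#' @export
synth_feature_matrix <- function(ds, features = c("evolutionary", "sequence")) {
  features <- match.arg(features)
  X <- if (features == "evolutionary") {
    encode_evolutionary_batch(ds$profiles)
  } else {
    encode_sequence_batch(ds$records)
  }
  feature_matrix(X, ds$labels[rownames(X)])
}
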