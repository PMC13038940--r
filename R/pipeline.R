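# Batch orchestration: FASTA + PSSM directory -> filtered records ->
# feature table -> trained stacked model -> predictions and reports.

#' Extract a feature table from records and profiles
#'
#' Applies the dataset-hygiene filters, then encodes every kept record with
#' the evolutionary (860 features, needs a PSSM per id), classical sequence
#' (723 features) or combined (1583) encoder.
#'
#' @param records A [protein_records()] data frame.
#' @param profiles Named list of [pssm_profile()] objects keyed by record
#'   id; required unless `features = "sequence"`.
#' @param features `"evolutionary"`, `"sequence"` or `"both"`.
#' @param labels Optional named 0/1 vector keyed by id; attached as a
#'   `label` column.
#' @param min_len,forbidden Filter parameters (see [filter_records()]).
#' @return List of class `pvp_features`: `table` (data frame: `id`, named
#'   feature columns, optional `label`), `rejected` (rejection report),
#'   `feature_names`.
#' @export
extract_features <- function(records, profiles = NULL,
                             features = c("both", "evolutionary", "sequence"),
                             labels = NULL, min_len = 50L,
                             forbidden = DEFAULT_FORBIDDEN) {
  features <- match.arg(features)
  flt <- filter_records(records, min_len = min_len, forbidden = forbidden)
  kept <- flt$kept
  if (nrow(kept) == 0L) stop("no records survive the dataset filters")
  need_pssm <- features %in% c("both", "evolutionary")
  blocks <- list()
  if (need_pssm) {
    if (is.null(profiles)) stop("evolutionary features require PSSM profiles")
    missing <- setdiff(kept$id, names(profiles))
    if (length(missing)) {
      stop("missing PSSM profile(s) for id(s): ",
           paste(missing, collapse = ", "))
    }
    blocks$evolutionary <- encode_evolutionary_batch(profiles[kept$id])
  }
  if (features %in% c("both", "sequence")) {
    blocks$sequence <- encode_sequence_batch(kept)
  }
  X <- do.call(cbind, blocks)
  tab <- data.frame(id = kept$id, X, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  if (!is.null(labels)) {
    missing_lab <- setdiff(kept$id, names(labels))
    if (length(missing_lab)) {
      stop("missing label(s) for id(s): ", paste(missing_lab, collapse = ", "))
    }
    tab$label <- as.integer(labels[kept$id])
  }
  structure(list(table = tab, rejected = flt$rejected,
                 feature_names = colnames(X)),
            class = "pvp_features")
}

#' Extract a feature table from files on disk
#'
#' @param fasta Path to a FASTA file.
#' @param pssm_dir Directory of `<id>.pssm` files (required unless
#'   `features = "sequence"`).
#' @param labels_file Optional two-column (`id`, `label`) delimited file.
#' @inheritParams extract_features
#' @return A `pvp_features` list (see [extract_features()]).
#' @export
extract_features_files <- function(fasta, pssm_dir = NULL,
                                   features = c("both", "evolutionary",
                                                "sequence"),
                                   labels_file = NULL, min_len = 50L,
                                   forbidden = DEFAULT_FORBIDDEN) {
  features <- match.arg(features)
  records <- read_fasta(fasta)
  profiles <- NULL
  if (features %in% c("both", "evolutionary")) {
    if (is.null(pssm_dir)) stop("evolutionary features require --pssm-dir")
    flt <- filter_records(records, min_len = min_len, forbidden = forbidden)
    profiles <- read_pssm_dir(pssm_dir, flt$kept$id)
  }
  labels <- NULL
  if (!is.null(labels_file)) {
    lab <- utils::read.delim(labels_file, stringsAsFactors = FALSE)
    labels <- stats::setNames(as.integer(lab$label), lab$id)
  }
  extract_features(records, profiles, features = features, labels = labels,
                   min_len = min_len, forbidden = forbidden)
}

#' Feature matrix from an extracted feature table
#'
#' @param feats A `pvp_features` list with a `label` column, or a data
#'   frame shaped like its `table`.
#' @return A [feature_matrix()].
#' @export
features_to_matrix <- function(feats) {
  tab <- if (inherits(feats, "pvp_features")) feats$table else feats
  if (is.null(tab$label)) stop("feature table has no label column")
  X <- as.matrix(tab[, setdiff(colnames(tab), c("id", "label")), drop = FALSE])
  feature_matrix(X, tab$label, ids = tab$id)
}

#' Write a feature table as tab-separated text
#'
#' @param feats A `pvp_features` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(feats, path) {
  utils::write.table(feats$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @return Data frame shaped like `pvp_features$table`.
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
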