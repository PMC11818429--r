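# Peptide datasets are plain data.frames with columns
#   id, sequence, AMP, ACP, ADP, AHP, AIP
# (one 0/1 integer column per label, in the canonical order).

#' Assemble a peptide dataset data.frame
#'
#' @param id Character ids.
#' @param sequence Character sequences (upper-case standard amino acids).
#' @param labels Integer matrix (n x 5) of 0/1 label indicators, columns in
#'   [label_space()] order, or NULL for all-zero labels.
#' @return A validated peptide data.frame.
#' @export
peptide_set <- function(id, sequence, labels = NULL) {
  n <- length(sequence)
  if (is.null(labels)) {
    labels <- matrix(0L, n, length(label_space()))
  }
  labels <- matrix(as.integer(labels), nrow = n,
                   ncol = length(label_space()))
  colnames(labels) <- label_space()
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   labels, stringsAsFactors = FALSE)
  validate_peptides(df)
}

#' Validate a peptide dataset
#'
#' Checks the column contract, upper-cases sequences (with a warning when
#' lowercase input is seen), and rejects sequences containing characters
#' outside the 20 standard amino-acid letters.
#'
#' @param records Peptide data.frame (see [peptide_set()]).
#' @return The validated (possibly upper-cased) data.frame, invisibly usable.
#' @export
validate_peptides <- function(records) {
  needed <- c("id", "sequence", label_space())
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("peptide data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) return(records)
  seqs <- as.character(records$sequence)
  if (any(seqs != toupper(seqs))) {
    warning("lowercase residues found; sequences upper-cased on read")
    seqs <- toupper(seqs)
    records$sequence <- seqs
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record id ",
         records$id[which(!nzchar(seqs))[1L]])
  }
  ok <- grepl(paste0("^[", paste(STANDARD_AA, collapse = ""), "]+$"), seqs)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    badchar <- setdiff(strsplit(seqs[i], "")[[1L]], STANDARD_AA)[1L]
    stop("record '", records$id[i], "' contains non-standard residue '",
         badchar, "'")
  }
  for (lab in label_space()) {
    v <- records[[lab]]
    if (!all(v %in% c(0L, 1L))) {
      stop("label column ", lab, " must contain only 0/1")
    }
    records[[lab]] <- as.integer(v)
  }
  records
}

#' Extract the n x 5 label matrix of a peptide dataset
#'
#' @param records Peptide data.frame.
#' @return Integer matrix with one column per label, rownames = ids.
#' @export
label_matrix <- function(records) {
  m <- as.matrix(records[, label_space(), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- records$id
  m
}

parse_header_labels <- function(header, id) {
  # Header dialect: "id|AMP,ACP" or "id|11000"; a bare id means no labels.
  parts <- strsplit(header, "|", fixed = TRUE)[[1L]]
  if (length(parts) < 2L || !nzchar(parts[2L])) {
    return(rep(0L, length(label_space())))
  }
  tok <- trimws(parts[2L])
  if (grepl("^[01]{5}$", tok)) {
    return(as.integer(strsplit(tok, "")[[1L]]))
  }
  encode_labels(trimws(strsplit(tok, ",")[[1L]]))
}

#' Read a multi-label peptide dataset
#'
#' FASTA headers carry labels as `id|AMP,ACP` (comma-separated names) or
#' `id|11000` (a 5-bit string); CSV/TSV files carry `sequence` plus either
#' one 0/1 column per label name or a `labels` column of comma-separated
#' names. An `id` column is optional for delimited input.
#'
#' @param path Input file.
#' @param format One of "auto", "fasta", "csv", "tsv"; "auto" keys off the
#'   file extension.
#' @return A validated peptide data.frame (see [peptide_set()]).
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     fa = , faa = , fasta = "fasta",
                     csv = "csv",
                     tsv = , txt = "tsv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "fasta") {
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0L) {
      warning("empty FASTA file: ", path)
      return(peptide_set(character(0), character(0)))
    }
    headers <- names(aas)
    ids <- vapply(strsplit(headers, "|", fixed = TRUE), `[[`, "", 1L)
    labs <- t(vapply(seq_along(headers),
                     function(i) parse_header_labels(headers[i], ids[i]),
                     integer(length(label_space()))))
    return(peptide_set(ids, as.character(aas), labs))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("empty table: ", path)
    return(peptide_set(character(0), character(0)))
  }
  if (!"sequence" %in% names(df)) stop("missing required column 'sequence'")
  ids <- if ("id" %in% names(df)) as.character(df$id) else
    sprintf("pep%d", seq_len(nrow(df)))
  if (all(label_space() %in% names(df))) {
    labs <- as.matrix(df[, label_space(), drop = FALSE])
  } else if ("labels" %in% names(df)) {
    labs <- t(vapply(df$labels, function(s) {
      s <- trimws(s)
      if (!nzchar(s)) rep(0L, length(label_space()))
      else encode_labels(trimws(strsplit(s, ",")[[1L]]))
    }, integer(length(label_space()))))
  } else {
    stop("missing label columns: provide ",
         paste(label_space(), collapse = ", "), " or a 'labels' column")
  }
  peptide_set(ids, df$sequence, labs)
}

#' Write a peptide dataset
#'
#' Inverse of [read_peptides()] for both dialects.
#'
#' @param records Peptide data.frame.
#' @param path Output file.
#' @param format "fasta", "csv" or "tsv".
#' @export
write_peptides <- function(records, path, format = c("fasta", "csv", "tsv")) {
  format <- match.arg(format)
  records <- validate_peptides(records)
  if (format == "fasta") {
    labs <- label_matrix(records)
    toks <- apply(labs, 1L, function(b) paste(decode_labels(b), collapse = ","))
    headers <- ifelse(nzchar(toks), paste0(records$id, "|", toks), records$id)
    aas <- Biostrings::AAStringSet(records$sequence)
    names(aas) <- headers
    Biostrings::writeXStringSet(aas, path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(records, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Remove duplicate sequences, merging annotations
#'
#' Exactly one record is kept per distinct sequence string (first occurrence
#' order). When duplicates carry different label vectors the kept record
#' receives the bitwise union of all annotations, so no annotation is
#' discarded; each such merge is reported via `message()`.
#'
#' @param records Peptide data.frame.
#' @return Deduplicated peptide data.frame.
#' @export
deduplicate <- function(records) {
  records <- validate_peptides(records)
  if (nrow(records) <= 1L) return(records)
  groups <- split(seq_len(nrow(records)), factor(records$sequence,
                  levels = unique(records$sequence)))
  keep <- records[vapply(groups, `[[`, 0L, 1L), , drop = FALSE]
  for (g in which(lengths(groups) > 1L)) {
    idx <- groups[[g]]
    labs <- label_matrix(records[idx, , drop = FALSE])
    merged <- as.integer(colSums(labs) > 0L)
    if (!all(merged == labs[1L, ])) {
      message("deduplicate: merged labels for sequence of record '",
              records$id[idx[1L]], "' (union of ", length(idx), " records)")
    }
    keep[g, label_space()] <- as.list(merged)
  }
  rownames(keep) <- NULL
  keep
}

label_combo_key <- function(records) {
  apply(label_matrix(records), 1L, paste, collapse = "")
}

#' Group-stratified train/test split
#'
#' Records are grouped by exact label combination and each group is split at
#' `fraction`, rounding the test share to the nearest integer with at least
#' one test and one train record per group of size >= 2. The same seed
#' always reproduces the same split.
#'
#' @param records Deduplicated peptide data.frame.
#' @param fraction Training fraction in (0, 1); the benchmark convention
#'   is 0.8.
#' @param seed Integer RNG seed.
#' @return List with elements `train`, `test` (peptide data.frames),
#'   `fraction` and `seed`.
#' @export
split_train_test <- function(records, fraction = 0.8, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  records <- validate_peptides(records)
  combo <- label_combo_key(records)
  test_idx <- integer(0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (key in sort(unique(combo))) {
    idx <- which(combo == key)
    n <- length(idx)
    n_test <- round(n * (1 - fraction))
    if (n >= 2L) n_test <- min(max(n_test, 1L), n - 1L) else n_test <- 0L
    if (n_test > 0L) {
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  }
  test_idx <- sort(test_idx)
  train <- records[setdiff(seq_len(nrow(records)), test_idx), , drop = FALSE]
  test <- records[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, fraction = fraction, seed = as.integer(seed))
}

#' Write per-peptide predictions as TSV
#'
#' @param ids Character ids.
#' @param probs n x 5 probability matrix in label order.
#' @param decisions n x 5 0/1 matrix in label order.
#' @param path Output file.
#' @export
write_predictions <- function(ids, probs, decisions, path) {
  stopifnot(nrow(probs) == length(ids), nrow(decisions) == length(ids))
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(label_space())) {
    df[[paste0("prob_", label_space()[j])]] <- probs[, j]
  }
  for (j in seq_along(label_space())) {
    df[[paste0("pred_", label_space()[j])]] <- as.integer(decisions[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path Input file.
#' @return data.frame with id, prob_* and pred_* columns.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
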