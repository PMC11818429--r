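# In-silico saturation mutagenesis: enumerate every single-position
# substitution of a peptide, score each variant with a trained model (or
# ensemble), and report per-label probabilities and deltas against the
# wild type. Positions are 1-based; the wild-type record uses position 0
# with blank residue fields.

#' Enumerate all single-position substitutions
#'
#' For a peptide of length L this yields exactly 19 * L substitution
#' records (each position replaced by each of the 19 alternative standard
#' residues), ordered by (position, alphabetical mutant residue), plus one
#' leading wild-type record when `include_wildtype` is set — matching the
#' per-peptide record counts of saturation-mutagenesis scans (e.g. 210 for
#' an 11-mer).
#'
#' @param sequence Amino-acid string over the standard alphabet.
#' @param include_wildtype Prepend the unmutated record (default TRUE).
#' @return data.frame with columns position, wildtype_aa, mutant_aa,
#'   sequence.
#' @export
enumerate_mutants <- function(sequence, include_wildtype = TRUE) {
  sequence <- validate_peptides(peptide_set("q", sequence))$sequence
  chars <- strsplit(sequence, "")[[1L]]
  L <- length(chars)
  rows <- vector("list", L)
  for (pos in seq_len(L)) {
    alts <- setdiff(STANDARD_AA, chars[pos])
    muts <- vapply(alts, function(aa) {
      v <- chars
      v[pos] <- aa
      paste(v, collapse = "")
    }, "")
    rows[[pos]] <- data.frame(position = pos, wildtype_aa = chars[pos],
                              mutant_aa = alts, sequence = muts,
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (include_wildtype) {
    out <- rbind(data.frame(position = 0L, wildtype_aa = "", mutant_aa = "",
                            sequence = sequence, stringsAsFactors = FALSE),
                 out)
  }
  rownames(out) <- NULL
  out
}

#' Saturation-mutagenesis scan of one peptide
#'
#' Embeds and scores the wild type and every single-position variant;
#' deltas are mutant minus wild-type probability, per label.
#'
#' @param sequence Wild-type amino-acid string.
#' @param predictor A `label_gat_model` or `peptide_ensemble`.
#' @param backend An [embedding_backend()] used to embed the variants.
#' @param threshold Unused for scoring; kept for interface symmetry.
#' @return A `scan_result` list: `table` (data.frame with position,
#'   wildtype_aa, mutant_aa, sequence, prob_<label> and delta_<label>
#'   columns; first row = wild type), `wildtype_probs`, `label_space`.
#' @export
scan_peptide <- function(sequence, predictor, backend = embedding_backend(),
                         threshold = 0.5) {
  tab <- enumerate_mutants(sequence, include_wildtype = TRUE)
  recs <- peptide_set(sprintf("v%04d", seq_len(nrow(tab))), tab$sequence)
  P <- embed_peptides(recs, backend)
  probs <- predict_probs(predictor, P)
  wt <- probs[1L, ]
  deltas <- sweep(probs, 2L, wt)
  labs <- label_space()
  for (j in seq_along(labs)) tab[[paste0("prob_", labs[j])]] <- probs[, j]
  for (j in seq_along(labs)) tab[[paste0("delta_", labs[j])]] <- deltas[, j]
  structure(list(table = tab, wildtype_probs = wt, label_space = labs,
                 sequence = sequence),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  L <- nchar(x$sequence)
  cat("<saturation scan of '", x$sequence, "': ", 19L * L,
      " substitutions + wild type>\n", sep = "")
  cat("wild-type probabilities:\n")
  print(round(x$wildtype_probs, 4))
  invisible(x)
}

#' Write a scan result as TSV
#'
#' One row per record (wild type first), with per-label probability and
#' delta columns; row count = 1 + 19 * L.
#'
#' @param result A `scan_result` from [scan_peptide()].
#' @param path Output file.
#' @export
scan_report <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a scan TSV written by [scan_report()]
#'
#' @param path Input file.
#' @return data.frame in the [scan_peptide()] table layout.
#' @export
read_scan_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = character(0))
}
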