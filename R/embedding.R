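# Embedding backends turn a peptide sequence into one fixed-length numeric
# vector p. Pretrained protein-language-model backends (ESM-2, ProtT5,
# RoBERTa) are adapters around external checkpoints and are unavailable in
# a plain R session; the deterministic "kmer-test" backend and precomputed
# tables cover every in-package workflow.

KMER_TEST_DIM <- 20L + 400L  # normalized 1-mer block + 2-mer block

#' Describe an embedding backend
#'
#' @param name One of "kmer-test", "precomputed", "esm2", "prott5",
#'   "roberta".
#' @param dimension Embedding dimension d; inferred for "kmer-test" (420)
#'   and for precomputed tables, required otherwise.
#' @param pooling How per-residue representations are reduced to one
#'   vector: "mean" (default), "cls" or "max".
#' @param checkpoint Optional checkpoint identifier string for pretrained
#'   backends.
#' @return An `embedding_backend` object.
#' @export
embedding_backend <- function(name = "kmer-test", dimension = NULL,
                              pooling = c("mean", "cls", "max"),
                              checkpoint = NULL) {
  pooling <- match.arg(pooling)
  known <- c("kmer-test", "precomputed", "esm2", "prott5", "roberta")
  if (!name %in% known) {
    stop("unknown backend '", name, "'; known backends: ",
         paste(known, collapse = ", "))
  }
  if (name == "kmer-test") dimension <- KMER_TEST_DIM
  if (!is.null(dimension) && dimension <= 0) stop("dimension must be > 0")
  structure(list(name = name, dimension = dimension, pooling = pooling,
                 checkpoint = checkpoint),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat("<embedding backend '", x$name, "', d = ",
      if (is.null(x$dimension)) "?" else x$dimension,
      ", pooling = ", x$pooling, ">\n", sep = "")
  invisible(x)
}

.kmer_cache <- new.env(parent = emptyenv())

all_kmers <- function(k) {
  key <- as.character(k)
  if (is.null(.kmer_cache[[key]])) {
    .kmer_cache[[key]] <- if (k == 1L) STANDARD_AA else
      apply(expand.grid(rep(list(STANDARD_AA), k))[, k:1, drop = FALSE],
            1L, paste, collapse = "")
  }
  .kmer_cache[[key]]
}

kmer_block <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1L]]
  kmers <- all_kmers(k)
  v <- stats::setNames(numeric(length(kmers)), kmers)
  n <- length(chars) - k + 1L
  if (n >= 1L) {
    obs <- vapply(seq_len(n),
                  function(i) paste(chars[i:(i + k - 1L)], collapse = ""), "")
    tab <- table(obs)
    v[names(tab)] <- as.numeric(tab) / n
  }
  v
}

embed_kmer_test <- function(sequence) {
  c(kmer_block(sequence, 1L), kmer_block(sequence, 2L))
}

#' Embed one peptide sequence
#'
#' Deterministic for a fixed sequence and backend. The "kmer-test" backend
#' concatenates normalized 1-mer and 2-mer frequency vectors (d = 420);
#' each k-mer block sums to one for sequences of length >= k. Pretrained
#' backends require external checkpoints and raise an informative error
#' naming the fallback.
#'
#' @param sequence Amino-acid string (standard 20-letter alphabet).
#' @param spec An [embedding_backend()].
#' @return Numeric vector of length `spec$dimension`.
#' @export
embed_sequence <- function(sequence, spec = embedding_backend()) {
  stopifnot(inherits(spec, "embedding_backend"))
  seqs <- validate_peptides(peptide_set("q", sequence))$sequence
  if (spec$name == "kmer-test") {
    return(unname(embed_kmer_test(seqs)))
  }
  if (spec$name %in% c("esm2", "prott5", "roberta")) {
    stop("backend '", spec$name, "' not installed: pretrained ",
         "protein-language-model checkpoints are external artifacts; ",
         "use the 'kmer-test' backend or load precomputed embeddings ",
         "with load_precomputed()")
  }
  stop("backend '", spec$name, "' cannot embed sequences directly; ",
       "use load_precomputed()")
}

#' Embed a peptide dataset
#'
#' @param records Peptide data.frame (see [peptide_set()]).
#' @param spec An [embedding_backend()].
#' @return Numeric matrix, one row per record (rownames = ids).
#' @export
embed_peptides <- function(records, spec = embedding_backend()) {
  records <- validate_peptides(records)
  if (nrow(records) == 0L) {
    return(matrix(numeric(0), 0L, spec$dimension %||% 0L))
  }
  m <- t(vapply(records$sequence, embed_sequence,
                numeric(spec$dimension), spec = spec))
  rownames(m) <- records$id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool a per-residue representation matrix into one vector
#'
#' @param mat L x d matrix of per-residue vectors.
#' @param pooling "mean", "cls" (first row) or "max" (column-wise).
#' @return Numeric vector of length d.
#' @export
pool_residues <- function(mat, pooling = c("mean", "cls", "max")) {
  pooling <- match.arg(pooling)
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  switch(pooling,
         mean = colMeans(mat),
         cls = mat[1L, ],
         max = apply(mat, 2L, max))
}

#' Load precomputed embeddings from a delimited table
#'
#' Expects a TSV/CSV with an `id` column followed by a constant number of
#' numeric columns; the embedding dimension is inferred from the width.
#'
#' @param path Input table.
#' @param sep Field separator (default tab).
#' @return Numeric matrix (rownames = ids), with attribute "backend" =
#'   "precomputed".
#' @export
load_precomputed <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  widths <- utils::count.fields(path, sep = sep)
  if (length(widths) == 0L) {
    warning("empty embedding table: ", path)
    m <- matrix(numeric(0), 0L, 0L)
    attr(m, "backend") <- "precomputed"
    return(m)
  }
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged embedding table: row ", bad, " has ", widths[bad],
         " fields, expected ", widths[1L])
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("embedding table must have an 'id' column")
  ids <- as.character(df$id)
  if (anyDuplicated(ids)) {
    stop("duplicated id in embedding table: ", ids[duplicated(ids)][1L])
  }
  num <- df[, setdiff(names(df), "id"), drop = FALSE]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      stop("non-numeric cell in embedding column '", names(num)[j], "'")
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  attr(m, "backend") <- "precomputed"
  m
}

#' Write embeddings as a TSV table readable by [load_precomputed()]
#'
#' @param mat Numeric matrix with rownames = ids.
#' @param path Output file.
#' @export
write_embeddings <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
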