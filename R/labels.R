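#' The five-function label space
#'
#' The fixed, ordered set of functional labels used throughout the package:
#' antimicrobial (AMP), anticancer (ACP), antidiabetic (ADP),
#' antihypertensive (AHP) and anti-inflammatory (AIP) peptides. Every label
#' bit vector in the package follows this order, so a peptide that is both
#' antimicrobial and anticancer is encoded `c(1, 1, 0, 0, 0)`.
#'
#' @return Character vector of the five label names, in canonical order.
#' @export
#' @examples
#' label_space()
label_space <- function() {
  c("AMP", "ACP", "ADP", "AHP", "AIP")
}

#' Encode a set of label names as a bit vector
#'
#' @param names Character vector (possibly empty) of label names.
#' @param space Ordered label names; defaults to [label_space()].
#' @return Integer vector of length `length(space)` with 1 at the positions
#'   of `names`.
#' @export
#' @examples
#' encode_labels(c("AMP", "ACP"))  # 1 1 0 0 0
encode_labels <- function(names, space = label_space()) {
  names <- as.character(names)
  bad <- setdiff(names, space)
  if (length(bad) > 0L) {
    stop("unknown label name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(space, collapse = ", "))
  }
  as.integer(space %in% names)
}

#' Decode a bit vector into label names
#'
#' @param bits Integer 0/1 vector of length `length(space)`.
#' @param space Ordered label names.
#' @return Character vector of the names whose bit is set.
#' @export
decode_labels <- function(bits, space = label_space()) {
  stopifnot(length(bits) == length(space), all(bits %in% c(0L, 1L)))
  space[bits == 1L]
}

# The 20 standard amino-acid one-letter codes, alphabetical.
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Standard amino-acid alphabet
#'
#' @return The 20 one-letter codes, alphabetically ordered.
#' @export
amino_acids <- function() STANDARD_AA
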