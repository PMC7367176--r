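#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Normalize residues to the RNA alphabet
#'
#' Uppercases and converts DNA thymine to uracil. Ambiguity codes (N, R, Y,
#' ...) are kept as-is; they encode as all-zero columns downstream.
#'
#' @param x character vector of sequences.
#' @return character vector over the normalized alphabet.
#' @export
normalize_rna <- function(x) {
  x <- chartr("T", "U", toupper(x))
  bad <- grepl("[^A-Z]", x)
  if (any(bad)) {
    stop("non-letter characters in sequence(s): ",
         paste(which(bad), collapse = ", "))
  }
  x
}

# Coerce sequences to a named character vector, generating ids when absent.
as_named_seqs <- function(seqs, prefix = "seq") {
  if (is.list(seqs)) seqs <- unlist(seqs)
  if (!is.character(seqs)) stop("sequences must be a character vector")
  if (length(seqs) == 0L) stop("empty sequence set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    ids <- names(seqs) %||% rep("", length(seqs))
    blank <- !nzchar(ids)
    ids[blank] <- paste0(prefix, which(blank))
    names(seqs) <- ids
  }
  seqs
}

# RNA reverse complement preserving ambiguity codes where defined.
revcomp_rna <- function(x) {
  comp <- chartr("ACGUNRYSWKM", "UGCANYRSWMK", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
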