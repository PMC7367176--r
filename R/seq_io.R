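# Sequence and interval I/O: FASTA via Biostrings, BED as plain TSV, plus the
# interval container shared by peaks, genes, backgrounds and called sites.

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Records are normalized to the RNA alphabet: uppercase, with T converted to
#' U. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the FASTA ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  w <- Biostrings::width(set)
  if (any(w == 0L)) {
    stop("empty sequence for record(s): ",
         paste(names(set)[w == 0L], collapse = ", "), " in ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_rna(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_seqs(seqs)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a set of genomic intervals
#'
#' Strand-aware 0-based half-open intervals (the BED convention), used for
#' peaks, gene spans, sampled backgrounds and called binding sites.
#'
#' @param chrom character vector of chromosome / sequence names.
#' @param start,end integer vectors; 0-based start (inclusive), end
#'   (exclusive), with `start < end`.
#' @param strand `"+"` or `"-"`, recycled.
#' @param name optional record names.
#' @return data.frame of class `genomic_intervals` with columns `chrom`,
#'   `start`, `end`, `name`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+", name = NULL) {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  name <- if (is.null(name)) paste0("iv", seq_len(n)) else rep_len(name, n)
  bad <- which(!(start >= 0L & start < end))
  if (length(bad)) {
    stop("invalid interval(s) (need 0 <= start < end) at record(s): ",
         paste(bad, collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = name, strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

iv_width <- function(iv) iv$end - iv$start

# TRUE where intervals a[i] and b[j] overlap, for a single pair of rows.
iv_overlap_any <- function(iv, chrom, start, end) {
  any(iv$chrom == chrom & iv$start < end & start < iv$end)
}

#' Read intervals from a BED file (BED3 or BED6)
#'
#' Coordinates are 0-based half-open as in the BED standard. A missing strand
#' column defaults to `"+"`.
#'
#' @param path path to a BED file.
#' @return a [genomic_intervals()] data.frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", fill = TRUE)
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns: ", path)
  name <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    rep(NA_character_, nrow(tab))
  blank <- is.na(name) | !nzchar(name)
  name[blank] <- paste0("iv", which(blank))
  strand <- if (ncol(tab) >= 6L) as.character(tab[[6]]) else
    rep("+", nrow(tab))
  strand[is.na(strand) | !nzchar(strand)] <- "+"   # BED3 lines in a BED6 file
  genomic_intervals(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                    name = name, strand = strand)
}

#' Write intervals to a BED6 file
#'
#' @param iv a [genomic_intervals()] data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(iv, path) {
  out <- data.frame(iv$chrom, iv$start, iv$end, iv$name, 0L, iv$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract interval sequences from a genome
#'
#' Minus-strand intervals return the reverse complement, in the RNA alphabet.
#'
#' @param genome named character vector of chromosome sequences (or an object
#'   coercible with `as.character`, e.g. a `BStringSet`).
#' @param iv a [genomic_intervals()] data.frame.
#' @return named character vector of normalized RNA sequences.
#' @export
extract_sequence <- function(genome, iv) {
  if (!is.character(genome)) genome <- as.character(genome)
  res <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    chrom <- iv$chrom[i]
    if (is.na(match(chrom, names(genome)))) {
      stop("chromosome not in genome: ", chrom)
    }
    len <- nchar(genome[[chrom]])
    if (iv$end[i] > len) {
      stop("interval ", iv$name[i], " (", iv$start[i], ",", iv$end[i],
           ") out of bounds for ", chrom, " (length ", len, ")")
    }
    s <- normalize_rna(substr(genome[[chrom]], iv$start[i] + 1L, iv$end[i]))
    if (iv$strand[i] == "-") s <- revcomp_rna(s)
    res[i] <- s
  }
  names(res) <- iv$name
  res
}

BUNDLE_FORMAT <- "rbpnet_model"
BUNDLE_VERSION <- 1L

#' Save a fitted model to disk
#'
#' The bundle is a self-describing container holding every parameter array
#' (named, with shapes), the architecture/training configuration, the fixed
#' vocabulary and training metadata. `load_rbpnet(save_rbpnet(m))` reproduces
#' all parameters bit-exactly.
#'
#' @param object an object of class `rbpnet`.
#' @param path output path.
#' @return invisibly, `path`.
#' @seealso [load_rbpnet()]
#' @export
save_rbpnet <- function(object, path) {
  stopifnot(inherits(object, "rbpnet"))
  bundle <- list(format = BUNDLE_FORMAT, version = BUNDLE_VERSION,
                 model = object)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a fitted model from disk
#'
#' @param path path produced by [save_rbpnet()].
#' @return the restored `rbpnet` object.
#' @export
load_rbpnet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bundle <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model bundle (truncated or corrupt): ", path)
  })
  if (!is.list(bundle) || !identical(bundle$format, BUNDLE_FORMAT)) {
    stop("not a model bundle: ", path)
  }
  if (!identical(bundle$version, BUNDLE_VERSION)) {
    stop("model bundle version ", bundle$version,
         " not supported by this reader (expected ", BUNDLE_VERSION, ")")
  }
  bundle$model
}
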