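# One-hot encoding with zero padding. Every sequence in a batch is padded to
# max_length on the right of the real region, then given a symmetric margin of
# m_max - 1 zero columns so the largest convolution filter can run in "full"
# mode. The validity mask marks real bases; ambiguity codes keep mask 1 but
# encode as all-zero columns, so the bias-free network ignores them.

RNA_VOCAB <- c("A", "C", "G", "U")

#' One-hot encode a batch of RNA sequences
#'
#' @param seqs named character vector (or list) of normalized RNA sequences.
#' @param filter_sizes integer vector of convolution filter widths; the
#'   padding margin is `max(filter_sizes) - 1` on each flank.
#' @param max_length maximum real sequence length; defaults to the longest
#'   sequence in the batch. Sequences longer than this raise an error.
#' @return list of `encoded_rna` objects, each with elements `onehot`
#'   (padded_length x 4 matrix, columns A,C,G,U), `mask` (0/1 vector, 1 =
#'   real base), `left_pad`, `id`, `seq`, `length`.
#' @export
encode_rna <- function(seqs, filter_sizes = 4:8, max_length = NULL) {
  seqs <- as_named_seqs(seqs)
  if (length(filter_sizes) == 0L) stop("filter_sizes must be non-empty")
  seqs[] <- normalize_rna(seqs)
  lens <- nchar(seqs)
  max_len <- max_length %||% max(lens)
  if (any(lens > max_len)) {
    stop("sequence(s) longer than maximum length ", max_len, ": ",
         paste(names(seqs)[lens > max_len], collapse = ", "))
  }
  pad <- max(filter_sizes) - 1L
  L <- max_len + 2L * pad
  lapply(seq_along(seqs), function(i) {
    n <- lens[i]
    onehot <- matrix(0, nrow = L, ncol = 4L,
                     dimnames = list(NULL, RNA_VOCAB))
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    col <- match(ch, RNA_VOCAB)           # NA for ambiguity codes
    hit <- which(!is.na(col))
    onehot[cbind(pad + hit, col[hit])] <- 1
    mask <- numeric(L)
    mask[pad + seq_len(n)] <- 1
    structure(list(onehot = onehot, mask = mask, left_pad = pad,
                   id = names(seqs)[i], seq = seqs[[i]], length = n),
              class = "encoded_rna")
  })
}

# Batch tensor form used by the vectorized forward/backward passes:
# X is an array (B, L, 4); mask a (B, L) matrix.
encode_tensor <- function(seqs, filter_sizes, max_length = NULL) {
  encs <- encode_rna(seqs, filter_sizes, max_length)
  B <- length(encs)
  L <- nrow(encs[[1]]$onehot)
  X <- array(0, dim = c(B, L, 4L))
  mask <- matrix(0, B, L)
  for (b in seq_len(B)) {
    X[b, , ] <- encs[[b]]$onehot
    mask[b, ] <- encs[[b]]$mask
  }
  list(X = X, mask = mask,
       ids = vapply(encs, `[[`, character(1), "id"),
       lens = vapply(encs, `[[`, integer(1), "length"),
       left_pad = encs[[1]]$left_pad, L = L)
}
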