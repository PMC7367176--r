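# Pseudo position frequency matrices: high-scoring sequences contribute each
# positively convolving k-mer, weighted by the squared (pre-WTA, rectified)
# convolution score, restricted to regions the binding profile associates
# with class 1. Motifs are ranked by mean per-column information content.

#' Per-column information content of a frequency matrix
#'
#' With a uniform background over 4 bases, column IC = 2 + sum(f * log2 f)
#' bits (0 * log 0 = 0), ranging from 0 (uniform) to 2 (point mass).
#'
#' @param frequencies 4 x m matrix whose columns sum to 1.
#' @return list with `per_column` (bits) and `mean` (average over columns).
#' @export
information_content <- function(frequencies) {
  cs <- colSums(frequencies)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("frequency columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  }
  per_col <- apply(frequencies, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  list(per_column = per_col, mean = mean(per_col))
}

#' Extract pseudo-PFMs from a trained model
#'
#' Scores all sequences with the model and selects either the `top_n`
#' highest-scoring (default 1000; ties keep input order) or all sequences
#' scoring above `score_threshold`. For each selected sequence and each
#' convolution filter, every placement with a positive (rectified, pre-WTA)
#' convolution score whose covered bases all have a strictly positive
#' binding-profile value contributes its covered k-mer with weight equal to
#' the squared convolution score. One PFM per filter, ranked by descending
#' mean information content.
#'
#' @param model a fitted `rbpnet` object.
#' @param seqs named character vector of sequences (typically the bound set).
#' @param top_n number of top-scoring sequences to use; ignored when
#'   `score_threshold` is given.
#' @param score_threshold optional classification-score cutoff (e.g. 0.5)
#'   used instead of `top_n`.
#' @return list of class `pseudo_pfm_set`; each element is a `pseudo_pfm`
#'   list with `filter_size`, `counts` (4 x m), `frequencies`, `ic`
#'   (per-column bits), `mean_ic`, `n_contributing`, `empty`.
#' @export
pseudo_pfms <- function(model, seqs, top_n = 1000L, score_threshold = NULL) {
  stopifnot(inherits(model, "rbpnet"))
  seqs <- as_named_seqs(seqs)
  scores <- predict(model, seqs, type = "score")
  if (is.null(score_threshold)) {
    n_take <- min(top_n, length(seqs))
    sel <- order(-scores, seq_along(scores))[seq_len(n_take)]
  } else {
    sel <- which(scores > score_threshold)
  }
  sizes <- model$config$filter_sizes
  nf <- length(sizes)
  counts <- lapply(sizes, function(m) {
    matrix(0, 4L, m, dimnames = list(RNA_VOCAB, NULL))
  })
  n_contrib <- integer(nf)

  for (i in sel) {
    enc <- encode_rna(seqs[i], sizes, model$config$max_length)[[1]]
    conv <- conv_scan(enc, model$params$filters)
    prof <- forward_pass(model, enc)
    pad <- enc$left_pad
    n <- enc$length
    bases <- strsplit(enc$seq, "", fixed = TRUE)[[1]]
    pos_ok <- prof$values > 0                 # class-1-associated bases
    for (k in seq_len(nf)) {
      m <- sizes[k]
      if (n < m) next
      s <- conv[[k]]
      # placements fully inside the real region
      starts <- (pad + 1L):(pad + n - m + 1L)
      for (p in starts) {
        if (s[p] <= 0) next
        covered <- (p - pad):(p - pad + m - 1L)
        if (!all(pos_ok[covered])) next
        w <- s[p]^2
        cols <- match(bases[covered], RNA_VOCAB)
        keep <- !is.na(cols)                  # ambiguity codes add nothing
        counts[[k]][cbind(cols[keep], which(keep))] <-
          counts[[k]][cbind(cols[keep], which(keep))] + w
        n_contrib[k] <- n_contrib[k] + 1L
      }
    }
  }

  pfms <- lapply(seq_len(nf), function(k) {
    cs <- colSums(counts[[k]])
    empty <- all(cs == 0)
    freq <- counts[[k]]
    if (!empty) {
      nz <- cs > 0
      freq[, nz] <- sweep(counts[[k]][, nz, drop = FALSE], 2, cs[nz], "/")
      freq[, !nz] <- 0.25                     # flagged-empty columns
    }
    ic <- if (empty) list(per_column = rep(0, sizes[k]), mean = 0) else
      information_content(freq)
    structure(list(filter_size = sizes[k], counts = counts[[k]],
                   frequencies = freq, ic = ic$per_column,
                   mean_ic = ic$mean, n_contributing = n_contrib[k],
                   empty = empty, empty_columns = which(cs == 0)),
              class = "pseudo_pfm")
  })
  ord <- order(-vapply(pfms, `[[`, numeric(1), "mean_ic"))
  structure(pfms[ord], class = "pseudo_pfm_set")
}

#' @export
print.pseudo_pfm <- function(x, ...) {
  cat("pseudo-PFM (filter size ", x$filter_size, "), mean IC ",
      format(x$mean_ic, digits = 3), " bits, ",
      x$n_contributing, " contributing placements",
      if (x$empty) " [EMPTY]", "\n", sep = "")
  print(round(x$frequencies, 3))
  invisible(x)
}

#' @export
print.pseudo_pfm_set <- function(x, ...) {
  cat("pseudo-PFM set (", length(x), " filters, ranked by mean IC)\n",
      sep = "")
  for (p in x) {
    cat("  size ", p$filter_size, ": mean IC ",
        format(p$mean_ic, digits = 3), " bits",
        if (p$empty) " [EMPTY]", "\n", sep = "")
  }
  invisible(x)
}

#' Export pseudo-PFMs to MEME minimal format and a counts table
#'
#' Writes a MEME minimal motif file (`<path>.meme`, frequencies, ordered by
#' descending mean information content) and a tab-separated counts table
#' (`<path>_counts.tsv`). Empty PFMs are omitted with a message.
#'
#' @param pfms a `pseudo_pfm_set` from [pseudo_pfms()].
#' @param path output path prefix.
#' @return invisibly, the paths written.
#' @export
export_pfms <- function(pfms, path) {
  keep <- !vapply(pfms, `[[`, logical(1), "empty")
  if (any(!keep)) {
    message("omitting empty PFM(s) for filter size(s): ",
            paste(vapply(pfms[!keep], `[[`, integer(1), "filter_size"),
                  collapse = ", "))
  }
  pfms <- pfms[keep]
  if (length(pfms) == 0L) stop("no non-empty PFMs to export")

  meme_path <- paste0(path, ".meme")
  lines <- c("MEME version 4", "", "ALPHABET= ACGU", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 U 0.25", "")
  counts_rows <- list()
  for (p in pfms) {
    nsites <- max(1L, p$n_contributing)
    lines <- c(lines,
               paste0("MOTIF filter_", p$filter_size),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       p$filter_size, nsites),
               apply(t(p$frequencies), 1, function(r) {
                 paste(sprintf("%.6f", r), collapse = " ")
               }),
               "")
    counts_rows[[length(counts_rows) + 1L]] <-
      data.frame(motif = paste0("filter_", p$filter_size),
                 position = seq_len(p$filter_size),
                 t(p$counts))
  }
  writeLines(lines, meme_path)
  counts_path <- paste0(path, "_counts.tsv")
  tab <- do.call(rbind, counts_rows)
  colnames(tab) <- c("motif", "position", RNA_VOCAB)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(meme = meme_path, counts = counts_path))
}

#' Point-mass PFM for a consensus sequence
#'
#' Convenience constructor: each column places probability 1 on the
#' corresponding base of `consensus`.
#'
#' @param consensus RNA string over A/C/G/U (T accepted, converted to U).
#' @return 4 x nchar(consensus) probability matrix (rows A, C, G, U).
#' @export
motif_pfm <- function(consensus) {
  ch <- strsplit(normalize_rna(consensus), "", fixed = TRUE)[[1]]
  idx <- match(ch, RNA_VOCAB)
  if (anyNA(idx)) stop("consensus must use only A, C, G, U/T")
  m <- matrix(0, 4L, length(ch), dimnames = list(RNA_VOCAB, NULL))
  m[cbind(idx, seq_along(ch))] <- 1
  m
}

#' Best-offset Pearson correlation between two PFMs
#'
#' Slides one matrix over the other (minimum overlap `min_overlap` columns),
#' flattens the overlapping columns, and returns the maximum Pearson
#' correlation over all offsets.
#'
#' @param a,b 4 x m probability matrices.
#' @param min_overlap minimum overlapping columns considered.
#' @return list with `correlation` and `offset` (columns of `b` shifted
#'   relative to `a`).
#' @export
pfm_best_correlation <- function(a, b, min_overlap = 4L) {
  wa <- ncol(a); wb <- ncol(b)
  best <- -Inf; best_off <- NA_integer_
  for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
    ia <- max(1L, 1L + off):min(wa, wb + off)
    ib <- ia - off
    if (length(ia) < min_overlap) next
    va <- as.vector(a[, ia]); vb <- as.vector(b[, ib])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    r <- stats::cor(va, vb)
    if (r > best) { best <- r; best_off <- off }
  }
  list(correlation = best, offset = best_off)
}
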