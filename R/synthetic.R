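# Synthetic CLIP-like fixtures: positives with a planted (possibly
# degenerate) motif at a recorded offset, composition-matched negatives, and
# a toy genome with gene and peak annotations for the background sampler.

#' Simulate a planted-motif CLIP-like dataset
#'
#' Positives are random sequences with one motif instance sampled column-wise
#' from `pfm` overwritten at a uniformly random offset (with probability
#' `occurrence_rate`); negatives are composition-matched random sequences.
#' The truth table records the exact planted offset of every positive.
#'
#' @param pfm 4 x m probability matrix (rows A, C, G, U; columns sum to 1),
#'   e.g. from [motif_pfm()].
#' @param n_pos,n_neg class sizes (default 1000 each).
#' @param seq_length sequence length in nt (default 40).
#' @param occurrence_rate probability a positive carries the motif
#'   (default 1).
#' @param background base probabilities for A, C, G, U (default uniform).
#' @param seed integer seed; the dataset is fully deterministic given it.
#' @return list with `pos`, `neg` (named character vectors) and `truth`
#'   (data.frame `id`, `offset` 0-based, NA when no motif was planted).
#' @export
simulate_clip <- function(pfm, n_pos = 1000L, n_neg = 1000L,
                          seq_length = 40L, occurrence_rate = 1,
                          background = c(0.25, 0.25, 0.25, 0.25), seed = 1L) {
  m <- ncol(pfm)
  if (m > seq_length) stop("motif width ", m, " exceeds seq_length ", seq_length)
  if (any(abs(colSums(pfm) - 1) > 1e-9)) stop("pfm columns must sum to 1")
  stopifnot(occurrence_rate > 0, occurrence_rate <= 1)
  set.seed(seed)
  rand_seq <- function(n) {
    paste(sample(RNA_VOCAB, n, replace = TRUE, prob = background),
          collapse = "")
  }
  pos <- character(n_pos)
  offset <- rep(NA_integer_, n_pos)
  for (i in seq_len(n_pos)) {
    s <- strsplit(rand_seq(seq_length), "", fixed = TRUE)[[1]]
    if (stats::runif(1) <= occurrence_rate) {
      off <- sample.int(seq_length - m + 1L, 1L) - 1L
      inst <- vapply(seq_len(m), function(j) {
        sample(RNA_VOCAB, 1L, prob = pfm[, j])
      }, character(1))
      s[off + seq_len(m)] <- inst
      offset[i] <- off
    }
    pos[i] <- paste(s, collapse = "")
  }
  neg <- vapply(seq_len(n_neg), function(i) rand_seq(seq_length), character(1))
  names(pos) <- sprintf("pos_%d", seq_len(n_pos))
  names(neg) <- sprintf("neg_%d", seq_len(n_neg))
  list(pos = pos, neg = neg,
       truth = data.frame(id = names(pos), offset = offset,
                          stringsAsFactors = FALSE))
}

#' Simulate a toy genome with genes and CLIP peaks
#'
#' Chromosomes each carry one gene (`gene<i>` spanning the chromosome); peaks
#' of fixed width are placed uniformly within each gene without overlap.
#'
#' @param n_genes number of genes (one per chromosome).
#' @param gene_length gene span in nt.
#' @param peaks_per_gene peaks placed in each gene.
#' @param peak_width peak width in nt.
#' @param seed integer seed.
#' @return list with `genome` (named character vector of chromosome DNA),
#'   `genes` and `peaks` (both [genomic_intervals()]).
#' @export
simulate_toy_genome <- function(n_genes = 3L, gene_length = 200L,
                                peaks_per_gene = 2L, peak_width = 10L,
                                seed = 1L) {
  if (peaks_per_gene * (2L * peak_width) > gene_length) {
    stop("cannot pack ", peaks_per_gene, " non-overlapping peaks of width ",
         peak_width, " into genes of length ", gene_length)
  }
  set.seed(seed)
  genome <- vapply(seq_len(n_genes), function(i) {
    paste(sample(c("A", "C", "G", "T"), gene_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(genome) <- paste0("chr", seq_len(n_genes))
  genes <- genomic_intervals(names(genome), 0L, gene_length,
                             strand = rep(c("+", "-"), length.out = n_genes),
                             name = paste0("gene", seq_len(n_genes)))
  rows <- list()
  for (g in seq_len(n_genes)) {
    placed <- integer(0)
    for (p in seq_len(peaks_per_gene)) {
      for (try in seq_len(1000L)) {
        s <- sample.int(gene_length - peak_width + 1L, 1L) - 1L
        if (!any(s < placed + peak_width & placed < s + peak_width)) break
      }
      placed <- c(placed, s)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = names(genome)[g], start = s, end = s + peak_width,
                   strand = genes$strand[g],
                   name = sprintf("peak_%d_%d", g, p))
    }
  }
  pk <- do.call(rbind, rows)
  peaks <- genomic_intervals(pk$chrom, pk$start, pk$end, pk$strand, pk$name)
  list(genome = genome, genes = genes, peaks = peaks)
}
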