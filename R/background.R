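# Class-0 (unbound) sequence construction: peak width adjustment, same-gene
# random genomic placement, and composition-preserving scrambling.

#' Expand peaks and/or fix them to a constant width
#'
#' Expansion adds `expand_by` to both flanks; `fixed_width` then re-centers
#' each peak on its original midpoint (left-biased when the required shift is
#' odd). Input order is preserved.
#'
#' @param peaks a [genomic_intervals()] data.frame.
#' @param expand_by non-negative flank extension in nt.
#' @param fixed_width optional target width in nt.
#' @return adjusted [genomic_intervals()].
#' @export
adjust_peaks <- function(peaks, expand_by = 0L, fixed_width = NULL) {
  stopifnot(expand_by >= 0L)
  start <- peaks$start - as.integer(expand_by)
  end <- peaks$end + as.integer(expand_by)
  if (!is.null(fixed_width)) {
    mid <- (start + end) %/% 2L           # left-biased midpoint at odd widths
    half <- as.integer(fixed_width) %/% 2L
    start <- mid - half
    end <- start + as.integer(fixed_width)
  }
  clipped <- start < 0L
  if (any(clipped)) {
    warning("start clipped at 0 for peak(s): ",
            paste(peaks$name[clipped], collapse = ", "))
    start[clipped] <- 0L
  }
  genomic_intervals(peaks$chrom, start, end, peaks$strand, peaks$name)
}

# Host gene for each peak: the gene with the largest overlap; ties go to the
# first gene in annotation order. NA when no gene overlaps.
assign_host_gene <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ov <- pmin(genes$end, peaks$end[i]) - pmax(genes$start, peaks$start[i])
    ov[genes$chrom != peaks$chrom[i]] <- 0L
    if (all(ov <= 0L)) NA_integer_ else which.max(ov)
  }, integer(1))
}

#' Sample same-gene genomic background regions
#'
#' For each peak, draws a random interval of identical width uniformly within
#' the peak's host gene such that no background overlaps any positive peak or
#' any previously placed background. Placement uses rejection sampling
#' (`max_tries` draws per peak) and processes peaks in input order; a peak
#' with no legal placement is reported and skipped with a warning. Placement
#' ignores strand, but the background inherits the peak's strand so its
#' sequence is extracted on the same strand.
#'
#' @param peaks positive binding sites, a [genomic_intervals()] data.frame.
#' @param genes gene spans, a [genomic_intervals()] data.frame.
#' @param seed integer seed (required for reproducibility).
#' @param max_tries rejection-sampling attempts per peak.
#' @return list with `background` ([genomic_intervals()]), `pairs`
#'   (data.frame of peak name, background name, host gene), and `skipped`
#'   (peak names with no placement).
#' @export
sample_background <- function(peaks, genes, seed, max_tries = 1000L) {
  stopifnot(nrow(peaks) >= 1L, nrow(genes) >= 1L)
  set.seed(seed)
  host <- assign_host_gene(peaks, genes)
  placed <- peaks[0, ]
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(peaks))) {
    w <- peaks$end[i] - peaks$start[i]
    gi <- host[i]
    if (is.na(gi) || (genes$end[gi] - genes$start[gi]) < w) {
      warning("no host gene can hold peak ", peaks$name[i], "; skipped")
      skipped <- c(skipped, peaks$name[i])
      next
    }
    lo <- genes$start[gi]; hi <- genes$end[gi] - w
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      e <- s + w
      if (iv_overlap_any(peaks, peaks$chrom[i], s, e)) next
      if (nrow(placed) && iv_overlap_any(placed, peaks$chrom[i], s, e)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      warning("no legal background placement for peak ", peaks$name[i],
              " after ", max_tries, " tries; skipped")
      skipped <- c(skipped, peaks$name[i])
      next
    }
    bg <- genomic_intervals(peaks$chrom[i], s, e, peaks$strand[i],
                            paste0("bg_", peaks$name[i]))
    placed <- rbind(placed, bg)
    rows[[length(rows) + 1L]] <- data.frame(peak = peaks$name[i],
                                            background = bg$name,
                                            gene = genes$name[gi],
                                            stringsAsFactors = FALSE)
  }
  class(placed) <- c("genomic_intervals", "data.frame")
  list(background = placed,
       pairs = if (length(rows)) do.call(rbind, rows) else
         data.frame(peak = character(0), background = character(0),
                    gene = character(0)),
       skipped = skipped)
}

#' Scramble sequences preserving mononucleotide composition
#'
#' Each sequence is replaced by an independent random permutation of its own
#' residues, so base counts are exactly preserved. A dinucleotide-preserving
#' shuffle (random Eulerian-walk reconstruction of the dinucleotide graph) is
#' available behind `preserve = "dinucleotide"`, off by default.
#'
#' @param seqs named character vector of sequences.
#' @param seed integer seed.
#' @param preserve `"mononucleotide"` (default) or `"dinucleotide"`.
#' @return named character vector of scrambled sequences (names suffixed
#'   `_scr`).
#' @export
scramble_sequences <- function(seqs, seed,
                               preserve = c("mononucleotide", "dinucleotide")) {
  preserve <- match.arg(preserve)
  seqs <- as_named_seqs(seqs)
  set.seed(seed)
  out <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (preserve == "mononucleotide" || length(ch) < 3L) {
      paste(sample(ch), collapse = "")
    } else {
      dinuc_shuffle(ch)
    }
  }, character(1))
  names(out) <- paste0(names(seqs), "_scr")
  out
}

# Altschul-Erickson style shuffle: permute, per predecessor base, the list of
# followers, keeping the last follower of the terminal base fixed so a valid
# walk exists; falls back to resampling until the walk covers the sequence.
dinuc_shuffle <- function(ch, max_tries = 100L) {
  n <- length(ch)
  for (try in seq_len(max_tries)) {
    followers <- split(ch[-1], ch[-n])
    followers <- lapply(followers, sample)
    counts <- lapply(followers, function(x) 0L)
    out <- character(n)
    out[1] <- ch[1]
    ok <- TRUE
    for (i in 2:n) {
      prev <- out[i - 1]
      k <- counts[[prev]] + 1L
      if (is.null(followers[[prev]]) || k > length(followers[[prev]])) {
        ok <- FALSE
        break
      }
      out[i] <- followers[[prev]][k]
      counts[[prev]] <- k
    }
    if (ok) return(paste(out, collapse = ""))
  }
  paste(sample(ch), collapse = "")        # degenerate graphs: plain shuffle
}
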