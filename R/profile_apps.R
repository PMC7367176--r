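# Applied prediction modes: wild-type/mutant comparison, sliding-window
# profiling of long sequences, profile-based binding-site calling, and
# anchored region-profile aggregation across inputs.

#' Score a wild-type / mutant sequence pair
#'
#' Both sequences are scored independently; `delta = mut_score - wt_score`.
#' When the sequences have equal length a per-base profile difference
#' (mutant minus wild type) is also returned; positive values indicate a
#' higher profile in the variant. A warning is issued when any differing
#' position lies within `max(filter_sizes)` nt of a sequence end, where edge
#' effects make the comparison unreliable.
#'
#' @param model a fitted `rbpnet` object.
#' @param wt,mut single sequences (character, optionally named).
#' @return list of class `variant_result`: `wt_score`, `mut_score`, `delta`,
#'   `wt_profile`, `mut_profile`, `profile_delta` (NULL for length-mismatched
#'   pairs).
#' @export
score_variant <- function(model, wt, mut) {
  wt <- as_named_seqs(wt, "wt")[1]
  mut <- as_named_seqs(mut, "mut")[1]
  if (!nzchar(wt) || !nzchar(mut)) stop("empty sequence")
  pw <- predict(model, wt, type = "profile")[[1]]
  pm <- predict(model, mut, type = "profile")[[1]]
  profile_delta <- NULL
  if (nchar(wt) == nchar(mut)) {
    diff_pos <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
    m_max <- max(model$config$filter_sizes)
    n <- nchar(wt)
    if (length(diff_pos) &&
        any(diff_pos <= m_max | diff_pos > n - m_max)) {
      warning("substitution(s) within ", m_max, " nt of a sequence end; ",
              "edge positions should not be analyzed")
    }
    profile_delta <- pm$values - pw$values
  }
  structure(list(wt_score = pw$score, mut_score = pm$score,
                 delta = pm$score - pw$score,
                 wt_profile = pw$values, mut_profile = pm$values,
                 profile_delta = profile_delta,
                 wt_id = names(wt), mut_id = names(mut)),
            class = "variant_result")
}

#' @export
print.variant_result <- function(x, ...) {
  cat("Variant scoring: ", x$wt_id, " -> ", x$mut_id, "\n", sep = "")
  cat(sprintf("  wt score %.5f | mutant score %.5f | delta %+.5f\n",
              x$wt_score, x$mut_score, x$delta))
  if (is.null(x$profile_delta)) {
    cat("  (lengths differ; no per-base profile difference)\n")
  } else {
    cat(sprintf("  max |profile delta| %.4f at position %d\n",
                max(abs(x$profile_delta)), which.max(abs(x$profile_delta))))
  }
  invisible(x)
}

#' Sliding-window binding profile of a long sequence
#'
#' Profiles every `window`-nt segment (step 1) and takes the central
#' nucleotide's profile value to build a profile covering the whole
#' sequence. The first and last `floor(window/2)` positions copy their
#' values from the first and last full window. Sequences shorter than the
#' window get a single direct forward pass.
#'
#' @param model a fitted `rbpnet` object.
#' @param seq one sequence of any length.
#' @param window odd window length, at most the model maximum; defaults to
#'   the model's maximum length (lowered by 1 if even).
#' @return a `binding_profile` whose `values` cover the full sequence;
#'   `score` is NA (scores are only defined for window-sized inputs).
#' @export
predict_long <- function(model, seq, window = NULL) {
  seq <- as_named_seqs(seq)[1]
  n <- nchar(seq)
  window <- window %||% model$config$max_length
  if (window > model$config$max_length) {
    stop("window must be at most the model maximum length")
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window - 1L
  if (n < window) {
    return(predict(model, seq, type = "profile")[[1]])
  }
  half <- window %/% 2L
  starts <- seq_len(n - window + 1L)
  subs <- substring(seq, starts, starts + window - 1L)
  names(subs) <- paste0(names(seq), "_w", starts)
  profs <- predict(model, subs, type = "profile")
  values <- numeric(n)
  # central value of the window centered at each interior position
  for (i in seq_along(starts)) {
    values[starts[i] + half] <- profs[[i]]$values[half + 1L]
  }
  values[seq_len(half)] <- profs[[1]]$values[seq_len(half)]
  values[(n - half + 1L):n] <-
    profs[[length(profs)]]$values[(window - half + 1L):window]
  structure(list(id = names(seq), seq = seq, values = values,
                 score = NA_real_, window = window),
            class = "binding_profile")
}

#' Call binding sites from a profile
#'
#' Slides a `window`-nt window across the profile and keeps windows with
#' mean value strictly greater than `threshold`; overlapping qualifying
#' windows are merged into maximal intervals, and each merged site's mean is
#' recomputed over the whole site. Coordinates are 0-based half-open on the
#' query.
#'
#' @param profile numeric vector (or a `binding_profile`).
#' @param window window length in nt (default 9).
#' @param threshold strict lower bound on the window mean (default 0.3).
#' @return data.frame with columns `start`, `end`, `width`, `mean_profile`.
#' @export
call_sites <- function(profile, window = 9L, threshold = 0.3) {
  if (inherits(profile, "binding_profile")) profile <- profile$values
  window <- as.integer(window)
  n <- length(profile)
  empty <- data.frame(start = integer(0), end = integer(0),
                      width = integer(0), mean_profile = numeric(0))
  if (n < window) {
    warning("profile shorter than window (", n, " < ", window, ")")
    return(empty)
  }
  cs <- c(0, cumsum(profile))
  starts0 <- 0:(n - window)                      # 0-based window starts (int)
  means <- (cs[starts0 + window + 1L] - cs[starts0 + 1L]) / window
  qual <- starts0[means > threshold]
  if (length(qual) == 0L) return(empty)
  # union of qualifying windows [q, q + window): overlapping or abutting
  # windows cover one contiguous region and form a single site
  s <- qual[1]; e <- qual[1] + window
  out <- list()
  for (q in qual[-1]) {
    if (q <= e) {
      e <- q + window
    } else {
      out[[length(out) + 1L]] <- c(s, e)
      s <- q; e <- q + window
    }
  }
  out[[length(out) + 1L]] <- c(s, e)
  res <- do.call(rbind, out)
  data.frame(start = res[, 1], end = res[, 2], width = res[, 2] - res[, 1],
             mean_profile = vapply(seq_len(nrow(res)), function(i) {
               mean(profile[(res[i, 1] + 1L):res[i, 2]])
             }, numeric(1)))
}

#' Aggregate anchored region profiles across sequences
#'
#' Extracts, from each full-length profile, the sub-profiles anchored at an
#' exon's boundaries — by default the last `intron_flank` nt of the upstream
#' intron, the first and last `exon_edge` nt of the exon, and the first
#' `intron_flank` nt of the downstream intron — and returns the per-offset
#' mean with a normal-approximation 95% confidence band
#' (mean +/- 1.96 * sd / sqrt(n)) across inputs. Profiles too short for a
#' requested region are skipped with a warning.
#'
#' @param profiles list of numeric vectors (or `binding_profile`s).
#' @param exon_start,exon_end per-profile 0-based half-open exon coordinates
#'   within each profile (recycled if length 1).
#' @param exon_edge nt taken from each exon end (default 25).
#' @param intron_flank nt taken from each neighboring intron (default 50).
#' @return data.frame with columns `region`, `offset` (0-based within
#'   region), `mean`, `lower`, `upper`, `n`.
#' @export
aggregate_profiles <- function(profiles, exon_start, exon_end,
                               exon_edge = 25L, intron_flank = 50L) {
  profiles <- lapply(profiles, function(p) {
    if (inherits(p, "binding_profile")) p$values else p
  })
  np <- length(profiles)
  exon_start <- rep_len(as.integer(exon_start), np)
  exon_end <- rep_len(as.integer(exon_end), np)
  regions <- list(
    intron_up = function(s, e) (s - intron_flank):(s - 1L),
    exon_start = function(s, e) s:(s + exon_edge - 1L),
    exon_end = function(s, e) (e - exon_edge):(e - 1L),
    intron_down = function(s, e) e:(e + intron_flank - 1L)
  )
  out <- list()
  for (rn in names(regions)) {
    mat <- list()
    for (i in seq_len(np)) {
      idx <- regions[[rn]](exon_start[i], exon_end[i]) + 1L   # to 1-based
      if (min(idx) < 1L || max(idx) > length(profiles[[i]])) {
        warning("profile ", i, " too short for region ", rn, "; skipped")
        next
      }
      mat[[length(mat) + 1L]] <- profiles[[i]][idx]
    }
    if (length(mat) == 0L) next
    M <- do.call(rbind, mat)
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    sdv[is.na(sdv)] <- 0
    half <- 1.96 * sdv / sqrt(nrow(M))
    out[[length(out) + 1L]] <- data.frame(
      region = rn, offset = seq_len(ncol(M)) - 1L, mean = mu,
      lower = mu - half, upper = mu + half, n = nrow(M))
  }
  do.call(rbind, out)
}
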