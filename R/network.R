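# The forward computation, one sequence at a time: convolution bank ->
# winner-takes-all enhancement -> track reconstruction -> bidirectional LSTM
# -> per-base profile and sigmoid score. These single-sequence functions are
# the reference path; training uses the batched equivalents in train.R.
#
# LSTM gate parameters are stored packed: Wx (input_dim x 4H), Wh (H x 4H)
# and b (4H), with column blocks in gate order (input, forget, modulatory,
# output). `lstm_gates()` unpacks them.

#' Initialize model parameters
#'
#' Convolution filters start at the constant 0.01 with no bias terms; all
#' LSTM weights and biases are drawn from a Gaussian with mean 0 and standard
#' deviation 0.01; the single output node has fixed weight 1.0 and no bias,
#' and is never updated during training.
#'
#' @param filter_sizes integer widths of the convolution filters (one filter
#'   per size).
#' @param hidden_size LSTM hidden units per direction.
#' @return list with elements `filters` (list of size x 4 weight matrices),
#'   `fwd`, `bwd` (packed LSTM gate parameters) and `output_weight` (1.0).
#' @export
init_params <- function(filter_sizes = 4:8, hidden_size = 20) {
  nf <- length(filter_sizes)
  D <- 4L * (nf + 1L)
  H <- as.integer(hidden_size)
  filters <- lapply(filter_sizes, function(m) {
    matrix(0.01, nrow = m, ncol = 4L, dimnames = list(NULL, RNA_VOCAB))
  })
  names(filters) <- paste0("filter_", filter_sizes)
  dir_params <- function() {
    list(Wx = matrix(stats::rnorm(D * 4L * H, 0, 0.01), D, 4L * H),
         Wh = matrix(stats::rnorm(H * 4L * H, 0, 0.01), H, 4L * H),
         b = stats::rnorm(4L * H, 0, 0.01))
  }
  list(filters = filters, filter_sizes = as.integer(filter_sizes),
       hidden_size = H, fwd = dir_params(), bwd = dir_params(),
       output_weight = 1.0)
}

#' Unpack packed LSTM parameters into per-gate matrices
#'
#' @param p packed parameter list with `Wx`, `Wh`, `b`.
#' @return list with `Wxi`, `Wxf`, `Wxg`, `Wxo`, `Whi`, ..., `bi`, ..., `bo`.
#' @export
lstm_gates <- function(p) {
  H <- length(p$b) %/% 4L
  blk <- function(k) (k - 1L) * H + seq_len(H)
  list(Wxi = p$Wx[, blk(1), drop = FALSE], Wxf = p$Wx[, blk(2), drop = FALSE],
       Wxg = p$Wx[, blk(3), drop = FALSE], Wxo = p$Wx[, blk(4), drop = FALSE],
       Whi = p$Wh[, blk(1), drop = FALSE], Whf = p$Wh[, blk(2), drop = FALSE],
       Whg = p$Wh[, blk(3), drop = FALSE], Who = p$Wh[, blk(4), drop = FALSE],
       bi = p$b[blk(1)], bf = p$b[blk(2)], bg = p$b[blk(3)], bo = p$b[blk(4)])
}

#' Scan an encoded sequence with the convolution filter bank
#'
#' Filters slide one whole base at a time (stride = |vocabulary| on the
#' linearized input) and apply the rectifier; there are no bias terms, so
#' placements over all-zero (padding) columns score exactly 0.
#'
#' @param enc an `encoded_rna` object.
#' @param filters list of size x 4 filter weight matrices.
#' @return list of numeric vectors of length `padded_length`; entry p is the
#'   rectified score of the placement starting at position p (0 beyond the
#'   last valid placement).
#' @export
conv_scan <- function(enc, filters) {
  L <- nrow(enc$onehot)
  lapply(filters, function(W) {
    m <- nrow(W)
    if (m > L) stop("filter of size ", m, " wider than padded sequence (", L, ")")
    Y <- enc$onehot %*% t(W)           # L x m ; Y[p, j] = base p scored by row j
    nv <- L - m + 1L
    acc <- numeric(nv)
    for (j in seq_len(m)) acc <- acc + Y[j:(nv + j - 1L), j]
    s <- numeric(L)
    s[seq_len(nv)] <- pmax(acc, 0)
    s
  })
}

#' Winner-takes-all enhancement of a score vector
#'
#' The single highest value is multiplied by 2, then every entry is squared.
#' Ties break to the first (lowest-index) maximum.
#'
#' @param scores non-negative numeric vector of rectified convolution scores.
#' @return enhanced vector of the same length.
#' @export
wta_enhance <- function(scores) {
  if (any(scores < 0)) stop("scores must be non-negative")
  i <- which.max(scores)
  scores[i] <- 2 * scores[i]
  scores * scores
}

#' Rebuild scaled one-hot tracks from enhanced scores
#'
#' Recreates the one-hot sequence with each base's 1 replaced by the enhanced
#' convolution value assigned to it. Under the default `"start"` rule the
#' value at base j is the score of the placement whose first position is j
#' (every real base has one, thanks to the full-convolution margins); the
#' `"max_cover"` alternative takes the maximum over all placements covering j.
#'
#' @param enhanced list of enhanced vectors, one per filter (from
#'   [wta_enhance()]).
#' @param enc the `encoded_rna` the scores came from.
#' @param assign assignment rule, `"start"` (default) or `"max_cover"`.
#' @param filter_sizes filter widths; required for `"max_cover"`.
#' @return list of padded_length x 4 matrices, one per filter.
#' @export
build_tracks <- function(enhanced, enc, assign = c("start", "max_cover"),
                         filter_sizes = NULL) {
  assign <- match.arg(assign)
  L <- nrow(enc$onehot)
  if (assign == "start") {
    lapply(enhanced, function(e) enc$onehot * e)
  } else {
    if (is.null(filter_sizes)) stop("filter_sizes required for max_cover")
    lapply(seq_along(enhanced), function(k) {
      e <- enhanced[[k]]
      m <- filter_sizes[k]
      val <- vapply(seq_len(L), function(t) {
        p <- max(1L, t - m + 1L):min(t, L - m + 1L)
        max(e[p])
      }, numeric(1))
      enc$onehot * val
    })
  }
}

#' Assemble per-base BLSTM inputs from tracks and the raw one-hot sequence
#'
#' @param tracks list of per-filter tracks from [build_tracks()].
#' @param enc the `encoded_rna` object.
#' @return padded_length x (4 * (n_filters + 1)) matrix; row t is the
#'   timestep input x_t (filter tracks first, raw one-hot last).
#' @export
assemble_timesteps <- function(tracks, enc) {
  do.call(cbind, c(unname(tracks), list(enc$onehot)))
}

#' One LSTM step
#'
#' Gate equations: i = sigma(Wxi x + Whi h + bi), f likewise, g with tanh,
#' c = f * c_prev + i * g, o = sigma(Wxo x + Who h + bo), h = o * tanh(c).
#'
#' @param x input vector for this timestep.
#' @param state list with `h` and `c` from the previous step.
#' @param params packed gate parameters (`Wx`, `Wh`, `b`).
#' @return list with the new `h` and `c`.
#' @export
lstm_step <- function(x, state, params) {
  H <- length(params$b) %/% 4L
  a <- drop(x %*% params$Wx) + drop(state$h %*% params$Wh) + params$b
  i <- sigmoid(a[seq_len(H)])
  f <- sigmoid(a[H + seq_len(H)])
  g <- tanh(a[2L * H + seq_len(H)])
  o <- sigmoid(a[3L * H + seq_len(H)])
  c_new <- f * state$c + i * g
  list(h = o * tanh(c_new), c = c_new)
}

#' Bidirectional LSTM over a timestep sequence
#'
#' The forward LSTM reads x_1..x_T, the backward LSTM reads x_T..x_1 and its
#' outputs are re-reversed, so row t of the result is the concatenation
#' of the forward and backward hidden vectors at position t. Initial states
#' are zero. At mask-0 (padding) positions the recurrent state is carried
#' through unchanged, so extra zero padding never alters the hidden states at
#' real bases.
#'
#' @param xs T x D matrix of timestep inputs.
#' @param fwd,bwd packed gate parameters for the two directions.
#' @param mask optional 0/1 vector of length T (default all 1).
#' @return T x (2 * hidden_size) matrix H.
#' @export
blstm_forward <- function(xs, fwd, bwd, mask = NULL) {
  Tn <- nrow(xs)
  H <- length(fwd$b) %/% 4L
  mask <- mask %||% rep(1, Tn)
  run <- function(p, order) {
    st <- list(h = numeric(H), c = numeric(H))
    out <- matrix(0, Tn, H)
    for (t in order) {
      if (mask[t] == 1) st <- lstm_step(xs[t, ], st, p)
      out[t, ] <- st$h
    }
    out
  }
  cbind(run(fwd, seq_len(Tn)), run(bwd, rev(seq_len(Tn))))
}

#' Binding profile and classification score from the BLSTM output
#'
#' Per-position values are row sums of H with padding rows forced to zero;
#' the profile keeps only real-base positions, and the score is the sigmoid
#' of the fixed unit-weight, bias-free output node applied to the sum of the
#' values.
#'
#' @param H matrix from [blstm_forward()], rows aligned to padded positions.
#' @param enc the `encoded_rna` object.
#' @param output_weight fixed output-node weight (1.0).
#' @return list with `values` (length = real sequence length) and `score`.
#' @export
profile_and_score <- function(H, enc, output_weight = 1.0) {
  u <- rowSums(H)
  u[enc$mask == 0] <- 0
  list(values = u[enc$mask == 1], score = sigmoid(output_weight * sum(u)))
}

#' Full forward pass for one sequence
#'
#' @param model an `rbpnet` object or a raw parameter list from
#'   [init_params()].
#' @param seq a single sequence (character) or `encoded_rna` object.
#' @param max_length padding target; defaults to the model's configured
#'   maximum (or the sequence length for raw parameter lists).
#' @return a `binding_profile` object: list with `id`, `seq`, `values`
#'   (per-base profile) and `score`.
#' @export
forward_pass <- function(model, seq, max_length = NULL) {
  params <- if (inherits(model, "rbpnet")) model$params else model
  if (inherits(model, "rbpnet")) max_length <- max_length %||% model$config$max_length
  if (inherits(seq, "encoded_rna")) {
    enc <- seq
  } else {
    enc <- encode_rna(seq, params$filter_sizes, max_length)[[1]]
  }
  s <- conv_scan(enc, params$filters)
  e <- lapply(s, wta_enhance)
  tracks <- build_tracks(e, enc)
  xs <- assemble_timesteps(tracks, enc)
  H <- blstm_forward(xs, params$fwd, params$bwd, enc$mask)
  ps <- profile_and_score(H, enc, params$output_weight)
  structure(list(id = enc$id, seq = enc$seq, values = ps$values,
                 score = ps$score),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("Binding profile for '", x$id, "' (", nchar(x$seq), " nt)\n", sep = "")
  cat("  score:", format(x$score, digits = 5), "\n")
  cat("  profile sum:", format(sum(x$values), digits = 5), "\n")
  invisible(x)
}

#' Plot a per-nucleotide binding profile
#'
#' @param x a `binding_profile`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.binding_profile <- function(x, ...) {
  bases <- strsplit(x$seq, "", fixed = TRUE)[[1]]
  graphics::barplot(x$values, names.arg = bases, border = NA,
                    col = ifelse(x$values >= 0, "steelblue", "firebrick"),
                    ylab = "profile value", xlab = "sequence", ...)
  invisible(x)
}
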