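# Independent straight-line oracle of the full forward computation, written
# directly from the defining equations (explicit placement dot products, the
# literal WTA rule, per-gate LSTM algebra, masked state carry, row-sum
# profile). Used to validate the package's vectorized implementation.

oracle_forward <- function(seq, params, max_length) {
  vocab <- c("A", "C", "G", "U")
  fs <- params$filter_sizes
  pad <- max(fs) - 1L
  L <- max_length + 2L * pad
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  X <- matrix(0, L, 4)
  for (t in seq_len(n)) {
    j <- match(ch[t], vocab)
    if (!is.na(j)) X[pad + t, j] <- 1
  }
  mask <- c(rep(0, pad), rep(1, n), rep(0, L - pad - n))

  E <- vector("list", length(fs))
  for (k in seq_along(fs)) {
    W <- params$filters[[k]]
    m <- fs[k]
    s <- numeric(L)
    for (p in 1:(L - m + 1)) {
      acc <- 0
      for (j in 1:m) {
        for (b in 1:4) acc <- acc + W[j, b] * X[p + j - 1, b]
      }
      s[p] <- max(0, acc)
    }
    im <- which(s == max(s))[1]          # first-occurrence tie-break
    s[im] <- 2 * s[im]
    E[[k]] <- s^2
  }

  D <- 4L * (length(fs) + 1L)
  xt <- matrix(0, L, D)
  for (t in 1:L) {
    v <- numeric(0)
    for (k in seq_along(fs)) v <- c(v, X[t, ] * E[[k]][t])
    xt[t, ] <- c(v, X[t, ])
  }

  H <- length(params$fwd$b) %/% 4L
  sig <- function(z) 1 / (1 + exp(-z))
  run_dir <- function(p, ord) {
    Wxi <- p$Wx[, 1:H, drop = FALSE]; Wxf <- p$Wx[, H + 1:H, drop = FALSE]
    Wxg <- p$Wx[, 2 * H + 1:H, drop = FALSE]; Wxo <- p$Wx[, 3 * H + 1:H, drop = FALSE]
    Whi <- p$Wh[, 1:H, drop = FALSE]; Whf <- p$Wh[, H + 1:H, drop = FALSE]
    Whg <- p$Wh[, 2 * H + 1:H, drop = FALSE]; Who <- p$Wh[, 3 * H + 1:H, drop = FALSE]
    bi <- p$b[1:H]; bf <- p$b[H + 1:H]; bg <- p$b[2 * H + 1:H]; bo <- p$b[3 * H + 1:H]
    h <- rep(0, H); cc <- rep(0, H)
    out <- matrix(0, L, H)
    for (t in ord) {
      if (mask[t] == 1) {
        x <- xt[t, ]
        i <- sig(as.vector(x %*% Wxi) + as.vector(h %*% Whi) + bi)
        f <- sig(as.vector(x %*% Wxf) + as.vector(h %*% Whf) + bf)
        g <- tanh(as.vector(x %*% Wxg) + as.vector(h %*% Whg) + bg)
        o <- sig(as.vector(x %*% Wxo) + as.vector(h %*% Who) + bo)
        cc <- f * cc + i * g
        h <- o * tanh(cc)
      }
      out[t, ] <- h
    }
    out
  }
  Hf <- run_dir(params$fwd, 1:L)
  Hb <- run_dir(params$bwd, L:1)
  u <- numeric(L)
  for (t in 1:L) u[t] <- sum(Hf[t, ]) + sum(Hb[t, ])
  u[mask == 0] <- 0
  list(values = u[mask == 1], score = sig(sum(u)))
}

# Random parameter draw around an init_params() skeleton.
rand_params <- function(filter_sizes = 4:8, hidden_size = 5, sd = 0.3) {
  p <- init_params(filter_sizes, hidden_size)
  p$filters <- lapply(p$filters, function(W) {
    matrix(stats::rnorm(length(W), 0, sd), nrow(W), 4,
           dimnames = dimnames(W))
  })
  for (dir in c("fwd", "bwd")) {
    for (nm in c("Wx", "Wh")) {
      W <- p[[dir]][[nm]]
      p[[dir]][[nm]] <- matrix(stats::rnorm(length(W), 0, sd),
                               nrow(W), ncol(W))
    }
    p[[dir]]$b <- stats::rnorm(length(p[[dir]]$b), 0, sd)
  }
  p
}

rand_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Brute-force site caller: enumerate qualifying windows, take their union.
brute_call_sites <- function(profile, window = 9L, threshold = 0.3) {
  n <- length(profile)
  if (n < window) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  covered <- rep(FALSE, n)
  any_window <- FALSE
  for (s0 in 0:(n - window)) {
    if (mean(profile[(s0 + 1):(s0 + window)]) > threshold) {
      covered[(s0 + 1):(s0 + window)] <- TRUE
      any_window <- TRUE
    }
  }
  if (!any_window) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# Tiny trained model shared by tests that need non-trivial binding behaviour
# (built once per test run; ~10 s).
tiny_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_clip(motif_pfm("UGCAUGU"), n_pos = 150, n_neg = 150,
                           seq_length = 25, seed = 401)
      # a small fixture needs few updates per epoch, so a larger step size
      cache <<- rbpnet(sim$pos, sim$neg,
                       config = rbpnet_config(hidden_size = 10,
                                              max_epochs = 15, patience = 15,
                                              learning_rate = 1e-3,
                                              seed = 402))
    }
    cache
  }
})
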