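# Batched network evaluation and training. The batched forward pass is
# algebraically identical to the single-sequence reference path in network.R
# (a test asserts the equivalence); gradients are derived by straight
# backpropagation through the WTA/track algebra and through time for both
# LSTM directions, with state pass-through at masked (padding) steps.

# ---- batched forward ------------------------------------------------------

# X: (B, L, 4) array; mask: (B, L). Returns scores, per-position values u,
# and (optionally) every intermediate needed for the backward pass.
nn_forward <- function(X, mask, params, drop_mask = NULL, keep_cache = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]
  nf <- length(params$filters)
  H <- params$hidden_size
  D <- 4L * (nf + 1L)

  Xm <- matrix(X, B * L, 4L)
  Z <- array(0, c(B, L, D))
  conv <- vector("list", nf)
  for (k in seq_len(nf)) {
    W <- params$filters[[k]]
    m <- nrow(W)
    nv <- L - m + 1L
    Y <- array(Xm %*% t(W), c(B, L, m))
    S <- matrix(0, B, L)
    for (j in seq_len(m)) {
      S[, seq_len(nv)] <- S[, seq_len(nv)] + Y[, j:(nv + j - 1L), j]
    }
    S[S < 0] <- 0
    mp <- max.col(S, ties.method = "first")
    idx <- cbind(seq_len(B), mp)
    E <- S * S
    E[idx] <- 4 * S[idx]^2
    Z[, , (4L * k - 3L):(4L * k)] <- X * array(E, c(B, L, 4L))
    conv[[k]] <- list(S = S, idx = idx, m = m, nv = nv)
  }
  Z[, , (4L * nf + 1L):D] <- X

  fwd <- run_lstm_batch(Z, params$fwd, seq_len(L), mask, keep_cache)
  bwd <- run_lstm_batch(Z, params$bwd, rev(seq_len(L)), mask, keep_cache)

  Hcomb <- array(0, c(B, L, 2L * H))
  Hcomb[, , seq_len(H)] <- fwd$Hout
  Hcomb[, , H + seq_len(H)] <- bwd$Hout
  Hd <- if (is.null(drop_mask)) Hcomb else Hcomb * drop_mask

  u <- matrix(rowSums(matrix(Hd, B * L, 2L * H)), B, L)
  u <- u * mask
  z <- rowSums(u)
  score <- sigmoid(params$output_weight * z)

  out <- list(score = score, u = u)
  if (keep_cache) {
    out$cache <- list(X = X, mask = mask, Z = Z, conv = conv, fwd = fwd,
                      bwd = bwd, drop_mask = drop_mask, B = B, L = L,
                      nf = nf, H = H, D = D)
  }
  out
}

# One LSTM direction over the whole batch. `pos` is the read order (1:L or
# L:1). Masked steps carry h and c through unchanged.
run_lstm_batch <- function(Z, p, pos, mask, keep_cache) {
  B <- dim(Z)[1]; L <- dim(Z)[2]; D <- dim(Z)[3]
  H <- length(p$b) %/% 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hout <- array(0, c(B, L, H))
  if (keep_cache) {
    Gi <- Gf <- Gg <- Go <- Tc <- Hprev <- Cprev <- array(0, c(B, L, H))
  }
  bmat <- matrix(p$b, B, 4L * H, byrow = TRUE)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in pos) {
    x <- matrix(Z[, t, ], B, D)
    a <- x %*% p$Wx + h %*% p$Wh + bmat
    gi <- sigmoid(a[, i1, drop = FALSE])
    gf <- sigmoid(a[, i2, drop = FALSE])
    gg <- tanh(a[, i3, drop = FALSE])
    go <- sigmoid(a[, i4, drop = FALSE])
    c_cand <- gf * cc + gi * gg
    tc <- tanh(c_cand)
    h_cand <- go * tc
    m <- mask[, t]
    if (keep_cache) {
      Gi[, t, ] <- gi; Gf[, t, ] <- gf; Gg[, t, ] <- gg; Go[, t, ] <- go
      Tc[, t, ] <- tc; Hprev[, t, ] <- h; Cprev[, t, ] <- cc
    }
    cc <- c_cand * m + cc * (1 - m)
    h <- h_cand * m + h * (1 - m)
    Hout[, t, ] <- h
  }
  out <- list(Hout = Hout, pos = pos)
  if (keep_cache) {
    out <- c(out, list(Gi = Gi, Gf = Gf, Gg = Gg, Go = Go, Tc = Tc,
                       Hprev = Hprev, Cprev = Cprev))
  }
  out
}

# ---- batched backward -----------------------------------------------------

# Backpropagation-through-time for one direction. dH: (B, L, H) gradient on
# this direction's hidden outputs. Returns weight gradients and the gradient
# on the timestep inputs Z.
bptt_lstm <- function(dir, p, Z, mask, dH) {
  B <- dim(Z)[1]; L <- dim(Z)[2]; D <- dim(Z)[3]
  H <- length(p$b) %/% 4L
  dWx <- matrix(0, D, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dZ <- array(0, c(B, L, D))
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  tWx <- t(p$Wx); tWh <- t(p$Wh)
  for (t in rev(dir$pos)) {
    m <- mask[, t]
    gi <- matrix(dir$Gi[, t, ], B, H); gf <- matrix(dir$Gf[, t, ], B, H)
    gg <- matrix(dir$Gg[, t, ], B, H); go <- matrix(dir$Go[, t, ], B, H)
    tc <- matrix(dir$Tc[, t, ], B, H)
    hprev <- matrix(dir$Hprev[, t, ], B, H)
    cprev <- matrix(dir$Cprev[, t, ], B, H)
    dh_eff <- dh_carry + matrix(dH[, t, ], B, H)
    dh_cand <- dh_eff * m
    dgo <- dh_cand * tc
    dc_cand <- dc_carry * m + dh_cand * go * (1 - tc * tc)
    dgi <- dc_cand * gg
    dgf <- dc_cand * cprev
    dgg <- dc_cand * gi
    dc_carry <- dc_cand * gf + dc_carry * (1 - m)
    da <- cbind(dgi * gi * (1 - gi), dgf * gf * (1 - gf),
                dgg * (1 - gg * gg), dgo * go * (1 - go))
    x <- matrix(Z[, t, ], B, D)
    dWx <- dWx + crossprod(x, da)
    dWh <- dWh + crossprod(hprev, da)
    db <- db + colSums(da)
    dZ[, t, ] <- da %*% tWx
    dh_carry <- da %*% tWh + dh_eff * (1 - m)
  }
  list(Wx = dWx, Wh = dWh, b = db, dZ = dZ)
}

# Full backward pass for mean binary cross-entropy. y: 0/1 labels. Returns
# gradients shaped like params; the fixed output node is excluded.
nn_backward <- function(fw, y, params) {
  cc <- fw$cache
  B <- cc$B; L <- cc$L; nf <- cc$nf; H <- cc$H
  X <- cc$X; mask <- cc$mask

  dz <- params$output_weight * (fw$score - y) / B
  du <- mask * dz                             # dz (length B) recycles by column
  dHd <- array(du, c(B, L, 2L * H))
  if (!is.null(cc$drop_mask)) dHd <- dHd * cc$drop_mask

  gfwd <- bptt_lstm(cc$fwd, params$fwd, cc$Z, mask,
                    dHd[, , seq_len(H), drop = FALSE])
  gbwd <- bptt_lstm(cc$bwd, params$bwd, cc$Z, mask,
                    dHd[, , H + seq_len(H), drop = FALSE])
  dZ <- gfwd$dZ + gbwd$dZ

  dfilters <- vector("list", nf)
  for (k in seq_len(nf)) {
    info <- cc$conv[[k]]
    S <- info$S; idx <- info$idx; m <- info$m; nv <- info$nv
    blk <- (4L * k - 3L):(4L * k)
    tmp <- X * dZ[, , blk, drop = FALSE]
    dE <- matrix(rowSums(matrix(tmp, B * L, 4L)), B, L)
    dS <- 2 * S * dE
    dS[idx] <- 8 * S[idx] * dE[idx]           # doubled winner: E = 4 S^2
    dW <- matrix(0, m, 4L)
    dPv <- dS[, seq_len(nv), drop = FALSE]
    for (j in seq_len(m)) {
      Xj <- X[, j:(nv + j - 1L), , drop = FALSE]
      dW[j, ] <- colSums(matrix(Xj * array(dPv, c(B, nv, 4L)), B * nv, 4L))
    }
    dfilters[[k]] <- dW
  }
  names(dfilters) <- names(params$filters)
  list(filters = dfilters,
       fwd = gfwd[c("Wx", "Wh", "b")],
       bwd = gbwd[c("Wx", "Wh", "b")])
}

# ---- optimizer ------------------------------------------------------------

# Flat views of the trainable parameters (the fixed output node is absent).
param_leaves <- function(params) {
  c(lapply(params$filters, identity),
    list(fwd.Wx = params$fwd$Wx, fwd.Wh = params$fwd$Wh, fwd.b = params$fwd$b,
         bwd.Wx = params$bwd$Wx, bwd.Wh = params$bwd$Wh, bwd.b = params$bwd$b))
}

grad_leaves <- function(grads) {
  c(lapply(grads$filters, identity),
    list(fwd.Wx = grads$fwd$Wx, fwd.Wh = grads$fwd$Wh, fwd.b = grads$fwd$b,
         bwd.Wx = grads$bwd$Wx, bwd.Wh = grads$bwd$Wh, bwd.b = grads$bwd$b))
}

set_leaves <- function(params, leaves) {
  nf <- length(params$filters)
  for (k in seq_len(nf)) params$filters[[k]] <- leaves[[k]]
  params$fwd$Wx <- leaves[[nf + 1L]]; params$fwd$Wh <- leaves[[nf + 2L]]
  params$fwd$b <- leaves[[nf + 3L]]
  params$bwd$Wx <- leaves[[nf + 4L]]; params$bwd$Wh <- leaves[[nf + 5L]]
  params$bwd$b <- leaves[[nf + 6L]]
  params
}

adam_init <- function(params) {
  leaves <- param_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  leaves <- param_leaves(params)
  gl <- grad_leaves(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(leaves)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * gl[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * gl[[i]]^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    leaves[[i]] <- leaves[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = set_leaves(params, leaves), state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- configuration --------------------------------------------------------

#' Training and architecture configuration
#'
#' Defaults follow the reference settings: ADAM with learning rate 0.0002,
#' beta1 0.9, beta2 0.999, epsilon 1e-8; binary cross-entropy loss; 10%
#' dropout on the BLSTM output; batch size 64; convolution filters of sizes
#' 4-8 initialized to 0.01; LSTM parameters drawn from a Gaussian with mean 0
#' and standard deviation 0.01; model selection by validation AUROC with
#' early stopping after `patience` epochs without improvement (by default 10%
#' of `max_epochs`, rounded up).
#'
#' @param filter_sizes integer filter widths, one filter per size.
#' @param hidden_size LSTM hidden units per direction.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without selection-metric improvement before early
#'   stopping.
#' @param selection `"auroc"` (validation AUROC, default) or `"loss"`
#'   (validation binary cross-entropy).
#' @param batch_size minibatch size.
#' @param learning_rate,beta1,beta2,eps ADAM hyperparameters.
#' @param dropout dropout rate on the BLSTM output matrix.
#' @param max_length maximum real sequence length (set from data when NULL).
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return a list of class `rbpnet_config`.
#' @export
rbpnet_config <- function(filter_sizes = 4:8, hidden_size = 20,
                          max_epochs = 30, patience = ceiling(0.1 * max_epochs),
                          selection = c("auroc", "loss"), batch_size = 64,
                          learning_rate = 2e-4, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, dropout = 0.1, max_length = NULL,
                          seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(patience <= max_epochs || max_epochs == 0)
  structure(list(filter_sizes = as.integer(filter_sizes),
                 hidden_size = as.integer(hidden_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), selection = selection,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, dropout = dropout, max_length = max_length,
                 seed = as.integer(seed), vocabulary = RNA_VOCAB),
            class = "rbpnet_config")
}

# ---- training loop --------------------------------------------------------

#' Train a model on explicit training and validation sets
#'
#' Minimizes mean binary cross-entropy by ADAM. After every epoch the
#' selection metric (validation AUROC by default, or validation loss) is
#' computed and the best parameters so far are retained; training stops at
#' `max_epochs` or after `patience` epochs without improvement. Ties keep the
#' earlier checkpoint. The output node weight is fixed at 1.0 throughout.
#'
#' @param train,validation lists with elements `sequences` (named character
#'   vector) and `labels` (0/1 vector). Validation must contain both classes.
#' @param config an [rbpnet_config()].
#' @return list with `params` (best checkpoint), `history` (data.frame with
#'   epoch, train_loss, val_metric, best), `best_epoch`, `epochs_run`.
#' @export
train_model <- function(train, validation, config = rbpnet_config()) {
  stopifnot(length(train$sequences) == length(train$labels),
            length(validation$sequences) == length(validation$labels))
  if (length(unique(validation$labels)) < 2L && config$selection == "auroc") {
    stop("validation set must contain both classes (AUROC undefined)")
  }
  if (length(train$sequences) == 0L) stop("empty training set")
  if (abs(mean(train$labels) - 0.5) > 0.1) {
    warning("training classes are imbalanced (fraction positive = ",
            round(mean(train$labels), 3), "); no reweighting is applied")
  }
  max_len <- config$max_length %||%
    max(nchar(train$sequences), nchar(validation$sequences))
  config$max_length <- max_len

  set.seed(config$seed)
  params <- init_params(config$filter_sizes, config$hidden_size)

  tr <- encode_tensor(train$sequences, config$filter_sizes, max_len)
  va <- encode_tensor(validation$sequences, config$filter_sizes, max_len)
  y_tr <- as.numeric(train$labels)
  y_va <- as.numeric(validation$labels)
  ntr <- length(y_tr)
  H2 <- 2L * config$hidden_size

  metric_of <- function(p) {
    sc <- nn_forward(va$X, va$mask, p)$score
    if (config$selection == "auroc") auroc(sc, y_va) else bce_loss(sc, y_va)
  }
  better <- if (config$selection == "auroc") {
    function(a, b) a > b
  } else {
    function(a, b) a < b
  }

  best_params <- params
  best_metric <- metric_of(params)
  best_epoch <- 0L
  history <- data.frame(epoch = 0L, train_loss = NA_real_,
                        val_metric = best_metric, best = TRUE)
  opt <- adam_init(params)
  since_best <- 0L
  epochs_run <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    losses <- numeric(0)
    for (start in seq(1L, ntr, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, ntr)]
      Xb <- tr$X[take, , , drop = FALSE]
      mb <- tr$mask[take, , drop = FALSE]
      yb <- y_tr[take]
      B <- length(take)
      dm <- NULL
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        dm <- array(stats::rbinom(B * tr$L * H2, 1L, keep) / keep,
                    c(B, tr$L, H2))
      }
      fw <- nn_forward(Xb, mb, params, drop_mask = dm, keep_cache = TRUE)
      losses <- c(losses, bce_loss(fw$score, yb))
      grads <- nn_backward(fw, yb, params)
      upd <- adam_step(params, grads, opt, config$learning_rate,
                       config$beta1, config$beta2, config$eps)
      params <- upd$params
      opt <- upd$state
    }
    metric <- metric_of(params)
    improved <- better(metric, best_metric)
    if (improved) {
      best_metric <- metric
      best_params <- params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = mean(losses),
                                val_metric = metric, best = improved))
    epochs_run <- epoch
    if (since_best >= config$patience) break
  }
  list(params = best_params, history = history, best_epoch = best_epoch,
       best_metric = best_metric, epochs_run = epochs_run, config = config)
}

# ---- splitting and cross-validation ---------------------------------------

#' Stratified 80/10/10 split
#'
#' Splits positives and negatives independently into training, validation and
#' test partitions (validation and test each get `floor(n/10)` items per
#' class; the remainder trains). Deterministic given the seed.
#'
#' @param pos,neg vectors (or lists) of class-1 and class-0 items.
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test`, each a list with `pos`
#'   and `neg` components.
#' @export
split_train_val_test <- function(pos, neg, seed = 1L) {
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes required")
  if (length(pos) < 10L || length(neg) < 10L) {
    warning("a class has fewer than 10 members; validation/test allocations ",
            "fall to floor(n/10) and may be empty")
  }
  set.seed(seed)
  one <- function(x) {
    n <- length(x)
    k <- floor(n / 10)
    ord <- sample.int(n)
    list(validation = x[ord[seq_len(k)]],
         test = x[ord[k + seq_len(k)]],
         train = x[ord[if (2 * k < n) (2 * k + 1):n else integer(0)]])
  }
  p <- one(pos); n <- one(neg)
  list(train = list(pos = p$train, neg = n$train),
       validation = list(pos = p$validation, neg = n$validation),
       test = list(pos = p$test, neg = n$test))
}

#' Build a 10-fold cross-validation plan
#'
#' Indices are shuffled once and divided into 10 (near-)equal bins. In fold
#' k, bin k is the test set, bin k+1 (mod 10) the validation set, and the
#' remaining 8 bins train — so every bin is test exactly once, validation
#' exactly once, and trains 8 times.
#'
#' @param n_items number of items (must be at least 10).
#' @param seed integer seed for the shuffle.
#' @return list of class `fold_plan`: `bins` (list of 10 index vectors) and
#'   `folds` (list of 10 lists with `test`, `validation`, `train` indices).
#' @export
make_cv_folds <- function(n_items, seed = 1L) {
  if (n_items < 10L) stop("need at least 10 items for 10-fold CV")
  set.seed(seed)
  ord <- sample.int(n_items)
  bins <- split(ord, rep_len(1:10, n_items))
  folds <- lapply(1:10, function(k) {
    v <- if (k == 10L) 1L else k + 1L
    list(test = bins[[k]], validation = bins[[v]],
         train = sort(unlist(bins[-c(k, v)], use.names = FALSE)))
  })
  structure(list(bins = bins, folds = folds, n_items = n_items),
            class = "fold_plan")
}

#' Rank-based AUROC
#'
#' Mann-Whitney form: the probability that a random positive outranks a
#' random negative, with ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 class labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("AUROC undefined for a single class")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' 10-fold cross-validated training
#'
#' Trains one model per fold (stratified fold plans per class, identical
#' role rotation) and pools the held-out test predictions of all folds into a
#' single AUROC, so every input is predicted exactly once.
#'
#' @param pos,neg named character vectors of bound (class-1) and unbound
#'   (class-0) sequences.
#' @param config an [rbpnet_config()].
#' @return list with `auroc` (pooled), `scores`, `labels`, `ids`, `folds`
#'   (per-fold results of [train_model()], without caches).
#' @export
cv_rbpnet <- function(pos, neg, config = rbpnet_config()) {
  pos <- as_named_seqs(pos, "pos"); neg <- as_named_seqs(neg, "neg")
  plan_p <- make_cv_folds(length(pos), seed = config$seed)
  plan_n <- make_cv_folds(length(neg), seed = config$seed + 1L)
  config$max_length <- config$max_length %||% max(nchar(c(pos, neg)))
  scores <- numeric(0); labels <- numeric(0); ids <- character(0)
  folds <- vector("list", 10L)
  for (k in 1:10) {
    fp <- plan_p$folds[[k]]; fn <- plan_n$folds[[k]]
    train <- list(sequences = c(pos[fp$train], neg[fn$train]),
                  labels = c(rep(1, length(fp$train)), rep(0, length(fn$train))))
    val <- list(sequences = c(pos[fp$validation], neg[fn$validation]),
                labels = c(rep(1, length(fp$validation)),
                           rep(0, length(fn$validation))))
    fit <- train_model(train, val, config)
    test_seqs <- c(pos[fp$test], neg[fn$test])
    te <- encode_tensor(test_seqs, config$filter_sizes, config$max_length)
    sc <- nn_forward(te$X, te$mask, fit$params)$score
    scores <- c(scores, sc)
    labels <- c(labels, rep(1, length(fp$test)), rep(0, length(fn$test)))
    ids <- c(ids, names(test_seqs))
    folds[[k]] <- fit
  }
  list(auroc = auroc(scores, labels), scores = scores, labels = labels,
       ids = ids, folds = folds)
}

#' Top/bottom class assignment from per-sequence intensities
#'
#' Sorts by measured intensity and takes the `n` highest-scoring items as the
#' positive class and the `n` lowest as the negative class (the construction
#' used for in vitro binding-affinity compendia). Ties resolve by input
#' order.
#'
#' @param intensities named numeric vector.
#' @param n class size (default 1000).
#' @return list with `pos` and `neg` name vectors.
#' @export
rnacompete_classes <- function(intensities, n = 1000L) {
  N <- length(intensities)
  if (N < 2L * n) stop("need at least 2n = ", 2L * n, " items, got ", N)
  ord <- order(-intensities, seq_len(N))   # one ordering: disjoint ends
  pos <- names(intensities)[ord[seq_len(n)]]
  neg <- names(intensities)[ord[N + 1L - seq_len(n)]]
  stopifnot(length(intersect(ord[seq_len(n)], ord[N + 1L - seq_len(n)])) == 0L)
  list(pos = pos, neg = neg)
}
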