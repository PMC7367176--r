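test_that("conv_scan computes rectified whole-base placements without bias", {
  enc <- encode_rna("AAC", filter_sizes = 2)[[1]]
  # filter scoring +1 for (pos1=A, pos2=C), -1 elsewhere
  W <- matrix(-1, 2, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  W[1, "A"] <- 1; W[2, "C"] <- 1
  s <- conv_scan(enc, list(W))[[1]]
  # placements: [pad][A], [A][A], [A][C], [C][pad]
  expect_equal(s[1], 0)        # margin+A: -1 + 1? margin column contributes 0 -> 1*0 + A(-? ) rectified
  expect_equal(s[2], 0)        # "AA": 1 - 1 = 0
  expect_equal(s[3], 2)        # "AC": 1 + 1
  expect_equal(s[4], 0)        # trailing: rectified
  # zero-weight filter scores zero everywhere
  s0 <- conv_scan(enc, list(matrix(0, 2, 4)))[[1]]
  expect_true(all(s0 == 0))
  # placements fully inside the zero margin score 0 (no bias)
  enc2 <- encode_rna("ACGU", filter_sizes = 4)[[1]]
  Wr <- matrix(rnorm(8), 2, 4)
  sr <- conv_scan(enc2, list(Wr))[[1]]
  expect_equal(sr[1:2], c(0, 0))
  expect_error(conv_scan(enc, list(matrix(0, 50, 4))), "wider")
})

test_that("WTA doubles the single (first) maximum then squares", {
  expect_equal(wta_enhance(c(1, 3, 2)), c(1, 36, 4))
  expect_equal(wta_enhance(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(wta_enhance(c(2, 2, 0)), c(16, 4, 0))   # first-occurrence tie
  expect_error(wta_enhance(c(-1, 2)), "non-negative")
})

test_that("WTA preserves the argmax", {
  set.seed(21)
  for (i in 1:50) {
    s <- abs(rnorm(12))
    e <- wta_enhance(s)
    expect_equal(which.max(e), which.max(s))
  }
})

test_that("tracks place the start-placement value on each base", {
  enc <- encode_rna("ACG", filter_sizes = 2)[[1]]
  e <- c(0, 5, 0, 3, 0)                       # enhanced values by start position
  tr <- build_tracks(list(e), enc)[[1]]
  expect_equal(dim(tr), dim(enc$onehot))
  expect_equal(unname(tr[2, "A"]), 5)                 # base at padded position 2
  expect_equal(unname(tr[3, "C"]), 0)
  expect_equal(unname(tr[4, "G"]), 3)
  expect_true(all(tr[enc$mask == 0, ] == 0))  # padding columns stay zero
  expect_equal(build_tracks(list(rep(0, 5)), enc)[[1]],
               matrix(0, 5, 4), ignore_attr = TRUE)
})

test_that("track assignment matches an exhaustive per-position oracle", {
  set.seed(22)
  enc <- encode_rna("ACG", filter_sizes = 2)[[1]]
  e <- abs(rnorm(nrow(enc$onehot)))
  e[nrow(enc$onehot)] <- 0                    # no placement starts at last pos
  tr <- build_tracks(list(e), enc)[[1]]
  for (t in seq_len(nrow(enc$onehot))) {
    for (b in 1:4) {
      expected <- if (enc$onehot[t, b] == 1) e[t] else 0
      expect_equal(unname(tr[t, b]), expected)
    }
  }
})

test_that("timestep assembly concatenates tracks then the raw one-hot", {
  enc <- encode_rna("ACGUA", filter_sizes = 4:8)[[1]]
  p <- init_params(4:8, 3)
  s <- conv_scan(enc, p$filters)
  xs <- assemble_timesteps(build_tracks(lapply(s, wta_enhance), enc), enc)
  expect_equal(ncol(xs), 24L)                 # 4 * (5 + 1)
  expect_true(all(xs[enc$mask == 0, ] == 0))
  # zero conv weights reduce x_t to [0...0, onehot_t]
  pz <- p; pz$filters <- lapply(pz$filters, function(W) W * 0)
  sz <- conv_scan(enc, pz$filters)
  xz <- assemble_timesteps(build_tracks(lapply(sz, wta_enhance), enc), enc)
  expect_true(all(xz[, 1:20] == 0))
  expect_equal(unname(xz[, 21:24]), unname(enc$onehot))
})

test_that("lstm_step reproduces closed forms at zero parameters", {
  H <- 3
  p <- list(Wx = matrix(0, 2, 4 * H), Wh = matrix(0, H, 4 * H),
            b = rep(0, 4 * H))
  st <- lstm_step(c(1, 1), list(h = rep(0, H), c = rep(0, H)), p)
  expect_equal(st$c, rep(0, H))               # i=f=o=0.5, g=0
  expect_equal(st$h, rep(0, H))
  # strong forget bias preserves the cell
  p2 <- p; p2$b[H + 1:H] <- 10
  st2 <- lstm_step(c(0, 0), list(h = rep(0, H), c = rep(1, H)), p2)
  f <- 1 / (1 + exp(-10))
  expect_equal(st2$c, rep(f, H), tolerance = 1e-12)
  expect_equal(st2$h, rep(0.5 * tanh(f), H), tolerance = 1e-12)
})

test_that("lstm_step agrees with a per-equation scalar oracle on random draws", {
  set.seed(23)
  H <- 4; D <- 6
  sig <- function(z) 1 / (1 + exp(-z))
  for (rep in 1:20) {
    p <- list(Wx = matrix(rnorm(D * 4 * H), D, 4 * H),
              Wh = matrix(rnorm(H * 4 * H), H, 4 * H),
              b = rnorm(4 * H))
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    st <- lstm_step(x, list(h = h0, c = c0), p)
    g <- lstm_gates(p)
    i <- sig(as.vector(x %*% g$Wxi) + as.vector(h0 %*% g$Whi) + g$bi)
    f <- sig(as.vector(x %*% g$Wxf) + as.vector(h0 %*% g$Whf) + g$bf)
    gg <- tanh(as.vector(x %*% g$Wxg) + as.vector(h0 %*% g$Whg) + g$bg)
    o <- sig(as.vector(x %*% g$Wxo) + as.vector(h0 %*% g$Who) + g$bo)
    cexp <- f * c0 + i * gg
    expect_lt(max(abs(st$c - cexp)), 1e-10)
    expect_lt(max(abs(st$h - o * tanh(cexp))), 1e-10)
  }
})

test_that("blstm_forward aligns the re-reversed backward half", {
  set.seed(24)
  H <- 3; D <- 4; Tn <- 6
  mk <- function() list(Wx = matrix(rnorm(D * 4 * H, 0, 0.5), D, 4 * H),
                        Wh = matrix(rnorm(H * 4 * H, 0, 0.5), H, 4 * H),
                        b = rnorm(4 * H, 0, 0.5))
  fwd <- mk(); bwd <- mk()
  xs <- matrix(rnorm(Tn * D), Tn, D)
  Hm <- blstm_forward(xs, fwd, bwd)
  expect_equal(dim(Hm), c(Tn, 2 * H))
  # zero params give an all-zero H
  z <- list(Wx = matrix(0, D, 4 * H), Wh = matrix(0, H, 4 * H), b = rep(0, 4 * H))
  expect_true(all(blstm_forward(xs, z, z) == 0))
  # reversal symmetry: swapping directions and reversing inputs reverses rows
  # and swaps the halves
  Hr <- blstm_forward(xs[Tn:1, , drop = FALSE], bwd, fwd)
  expect_equal(Hr[Tn:1, c(H + 1:H, 1:H)], Hm, tolerance = 1e-12)
  # T = 1 works with zero initial state
  H1 <- blstm_forward(xs[1, , drop = FALSE], fwd, bwd)
  s1f <- lstm_step(xs[1, ], list(h = rep(0, H), c = rep(0, H)), fwd)
  s1b <- lstm_step(xs[1, ], list(h = rep(0, H), c = rep(0, H)), bwd)
  expect_equal(unname(H1[1, ]), c(s1f$h, s1b$h))
})

test_that("profile_and_score sums rows, zeroes padding, applies the sigmoid", {
  enc <- encode_rna("ACG", filter_sizes = 2)[[1]]
  Hm <- matrix(0, 5, 4)
  expect_equal(profile_and_score(Hm, enc)$score, 0.5)
  Hm[2, ] <- c(1, 0, 0, 0); Hm[3, ] <- c(-1, 0, 0, 0); Hm[4, ] <- c(0.5, 0, 0, 0)
  Hm[1, ] <- 99; Hm[5, ] <- -99                 # padding rows must be ignored
  ps <- profile_and_score(Hm, enc)
  expect_equal(ps$values, c(1, -1, 0.5))
  expect_equal(ps$score, 1 / (1 + exp(-0.5)), tolerance = 1e-9)
})

test_that("forward_pass is deterministic and internally consistent", {
  set.seed(25)
  p <- rand_params(4:8, 5)
  seqs <- rand_rna(10, 14)
  for (s in seqs) {
    a <- forward_pass(p, s, max_length = 14)
    b <- forward_pass(p, s, max_length = 14)
    expect_identical(a$values, b$values)
    expect_length(a$values, nchar(s))
    expect_true(a$score > 0 && a$score < 1)
    expect_lt(abs(a$score - 1 / (1 + exp(-sum(a$values)))), 1e-6)
  }
})

test_that("batched forward equals the single-sequence reference path", {
  set.seed(26)
  p <- rand_params(4:8, 6)
  seqs <- rand_rna(8, 12)
  names(seqs) <- paste0("s", 1:8)
  te <- rbpnet:::encode_tensor(seqs, 4:8, 15)
  fb <- rbpnet:::nn_forward(te$X, te$mask, p)
  for (i in seq_along(seqs)) {
    ref <- forward_pass(p, seqs[i], max_length = 15)
    expect_lt(abs(fb$score[i] - ref$score), 1e-12)
    expect_lt(max(abs(fb$u[i, te$mask[i, ] == 1] - ref$values)), 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(27)
  fs <- c(2, 3); H <- 3
  p <- rand_params(fs, H)
  seqs <- c(x = "ACGUA", y = "GGCAU")
  te <- rbpnet:::encode_tensor(seqs, fs, 5)
  y <- c(1, 0)
  fw <- rbpnet:::nn_forward(te$X, te$mask, p, keep_cache = TRUE)
  gr <- rbpnet:::nn_backward(fw, y, p)
  lossfn <- function(pp) {
    s <- rbpnet:::nn_forward(te$X, te$mask, pp)$score
    -mean(y * log(s) + (1 - y) * log(1 - s))
  }
  eps <- 1e-6
  worst <- 0
  for (k in 1:2) {
    for (idx in sample(length(p$filters[[k]]), 4)) {
      pp <- p; pp$filters[[k]][idx] <- pp$filters[[k]][idx] + eps; l1 <- lossfn(pp)
      pp$filters[[k]][idx] <- pp$filters[[k]][idx] - 2 * eps; l2 <- lossfn(pp)
      worst <- max(worst, abs((l1 - l2) / (2 * eps) - gr$filters[[k]][idx]))
    }
  }
  for (dir in c("fwd", "bwd")) {
    for (nm in c("Wx", "Wh", "b")) {
      for (idx in sample(length(p[[dir]][[nm]]), 4)) {
        pp <- p; pp[[dir]][[nm]][idx] <- pp[[dir]][[nm]][idx] + eps; l1 <- lossfn(pp)
        pp[[dir]][[nm]][idx] <- pp[[dir]][[nm]][idx] - 2 * eps; l2 <- lossfn(pp)
        worst <- max(worst, abs((l1 - l2) / (2 * eps) - gr[[dir]][[nm]][idx]))
      }
    }
  }
  expect_lt(worst, 1e-6)
})
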