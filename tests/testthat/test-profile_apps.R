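test_that("variant scoring: identity pair gives zero delta, others match definition", {
  fit <- tiny_trained_model()
  sim <- simulate_clip(motif_pfm("UGCAUGU"), n_pos = 2, n_neg = 2,
                       seq_length = 25, seed = 71)
  v <- score_variant(fit, sim$pos[1], sim$pos[1])
  expect_equal(v$delta, 0)
  expect_equal(v$profile_delta, rep(0, 25))
  w <- suppressWarnings(score_variant(fit, sim$pos[1], sim$neg[1]))
  expect_equal(w$delta,
               unname(predict(fit, sim$neg[1]) - predict(fit, sim$pos[1])))
  expect_length(w$profile_delta, 25)
})

test_that("variant antisymmetry and edge warnings", {
  fit <- tiny_trained_model()
  wt <- c(w = "AAAAAAAAAUGCAUGUAAAAAAAAA")
  mut <- c(m = "AAAAAAAAAUGAAUGUAAAAAAAAA")    # central substitution: no warning
  a <- score_variant(fit, wt, mut)
  b <- score_variant(fit, mut, wt)
  expect_equal(a$delta, -b$delta, tolerance = 1e-12)
  expect_equal(a$profile_delta, -b$profile_delta, tolerance = 1e-12)
  edge_mut <- c(m = "CAAAAAAAAUGCAUGUAAAAAAAAA")  # position 1 differs
  expect_warning(score_variant(fit, wt, edge_mut), "edge")
  expect_error(score_variant(fit, "", "A"), "empty|non-letter|empty sequence")
})

test_that("variants destroying the planted motif core lower the score", {
  fit <- tiny_trained_model()
  sim <- simulate_clip(motif_pfm("UGCAUGU"), n_pos = 10, n_neg = 1,
                       seq_length = 25, seed = 401)
  deltas <- vapply(seq_len(10), function(i) {
    off <- sim$truth$offset[i]
    s <- strsplit(sim$pos[[i]], "")[[1]]
    s[off + 3:4] <- c("G", "G")                # UGCAUGU core CA -> GG
    suppressWarnings(
      score_variant(fit, sim$pos[i], paste(s, collapse = ""))$delta)
  }, numeric(1))
  expect_lt(mean(deltas), 0)
  expect_gte(sum(deltas < 0), 8L)
})

test_that("long prediction reduces to forward() at window length and stitches centers", {
  fit <- tiny_trained_model()
  win <- 25L
  s <- c(q = paste(rep("ACGUA", 5), collapse = ""))
  lp <- predict_long(fit, s, window = win)
  direct <- predict(fit, s, type = "profile")[[1]]
  expect_equal(lp$values, direct$values, tolerance = 1e-12)

  long_seq <- c(q = paste(rand_rna(1, 60), collapse = ""))
  lp2 <- predict_long(fit, long_seq, window = win)
  expect_length(lp2$values, 60L)
  # interior positions equal the central value of their own window
  half <- win %/% 2
  for (p in c(half + 1, 30, 60 - half)) {
    wseq <- substr(long_seq, p - half, p + half)
    wprof <- predict(fit, wseq, type = "profile")[[1]]
    expect_equal(lp2$values[p], wprof$values[half + 1], tolerance = 1e-12)
  }
  # edges copy from the first/last full window
  first <- predict(fit, substr(long_seq, 1, win), type = "profile")[[1]]
  expect_equal(lp2$values[1:half], first$values[1:half], tolerance = 1e-12)
  last <- predict(fit, substr(long_seq, 60 - win + 1, 60),
                  type = "profile")[[1]]
  expect_equal(lp2$values[(60 - half + 1):60],
               last$values[(win - half + 1):win], tolerance = 1e-12)
})

test_that("long prediction is translation-consistent inside a constant background", {
  fit <- tiny_trained_model()
  core <- "UGCAUGUCCGG"
  bg <- function(off, total = 70) {
    paste0(strrep("A", off), core, strrep("A", total - off - nchar(core)))
  }
  win <- 21L
  p1 <- predict_long(fit, c(a = bg(15)), window = win)
  p2 <- predict_long(fit, c(b = bg(25)), window = win)
  half <- win %/% 2
  # positions whose windows lie fully inside [core +/- constant flank]
  idx <- (15 + 1):(15 + nchar(core))
  shift <- 10L
  expect_equal(p1$values[idx], p2$values[idx + shift], tolerance = 1e-10)
})

test_that("sequences shorter than the window fall back to a direct pass", {
  fit <- tiny_trained_model()
  s <- c(short = "ACGUACGUAC")
  lp <- predict_long(fit, s, window = 25)
  expect_equal(lp$values, predict(fit, s, type = "profile")[[1]]$values)
})

test_that("site calling matches hand-built cases", {
  # high threshold: only the all-ones window qualifies
  prof <- c(rep(0, 20), rep(1, 9), rep(0, 20))
  sites <- call_sites(prof, window = 9, threshold = 0.9)
  expect_equal(nrow(sites), 1L)
  expect_equal(c(sites$start, sites$end, sites$width), c(20L, 29L, 9L))
  expect_equal(sites$mean_profile, 1)

  # at threshold 0.3, every window with >= 3 ones (mean 1/3) qualifies:
  # starts 14..26, union [14, 35)
  s03 <- call_sites(prof, window = 9, threshold = 0.3)
  expect_equal(nrow(s03), 1L)
  expect_equal(c(s03$start, s03$end), c(14L, 35L))

  prof10 <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  s10 <- call_sites(prof10, window = 9, threshold = 0.9)
  expect_equal(nrow(s10), 1L)
  expect_equal(s10$width, 10L)                 # overlapping windows merge

  # strictly-greater comparison: a profile exactly at the threshold
  # (exactly representable value) yields nothing
  expect_equal(nrow(call_sites(rep(0.5, 50), window = 9, threshold = 0.5)), 0L)
  expect_equal(nrow(call_sites(rep(0.25, 50), window = 9, threshold = 0.3)), 0L)
  expect_warning(out <- call_sites(rep(1, 5), window = 9), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("site calling equals the brute-force window union oracle", {
  set.seed(72)
  for (rep in 1:100) {
    n <- sample(9:200, 1)
    prof <- rnorm(n, mean = 0.2, sd = 0.4)
    got <- call_sites(prof, window = 9, threshold = 0.3)
    want <- brute_call_sites(prof, window = 9, threshold = 0.3)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("region aggregation averages anchored offsets with a 95% CI band", {
  # identical profiles: mean equals the profile, CI width 0
  prof <- seq(0, 1, length.out = 200)
  agg <- aggregate_profiles(list(prof, prof), exon_start = 100, exon_end = 140,
                            exon_edge = 25, intron_flank = 50)
  expect_equal(unique(agg$n), 2L)
  expect_equal(agg$mean[agg$region == "exon_start"], prof[101:125])
  expect_equal(agg$upper, agg$mean)
  expect_equal(nrow(agg), 50 + 25 + 25 + 50)

  # two differing profiles: mean and the stated normal-approximation CI
  p1 <- rep(0.2, 200); p2 <- rep(0.6, 200)
  agg2 <- aggregate_profiles(list(p1, p2), exon_start = 100, exon_end = 140)
  expect_equal(unique(agg2$mean), 0.4)
  sdv <- sd(c(0.2, 0.6))
  expect_equal(unique(agg2$upper), 0.4 + 1.96 * sdv / sqrt(2))

  # profile too short for the downstream intron region: skipped there only
  expect_warning(
    agg3 <- aggregate_profiles(list(prof, rep(0, 180)),
                               exon_start = 100, exon_end = 140),
    "skipped")
  expect_equal(unique(agg3$n[agg3$region == "intron_down"]), 1L)
  expect_equal(unique(agg3$n[agg3$region != "intron_down"]), 2L)
})
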