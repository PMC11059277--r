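test_that("cNorm divides ribo by rna and masks zero-RNA positions", {
  b <- make_bundle("g", ribo = c(2, 4, 5), rna = c(1, 2, 5))
  expect_equal(as.numeric(normalize_coverage(b)), c(2, 2, 1))
  b0 <- make_bundle("g", ribo = c(1, 1, 1), rna = c(1, 0, 1))
  cn <- normalize_coverage(b0)
  expect_true(is.na(cn[2, 1]))
  expect_false(any(is.infinite(cn)))
  expect_error(coverage_bundle("g", matrix(1, 3, 1), matrix(1, 4, 1)),
               "shape")
})

test_that("diff_track implements the printed mean/SD/threshold formulas", {
  # null: identical conditions give a constant-zero track and no peaks
  b <- make_bundle("g", ribo = c(5, 5, 5, 5), rna = c(1, 1, 1, 1))
  tr <- diff_track(b, b)
  expect_equal(tr$cmean, rep(0, 4))
  expect_equal(tr$threshold, 0)
  expect_equal(nrow(call_peaks(tr)), 0L)

  # single replicate, cdiff = [0,0,0,10]
  test <- make_bundle("g", ribo = c(0, 0, 0, 10), rna = rep(1, 4))
  ctrl <- make_bundle("g", ribo = rep(0, 4), rna = rep(1, 4))
  tr <- diff_track(test, ctrl)
  expect_equal(tr$meancov, 2.5)
  expect_equal(tr$stdmean, sqrt(18.75))
  expect_equal(tr$threshold, 2.5 + 3 * sqrt(18.75))
  expect_equal(nrow(call_peaks(tr)), 0L)  # 10 < 15.49

  # one position at 100 over L = 100: population SD gives
  # T = 1 + 3 * sqrt(99) ~ 30.85 and a single 1-nt peak
  ribo <- rep(0, 100); ribo[43] <- 100
  tr2 <- diff_track(make_bundle("g", ribo, rep(1, 100)),
                    make_bundle("g", rep(0, 100), rep(1, 100)))
  expect_equal(tr2$threshold, 1 + 3 * sqrt(99))
  pk <- call_peaks(tr2)
  expect_equal(pk, data.frame(start = 42L, end = 43L))

  # two separated super-threshold runs give two peaks with correct bounds
  # (spikes must be rare: a 0/h track exceeds mean + 3 SD only when the
  # high fraction is below 10%)
  ribo3 <- rep(0, 60)
  ribo3[c(2, 3, 30, 31)] <- 9
  rna3 <- rep(1, 60)
  tr3 <- diff_track(make_bundle("g", ribo3, rna3),
                    make_bundle("g", rep(0, 60), rna3))
  pk3 <- call_peaks(tr3)
  expect_equal(pk3$start, c(1L, 29L))
  expect_equal(pk3$end, c(3L, 31L))
})

test_that("all-masked genes are skipped with a reason", {
  b <- make_bundle("g", ribo = c(1, 1), rna = c(0, 0))
  tr <- diff_track(b, b)
  expect_equal(tr$skipped, "all_positions_masked")
  expect_equal(nrow(call_peaks(tr)), 0L)
})

test_that("scores use (e-s)T and the filters are strict", {
  # hand-built track: T = 10, three replicates
  track <- structure(list(
    gene_id = "g",
    cdiff = cbind(rep(10.4, 4), rep(10.4, 4), rep(2, 4)),
    cmean = rep((10.4 + 10.4 + 2) / 3, 4),
    meancov = 0, stdmean = 10 / 3, threshold = 10,
    defined = rep(TRUE, 4), skipped = NULL), class = "diff_track")
  peaks <- data.frame(start = 0L, end = 4L)
  rna_hi <- matrix(5, 4, 3)
  res <- score_and_filter(peaks, track, rna_hi)
  # per-replicate scores: (10.4/10 - 1)*100 = 4 > 3 in two replicates -> kept
  expect_true(res$kept)
  expect_equal(res$score_rep1, 4)
  expect_equal(res$score_rep3, -80)
  # mean coverage exactly T -> score 0, not kept
  track0 <- track
  track0$cdiff <- cbind(rep(10, 4), rep(10, 4), rep(10, 4))
  track0$cmean <- rep(10, 4)
  res0 <- score_and_filter(peaks, track0, rna_hi)
  expect_equal(res0$score_mean, 0)
  expect_false(res0$kept)
  # strictness at the score cutoff: 33/32 is exactly representable, so a
  # score of exactly 3.125 against min_score = 3.125 must fail the strict >
  track3 <- track
  track3$cdiff <- cbind(rep(10.3125, 4), rep(10.3125, 4), rep(10.3125, 4))
  track3$cmean <- rep(10.3125, 4)
  res3 <- score_and_filter(peaks, track3, rna_hi, min_score = 3.125)
  expect_identical(res3$score_mean, 3.125)
  expect_false(res3$kept)
  # RNA coverage below 3 discards regardless of score
  res_low <- score_and_filter(peaks, track, matrix(2.9, 4, 3))
  expect_false(res_low$kept)
  expect_equal(res_low$reason, "rna_coverage_below_min")
  # non-positive threshold: kept on coverage alone, flagged
  trackneg <- track
  trackneg$threshold <- 0
  resneg <- score_and_filter(peaks, trackneg, rna_hi)
  expect_true(resneg$kept)
  expect_true(resneg$threshold_flag)
  expect_error(score_and_filter(data.frame(start = 2L, end = 2L), track,
                                rna_hi), "invalid peak")
})

test_that("peak calling is invariant to a common coverage scale", {
  set.seed(20)
  L <- 150L
  mk <- function(f) list(
    test = coverage_bundle("g", f * matrix(rpois(L * 3, 20), L),
                           f * matrix(rpois(L * 3, 20) + 1, L)),
    ctrl = coverage_bundle("g", f * matrix(rpois(L * 3, 20), L),
                           f * matrix(rpois(L * 3, 20) + 1, L)))
  set.seed(33); a <- mk(1)
  set.seed(33); b <- mk(7)
  ra <- call_gene_peaks(a$test, a$ctrl)
  rb <- call_gene_peaks(b$test, b$ctrl)
  expect_equal(ra$peaks$start, rb$peaks$start)
  expect_equal(ra$peaks$end, rb$peaks$end)
  expect_equal(ra$peaks$score_mean, rb$peaks$score_mean)
  # rna_mean_coverage is not scale-free, so kept can differ; threshold is
  expect_equal(ra$track$threshold, rb$track$threshold)
})

test_that("swapping conditions exactly exchanges TC and CC calls", {
  set.seed(44)
  L <- 200L
  bundles <- list(g1 = list(
    test = coverage_bundle("g1", matrix(rpois(L * 3, 30), L),
                           matrix(rpois(L * 3, 30) + 1, L)),
    ctrl = coverage_bundle("g1", matrix(rpois(L * 3, 30), L),
                           matrix(rpois(L * 3, 30) + 1, L))))
  swapped <- list(g1 = list(test = bundles$g1$ctrl, ctrl = bundles$g1$test))
  a <- bidirectional_call(bundles)
  b <- bidirectional_call(swapped)
  a$direction <- c(TC = "CC", CC = "TC")[a$direction]
  a <- a[order(a$direction, a$start), ]
  b <- b[order(b$direction, b$start), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("caller agrees exactly with the naive oracle on random genes", {
  set.seed(55)
  for (rep in 1:10) {
    L <- 200L; N <- 3L
    ribo_t <- matrix(rpois(L * N, 15), L)
    rna_t <- matrix(rpois(L * N, 10), L)   # contains zeros -> masking
    ribo_c <- matrix(rpois(L * N, 15), L)
    rna_c <- matrix(rpois(L * N, 10), L)
    # plant an elevation so peaks exist sometimes
    w <- sample(L - 3L, 1L); ribo_t[w:(w + 2L), ] <- ribo_t[w:(w + 2L), ] * 8L
    res <- call_gene_peaks(coverage_bundle("g", ribo_t, rna_t),
                           coverage_bundle("g", ribo_c, rna_c))
    orc <- naive_peak_oracle(ribo_t, rna_t, ribo_c, rna_c)
    expect_equal(res$track$threshold, orc$threshold, tolerance = 1e-12)
    expect_equal(res$track$meancov, orc$meancov, tolerance = 1e-12)
    expect_equal(res$peaks$start, orc$peaks[, 1L])
    expect_equal(res$peaks$end, orc$peaks[, 2L])
    if (nrow(res$peaks))
      expect_equal(res$peaks$score_mean, orc$scores, tolerance = 1e-10)
  }
})

test_that("kept peaks honor the coverage and replicate invariants", {
  cfg <- sim_config(n_genes = 15L, gene_length_codons = c(60L, 120L),
                    pause_gene_fraction = 0.6, seed = 66L)
  tr <- simulate_transcriptome(cfg)
  cov <- suppressWarnings(simulate_ribo_rna_coverage(cfg, tr))
  pk <- bidirectional_call(cov$bundles)
  kept <- pk[pk$kept & !pk$threshold_flag, ]
  expect_true(all(kept$rna_mean_coverage >= 3))
  score_cols <- grep("^score_rep", names(kept))
  expect_true(all(rowSums(kept[, score_cols, drop = FALSE] > 3) >= 2))
})
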