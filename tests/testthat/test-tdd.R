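test_that("compute_cpm normalizes columns to one million", {
  m <- matrix(c(100, 30, 70, 0), 2L, 2L,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m["g1", "s1"] <- 100; m["g2", "s1"] <- 0
  m["g1", "s2"] <- 30; m["g2", "s2"] <- 70
  cpm <- compute_cpm(m)
  expect_equal(unname(cpm[, "s1"]), c(1e6, 0))
  expect_equal(unname(cpm[, "s2"]), c(3e5, 7e5))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  m0 <- cbind(m, s3 = c(0, 0))
  expect_error(compute_cpm(m0), "s3")
})

test_that("stable-gene criteria apply per replicate and per time", {
  design <- data.frame(
    sample = c("t0", "tci3", "tci5"),
    condition = "CTRL", regime = c("none", "Tci", "Tci"),
    time_h = c(0, 3, 5), replicate = 1L, stringsAsFactors = FALSE)
  cpm <- rbind(
    low0   = c(0.15, 1.0, 1.0),   # fails (i): CPM0 <= 0.2
    stable = c(1.0, 1.2, 1.15),   # passes all three at both times
    blowup = c(1.0, 15.0, 1.2),   # fails (iii) at t3: 1.0 <= 1.5
    flat   = c(1.0, 1.0, 1.0))    # fails (ii) literal: 1.0 < 1.1
  colnames(cpm) <- design$sample
  expect_equal(detect_stable_genes(cpm, design), "stable")
  # ratio mode: (ii) becomes a lower 10-fold bound, so "flat" passes too
  expect_setequal(detect_stable_genes(cpm, design, mode = "ratio"),
                  c("stable", "flat"))
  # any-time mode: "blowup" passes at t5 even though t3 fails
  expect_setequal(detect_stable_genes(cpm, design, times = "any"),
                  c("stable", "blowup"))
  expect_error(detect_stable_genes(cpm, design[design$time_h > 0, ]),
               "t = 0")
})

test_that("stable size factors match identity, scaling and a brute force", {
  cnt <- matrix(rpois(20, 50) + 1, 5L, 4L,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  same <- cnt[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(stable_size_factors(same, rownames(cnt))),
               rep(1, 3))
  doubled <- cbind(s1 = cnt[, 1], s2 = 2 * cnt[, 1])
  sf <- stable_size_factors(doubled, rownames(cnt))
  expect_equal(unname(sf[2] / sf[1]), 2)
  # independent brute-force median-of-ratios
  set.seed(3)
  brute <- apply(cnt, 2L, function(col) {
    ref <- exp(rowMeans(log(cnt)))
    stats::median(col / ref)
  })
  expect_equal(stable_size_factors(cnt, rownames(cnt)), brute,
               tolerance = 1e-12)
})

test_that("size factors equal DESeq2 median-of-ratios when all genes are stable", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  cnt <- matrix(rnbinom(300, mu = 100, size = 10) + 1, 50L, 6L,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  expect_equal(unname(stable_size_factors(cnt, rownames(cnt))),
               unname(DESeq2::estimateSizeFactorsForMatrix(cnt)),
               tolerance = 1e-10)
})

test_that("TDD index formula, invariances and exclusions", {
  expect_equal(compute_tdd_index(100, 50, 80), 0.3)
  expect_equal(compute_tdd_index(10, 7, 7), 0)
  expect_equal(compute_tdd_index(200, 120, 90), -0.15)
  # scale invariance
  expect_equal(compute_tdd_index(5 * 100, 5 * 50, 5 * 80),
               compute_tdd_index(100, 50, 80))
  idx <- compute_tdd_index(c(100, 0), c(50, 10), c(80, 20))
  expect_true(is.na(idx[2]))
  expect_equal(attr(idx, "reason"), "R0_not_positive")
})

test_that("noiseless pipeline recovers the closed-form index exactly", {
  cfg <- sim_config(n_genes = 60L, k_base = 0.1, k_tdd = 0.2,
                    tdd_gene_fraction = 0.5, induced_tdd_fraction = 0,
                    stable_gene_fraction = 0.15, seed = 8L)
  sim <- simulate_tdd_counts(cfg, 60L, noise = "none")
  stable_truth <- sim$truth$gene_id[sim$truth$stable]
  tab <- tdd_index_table(sim$counts, sim$design, stable_set = stable_truth)
  tdd_genes <- sim$truth$gene_id[sim$truth$k_tdd_ctrl > 0]
  got <- tab$indices$index[tab$indices$gene_id %in% tdd_genes &
                           tab$indices$time_h == 3]
  expect_equal(got, rep(exp(-0.3) - exp(-0.9), length(got)),
               tolerance = 1e-9)
  got5 <- tab$indices$index[tab$indices$gene_id %in% tdd_genes &
                            tab$indices$time_h == 5]
  expect_equal(got5, rep(exp(-0.5) - exp(-1.5), length(got5)),
               tolerance = 1e-9)
})

test_that("stable genes are detected when bulk decay outpaces them", {
  # the CPM criteria are compositional: they isolate near-zero-decay genes
  # only when typical genes decay faster than 1.1x the bulk mixture, so this
  # world uses a faster basal turnover than the defaults
  cfg <- sim_config(n_genes = 80L, k_base = 0.4, k_tdd = 0.2,
                    tdd_gene_fraction = 0.3, induced_tdd_fraction = 0.15,
                    stable_gene_fraction = 0.1, seed = 9L)
  sim <- simulate_tdd_counts(cfg, 80L, noise = "none")
  cpm <- compute_cpm(sim$counts)
  stable <- detect_stable_genes(cpm, sim$design)
  expect_setequal(stable, sim$truth$gene_id[sim$truth$stable])
})

test_that("condition-shift test matches per-gene lm and classifies by sign", {
  set.seed(10)
  design <- expand.grid(condition = c("CTRL", "TRT"), time_h = c(3, 5),
                        replicate = 1:3, stringsAsFactors = FALSE)
  mk <- function(gene_id, shift) {
    d <- design
    d$gene_id <- gene_id
    d$index <- rnorm(nrow(d), 0.2, 0.05) + shift * (d$condition == "TRT")
    d
  }
  df <- rbind(mk("up", 0.4), mk("null", 0), mk("down", -0.4))
  res <- test_tdd_shift(df, treated = "TRT")
  expect_equal(res$class[match(c("up", "down"), res$gene_id)],
               c("increased", "decreased"))
  # fast matrix path equals stats::lm gene by gene
  for (g in res$gene_id) {
    d <- df[df$gene_id == g, ]
    fit <- summary(lm(index ~ condition + factor(time_h) + factor(replicate),
                      data = d))$coefficients
    expect_equal(res$estimate[res$gene_id == g],
                 unname(fit["conditionTRT", "Estimate"]), tolerance = 1e-10)
    expect_equal(res$p_value[res$gene_id == g],
                 unname(fit["conditionTRT", "Pr(>|t|)"]), tolerance = 1e-10)
  }
  # degenerate: identical indices -> coefficient 0, unchanged
  flat <- design
  flat$gene_id <- "flat"; flat$index <- 0.3
  res_flat <- test_tdd_shift(rbind(df, flat), treated = "TRT")
  expect_equal(res_flat$estimate[res_flat$gene_id == "flat"], 0)
  expect_equal(res_flat$class[res_flat$gene_id == "flat"], "unchanged")
  # incomplete layout goes through the lm fallback and still reports
  part <- mk("partial", 0.4)[-1, ]
  res_p <- test_tdd_shift(rbind(df, part), treated = "TRT")
  expect_true("partial" %in% res_p$gene_id)
  expect_false(is.na(res_p$p_value[res_p$gene_id == "partial"]))
})
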