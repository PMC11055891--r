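test_that("RFD arithmetic and degenerate bins follow the strand convention", {
  r <- compute_rfd(c(30, 10, 0, 5), c(10, 10, 0, 5))
  expect_equal(r$rfd, c(-0.5, 0, NA, 0))
})

test_that("LOESS zero-crossings of a sine RFD alternate IZ/TZ at known positions", {
  n <- 400
  x <- seq_len(n)
  period <- 80
  rfd_true <- sin(2 * pi * x / period)
  set.seed(31)
  rfd <- compute_rfd(50 * (1 - rfd_true * 0.9) / 2 + 0,
                     50 * (1 + rfd_true * 0.9) / 2 + 0)
  lab <- reference_iz_tz(rfd, loess_span = 0.05)
  # ascending crossings at multiples of the period
  expected_iz <- period * (1:4)
  expected_tz <- period * (0:4) + period / 2
  expect_gte(length(lab$iz_bins), 3)
  for (b in lab$iz_bins) expect_lte(min(abs(expected_iz - b)), 2)
  for (b in lab$tz_bins) expect_lte(min(abs(expected_tz - b)), 2)
  # every retained IZ is flanked by TZs
  for (b in lab$iz_bins) {
    expect_true(any(lab$tz_bins < b) && any(lab$tz_bins > b))
  }

  # monotone RFD: no initiation zone
  mono <- compute_rfd(seq(100, 10, length.out = 50), seq(10, 100, length.out = 50))
  lab_mono <- reference_iz_tz(mono, loess_span = 0.5)
  expect_length(lab_mono$iz_bins, 0)
})

test_that("window tiling arithmetic and label filtering match the design", {
  m <- matrix(runif(16 * 1800), 16)
  m <- sweep(m, 2, colSums(m), "/")
  rm <- repliseq_matrix(m, "chr1")
  rm$values <- m
  # labels in every window: candidate count is floor((1800-30)/24)+1 = 74
  labels_all <- list(iz_bins = seq(1, 1800, by = 10),
                     tz_bins = seq(5, 1800, by = 10))
  w <- make_training_windows(rm, labels_all, scales = 1L)
  expect_length(w, 74)
  expect_equal(vapply(w, function(x) x$start, numeric(1)),
               seq(1, by = 24, length.out = 74))
  expect_true(all(vapply(w, function(x) ncol(x$x) == 30, logical(1))))
  expect_equal(w[[1]]$core, 4:27)

  # windows without an IZ (or TZ) are excluded
  labels_one <- list(iz_bins = 100L, tz_bins = 110L)
  w1 <- make_training_windows(rm, labels_one, scales = 1L)
  expect_true(all(vapply(w1, function(x) any(x$y == 1), logical(1))))
  expect_lt(length(w1), 5)

  # 2x downscale halves the bin count: a 30-bin window covers 3 Mb at 100 kb
  w2 <- make_training_windows(rm, labels_all, scales = 2L)
  expect_length(w2, floor((900 - 30) / 24) + 1)

  # short regions are skipped
  short <- repliseq_matrix(m[, 1:20], "chr1")
  expect_length(make_training_windows(short, labels_all, scales = 1L), 0)
})

test_that("Dice loss spans [0,1] with the right extremes and gradient direction", {
  y <- c(0, 0, 1, 0, 1)
  perfect <- dice_loss(y, y)
  expect_equal(perfect$loss, 0, tolerance = 1e-5)
  wrong <- dice_loss(1 - y, y)
  expect_equal(wrong$loss, 1, tolerance = 1e-5)
  mid <- dice_loss(rep(0.5, 5), y)
  expect_gt(mid$loss, 0); expect_lt(mid$loss, 1)
  # raising probability at a true bin lowers the loss
  expect_lt(mid$dprob[3], 0)
  # masking restricts the evaluation
  m1 <- dice_loss(c(1, 1, 1, 0, 1), y, mask = 3:5)
  expect_equal(m1$loss, 0, tolerance = 1e-5)
})

test_that("an untrained network already honors the sigmoid output contract", {
  w <- list(list(x = matrix(runif(16 * 30), 16), y = c(rep(0, 15), 1, rep(0, 14)),
                 core = 4:27, scale = 1L, start = 1L))
  m <- train_tz_model(rep(w, 3), seed = 1, epochs = 1, dropout = 0)
  pr <- predict_tz(m, matrix(rnorm(16 * 60, sd = 5), 16))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_length(pr$prob, 60)
  # threshold 1 is unreachable for a sigmoid
  expect_length(predict_tz(m, matrix(runif(16 * 40), 16), threshold = 1)$anchors, 0)
  # degenerate labels refuse to train
  w0 <- list(list(x = matrix(runif(16 * 30), 16), y = rep(0, 30),
                  core = 4:27, scale = 1L, start = 1L))
  expect_error(train_tz_model(w0, epochs = 1), "degenerate")
})

test_that("the network is fully convolutional: segment and full-track predictions agree", {
  set.seed(9)
  w <- lapply(1:8, function(i) {
    y <- rep(0, 30); y[sample(5:25, 1)] <- 1
    list(x = matrix(runif(16 * 30), 16), y = y, core = 4:27,
         scale = 1L, start = 1L)
  })
  m <- train_tz_model(w, seed = 2, epochs = 2, dropout = 0)
  x_full <- matrix(runif(16 * 60), 16)
  p_full <- predict_tz(m, x_full)$prob
  p_left <- predict_tz(m, x_full[, 1:40])$prob
  p_right <- predict_tz(m, x_full[, 21:60])$prob
  # interior bins (>= 10 bins from any segment edge, beyond the receptive
  # field) agree exactly with the full-track pass
  expect_equal(p_full[10:30], p_left[10:30], tolerance = 1e-10)
  expect_equal(p_full[31:50], p_right[11:30], tolerance = 1e-10)
})

test_that("training is seed-reproducible and reduces the Dice loss on synthetic data", {
  cfg <- sim_config(seed = 77, chrom_sizes = c(chrSim = 40e6, chrBait = 5e6))
  sim <- simulate_replication(cfg)
  ok <- simulate_okseq(cfg, sim$truth)
  lab <- reference_iz_tz(compute_rfd(ok$F, ok$R),
                         loess_span = 0.02 * 1000 / ncol(sim$matrix$values))
  nm <- normalize_and_smooth(sim$matrix, sigma_bins = 1)
  w <- make_training_windows(nm, lab)
  expect_gt(length(w), 10)
  m1 <- train_tz_model(w, seed = 5, epochs = 8)
  m2 <- train_tz_model(w, seed = 5, epochs = 8)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # loss decreases on average over the first epochs
  expect_lt(mean(tail(m1$history, 3)), mean(head(m1$history, 3)))
  expect_true(all(m1$history >= 0 & m1$history <= 1))
})

test_that("a planted single termination is recovered within one bin", {
  # train under the standard synthetic conditions ...
  cfg <- sim_config(seed = 7, chrom_sizes = c(chrSim = 150e6, chrBait = 10e6))
  sim <- simulate_replication(cfg)
  ok <- simulate_okseq(cfg, sim$truth)
  lab <- reference_iz_tz(compute_rfd(ok$F, ok$R),
                         loess_span = 0.02 * 1000 / ncol(sim$matrix$values))
  nm <- normalize_and_smooth(sim$matrix, sigma_bins = 1)
  m <- train_tz_model(make_training_windows(nm, lab), seed = 3, epochs = 80)
  # ... then predict on a toy with exactly one meeting point between two
  # origins, whose position is known in closed form
  toy <- sim_config(seed = 101, chrom_sizes = c(chrSim = 16e6, chrBait = 5e6),
                    origins = data.frame(pos = c(5e6, 7e6), fraction = c(2, 3)))
  ts <- simulate_replication(toy)
  expect_length(ts$truth$tz_pos, 1)
  truth_bin <- pos_to_bin_test(ts$truth$tz_pos)
  pr <- predict_tz(m, normalize_and_smooth(ts$matrix, sigma_bins = 1))
  between <- pr$anchors[pr$anchors > 100 & pr$anchors < 140]
  expect_length(between, 1)               # exactly one anchor between origins
  expect_lte(abs(between - truth_bin), 1) # within one 50-kb bin of truth

  # an all-zero matrix triggers nothing at the default threshold
  expect_length(predict_tz(m, matrix(0, 16, 50))$anchors, 0)
})
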