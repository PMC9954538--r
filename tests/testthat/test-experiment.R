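test_that("rotating-quarter folds give stratified 50/25/25 partitions", {
  labels <- rep(c("t", "n"), each = 40)
  folds <- split_trials(labels, split_scheme("cv4", seed = 1))
  expect_length(folds, 4)
  for (f in folds) {
    expect_equal(sapply(f, length), c(train = 40L, val = 20L, test = 20L))
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_setequal(c(f$train, f$val, f$test), 1:80)
    for (role in f)   # stratification: both classes in every role
      expect_setequal(unique(labels[role]), c("t", "n"))
  }
  # test quarters rotate: they tile the trial set across folds
  expect_setequal(unlist(lapply(folds, `[[`, "test")), 1:80)
})

test_that("the partition property holds over random label configurations", {
  for (i in 1:100) {
    set.seed(i)
    k <- sample(2:3, 1)
    counts <- sample(4:12, k, replace = TRUE)
    labels <- sample(rep(seq_len(k), counts))
    folds <- split_trials(labels, split_scheme("cv4", seed = i))
    for (f in folds) {
      all_idx <- c(f$train, f$val, f$test)
      expect_equal(sort(all_idx), seq_along(labels))   # partition, no overlap
      for (role in f) expect_equal(sort(unique(labels[role])), seq_len(k))
    }
  }
  expect_error(split_trials(rep(1:2, c(3, 8)), split_scheme("cv4")),
               class = "eegtrm_stratification_error")
})

test_that("fixed-test splitting keeps the test set and cuts the pool 80/20", {
  labels <- rep(1:4, 260)       # 1040 trials, cues cycling through classes
  test_idx <- 881:1040                            # last ~160 kept untouched
  folds <- split_trials(labels, split_scheme("fixed-test", seed = 2,
                                             test_indices = test_idx))
  expect_length(folds, 4)
  for (f in folds) {
    expect_identical(f$test, test_idx)
    expect_equal(length(f$train), 704L)
    expect_equal(length(f$val), 176L)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), setdiff(1:1040, test_idx))
  }
  # repeats differ in their validation draw
  expect_false(identical(folds[[1]]$val, folds[[2]]$val))
})

test_that("checkpointing selects the epoch of minimum validation loss", {
  expect_equal(eegtrm:::best_checkpoint_epoch(c(5, 4, 3, 2, 1)), 5L)
  expect_equal(eegtrm:::best_checkpoint_epoch(c(3, 1, 2, 1)), 2L)  # first min
  expect_equal(eegtrm:::best_checkpoint_epoch(c(0.2, 0.5, 0.9)), 1L)
  for (i in 1:20) {
    set.seed(i)
    v <- runif(sample(3:30, 1))
    expect_equal(eegtrm:::best_checkpoint_epoch(v), which.min(v))
  }
})

test_that("training runs are deterministic and honor the checkpoint rule", {
  es <- tiny_training_set(seed = 5)
  m <- make_random_montage(6, 3, 3, seed = 99)
  build_net <- function() embed(build_trm(m, 3, seed = 1),
                                build_backbone("compact", 6, 40, 2, seed = 1))
  folds <- split_trials(es, split_scheme("cv4", seed = 5))[1:2]
  cfg <- training_config(max_epochs = 3, seed = 5)
  r1 <- train_eval(build_net(), es, folds, cfg)
  r2 <- train_eval(build_net(), es, folds, cfg)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$val_loss, r2$val_loss)
  expect_identical(r1$train_loss, r2$train_loss)
  expect_equal(length(r1$val_loss[[1]]), 3L)
  expect_equal(r1$best_epoch[1], which.min(r1$val_loss[[1]]))
  expect_true(all(r1$fold_accuracy >= 0 & r1$fold_accuracy <= 100))
  # a single epoch gives curves of length one and checkpoint at epoch 1
  r3 <- train_eval(build_net(), es, folds[1],
                   training_config(max_epochs = 1, seed = 5))
  expect_length(r3$val_loss[[1]], 1L)
  expect_equal(r3$best_epoch[1], 1L)
  expect_true(r3$single_fold)
  expect_equal(r3$sd_accuracy, 0)
})

test_that("the paired t test matches the closed form and an independent implementation", {
  # frozen closed-form example: differences 1..4
  r <- compare_paired(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(r$mean_diff, 2.5)
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  # identical pairs: zero difference, p = 1
  a <- c(80, 85, 90)
  r0 <- compare_paired(a, a)
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)
  # swapping the arguments negates t and preserves p
  set.seed(3)
  x <- rnorm(10, 80, 5); y <- x + rnorm(10, 1)
  rxy <- compare_paired(x, y); ryx <- compare_paired(y, x)
  expect_equal(rxy$t, -ryx$t)
  expect_equal(rxy$p, ryx$p)
  expect_error(compare_paired(1:3, 1:4), class = "eegtrm_pairing_error")
  # independent oracle: stats::t.test on 100 random paired vectors
  for (i in 1:100) {
    set.seed(i)
    n <- sample(3:20, 1)
    a <- rnorm(n, 80, 10); b <- a + rnorm(n, 0.5, 2)
    mine <- compare_paired(a, b)
    ref <- stats::t.test(b, a, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$mean_diff, unname(ref$estimate), tolerance = 1e-10)
  }
})

test_that("summaries tabulate variants and compute deltas against the original", {
  res <- data.frame(
    subject = rep(c("s1", "s2"), each = 3),
    backbone = "shallow",
    variant = rep(c("original", "trm-5", "trm-3"), 2),
    accuracy = c(90, 94, 93, 80, 82, 85))
  sm <- summarize_runs(res)
  expect_equal(sm$table["Average", "shallow+original"], 85)
  expect_equal(sm$table["Average", "shallow+trm-5"], 88)
  d5 <- sm$deltas[sm$deltas$variant == "trm-5", ]
  expect_equal(d5$delta, mean(c(94 - 90, 82 - 80)))   # hand-checked
  d3 <- sm$deltas[sm$deltas$variant == "trm-3", ]
  expect_equal(d3$delta, 4)
  # a missing cell stays an explicit gap
  sm2 <- summarize_runs(res[-2, ])
  expect_true(is.na(sm2$table["s1", "shallow+trm-5"]))
})
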