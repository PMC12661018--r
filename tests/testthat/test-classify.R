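test_that("individual stairs threshold follows the walking lean quantile", {
  set.seed(11)
  lean <- stats::rnorm(100, 20, 2)
  feats <- do.call(rbind, lapply(lean, function(l) {
    feat_row(sd_corr = 0.3, inclination = l, forward_lean = l, cadence = 1.8)
  }))
  th <- estimate_stairs_threshold(feats)
  # empirical-quantile oracle on the same sample
  expect_equal(as.numeric(th), stats::quantile(lean, 0.95, names = FALSE) + 2,
               tolerance = 1e-9)
  expect_equal(as.numeric(th), 20 + 1.645 * 2 + 2, tolerance = 1)
  expect_false(attr(th, "fallback"))

  # too few qualifying epochs -> population fallback, flagged
  few <- feats[1:10, ]
  thf <- estimate_stairs_threshold(few)
  expect_equal(as.numeric(thf), 25)
  expect_true(attr(thf, "fallback"))

  allstill <- feat_row(sd_corr = 0.02, inclination = 70, cadence = 0)
  ths <- estimate_stairs_threshold(allstill)
  expect_true(attr(ths, "fallback"))

  expect_error(estimate_stairs_threshold(feats[0, ]), "empty")
})

test_that("the decision tree resolves each documented branch", {
  cfg <- classifier_config()
  expect_equal(classify_epoch(feat_row(0.02, inclination = 70), 25, cfg),
               "sedentary")
  expect_equal(classify_epoch(feat_row(0.02, inclination = 10), 25, cfg),
               "stand")
  expect_equal(classify_epoch(feat_row(0.3, forward_lean = 20,
                                       cadence = 1.8), 25, cfg), "walk")
  expect_equal(classify_epoch(feat_row(0.3, forward_lean = 55,
                                       cadence = 1.1), 25, cfg), "cycle")
  expect_equal(classify_epoch(feat_row(0.3, forward_lean = 20,
                                       cadence = 2.8), 25, cfg), "run")
  expect_equal(classify_epoch(feat_row(0.9, forward_lean = 20,
                                       cadence = 0), 25, cfg), "run")
  expect_equal(classify_epoch(feat_row(0.3, forward_lean = 20,
                                       cadence = 0.2), 25, cfg), "move")
  # threshold sensitivity: the same epoch flips stairs -> walk when the
  # individual threshold rises past its lean
  e <- feat_row(0.3, forward_lean = 30, cadence = 1.6)
  expect_equal(classify_epoch(e, 25, cfg), "stairs")
  expect_equal(classify_epoch(e, 35, cfg), "walk")
})

test_that("threshold monotonicity holds on feature sweeps", {
  set.seed(12)
  feats <- do.call(rbind, lapply(1:200, function(i) {
    feat_row(sd_corr = stats::runif(1, 0.01, 0.4),
             inclination = stats::runif(1, 0, 90),
             forward_lean = stats::runif(1, 0, 60),
             cadence = stats::runif(1, 0, 3))
  }))
  # raising theta_sit only ever converts stand -> sedentary
  l1 <- actithigh:::classify_epochs_(feats, 25, classifier_config())
  l2 <- actithigh:::classify_epochs_(feats, 25,
                                     classifier_config(theta_sit_deg = 60))
  changed <- l1 != l2
  expect_true(all(l1[changed] == "sedentary" & l2[changed] == "stand"))

  # raising theta_stairs monotonically moves epochs from stairs to walk
  sweep_th <- seq(15, 55, by = 5)
  stairs_n <- vapply(sweep_th, function(th) {
    sum(actithigh:::classify_epochs_(feats, th, classifier_config()) ==
          "stairs")
  }, numeric(1))
  expect_true(all(diff(stairs_n) <= 0))
})

test_that("label smoothing matches the brute-force modal oracle", {
  cfg <- classifier_config()
  lab <- rep("walk", 60)
  lab[30] <- "run"
  sm <- smooth_labels(epoch_labels(lab), cfg)
  expect_true(all(as.character(sm) == "walk"))

  # modal stage against a brute-force oracle, on a series whose bouts all
  # exceed their minima after the modal pass (so absorption is a no-op)
  set.seed(14)
  runs <- sample(behaviour_levels()[c(1, 2, 4)], 12, replace = TRUE)
  series <- unlist(lapply(runs, rep, times = 20))
  intruders <- seq(10, length(series) - 10, by = 23)
  series[intruders] <- "stairs"
  smr <- as.character(smooth_labels(epoch_labels(series), cfg))
  expect_equal(smr, modal_oracle(series, 5))

  # every-epoch alternation collapses to a single label (modal ties keep
  # the centre, then sub-minimum bouts are absorbed)
  alt <- rep(c("stand", "sedentary"), 30)
  sm2 <- as.character(smooth_labels(epoch_labels(alt), cfg))
  expect_equal(length(unique(sm2)), 1L)

  short <- epoch_labels(c("walk", "run", "walk"))
  expect_identical(as.character(smooth_labels(short, cfg)),
                   c("walk", "run", "walk"))

  # minimum-bout absorption: a 3-s run bout survives (min 2 s) but a
  # 10-s cycle bout is absorbed (min 15 s)
  series <- epoch_labels(c(rep("walk", 30), rep("cycle", 10),
                           rep("walk", 30)))
  smc <- smooth_labels(series, cfg)
  expect_true(all(as.character(smc) == "walk"))
  series2 <- epoch_labels(c(rep("walk", 30), rep("run", 3),
                            rep("walk", 30)))
  expect_equal(sum(as.character(smooth_labels(series2, cfg)) == "run"), 3)
})

test_that("whole pipeline classifies clean scripts and chunks identically", {
  sim <- simulate_recording(lab_protocol_script(), fs_hz = 25, seed = 2)
  whole <- classify_recording(sim$recording)
  chunked <- classify_recording(sim$recording, chunk_s = 60)
  expect_identical(as.character(whole), as.character(chunked))

  sed <- simulate_recording(behaviour_script("sedentary", 120), fs_hz = 25,
                            seed = 3)
  lab <- classify_recording(sed$recording)
  expect_true(all(as.character(lab) == "sedentary"))
})

test_that("daily aggregation conserves time and respects day windows", {
  agg <- aggregate_daily(epoch_labels(rep("sedentary", 2 * 86400)))
  expect_equal(agg$n_complete_days, 2)
  expect_equal(unname(agg$mean["sedentary"]), 1440)
  expect_equal(unname(agg$mean["walk"]), 0)

  # behaviours in a complete day always sum to 1440 minutes
  set.seed(13)
  lab <- sample(behaviour_levels(), 86400 + 3600, replace = TRUE)
  agg2 <- aggregate_daily(epoch_labels(lab))
  sums <- unname(rowSums(agg2$per_day[, behaviour_levels()]))
  expect_equal(sums[1], 1440)
  expect_equal(sum(sums), length(lab) / 60)

  # 36 h: one complete day feeds the mean, the partial day is reported
  agg3 <- aggregate_daily(epoch_labels(rep(c("sedentary", "walk"),
                                           c(86400, 43200))))
  expect_equal(agg3$n_complete_days, 1)
  expect_equal(unname(agg3$mean["sedentary"]), 1440)
  expect_equal(nrow(agg3$per_day), 2)

  short <- aggregate_daily(epoch_labels(rep("walk", 100)))
  expect_null(short$mean)
})
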