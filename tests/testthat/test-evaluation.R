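test_that("balanced labels give paired folds covering every trial once", {
  labels <- rep(c("remembered", "forgotten"), each = 20)
  plan <- makeFolds(labels, seed = 1)
  expect_equal(plan@k, 20)
  for (f in plan@folds) {
    expect_length(f$test, 2)
    expect_setequal(labels[f$test], c("remembered", "forgotten"))
    expect_setequal(c(f$test, f$train), seq_along(labels))
  }
  tested <- unlist(lapply(plan@folds, `[[`, "test"))
  expect_setequal(tested, seq_along(labels))
  expect_false(anyDuplicated(tested) > 0)
})

test_that("unbalanced labels add singleton folds for the majority class", {
  labels <- c(rep("remembered", 5), rep("forgotten", 3))
  plan <- makeFolds(labels, seed = 2)
  expect_equal(plan@k, 5)
  sizes <- vapply(plan@folds, function(f) length(f$test), integer(1))
  expect_equal(sum(sizes == 2), 3)
  expect_equal(sum(sizes == 1), 2)
  expect_setequal(unlist(lapply(plan@folds, `[[`, "test")), 1:8)
  expect_error(makeFolds(c("remembered", "forgotten"), seed = 1),
               "empty training set")
  expect_error(makeFolds(rep("remembered", 4), seed = 1), "both classes")
})

test_that("fold coverage holds for arbitrary imbalance (property)", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    labels <- sample(c("remembered", "forgotten"), n, replace = TRUE,
                     prob = c(runif(1, 0.2, 0.8), 1))
    if (length(unique(labels)) < 2 || min(table(labels)) < 1 || n < 3) next
    plan <- makeFolds(labels, seed = rep)
    tested <- unlist(lapply(plan@folds, `[[`, "test"))
    expect_setequal(tested, seq_len(n))
    expect_equal(length(tested), n)    # disjoint: each exactly once
    for (f in plan@folds)
      expect_setequal(union(f$test, f$train), seq_len(n))
  }
})

test_that("binomial significance equals the exact tail sum", {
  expect_equal(binomialSignificance(10, 10), 2^-10)
  # frozen from the closed form: sum_{k=5}^{10} C(10,k) 0.5^10
  expect_equal(binomialSignificance(5, 10), 0.623046875)
  expect_gt(binomialSignificance(50, 100), 0.05)
  expect_lt(binomialSignificance(60, 100), 0.05)
  expect_error(binomialSignificance(1, 0), "positive")
  expect_error(binomialSignificance(5, 4), "nCorrect")
})

test_that("key presses map onto remembered/forgotten labels", {
  lab <- labelTrials(data.frame(trial_id = 1:5, key = 1:5))
  expect_equal(unname(lab), c("remembered", "remembered", "forgotten",
                              "forgotten", "forgotten"))
  expect_error(labelTrials(data.frame(trial_id = 1, key = 6)), "1..5")
})

test_that("participant inclusion applies both thresholds as documented", {
  rec <- data.frame(
    participant = c("P1", "P2", "P3", "P4"),
    n_remembered = c(14, 40, 15, 50),
    n_forgotten = c(50, 40, 15, 10),
    response_bias = c(0, 0.25, 0.2, 0.1))
  out <- selectParticipants(rec)
  expect_equal(out$included$participant, "P3")   # boundary case included
  expect_equal(out$report$reason, c("count", "bias", "", "count"))
  expect_equal(responseBias(c(1, 2, 3, 4, 5)), 0.4)
})

test_that("a constant predictor scores one half on balanced data", {
  setClass("ConstantSpec", contains = "ClassifierSpec",
           where = topenv(environment()))
  setMethod("prepareContext", "ConstantSpec",
            function(spec, epochs, window = "entire")
              list(labels = trialLabels(epochs)),
            where = topenv(environment()))
  setMethod("fitClassifier", "ConstantSpec",
            function(spec, context, trainIdx, seed = NULL) list(),
            where = topenv(environment()))
  setMethod("predictClassifier", "ConstantSpec",
            function(spec, model, context, testIdx)
              rep("remembered", length(testIdx)),
            where = topenv(environment()))
  ep <- simulateEpochs(simConfig(nTrials = 30, pRemembered = 0.5,
                                 noiseSigma = 2, seed = 40))
  # force perfect balance by construction
  lab <- rep(c("remembered", "forgotten"), 15)
  ep@labels <- lab
  cv <- crossValidate(ep, new("ConstantSpec", name = "constant"),
                      "pre", seed = 1)
  expect_equal(cv@accuracy, 0.5)
  expect_false(cv@significant)
})

test_that("fold fits depend only on their training trials (no leakage)", {
  ep <- simulateEpochs(simConfig(nTrials = 20, noiseSigma = 3, seed = 41))
  spec <- classifierSpec("lda")
  ctx <- prepareContext(spec, ep, "pre")
  train <- 1:14
  m1 <- fitClassifier(spec, ctx, train, seed = 5)
  # normalization statistics are computed from the training trials only
  expect_equal(m1$stats,
               conveegnn:::chanStats(ctx$arr, train, ctx$channelNames))
  # altering held-out trials does not change the fitted model
  ctx2 <- ctx
  ctx2$arr[15:20, , ] <- ctx2$arr[15:20, , ] * 5 + 3
  m2 <- fitClassifier(spec, ctx2, train, seed = 5)
  expect_identical(m1$lda$w, m2$lda$w)
  expect_identical(m1$stats, m2$stats)
})

test_that("cross-validation recovers a strong planted effect", {
  ep <- simulateEpochs(simConfig(nTrials = 60, noiseSigma = 1.5,
                                 transientRate = 0, seed = 42))
  cv <- crossValidate(ep, classifierSpec("lda"), "entire", seed = 3)
  expect_gte(cv@accuracy, 0.85)
  expect_true(cv@significant)
  expect_equal(cv@nTotal, 60L)
  expect_equal(cv@accuracy, cv@nCorrect / cv@nTotal)
  # pooled predictions cover every trial exactly once
  expect_setequal(cv@predictions$trial_id, trialIds(ep))
})
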