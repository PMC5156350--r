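#' Build a leave-pair-out fold plan
#'
#' Pairs one random remembered with one random forgotten trial (without
#' replacement) into \code{min(n_rem, n_forg)} two-trial test folds; any
#' leftover majority-class trials are tested in singleton folds. Every trial
#' is tested exactly once and each fold trains on the complement of its test
#' set.
#'
#' @param labels per-trial "remembered"/"forgotten".
#' @param seed integer seed for the random pairing.
#' @return a [FoldPlan-class].
#' @export
#' @examples
#' makeFolds(rep(c("remembered", "forgotten"), each = 5), seed = 1)
makeFolds <- function(labels, seed = 1L) {
  chkLabels(labels)
  idx <- seq_along(labels)
  i1 <- idx[labels == "remembered"]
  i0 <- idx[labels == "forgotten"]
  if (!length(i1) || !length(i0))
    stop("both classes must be present to build folds")
  withSeed(seed, {
    i1 <- i1[sample.int(length(i1))]
    i0 <- i0[sample.int(length(i0))]
  })
  nPair <- min(length(i1), length(i0))
  folds <- lapply(seq_len(nPair), function(j) {
    test <- c(i1[j], i0[j])
    list(test = test, train = setdiff(idx, test))
  })
  leftover <- c(i1[-seq_len(nPair)], i0[-seq_len(nPair)])
  folds <- c(folds, lapply(leftover, function(t)
    list(test = t, train = setdiff(idx, t))))
  if (any(vapply(folds, function(f) length(f$train) == 0L, logical(1))))
    stop("degenerate fold plan: a fold has an empty training set")
  new("FoldPlan", folds = folds, k = length(folds))
}

#' Exact one-sided binomial significance against chance
#'
#' Tail probability P(X >= nCorrect) for X ~ Binomial(nTotal, 0.5): the
#' probability of at least the observed number of correct predictions under
#' chance-level decoding.
#'
#' @param nCorrect,nTotal counts.
#' @return the p-value.
#' @export
#' @examples
#' binomialSignificance(10, 10)   # 2^-10
#' binomialSignificance(50, 100)  # not significant
binomialSignificance <- function(nCorrect, nTotal) {
  if (nTotal <= 0L) stop("nTotal must be positive")
  if (nCorrect < 0L || nCorrect > nTotal)
    stop("nCorrect must lie in [0, nTotal]")
  stats::pbinom(nCorrect - 1L, nTotal, 0.5, lower.tail = FALSE)
}

#' Leave-pair-out cross-validation
#'
#' Runs the full protocol for one classifier: builds the fold plan, and for
#' each fold fits the classifier on that fold's training trials only (all
#' label-dependent computation — normalization statistics, internal 70/30
#' split, class balancing, CSP filters — happens inside the fold), then pools
#' the held-out predictions over all folds into a single accuracy with an
#' exact binomial significance test.
#'
#' @param epochs a labeled [EpochSet-class] (post artifact rejection).
#' @param spec a [ClassifierSpec-class], see [classifierSpec()].
#' @param window "entire", "pre" or "during".
#' @param seed integer seed driving the fold plan and every fold's fit.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(epochs, spec, window = "entire", seed = 1L) {
  labels <- trialLabels(epochs)
  if (anyNA(labels)) stop("all trials must be labeled")
  plan <- makeFolds(labels, seed)
  context <- prepareContext(spec, epochs, window)
  pred <- character(length(labels))
  foldOf <- integer(length(labels))
  for (f in seq_len(plan@k)) {
    fold <- plan@folds[[f]]
    foldSeed <- (as.integer(seed) %% 1000003L) * 1009L + f
    model <- tryCatch(
      fitClassifier(spec, context, fold$train, seed = foldSeed),
      error = function(e)
        stop("training failed in fold ", f, ": ", conditionMessage(e)))
    pred[fold$test] <- predictClassifier(spec, model, context, fold$test)
    foldOf[fold$test] <- f
  }
  nCorrect <- sum(pred == labels)
  n <- length(labels)
  p <- binomialSignificance(nCorrect, n)
  new("CVResult",
      predictions = data.frame(trial_id = trialIds(epochs), fold = foldOf,
                               truth = labels, predicted = pred),
      accuracy = nCorrect / n, nCorrect = as.integer(nCorrect),
      nTotal = as.integer(n), pValue = p, significant = p < 0.05,
      model = spec@name, window = window)
}

#' Apply the participant inclusion rules
#'
#' A participant is excluded when they remembered fewer than 15 words,
#' forgot fewer than 15 words (too few samples for training), or show a
#' response bias above 0.2 (too prone to calling new words familiar). Both
#' count thresholds are inclusive at 15 and the bias threshold is strict.
#'
#' @param records data.frame with columns \code{participant},
#'   \code{n_remembered}, \code{n_forgotten}, \code{response_bias}.
#' @return list with \code{included} (subset of \code{records}) and
#'   \code{report} (per-participant inclusion flag and reason).
#' @export
#' @examples
#' selectParticipants(data.frame(
#'   participant = c("P1", "P2", "P3"),
#'   n_remembered = c(14, 40, 15), n_forgotten = c(50, 40, 15),
#'   response_bias = c(0, 0.25, 0.2)))
selectParticipants <- function(records) {
  reason <- character(nrow(records))
  tooFew <- records$n_remembered < 15 | records$n_forgotten < 15
  highBias <- records$response_bias > 0.2
  reason[highBias] <- "bias"
  reason[tooFew] <- "count"   # count rule reported first when both apply
  included <- !tooFew & !highBias
  report <- data.frame(participant = records$participant,
                       included = included,
                       reason = ifelse(included, "", reason))
  list(included = records[included, , drop = FALSE], report = report)
}

#' Response bias from memory-test answers to new words
#'
#' Implemented as the proportion of genuinely new test words answered
#' "definitely familiar" or "possibly familiar" (keys 1-2): a participant's
#' tendency to call unseen items familiar. The exclusion threshold used by
#' [selectParticipants()] is 0.2.
#'
#' @param newWordKeys integer keys (1-5) given to new words.
#' @return the bias statistic in [0, 1].
#' @export
responseBias <- function(newWordKeys) {
  if (any(!newWordKeys %in% 1:5)) stop("keys must be in 1..5")
  mean(newWordKeys <= 2)
}
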