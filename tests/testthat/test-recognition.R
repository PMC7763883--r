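toy_cycles <- function(n_per = 6, len = 40, classes = 3, sep = 4, seed = 71) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(classes))
  rows <- list(); meta <- list()
  for (k in seq_len(classes)) {
    center <- rnorm(len) * sep
    for (state in c("pre", "post")) for (i in seq_len(n_per)) {
      rows[[length(rows) + 1L]] <- center + rnorm(len, sd = 0.3)
      meta[[length(meta) + 1L]] <- data.frame(subject = subj[k], state = state,
                                              session = 1L, cycle = i)
    }
  }
  cycle_set(do.call(rbind, rows), do.call(rbind, meta), 500)
}

test_that("feature blocks concatenate consecutive cycles per subject and state", {
  set <- toy_cycles(n_per = 10, len = 25)
  f1 <- build_features(set, 1)
  expect_equal(nrow(f1$x), nrow(set$cycles))
  f4 <- build_features(set, 4)
  # 10 cycles per subject/state: floor(10/4) = 2 blocks each
  expect_equal(nrow(f4$x), 3 * 2 * 2)
  expect_equal(ncol(f4$x), 4 * 25)
  expect_equal(f4$n_leftover, 3 * 2 * 2)
  expect_error(build_features(set, 0), "block_size")
})

test_that("discriminant reduction matches an independent eigen-oracle subspace", {
  set.seed(72)
  # well-conditioned 3-class toy problem, p << n
  n <- 60; p <- 5
  y <- rep(c("a", "b", "c"), each = n / 3)
  mu <- matrix(rnorm(3 * p, sd = 3), 3)
  x <- mu[as.integer(factor(y)), ] + matrix(rnorm(n * p), n)
  fm <- structure(list(x = x, labels = y), class = "feature_matrix")
  red <- reduce_discriminant(fm)
  expect_equal(ncol(red$train$x), 2)  # C - 1 dimensions
  # oracle: MASS::lda scalings span the same subspace (compare canonical
  # correlations of the projected data)
  proj_oracle <- predict(MASS::lda(x, grouping = y))$x
  cc <- cancor(red$train$x, proj_oracle)$cor
  expect_true(all(cc > 0.999))
  # 2 classes give a single discriminant direction
  fm2 <- structure(list(x = x[y != "c", ], labels = y[y != "c"]),
                   class = "feature_matrix")
  expect_equal(ncol(reduce_discriminant(fm2)$train$x), 1)
  # singular within-class scatter (p > n) triggers shrinkage, not failure
  keep <- c(1:4, 21:24, 41:44)
  xp <- cbind(x, matrix(rnorm(n * 80), n))[keep, ]
  fmp <- structure(list(x = xp, labels = y[keep]), class = "feature_matrix")
  redp <- reduce_discriminant(fmp)
  expect_gt(attr(redp, "shrinkage"), 0)
  # mismatched width is rejected
  bad <- structure(list(x = x[, 1:3], labels = y), class = "feature_matrix")
  expect_error(reduce_discriminant(fm, bad), "width")
})

test_that("classifiers assign enrolled identities in closed set", {
  set <- toy_cycles(n_per = 8, len = 30, sep = 6)
  enroll <- build_features(ecgfuse:::subset_cycles(set, set$meta$state == "pre"), 2)
  recog <- build_features(ecgfuse:::subset_cycles(set, set$meta$state == "post"), 2)
  # knn, K=1: a probe identical to an enrollment row gets that row's label
  probe <- recog; probe$x[1, ] <- enroll$x[5, ]
  pred <- train_and_identify(classifier_spec("knn"), enroll, probe)
  expect_equal(pred[1], enroll$labels[5])
  # separable classes: svm identifies every probe
  pred_svm <- train_and_identify(classifier_spec("svm", gamma = 0.01), enroll, recog)
  expect_equal(pred_svm, recog$labels)
  # shallow autoencoder is deterministic under a fixed seed
  sp <- classifier_spec("autoencoder", seed = 99, epochs = 50)
  a1 <- train_and_identify(sp, enroll, recog)
  a2 <- train_and_identify(sp, enroll, recog)
  expect_identical(a1, a2)
  # the recurrent kind requires an explicit backend
  expect_error(train_and_identify(classifier_spec("lstm"), enroll, recog),
               "backend")
  # and a supplied backend is honored
  sp_b <- classifier_spec("lstm",
                          backend = function(ex, ey, rx, spec) rep(ey[1], nrow(rx)))
  expect_equal(train_and_identify(sp_b, enroll, recog),
               rep(enroll$labels[1], nrow(recog$x)))
})

test_that("identification metrics reproduce the confusion-count formulas", {
  r <- score_identification(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  expect_equal(r$f1, 1); expect_equal(r$accuracy, 1)
  # fixed counts: precision 8/9, recall 0.8, accuracy 0.97
  r2 <- score_identification(counts = c(tp = 8, tn = 89, fp = 1, fn = 2))
  expect_equal(r2$precision, 8 / 9)
  expect_equal(r2$recall, 0.8)
  expect_equal(r2$accuracy, 0.97)
  expect_equal(r2$f1, 2 * r2$precision * r2$recall / (r2$precision + r2$recall))
  # micro-averaged precision/recall/F1 equal the plain fraction correct
  set.seed(73)
  truth <- sample(letters[1:4], 60, replace = TRUE)
  pred <- truth; flip <- sample(60, 15)
  pred[flip] <- sample(letters[1:4], 15, replace = TRUE)
  r3 <- score_identification(pred, truth)
  expect_equal(r3$precision, mean(pred == truth))
  expect_equal(r3$recall, mean(pred == truth))
  expect_equal(r3$f1, mean(pred == truth))
  expect_error(score_identification(character(0), character(0)), "non-empty")
})
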