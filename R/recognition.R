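#' Build a feature matrix of concatenated cycle blocks
#'
#' Every observation is the concatenation of `block_size` consecutive cycles
#' of one subject / state / session — the whole-cycle samples are the
#' morphological feature vector. Leftover cycles that cannot fill a block are
#' dropped (counted in the `n_leftover` attribute).
#'
#' @param set a [cycle_set()].
#' @param block_size cycles per observation (>= 1).
#' @return A `feature_matrix`: list with `x` (observations x features),
#'   `labels` (subject ids) and `meta` (state, session, block index).
#' @export
build_features <- function(set, block_size = 1L) {
  stopifnot(inherits(set, "cycle_set"))
  block_size <- as.integer(block_size)
  if (block_size < 1) stop("block_size must be >= 1", call. = FALSE)
  key <- interaction(set$meta$subject, set$meta$state, set$meta$session,
                     drop = TRUE)
  rows <- list(); labels <- character(0); meta <- list()
  leftover <- 0L
  for (g in levels(key)) {
    idx <- which(key == g)
    nb <- length(idx) %/% block_size
    leftover <- leftover + length(idx) - nb * block_size
    if (nb == 0) next
    for (b in seq_len(nb)) {
      take <- idx[((b - 1) * block_size + 1):(b * block_size)]
      rows[[length(rows) + 1L]] <- as.numeric(t(set$cycles[take, , drop = FALSE]))
      labels <- c(labels, set$meta$subject[idx[1]])
      meta[[length(meta) + 1L]] <- data.frame(
        subject = set$meta$subject[idx[1]], state = set$meta$state[idx[1]],
        session = set$meta$session[idx[1]], block = b,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(x = do.call(rbind, rows), labels = labels,
                 meta = do.call(rbind, meta),
                 n_leftover = leftover),
            class = "feature_matrix")
}

#' Discriminant-analysis dimensionality reduction
#'
#' Fisher linear discriminant projection fitted on the enrollment rows only
#' and applied to both matrices. Solves the generalized eigenproblem of the
#' between-class against the within-class scatter; when the within-class
#' scatter is singular (more features than enrollment rows) a shrinkage ridge
#' `lambda * mean(diag(Sw))` is added and reported via the `shrinkage`
#' attribute. The output dimension is at most `n_classes - 1`.
#'
#' @param train a `feature_matrix` with >= 2 classes and more rows than
#'   classes.
#' @param apply_to a `feature_matrix` with the same feature width.
#' @param lambda shrinkage intensity used when regularization is needed.
#' @return List with reduced matrices `train` and `apply_to`, the projection
#'   `w`, and the training column means `center`.
#' @export
reduce_discriminant <- function(train, apply_to = NULL, lambda = 1e-3) {
  stopifnot(inherits(train, "feature_matrix"))
  x <- train$x; y <- factor(train$labels)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (nrow(x) <= nlevels(y)) stop("need more rows than classes", call. = FALSE)
  if (!is.null(apply_to) && ncol(apply_to$x) != ncol(x))
    stop("apply_to feature width does not match the training width", call. = FALSE)
  p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sw <- matrix(0, p, p); sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    xi <- xc[y == cl, , drop = FALSE]
    mi <- colMeans(xi)
    xi <- sweep(xi, 2, mi)
    sw <- sw + crossprod(xi)
    sb <- sb + nrow(xi) * tcrossprod(mi)
  }
  shrunk <- FALSE
  ridge <- lambda * mean(diag(sw))
  swr <- sw
  ev <- tryCatch(eigen(solve(sw, sb), symmetric = FALSE),
                 error = function(e) NULL)
  if (is.null(ev) || rcond(sw) < 1e-10) {
    shrunk <- TRUE
    swr <- sw + diag(ridge, p)
    ev <- eigen(solve(swr, sb), symmetric = FALSE)
  }
  d <- min(nlevels(y) - 1L, p)
  w <- Re(ev$vectors[, seq_len(d), drop = FALSE])
  # sphere the discriminant directions: unit pooled within-class variance per
  # output dimension, so downstream distance-based classifiers are well scaled
  denom <- nrow(x) - nlevels(y)
  for (j in seq_len(d)) {
    v <- sqrt(drop(crossprod(w[, j], swr %*% w[, j])) / denom)
    if (v > 0) w[, j] <- w[, j] / v
  }
  project <- function(fm) {
    fm$x <- sweep(fm$x, 2, mu) %*% w
    fm
  }
  structure(list(train = project(train),
                 apply_to = if (is.null(apply_to)) NULL else project(apply_to),
                 w = w, center = mu),
            shrinkage = if (shrunk) ridge else 0)
}

#' Classifier specification
#'
#' Hyperparameters follow a grid-search-tuned setup: 1-nearest-neighbor;
#' RBF-kernel SVM with `gamma = 100`, `cost = 10`; a shallow autoencoder
#' (single hidden layer, nearest-neighbor matching in code space — a reduced
#' variant of a stacked design); and an LSTM hook that dispatches to a
#' user-supplied backend function, since no recurrent backend is bundled.
#'
#' @param kind `"knn"`, `"svm"`, `"autoencoder"` or `"lstm"`.
#' @param k neighbors for knn.
#' @param gamma,cost RBF-SVM parameters; `gamma = NULL` defers to the SVM
#'   library's own heuristics (per-column standardization, gamma = 1/width).
#' @param hidden hidden-layer size for the autoencoder (`NULL`: half the
#'   feature width, at least 2).
#' @param epochs training iterations for the autoencoder.
#' @param seed seed for stochastic kinds.
#' @param backend for `kind = "lstm"`: a function
#'   `f(enroll_x, enroll_labels, recog_x, spec)` returning predicted labels.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "svm", "autoencoder", "lstm"),
                            k = 1L, gamma = 100, cost = 10,
                            hidden = NULL, epochs = 100L, seed = 1L,
                            backend = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), gamma = gamma, cost = cost,
                 hidden = hidden, epochs = as.integer(epochs),
                 seed = as.integer(seed), backend = backend),
            class = "classifier_spec")
}

#' Train on enrollment features and identify recognition features
#'
#' Closed-set 1:N identification: the model is fitted on the enrollment
#' (pre-exercise) observations and every recognition (post-exercise)
#' observation is assigned one enrolled identity.
#'
#' @param spec a [classifier_spec()].
#' @param enroll,recog `feature_matrix` objects (typically after
#'   [reduce_discriminant()]).
#' @return Character vector of predicted subject ids, one per recognition row.
#' @export
train_and_identify <- function(spec, enroll, recog) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(enroll, "feature_matrix"),
            inherits(recog, "feature_matrix"))
  if (ncol(enroll$x) != ncol(recog$x))
    stop("feature widths differ between enrollment and recognition", call. = FALSE)
  y <- factor(enroll$labels)
  if (nlevels(y) < 2) stop("enrollment must cover at least 2 identities", call. = FALSE)
  switch(spec$kind,
    knn = as.character(class::knn(enroll$x, recog$x, y, k = spec$k)),
    svm = {
      # gamma = NULL: fall back to the library's own heuristics (per-column
      # standardization and gamma = 1/width), which stay well-conditioned
      # when probe features shift relative to enrollment
      if (is.null(spec$gamma))
        fit <- e1071::svm(enroll$x, y, kernel = "radial", cost = spec$cost)
      else
        fit <- e1071::svm(enroll$x, y, kernel = "radial",
                          gamma = spec$gamma, cost = spec$cost, scale = FALSE)
      as.character(stats::predict(fit, recog$x))
    },
    autoencoder = with_seed(spec$seed, {
      h <- spec$hidden
      if (is.null(h)) h <- max(2L, ncol(enroll$x) %/% 2L)
      fit <- nnet::nnet(enroll$x, enroll$x, size = h, linout = TRUE,
                        maxit = spec$epochs, trace = FALSE,
                        MaxNWts = 1e6, decay = 1e-4)
      encode <- function(m) {
        # hidden activations: sigmoid(cbind(1, m) %*% W1)
        w1 <- matrix(fit$wts[seq_len((ncol(enroll$x) + 1) * h)],
                     nrow = ncol(enroll$x) + 1)
        z <- cbind(1, m) %*% w1
        1 / (1 + exp(-z))
      }
      as.character(class::knn(encode(enroll$x), encode(recog$x), y, k = 1))
    }),
    lstm = {
      if (is.null(spec$backend))
        stop("kind 'lstm' needs a backend function in classifier_spec(backend=)",
             call. = FALSE)
      with_seed(spec$seed,
                as.character(spec$backend(enroll$x, enroll$labels, recog$x, spec)))
    })
}

#' Identification metrics from predicted and true labels
#'
#' Accumulates the multiclass confusion one-vs-rest and pools the counts
#' (micro-averaging) into precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their
#' harmonic-mean F1, and accuracy `(TP+TN)/(TP+TN+FP+FN)`. With pooled
#' one-vs-rest counts, micro precision, recall and F1 all equal the plain
#' fraction of correct assignments, which is also reported as
#' `accuracy_simple`; the pooled accuracy is the more forgiving Eq-style
#' quantity over all class-wise binary decisions. Macro averages are included
#' for completeness.
#'
#' @param predicted,truth equal-length label vectors, or alternatively pass
#'   raw counts via `counts = c(tp=, tn=, fp=, fn=)` with both label
#'   arguments missing.
#' @param counts optional named counts bypassing label comparison.
#' @return A `recognition_report`: list of counts and rates.
#' @export
score_identification <- function(predicted, truth, counts = NULL) {
  if (is.null(counts)) {
    if (!length(predicted) || length(predicted) != length(truth))
      stop("predicted and truth must be equal-length, non-empty", call. = FALSE)
    classes <- sort(unique(c(predicted, truth)))
    tp <- tn <- fp <- fn <- 0
    macro_p <- macro_r <- numeric(0)
    for (cl in classes) {
      tpc <- sum(predicted == cl & truth == cl)
      fpc <- sum(predicted == cl & truth != cl)
      fnc <- sum(predicted != cl & truth == cl)
      tnc <- sum(predicted != cl & truth != cl)
      tp <- tp + tpc; fp <- fp + fpc; fn <- fn + fnc; tn <- tn + tnc
      if (tpc + fpc > 0) macro_p <- c(macro_p, tpc / (tpc + fpc))
      if (tpc + fnc > 0) macro_r <- c(macro_r, tpc / (tpc + fnc))
    }
    acc_simple <- mean(predicted == truth)
  } else {
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
    macro_p <- macro_r <- NA_real_
    acc_simple <- NA_real_
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, accuracy_simple = acc_simple,
                 precision_pct = 100 * precision, recall_pct = 100 * recall,
                 f1_pct = 100 * f1, accuracy_pct = 100 * accuracy,
                 macro_precision = mean(macro_p), macro_recall = mean(macro_r)),
            class = "recognition_report")
}

#' @export
print.recognition_report <- function(x, ...) {
  cat("Closed-set identification report\n")
  cat(sprintf("  counts: TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  if (!is.na(x$accuracy_simple))
    cat(sprintf("  fraction correct %.4f\n", x$accuracy_simple))
  invisible(x)
}

#' End-to-end identification on a normalized cycle set
#'
#' Splits a [cycle_set()] into enrollment (pre-exercise) and recognition
#' (post-exercise) observations, builds block features, applies discriminant
#' reduction, classifies, and scores.
#'
#' @param set a [cycle_set()] containing both states.
#' @param spec a [classifier_spec()].
#' @param block_size cycles per observation.
#' @param reduce apply [reduce_discriminant()] first? Default TRUE.
#' @return A `recognition_report` with the predictions in attribute
#'   `predicted`.
#' @export
identify_cohort <- function(set, spec = classifier_spec("knn"),
                            block_size = 2L, reduce = TRUE) {
  enroll <- build_features(subset_cycles(set, set$meta$state == "pre"), block_size)
  recog <- build_features(subset_cycles(set, set$meta$state == "post"), block_size)
  if (reduce && spec$kind != "lstm") {
    red <- reduce_discriminant(enroll, recog)
    enroll <- red$train; recog <- red$apply_to
  }
  pred <- train_and_identify(spec, enroll, recog)
  rep <- score_identification(pred, recog$labels)
  attr(rep, "predicted") <- pred
  rep
}
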