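# Automatic nasal/oral discrimination from LPC spectral descriptors.
#
# Each call is summarised by an order-8 LPC spectrogram (300 ms window,
# 30 ms step) over 0-500 Hz, averaged over time and block-subsampled to a
# 26-component envelope vector; LDA, a linear SVM and a nearest-neighbour
# classifier are trained on a stratified 1/3 split with 10-fold CV tuning
# and scored on the held-out 2/3.

#' Shared descriptor configuration
#'
#' One configuration object is used for both rumble types — descriptor
#' parameters are deliberately class-agnostic.
#'
#' @param window Analysis window in seconds (default 0.3).
#' @param step Window step in seconds (default 0.03).
#' @param order LPC model order (default 8).
#' @param fmax Upper band edge in Hz (default 500; calls are resampled to
#'   2 * fmax so the band is the full Nyquist range).
#' @param n_bins Envelope bins before subsampling (default 260).
#' @param n_components Descriptor length after block subsampling (default
#'   26).
#' @export
descriptor_config <- function(window = 0.3, step = 0.03, order = 8,
                              fmax = 500, n_bins = 260, n_components = 26) {
  stopifnot(n_bins %% n_components == 0)
  structure(list(window = window, step = step, order = order, fmax = fmax,
                 n_bins = n_bins, n_components = n_components),
            class = "descriptor_config")
}

#' LPC spectrogram of a call
#'
#' The call is resampled to `2 * fmax` Hz; each window is fitted with an
#' order-`order` LPC model whose dB envelope is evaluated on `n_bins`
#' frequencies over [0, fmax). Frame count is
#' `floor((duration - window) / step) + 1`; calls shorter than one window
#' fall back to a single full-call frame with a warning.
#'
#' @param call A `rumble_call`.
#' @param config A [descriptor_config()].
#' @return Matrix (frames x n_bins) of envelope dB values, with attributes
#'   `freqs` and `config`.
#' @export
lpc_spectrogram <- function(call, config = descriptor_config()) {
  fsd <- 2 * config$fmax
  x <- resample_to(call$waveform, call$sample_rate, fsd)
  nw <- round(config$window * fsd)
  hop <- round(config$step * fsd)
  freqs <- seq(0, config$fmax, length.out = config$n_bins + 1)[seq_len(config$n_bins)]
  if (length(x) < nw) {
    warning("call shorter than one descriptor window; using a single full-call frame")
    starts <- 1
    nw <- length(x)
  } else {
    n_frames <- floor((length(x) - nw) / hop) + 1
    starts <- (seq_len(n_frames) - 1) * hop + 1
  }
  env <- t(vapply(starts, function(i) {
    lp <- lpc_coeffs(x[i:(i + nw - 1)], config$order)
    lpc_envelope_db(lp, freqs, fsd)
  }, numeric(length(freqs))))
  attr(env, "freqs") <- freqs
  attr(env, "config") <- config
  env
}

#' Time-averaged, subsampled spectral descriptor
#'
#' Averages the LPC spectrogram over time (making the representation
#' time-invariant) and block-averages consecutive bins down to
#' `n_components` values.
#'
#' @param spectrogram Matrix from [lpc_spectrogram()].
#' @param n_components Output length (default from the attached config).
#' @return Numeric vector of length `n_components`.
#' @export
average_descriptor <- function(spectrogram, n_components = NULL) {
  config <- attr(spectrogram, "config")
  if (is.null(n_components)) {
    n_components <- if (!is.null(config)) config$n_components else 26
  }
  avg <- colMeans(spectrogram)
  block <- length(avg) / n_components
  if (block != round(block)) stop("bin count not divisible by n_components")
  as.numeric(tapply(avg, rep(seq_len(n_components), each = block), mean))
}

#' Descriptor table for a call population
#'
#' @param calls Tibble with `call` list-column, `call_id` and `emission`.
#' @param config A [descriptor_config()].
#' @return Tibble: `call_id`, `label`, `d01` ... `d26`.
#' @export
build_descriptors <- function(calls, config = descriptor_config()) {
  d <- t(vapply(calls$call, function(cl) {
    average_descriptor(lpc_spectrogram(cl, config))
  }, numeric(config$n_components)))
  colnames(d) <- sprintf("d%02d", seq_len(config$n_components))
  dplyr::bind_cols(
    tibble::tibble(call_id = calls$call_id, label = calls$emission),
    tibble::as_tibble(d)
  )
}

#' Stratified train/evaluation split
#'
#' @param descriptors Tibble with a `label` column.
#' @param train_fraction Fraction per class assigned to training (default
#'   1/3; the remaining 2/3 is the evaluation set).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return The tibble with a `set` column ("train"/"eval").
#' @export
split_dataset <- function(descriptors, train_fraction = 1 / 3, seed = 1) {
  counts <- table(descriptors$label)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need at least two samples of each class")
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(descriptors)), descriptors$label),
                  function(ix) sample(ix, max(round(length(ix) * train_fraction), 1))))
  })
  descriptors$set <- ifelse(seq_len(nrow(descriptors)) %in% idx, "train", "eval")
  descriptors
}

#' Exchange the training and evaluation sets of a split
#' @param split Tibble from [split_dataset()].
#' @export
swap_split <- function(split) {
  split$set <- ifelse(split$set == "train", "eval", "train")
  split
}

descriptor_cols <- function(tbl) grep("^d[0-9]+$", names(tbl), value = TRUE)

fold_assign <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

cv_accuracy <- function(x, y, k, seed, fit_predict) {
  folds <- fold_assign(length(y), k, seed)
  vapply(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    pred <- fit_predict(x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
}

fit_lda <- function(x, y) {
  # level removal leaves the components summing to zero, so one direction
  # is exactly collinear; that is expected, not a data problem
  quiet_lda <- function(x) {
    withCallingHandlers(
      MASS::lda(x, grouping = factor(y)),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  tryCatch(
    quiet_lda(x),
    error = function(e) {
      warning("LDA covariance degenerate; refitting with regularising jitter")
      xj <- x + matrix(rnorm(length(x), 0, 1e-6 * max(sd(x), 1e-9)),
                       nrow(x), ncol(x))
      quiet_lda(xj)
    }
  )
}

#' Tune and train the three linear classifiers
#'
#' Fits LDA (no tuned parameter), a linear-kernel SVM (cost selected by
#' `k`-fold cross-validation) and a nearest-neighbour classifier (k
#' selected the same way) on the training rows of a split descriptor
#' table.
#'
#' @param split Tibble from [split_dataset()] (rows with `set == "train"`
#'   are used).
#' @param k Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param svm_costs Candidate SVM cost values.
#' @param knn_k Candidate neighbourhood sizes.
#' @return A `rumble_classifiers` object; [tidy()] returns the CV scores,
#'   [glance()] the chosen parameters.
#' @export
tune_and_train <- function(split, k = 10, seed = 1,
                           svm_costs = 10^seq(-2, 2), knn_k = c(1, 3, 5, 7)) {
  train <- split[split$set == "train", ]
  if (nrow(train) < 4) stop("training set too small to cross-validate")
  if (nrow(train) < k) {
    warning("fewer training calls than CV folds; using k = ", nrow(train))
    k <- nrow(train)
  }
  cols <- descriptor_cols(train)
  x <- as.matrix(train[, cols])
  y <- factor(train$label)
  # remove each call's overall level, then z-score per component from the
  # training set: the distance-based classifiers must compare spectral
  # envelope shape, not recording level
  x <- x - rowMeans(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  x <- sweep(sweep(x, 2, center), 2, scale_, "/")

  cv <- list()
  cv$lda <- tibble::tibble(
    classifier = "lda", parameter = NA_real_,
    fold = seq_len(k),
    accuracy = cv_accuracy(x, y, k, seed, function(xt, yt, xe) {
      predict(fit_lda(xt, yt), xe)$class
    })
  )
  cv$svm <- dplyr::bind_rows(lapply(svm_costs, function(cost) {
    tibble::tibble(
      classifier = "svm", parameter = cost, fold = seq_len(k),
      accuracy = cv_accuracy(x, y, k, seed, function(xt, yt, xe) {
        fit <- e1071::svm(xt, yt, kernel = "linear", cost = cost, scale = FALSE)
        predict(fit, xe)
      })
    )
  }))
  cv$nn <- dplyr::bind_rows(lapply(knn_k, function(kk) {
    tibble::tibble(
      classifier = "nn", parameter = kk, fold = seq_len(k),
      accuracy = cv_accuracy(x, y, k, seed, function(xt, yt, xe) {
        class::knn(xt, xe, yt, k = kk)
      })
    )
  }))
  cv_tbl <- dplyr::bind_rows(cv)

  pick <- function(tbl) {
    means <- dplyr::summarise(dplyr::group_by(tbl, .data$parameter),
                              acc = mean(.data$accuracy, na.rm = TRUE))
    means$parameter[which.max(means$acc)]
  }
  best_cost <- pick(cv$svm)
  best_k <- pick(cv$nn)

  structure(
    list(
      lda = fit_lda(x, y),
      svm = e1071::svm(x, y, kernel = "linear", cost = best_cost, scale = FALSE),
      nn = list(x = x, y = y, k = best_k),
      best = list(svm_cost = best_cost, knn_k = best_k),
      cv = cv_tbl,
      feature_cols = cols,
      center = center,
      scale = scale_,
      n_train = nrow(train)
    ),
    class = "rumble_classifiers"
  )
}

#' @export
print.rumble_classifiers <- function(x, ...) {
  cat(sprintf("<rumble_classifiers: LDA + linear SVM (cost %g) + %d-NN, trained on %d calls>\n",
              x$best$svm_cost, x$best$knn_k, x$n_train))
  invisible(x)
}

#' @export
tidy.rumble_classifiers <- function(x, ...) x$cv

#' @export
glance.rumble_classifiers <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, svm_cost = x$best$svm_cost,
                 knn_k = x$best$knn_k,
                 mean_cv_accuracy = mean(x$cv$accuracy, na.rm = TRUE))
}

predict_all <- function(classifiers, x) {
  x <- x - rowMeans(x)
  x <- sweep(sweep(x, 2, classifiers$center), 2, classifiers$scale, "/")
  list(
    lda = as.character(predict(classifiers$lda, x)$class),
    svm = as.character(predict(classifiers$svm, x)),
    nn = as.character(class::knn(classifiers$nn$x, x, classifiers$nn$y,
                                 k = classifiers$nn$k))
  )
}

#' Evaluate trained classifiers on the held-out set
#'
#' @param classifiers A `rumble_classifiers` object.
#' @param split Tibble from [split_dataset()] (rows with `set == "eval"`
#'   are scored).
#' @return A `rumble_eval` object; [tidy()] gives per-classifier accuracy
#'   and confusion counts, [glance()] the accuracy range.
#' @export
evaluate <- function(classifiers, split) {
  eval_set <- split[split$set == "eval", ]
  x <- as.matrix(eval_set[, classifiers$feature_cols])
  y <- eval_set$label
  preds <- predict_all(classifiers, x)
  per <- dplyr::bind_rows(lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    tibble::tibble(
      classifier = nm,
      accuracy = mean(p == y),
      n_eval = length(y),
      tp_nasal = sum(p == "nasal" & y == "nasal"),
      fp_nasal = sum(p == "nasal" & y == "oral"),
      tp_oral = sum(p == "oral" & y == "oral"),
      fp_oral = sum(p == "oral" & y == "nasal")
    )
  }))
  structure(list(scores = per, predictions = preds, truth = y),
            class = "rumble_eval")
}

#' @export
print.rumble_eval <- function(x, ...) {
  s <- x$scores
  cat("<rumble_eval>\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s accuracy %.3f (n = %d)\n",
                s$classifier[i], s$accuracy[i], s$n_eval[i]))
  }
  invisible(x)
}

#' @export
tidy.rumble_eval <- function(x, ...) x$scores

#' @export
glance.rumble_eval <- function(x, ...) {
  tibble::tibble(min_accuracy = min(x$scores$accuracy),
                 max_accuracy = max(x$scores$accuracy),
                 n_eval = x$scores$n_eval[1])
}

#' Full classification experiment with swap replicate
#'
#' Splits the descriptor table 1/3 train, 2/3 evaluation (stratified),
#' tunes and trains the three classifiers with `k`-fold CV, scores the
#' held-out set, then exchanges training and evaluation sets and repeats.
#'
#' @param descriptors Tibble from [build_descriptors()].
#' @param train_fraction Training fraction (default 1/3).
#' @param k CV folds (default 10).
#' @param seed Seed for split and folds.
#' @return List with `split`, `classifiers`, `eval` (`rumble_eval`),
#'   `swap_eval`, and `accuracies` tibble (classifier, accuracy,
#'   swap_accuracy).
#' @export
classify_experiment <- function(descriptors, train_fraction = 1 / 3, k = 10,
                                seed = 1) {
  split <- split_dataset(descriptors, train_fraction, seed = seed)
  clf <- tune_and_train(split, k = k, seed = seed)
  ev <- evaluate(clf, split)
  swapped <- swap_split(split)
  clf_swap <- tune_and_train(swapped, k = k, seed = seed)
  ev_swap <- evaluate(clf_swap, swapped)
  acc <- dplyr::left_join(
    dplyr::select(ev$scores, "classifier", accuracy = "accuracy"),
    dplyr::select(ev_swap$scores, "classifier", swap_accuracy = "accuracy"),
    by = "classifier"
  )
  list(split = split, classifiers = clf, eval = ev, swap_eval = ev_swap,
       accuracies = acc)
}
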