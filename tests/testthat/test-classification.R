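test_that("LPC spectrogram frame counts and stationarity behave", {
  cl <- test_call(2.0, 20, duration = 2.0, seed = 23)
  sg <- lpc_spectrogram(cl)
  expect_equal(nrow(sg), 57)          # floor((2.0 - 0.3) / 0.03) + 1
  expect_equal(ncol(sg), 260)

  # stationary tone: all frames nearly identical
  tone <- structure(list(waveform = sin(2 * pi * 150 * (0:95999) / 48000),
                         sample_rate = 48000), class = "rumble_call")
  sgt <- lpc_spectrogram(tone)
  expect_lt(max(apply(sgt[2:(nrow(sgt) - 1), ], 2, function(col) diff(range(col)))), 1)

  # class spectral signatures: nasal energy low, oral energy mid-band
  freqs <- attr(sg, "freqs")
  avg_nasal <- colMeans(sg)
  expect_lt(freqs[which.max(avg_nasal)], 150)
  oral <- test_call(0.7, 27, duration = 2.0, seed = 23)
  avg_oral <- colMeans(lpc_spectrogram(oral))
  expect_true(freqs[which.max(avg_oral)] > 100 && freqs[which.max(avg_oral)] < 500)

  expect_warning(single <- lpc_spectrogram(test_call(0.7, 27, duration = 0.2,
                                                     seed = 24)),
                 "single")
  expect_equal(nrow(single), 1)
})

test_that("descriptors are 26-long, time invariant and block-averaged", {
  cl <- test_call(0.7, 27, duration = 1.5, seed = 25)
  sg <- lpc_spectrogram(cl)
  d <- average_descriptor(sg)
  expect_length(d, 26)
  # frame-order permutation changes nothing
  perm <- withr::with_seed(26, sg[sample(nrow(sg)), ])
  attr(perm, "config") <- attr(sg, "config")
  expect_equal(average_descriptor(perm), d, tolerance = 1e-12)
  # a single-frame spectrogram subsamples to itself
  one <- sg[1, , drop = FALSE]
  attr(one, "config") <- attr(sg, "config")
  expect_equal(average_descriptor(one),
               as.numeric(tapply(sg[1, ], rep(1:26, each = 10), mean)),
               tolerance = 1e-12)
})

test_that("stratified splits honour fractions, determinism and disjointness", {
  withr::with_seed(27, {
    desc <- tibble::tibble(
      call_id = sprintf("c%03d", 1:167),
      label = rep(c("nasal", "oral"), c(115, 52))
    )
    desc <- dplyr::bind_cols(desc, tibble::as_tibble(
      matrix(rnorm(167 * 26), 167, 26, dimnames = list(NULL, sprintf("d%02d", 1:26)))))
  })
  sp <- split_dataset(desc, seed = 7)
  expect_true(sum(sp$set == "train") %in% 54:57)
  expect_equal(sum(sp$set == "eval"), 167 - sum(sp$set == "train"))
  # stratification: both classes appear in the training third
  expect_equal(sum(sp$set == "train" & sp$label == "nasal"), round(115 / 3))
  expect_equal(sum(sp$set == "train" & sp$label == "oral"), round(52 / 3))
  expect_identical(sp, split_dataset(desc, seed = 7))
  expect_false(identical(sp$set, split_dataset(desc, seed = 8)$set))
  # swap exchanges the sets exactly
  sw <- swap_split(sp)
  expect_equal(sw$set == "train", sp$set == "eval")
  expect_error(split_dataset(desc[desc$label == "nasal", ]), "two samples")
})

test_that("cross-validation separates separable data and not shuffled labels", {
  withr::with_seed(28, {
    n <- 60
    x <- matrix(rnorm(n * 26), n, 26)
    y <- rep(c("nasal", "oral"), each = n / 2)
    # cleanly separable by envelope shape (a level offset alone would be
    # removed by the per-call normalization)
    x[y == "oral", 1:13] <- x[y == "oral", 1:13] + 8
    x[y == "oral", 14:26] <- x[y == "oral", 14:26] - 8
    desc <- dplyr::bind_cols(
      tibble::tibble(call_id = sprintf("c%02d", 1:n), label = y),
      tibble::as_tibble(`colnames<-`(x, sprintf("d%02d", 1:26)))
    )
  })
  desc$set <- "train"
  clf <- tune_and_train(desc, k = 10, seed = 1)
  expect_true(all(clf$cv$accuracy == 1, na.rm = TRUE))

  # permutation null: accuracy near chance
  withr::with_seed(29, desc$label <- sample(desc$label))
  clf0 <- tune_and_train(desc, k = 10, seed = 1)
  acc0 <- mean(clf0$cv$accuracy[clf0$cv$classifier == "lda"], na.rm = TRUE)
  expect_gt(acc0, 0.2)
  expect_lt(acc0, 0.8)

  # determinism of fitted decisions
  clf2 <- tune_and_train(dplyr::mutate(desc), k = 10, seed = 1)
  expect_identical(glance(clf2), glance(clf0))
})

test_that("evaluation reports coherent accuracies and confusions", {
  withr::with_seed(30, {
    n <- 90
    x <- matrix(rnorm(n * 26), n, 26)
    y <- rep(c("nasal", "oral"), length.out = n)
    x[y == "oral", 2] <- x[y == "oral", 2] + 8
    desc <- dplyr::bind_cols(
      tibble::tibble(call_id = sprintf("c%02d", 1:n), label = y),
      tibble::as_tibble(`colnames<-`(x, sprintf("d%02d", 1:26)))
    )
  })
  sp <- split_dataset(desc, seed = 3)
  clf <- tune_and_train(sp, k = 5, seed = 3)
  ev <- evaluate(clf, sp)
  scores <- tidy(ev)
  expect_setequal(scores$classifier, c("lda", "svm", "nn"))
  expect_true(all(scores$accuracy >= 0 & scores$accuracy <= 1))
  n_eval <- sum(sp$set == "eval")
  expect_true(all(scores$n_eval == n_eval))
  # confusion counts partition the evaluation set
  expect_true(all(scores$tp_nasal + scores$fp_nasal +
                    scores$tp_oral + scores$fp_oral == n_eval))
  # training-set accuracy (diagnostic) is at least the held-out accuracy
  train_as_eval <- sp
  train_as_eval$set <- ifelse(sp$set == "train", "eval", "train")
  ev_train <- evaluate(clf, train_as_eval)
  expect_true(all(tidy(ev_train)$accuracy >= scores$accuracy - 1e-9))
})
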