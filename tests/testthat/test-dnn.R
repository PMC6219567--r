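make_blobs <- function(n, p = 2, sep = 2.5, seed = 1) {
  set.seed(seed)
  y <- rep(c("nuclear", "cytosolic"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[y == "nuclear", 1] <- x[y == "nuclear", 1] + sep
  list(x = x, y = y)
}

fast_cfg <- function(...) {
  base <- list(hidden = c(16, 16, 8), input_dropout = 0, hidden_dropout = 0.2,
               l1 = 1e-5, l2 = 1e-4, learning_rate = 0.05, epochs = 30,
               batch_size = 32, patience = 30, seed = 3)
  do.call(dnn_config, utils::modifyList(base, list(...)))
}

test_that("standardization is fit on train only and guards zero variance", {
  set.seed(6)
  x <- cbind(a = rnorm(50, 10, 2), b = rep(3, 50), c = runif(50))
  sc <- standardize(x)
  expect_true(sc$zero_var[["b"]])
  xs <- apply_standardize(sc, x)
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_equal(unname(apply(xs[, c("a", "c")], 2, sd)), c(1, 1))
  expect_equal(unname(xs[, "b"]), rep(0, 50))

  # applied to a different sample, means are generally nonzero (no leakage)
  x2 <- cbind(a = rnorm(50, 12, 2), b = rep(3, 50), c = runif(50, 2, 3))
  xs2 <- apply_standardize(sc, x2)
  expect_gt(abs(mean(xs2[, "a"])), 0.1)
  expect_gt(abs(mean(xs2[, "c"])), 1)
})

test_that("the network separates linearly separable data (capacity check)", {
  d <- make_blobs(400, sep = 4)
  fit <- dnn_localizer(d$x, d$y,
                       config = fast_cfg(hidden_dropout = 0, epochs = 40))
  train_mis <- mean(predict(fit, d$x, type = "class") != d$y)
  expect_lt(train_mis, 0.02)
})

test_that("training is deterministic for a fixed seed", {
  d <- make_blobs(200)
  f1 <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 10))
  f2 <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 10))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  f3 <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 10, seed = 4))
  expect_false(identical(f1$weights, f3$weights))
})

test_that("label-permuted data yields chance-level validation accuracy", {
  d <- make_blobs(1200, sep = 2.5, seed = 10)
  set.seed(55)
  y_perm <- sample(d$y)
  tr <- 1:800; va <- 801:1200
  fit <- dnn_localizer(d$x[tr, ], y_perm[tr], d$x[va, ], y_perm[va],
                       config = fast_cfg(epochs = 15))
  val_acc <- 1 - min(fit$history$val_misclass)
  # "best epoch" selection is optimistically biased, so allow the band's
  # upper side only after accounting for it
  expect_gt(val_acc, 0.45)
  expect_lt(val_acc, 0.62)
})

test_that("predictions are valid probabilities, deterministic, and registry-checked", {
  d <- make_blobs(200)
  fit <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 5))
  p <- predict(fit, d$x)
  expect_equal(colnames(p), c("P_nuclear", "P_cytosolic"))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)

  dup <- d$x[c(1, 1), ]
  pd <- predict(fit, dup)
  expect_identical(pd[1, ], pd[2, ])

  bad <- d$x
  colnames(bad) <- c("f1", "oops")
  expect_error(predict(fit, bad), "registry")
  nax <- d$x; nax[1, 1] <- NA
  expect_error(predict(fit, nax), "missing")
})

test_that("classification uses a strict cutoff with ties going cytosolic", {
  expect_identical(as.character(classify(c(0.83, 0.5, 0.2))),
                   c("nuclear", "cytosolic", "cytosolic"))
  p <- cbind(P_nuclear = c(0.7, 0.3), P_cytosolic = c(0.3, 0.7))
  expect_identical(as.character(classify(p)), c("nuclear", "cytosolic"))
})

test_that("cutoff sweep reproduces ROC operating points", {
  d <- make_blobs(300, sep = 1.5, seed = 12)
  fit <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 10))
  p_nuc <- predict(fit, d$x)[, "P_nuclear"]
  ra <- roc_auc(p_nuc, d$y)
  for (cut in c(0.25, 0.5, 0.75)) {
    cm <- confusion(classify(p_nuc, cut), d$y)
    tpr <- cm[["TP"]] / (cm[["TP"]] + cm[["FN"]])
    fpr <- cm[["FP"]] / (cm[["FP"]] + cm[["TN"]])
    # the swept curve passes through this operating point
    i <- max(which(ra$roc$cutoff > cut))
    expect_equal(ra$roc$tpr[i], tpr)
    expect_equal(ra$roc$fpr[i], fpr)
  }
})

test_that("strong weight penalties shrink weight norms", {
  d <- make_blobs(200, seed = 2)
  weak <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 15, l2 = 1e-6))
  strong <- dnn_localizer(d$x, d$y, config = fast_cfg(epochs = 15, l2 = 0.05))
  norm <- function(fit) sqrt(sum(unlist(lapply(coef(fit)$W,
                                               function(w) sum(w^2)))))
  expect_lt(norm(strong), 0.5 * norm(weak))

  strong_l1 <- dnn_localizer(d$x, d$y,
                             config = fast_cfg(epochs = 15, l1 = 0.05))
  expect_lt(norm(strong_l1), 0.5 * norm(weak))
})

test_that("permutation importance recovers the designated signal features", {
  # class is a logistic function of 3 designated features among 40
  set.seed(91)
  n <- 800; p <- 40
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- 2 * x[, 1] - 2 * x[, 2] + 1.5 * x[, 3]
  y <- ifelse(runif(n) < plogis(eta), "nuclear", "cytosolic")
  tr <- 1:600; va <- 601:800
  fit <- dnn_localizer(x[tr, ], y[tr], x[va, ], y[va],
                       config = fast_cfg(epochs = 25))
  base_acc <- mean(predict(fit, x[va, ], type = "class") == y[va])
  set.seed(92)
  drop <- vapply(1:p, function(j) {
    xp <- x[va, ]
    xp[, j] <- sample(xp[, j])
    base_acc - mean(predict(fit, xp, type = "class") == y[va])
  }, numeric(1))
  top4 <- order(drop, decreasing = TRUE)[1:4]  # top decile of 40 features
  expect_true(all(1:3 %in% top4))
})

test_that("random search minimizes validation misclassification deterministically", {
  d <- make_blobs(300, sep = 3, seed = 30)
  tr <- 1:200; va <- 201:300
  space <- list(hidden = list(c(8, 8, 4)),
                learning_rate = c(0.05, 1e-6))
  one <- random_search(d$x[tr, ], d$y[tr], d$x[va, ], d$y[va],
                       space = space, budget = 1, seed = 2, epochs = 8)
  expect_s3_class(one$best_config, "dnn_config")
  expect_equal(nrow(one$trials), 1)

  res <- random_search(d$x[tr, ], d$y[tr], d$x[va, ], d$y[va],
                       space = space, budget = 6, seed = 2, epochs = 8)
  expect_true(any(res$trials$learning_rate == 0.05))
  expect_true(any(res$trials$learning_rate == 1e-6))
  # the workable rate beats the degenerate one
  expect_equal(res$best_config$learning_rate, 0.05)
  res2 <- random_search(d$x[tr, ], d$y[tr], d$x[va, ], d$y[va],
                        space = space, budget = 6, seed = 2, epochs = 8)
  expect_identical(res$trials, res2$trials)

  expect_error(random_search(d$x[tr, ], d$y[tr], d$x[va, ], d$y[va],
                             space = list(l1 = numeric(0)), budget = 2),
               "empty")
})

test_that("training aborts with diagnostics on divergence and validates inputs", {
  set.seed(44)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("f1", "f2")))
  y_rand <- sample(c("nuclear", "cytosolic"), 100, replace = TRUE)
  expect_error(
    dnn_localizer(x, y_rand,
                  config = fast_cfg(learning_rate = 1e4, epochs = 10,
                                    l2 = 0, l1 = 0)),
    "learning_rate")
  d <- make_blobs(100, sep = 3, seed = 44)
  expect_error(dnn_localizer(d$x, rep("up", 100)), "nuclear")
  expect_error(dnn_localizer(d$x, d$y[-1]), "differ")
  bad_val <- d$x
  colnames(bad_val) <- c("f1", "zz")
  expect_error(dnn_localizer(d$x, d$y, bad_val, d$y), "registry")
})
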