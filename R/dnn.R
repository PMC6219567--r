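#' Network configuration
#'
#' Hyperparameters of the localization network. The architecture is fixed by
#' design — an input layer, three ReLU hidden layers and a two-unit softmax
#' output — while everything the training procedure needs is configurable
#' and selected in practice by [random_search()] on validation
#' misclassification.
#'
#' @param hidden Integer vector of hidden-layer sizes (default
#'   `c(128, 128, 64)`).
#' @param input_dropout Dropout rate on the input features during training,
#'   in `[0, 1)` (default 0.1).
#' @param hidden_dropout Dropout rate on each hidden layer's activations
#'   during training (default 0.5, i.e. half the connections masked).
#' @param l1,l2 Non-negative L1/L2 weight-penalty coefficients added to the
#'   cross-entropy cost (biases are not penalized).
#' @param learning_rate Positive SGD step size.
#' @param momentum Classical momentum coefficient in `[0, 1)` (default
#'   0.9; set to 0 for plain SGD).
#' @param epochs Maximum number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without improvement in validation misclassification; the weights
#'   from the best epoch are kept. Use `Inf` to disable.
#' @param seed Integer seed fixing weight initialization, batch order and
#'   dropout masks; a fixed seed makes training fully reproducible.
#' @return List of class `dnn_config`.
#' @export
dnn_config <- function(hidden = c(128L, 128L, 64L), input_dropout = 0.1,
                       hidden_dropout = 0.5, l1 = 3e-3, l2 = 1e-3,
                       learning_rate = 0.005, momentum = 0.9, epochs = 100L,
                       batch_size = 64L, patience = 25L, seed = 1L) {
  stopifnot(all(hidden >= 1), input_dropout >= 0, input_dropout < 1,
            hidden_dropout >= 0, hidden_dropout < 1, l1 >= 0, l2 >= 0,
            learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1,
            batch_size >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), input_dropout = input_dropout,
                 hidden_dropout = hidden_dropout, l1 = l1, l2 = l2,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), patience = patience,
                 seed = as.integer(seed)),
            class = "dnn_config")
}

#' @export
print.dnn_config <- function(x, ...) {
  cat("Network configuration\n")
  cat("  hidden layers :", paste(x$hidden, collapse = "-"), "(ReLU)\n")
  cat(sprintf("  dropout       : input %.2f, hidden %.2f\n",
              x$input_dropout, x$hidden_dropout))
  cat(sprintf("  penalties     : l1 %g, l2 %g\n", x$l1, x$l2))
  cat(sprintf("  SGD           : lr %g, momentum %g, %d epochs, batch %d\n",
              x$learning_rate, x$momentum, x$epochs, x$batch_size))
  cat(sprintf("  patience %s, seed %d\n",
              format(x$patience), x$seed))
  invisible(x)
}

#' Standardization parameters from a training matrix
#'
#' Per-feature mean and standard deviation computed on the training split
#' only; applying them to validation or test data therefore cannot leak
#' information. Zero-variance features are centered but not scaled (their
#' sd is treated as 1) and flagged.
#'
#' @param x Numeric training matrix.
#' @return List of class `dnn_scaler`: `center`, `scale`, `zero_var`
#'   (logical flags).
#' @export
standardize <- function(x) {
  stopifnot(is.matrix(x) || inherits(x, "lnc_features"), nrow(x) >= 1L)
  x <- unclass(x)
  center <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  zero_var <- !is.finite(sds) | sds < .Machine$double.eps
  sds[zero_var] <- 1
  structure(list(center = center, scale = sds, zero_var = zero_var),
            class = "dnn_scaler")
}

#' Apply standardization parameters to any matrix
#'
#' @param scaler `dnn_scaler` from [standardize()].
#' @param x Matrix with the same columns as the training matrix.
#' @return Standardized matrix.
#' @export
apply_standardize <- function(scaler, x) {
  stopifnot(inherits(scaler, "dnn_scaler"),
            identical(colnames(x), names(scaler$center)))
  sweep(sweep(unclass(x), 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

dnn_classes <- function() c("nuclear", "cytosolic")

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

init_weights <- function(sizes) {
  # He initialization for the ReLU layers
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (i in seq_along(W)) {
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                  sd = sqrt(2 / sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- numeric(sizes[i + 1L])
  }
  list(W = W, b = b)
}

forward_pass <- function(W, b, x) {
  n_layer <- length(W)
  a <- x
  for (i in seq_len(n_layer - 1L)) {
    a <- relu(sweep(a %*% W[[i]], 2L, b[[i]], "+"))
  }
  softmax_rows(sweep(a %*% W[[n_layer]], 2L, b[[n_layer]], "+"))
}

# Cross-entropy (mean, natural log) with probability clipping.
xent <- function(p, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
}

#' Fit the localization network
#'
#' Trains a feed-forward neural network mapping transcript feature vectors
#' to nuclear/cytosolic class probabilities: three ReLU hidden layers, a
#' softmax output, inverted dropout on the inputs and on every hidden
#' layer's activations (active only during training), L1/L2 weight
#' penalties, mini-batch stochastic gradient descent by backpropagation,
#' and early stopping on validation misclassification. The positive class
#' is `nuclear` throughout.
#'
#' Features are standardized internally using parameters computed on the
#' training split only; the fitted scaler travels with the model and is
#' applied automatically by [predict.dnn_localizer()].
#'
#' @param x Training feature matrix (rows = transcripts); typically an
#'   `lnc_features` matrix from [assemble_feature_matrix()].
#' @param y Training labels: factor or character over
#'   \{"nuclear", "cytosolic"\}, aligned with `x` rows.
#' @param val_x,val_y Optional validation split (same feature registry);
#'   used for the early-stopping criterion and the history. When absent the
#'   training split itself is monitored.
#' @param config `dnn_config` object.
#' @return Object of class `dnn_localizer` with elements `weights`
#'   (list of `W`, `b`), `scaler`, `registry` (column names the model
#'   accepts), `registry_hash`, `config`, `history` (per-epoch data frame
#'   of train/val loss and misclassification), `best_epoch`, `classes`.
#' @seealso [predict.dnn_localizer()], [random_search()], [classify()]
#' @export
dnn_localizer <- function(x, y, val_x = NULL, val_y = NULL,
                          config = dnn_config()) {
  stopifnot(inherits(config, "dnn_config"))
  x <- as.matrix(unclass(x))
  y <- as.character(y)
  if (!all(y %in% dnn_classes())) {
    stop("labels must be 'nuclear' or 'cytosolic'")
  }
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  has_val <- !is.null(val_x)
  if (has_val) {
    if (!identical(colnames(val_x), colnames(x))) {
      stop("validation matrix has a different feature registry")
    }
    val_y <- as.character(val_y)
    stopifnot(all(val_y %in% dnn_classes()), nrow(val_x) == length(val_y))
  }
  scaler <- standardize(x)
  xs <- apply_standardize(scaler, x)
  vs <- if (has_val) apply_standardize(scaler, as.matrix(unclass(val_x)))
  y_onehot <- outer(y, dnn_classes(), "==") * 1
  vy_onehot <- if (has_val) outer(val_y, dnn_classes(), "==") * 1

  fit <- with_local_seed(config$seed,
                         train_loop(xs, y_onehot, vs, vy_onehot, config))

  structure(list(weights = fit$weights, scaler = scaler,
                 registry = colnames(x),
                 registry_hash = fnv1a_hash(colnames(x)),
                 config = config, history = fit$history,
                 best_epoch = fit$best_epoch, classes = dnn_classes(),
                 n_train = nrow(x)),
            class = "dnn_localizer")
}

train_loop <- function(xs, y_onehot, vs, vy_onehot, config) {
  n <- nrow(xs)
  sizes <- c(ncol(xs), config$hidden, 2L)
  par <- init_weights(sizes)
  vel <- lapply(par$W, function(w) w * 0)
  velb <- lapply(par$b, function(b) b * 0)
  n_layer <- length(par$W)
  lr <- config$learning_rate
  history <- data.frame()
  best <- list(mis = Inf, weights = par, epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- xs[idx, , drop = FALSE]
      yb <- y_onehot[idx, , drop = FALSE]
      m <- length(idx)

      # forward with inverted dropout
      if (config$input_dropout > 0) {
        keep <- 1 - config$input_dropout
        xb <- xb * (matrix(stats::runif(m * ncol(xb)), m) < keep) / keep
      }
      acts <- vector("list", n_layer)  # post-dropout inputs to each layer
      pre <- vector("list", n_layer)   # pre-activations
      a <- xb
      for (i in seq_len(n_layer - 1L)) {
        acts[[i]] <- a
        z <- sweep(a %*% par$W[[i]], 2L, par$b[[i]], "+")
        pre[[i]] <- z
        a <- relu(z)
        if (config$hidden_dropout > 0) {
          keep <- 1 - config$hidden_dropout
          a <- a * (matrix(stats::runif(m * ncol(a)), m) < keep) / keep
        }
      }
      acts[[n_layer]] <- a
      p <- softmax_rows(sweep(a %*% par$W[[n_layer]], 2L,
                              par$b[[n_layer]], "+"))
      if (any(!is.finite(p))) {
        stop(sprintf(paste0("NaN/Inf in network output at epoch %d; ",
                            "try a smaller learning_rate (current %g)"),
                     epoch, lr))
      }

      # backward
      delta <- (p - yb) / m
      for (i in n_layer:1) {
        gW <- crossprod(acts[[i]], delta) +
          config$l1 * sign(par$W[[i]]) + 2 * config$l2 * par$W[[i]]
        gb <- colSums(delta)
        if (i > 1L) {
          delta <- (delta %*% t(par$W[[i]])) * (pre[[i - 1L]] > 0)
        }
        vel[[i]] <- config$momentum * vel[[i]] - lr * gW
        velb[[i]] <- config$momentum * velb[[i]] - lr * gb
        par$W[[i]] <- par$W[[i]] + vel[[i]]
        par$b[[i]] <- par$b[[i]] + velb[[i]]
      }
    }

    p_tr <- forward_pass(par$W, par$b, xs)
    tr_mis <- mean(max.col(p_tr) != max.col(y_onehot))
    tr_loss <- xent(p_tr, y_onehot)
    if (!is.null(vs)) {
      p_v <- forward_pass(par$W, par$b, vs)
      v_mis <- mean(max.col(p_v) != max.col(vy_onehot))
      v_loss <- xent(p_v, vy_onehot)
    } else {
      v_mis <- tr_mis
      v_loss <- tr_loss
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr_loss, train_misclass = tr_mis,
      val_loss = v_loss, val_misclass = v_mis))
    if (v_mis < best$mis) {
      best <- list(mis = v_mis, weights = par, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  list(weights = best$weights, history = history, best_epoch = best$epoch)
}

#' Predict localization probabilities or labels
#'
#' Applies the fitted scaler and network (dropout disabled) to new feature
#' rows. The model refuses matrices whose column registry differs from the
#' one it was trained on.
#'
#' @param object `dnn_localizer` fit.
#' @param newdata Feature matrix with the model's registry.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param cutoff Probability cutoff on the nuclear class for `type =
#'   "class"` (default 0.5; prediction is nuclear iff `P(nuclear) > cutoff`).
#' @param ... Unused.
#' @return For `"prob"`, a matrix with columns `P_nuclear`, `P_cytosolic`
#'   (rows sum to 1); for `"class"`, a factor over the class levels.
#' @export
predict.dnn_localizer <- function(object, newdata, type = c("prob", "class"),
                                  cutoff = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(unclass(newdata))
  if (!identical(colnames(newdata), object$registry)) {
    stop("feature registry mismatch: this model was trained on a ",
         "different column registry (hash ", object$registry_hash, ")")
  }
  if (anyNA(newdata)) stop("newdata contains missing values")
  xs <- apply_standardize(object$scaler, newdata)
  p <- forward_pass(object$weights$W, object$weights$b, xs)
  colnames(p) <- paste0("P_", object$classes)
  rownames(p) <- rownames(newdata)
  if (type == "prob") p else classify(p, cutoff)
}

#' Hard-label a probability matrix or vector
#'
#' @param proba Matrix with a `P_nuclear` column (e.g. from
#'   [predict.dnn_localizer()]) or a numeric vector of nuclear
#'   probabilities.
#' @param cutoff Decision cutoff; the call is `nuclear` iff
#'   `P(nuclear) > cutoff` (strictly), so a tie at the cutoff is cytosolic.
#' @return Factor over \{nuclear, cytosolic\}.
#' @examples
#' classify(c(0.83, 0.5, 0.2))
#' @export
classify <- function(proba, cutoff = 0.5) {
  p_nuc <- if (is.matrix(proba)) proba[, "P_nuclear"] else proba
  stopifnot(all(p_nuc >= 0 & p_nuc <= 1))
  factor(ifelse(p_nuc > cutoff, "nuclear", "cytosolic"),
         levels = dnn_classes())
}

#' @export
print.dnn_localizer <- function(x, ...) {
  cat("Feed-forward lncRNA localization network\n")
  cat(sprintf("  inputs  : %d features (registry %s)\n",
              length(x$registry), x$registry_hash))
  cat("  hidden  :", paste(x$config$hidden, collapse = "-"), "(ReLU)\n")
  cat("  output  : softmax over", paste(x$classes, collapse = "/"), "\n")
  h <- x$history
  cat(sprintf("  trained : %d epochs on %d rows; best epoch %d (val misclass %.4f)\n",
              nrow(h), x$n_train, x$best_epoch, min(h$val_misclass)))
  invisible(x)
}

#' @method summary dnn_localizer
#' @export
summary.dnn_localizer <- function(object, ...) {
  h <- object$history
  out <- list(
    n_features = length(object$registry),
    n_parameters = n_parameters(object$config$hidden,
                                length(object$registry)),
    config = object$config,
    epochs_run = nrow(h),
    best_epoch = object$best_epoch,
    best_val_misclass = min(h$val_misclass),
    final_train_loss = h$train_loss[nrow(h)]
  )
  class(out) <- "summary.dnn_localizer"
  out
}

#' @export
print.summary.dnn_localizer <- function(x, ...) {
  cat(sprintf("Localization network: %d features, %d trainable parameters\n",
              x$n_features, x$n_parameters))
  print(x$config)
  cat(sprintf("Ran %d epochs; best epoch %d, validation misclassification %.4f\n",
              x$epochs_run, x$best_epoch, x$best_val_misclass))
  invisible(x)
}

#' @method coef dnn_localizer
#' @export
coef.dnn_localizer <- function(object, ...) {
  object$weights
}

#' Plot training history
#'
#' Loss and misclassification per epoch for the training and validation
#' splits, with the best (early-stopping) epoch marked.
#'
#' @param x `dnn_localizer` fit.
#' @param ... Passed to [graphics::matplot()].
#' @method plot dnn_localizer
#' @export
plot.dnn_localizer <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_misclass, h$val_misclass),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "misclassification", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

n_parameters <- function(hidden, n_in) {
  sizes <- c(n_in, hidden, 2L)
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

#' Random hyperparameter search
#'
#' Draws `budget` configurations uniformly from the candidate grid and
#' trains each on the training split, keeping the configuration with the
#' lowest validation misclassification. Ties are broken by smaller
#' parameter count, then by earlier draw. The full trial log is returned.
#'
#' @param x,y,val_x,val_y Train/validation splits as in [dnn_localizer()].
#' @param space Named list of candidate values: `hidden` (list of integer
#'   vectors) and numeric vectors for `input_dropout`, `hidden_dropout`,
#'   `l1`, `l2`, `learning_rate`; any omitted entry keeps the
#'   [dnn_config()] default.
#' @param budget Number of configurations to try (>= 1).
#' @param seed Integer seed for the draw sequence and for every trial's
#'   training.
#' @param epochs,batch_size,patience Fixed training-loop settings shared by
#'   all trials.
#' @return List with `best_config` (a `dnn_config`), `best_model`
#'   (its fitted `dnn_localizer`) and `trials` (data frame: one row per
#'   draw with the sampled values, validation misclassification and
#'   parameter count).
#' @export
random_search <- function(x, y, val_x, val_y, space, budget = 10L, seed = 1L,
                          epochs = 20L, batch_size = 64L, patience = 5L) {
  stopifnot(budget >= 1L, is.list(space), length(space) > 0L)
  known <- c("hidden", "input_dropout", "hidden_dropout", "l1", "l2",
             "learning_rate")
  bad <- setdiff(names(space), known)
  if (length(bad) > 0L) stop("unknown search dimensions: ",
                             paste(bad, collapse = ", "))
  if (any(vapply(space, length, integer(1)) == 0L)) {
    stop("empty candidate list in search space")
  }
  draws <- with_local_seed(seed, lapply(seq_len(budget), function(i) {
    lapply(space, function(cands) cands[[sample.int(length(cands), 1L)]])
  }))
  trials <- data.frame()
  models <- vector("list", budget)
  for (i in seq_len(budget)) {
    d <- draws[[i]]
    cfg <- do.call(dnn_config, c(d, list(epochs = epochs,
                                         batch_size = batch_size,
                                         patience = patience, seed = seed)))
    fit <- tryCatch(dnn_localizer(x, y, val_x, val_y, config = cfg),
                    error = function(e) e)
    diverged <- inherits(fit, "error")
    if (!diverged) models[[i]] <- fit
    trials <- rbind(trials, data.frame(
      draw = i,
      hidden = paste(cfg$hidden, collapse = "-"),
      input_dropout = cfg$input_dropout,
      hidden_dropout = cfg$hidden_dropout,
      l1 = cfg$l1, l2 = cfg$l2, learning_rate = cfg$learning_rate,
      n_parameters = n_parameters(cfg$hidden, ncol(x)),
      val_misclass = if (diverged) Inf else min(fit$history$val_misclass),
      error = if (diverged) conditionMessage(fit) else ""))
  }
  if (all(!is.finite(trials$val_misclass))) {
    stop("every trial diverged; widen the search space or lower the rates")
  }
  ord <- order(trials$val_misclass, trials$n_parameters, trials$draw)
  best <- ord[1L]
  list(best_config = models[[best]]$config, best_model = models[[best]],
       trials = trials)
}
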