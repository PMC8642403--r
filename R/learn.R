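#' Model configuration for the 3D CNN
#'
#' @param task `"classification"` (2 output scores, weighted
#'   cross-entropy) or `"regression"` (1 output, mean-squared error).
#' @param conv_filters filters per convolution block (default `c(8, 16)`).
#' @param kernel convolution kernel size (default 3).
#' @param fc_widths widths of fully connected layers before the output
#'   (default 84).
#' @param optimizer `"sgd"` or `"adam"`.
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay SGD weight decay (L2 on weights).
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (on validation
#'   loss); the best-validation-loss weights are restored.
#' @param class_weights `"auto"` (from the training labels via
#'   [class_weights()]), or a numeric pair `(w_negative, w_positive)`.
#' @param validation_split fraction of the data held out for validation
#'   when no explicit validation set is given.
#' @param seed RNG seed controlling initialization, splits and batch
#'   order.
#' @return object of class `ppi_model_config`.
#' @export
model_config <- function(task = "classification",
                         conv_filters = c(8, 16), kernel = 3,
                         fc_widths = 84,
                         optimizer = "adam", lr = 0.001, momentum = 0.9,
                         weight_decay = 0, batch_size = 8,
                         max_epochs = 30, patience = 10,
                         class_weights = "auto",
                         validation_split = 0.25, seed = 1) {
  task <- match.arg(task, c("classification", "regression"))
  optimizer <- match.arg(optimizer, c("adam", "sgd"))
  structure(list(task = task, conv_filters = conv_filters, kernel = kernel,
                 fc_widths = fc_widths, optimizer = optimizer, lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, class_weights = class_weights,
                 validation_split = validation_split, seed = seed),
            class = "ppi_model_config")
}

#' Preset: SGD classification setup
#'
#' Cross-entropy with log-softmax scoring, SGD with learning rate 5e-4,
#' momentum 0.9, weight decay 1e-3, batch size 8.
#'
#' @param ... overrides forwarded to [model_config()].
#' @return a [model_config()].
#' @export
preset_sgd_classifier <- function(...) {
  args <- utils::modifyList(
    list(task = "classification", optimizer = "sgd", lr = 0.0005,
         momentum = 0.9, weight_decay = 0.001, batch_size = 8),
    list(...))
  do.call(model_config, args)
}

#' Preset: Adam classification setup
#'
#' Adam optimizer with learning rate 1e-3, batch size 100, automatic
#' class weights.
#'
#' @param ... overrides forwarded to [model_config()].
#' @return a [model_config()].
#' @export
preset_adam_classifier <- function(...) {
  args <- utils::modifyList(
    list(task = "classification", optimizer = "adam", lr = 0.001,
         batch_size = 100, class_weights = "auto"),
    list(...))
  do.call(model_config, args)
}

#' Class weights proportional to the opposite class sizes
#'
#' `w_negative` is the fraction of positives and `w_positive` the
#' fraction of negatives, so the expected penalty on each class is
#' balanced; the weights sum to 1.
#'
#' @param labels binary labels: 0/1, logical, or
#'   `"wrong"`/`"near-native"`.
#' @return named numeric pair `c(negative = , positive = )`.
#' @export
class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  frac_pos <- mean(y == 1)
  if (frac_pos == 0 || frac_pos == 1)
    stop_ppi("ppi_weighting_error",
             "class weights need both classes present")
  c(negative = frac_pos, positive = 1 - frac_pos)
}

as_binary_labels <- function(labels) {
  if (is.character(labels)) as.integer(labels == "near-native")
  else as.integer(labels != 0)
}

## Stack a list of dataset entries into a 5D batch tensor + targets.
stack_entries <- function(entries) {
  d <- dim(entries[[1]]$x)
  x <- array(0, dim = c(d, length(entries)))
  xm <- matrix(x, ncol = length(entries))
  for (i in seq_along(entries)) xm[, i] <- as.vector(entries[[i]]$x)
  list(x = array(xm, dim = c(d, length(entries))),
       y = vapply(entries, function(e)
         if (is.null(e$y)) NA_real_ else as.numeric(e$y), numeric(1)),
       ids = vapply(entries, function(e) e$model_id, character(1)),
       case_ids = vapply(entries, function(e) e$case_id, character(1)))
}

batch_loss <- function(net, x, y, config, weights, training) {
  fw <- nn_forward(net, x, training = training)
  if (config$task == "classification") {
    l <- loss_cross_entropy(fw$out, y + 1L, weights)
  } else {
    l <- loss_mse(fw$out, y)
  }
  list(loss = l$loss, dz = l$dz, fw = fw)
}

eval_pass <- function(net, x, y, config, weights) {
  r <- batch_loss(net, x, y, config, weights, training = FALSE)
  acc <- NA_real_
  if (config$task == "classification") {
    pred <- apply(r$fw$out, 2, which.max) - 1L
    acc <- mean(pred == y)
  }
  list(loss = r$loss, accuracy = acc)
}

#' Train the 3D CNN on dataset entries
#'
#' Seeded, deterministic-given-seed training with minibatch SGD or Adam,
#' optional class weighting, and early stopping on the validation loss
#' with restoration of the best-epoch weights.
#'
#' @param data list of entries as returned by [read_selection()] (each
#'   with `x` 4D tensor and `y` target). For classification `y` must be
#'   0 (wrong) / 1 (near-native).
#' @param config a [model_config()].
#' @param val_data optional explicit validation entries; when `NULL` a
#'   fraction `config$validation_split` of `data` is held out
#'   (deterministically by seed).
#' @param history_path optional HDF5 file to which the per-epoch history
#'   and final predictions on the validation set are written
#'   (`/history/*`, `/predictions/*`).
#' @param verbose print per-epoch progress.
#' @return object of class `ppi_trained_model`: list with `net`,
#'   `config`, `history` (data frame), `best_epoch`, `weights` (class
#'   weights used), `channel_names`.
#' @export
train_model <- function(data, config = model_config(), val_data = NULL,
                        history_path = NULL, verbose = FALSE) {
  if (length(data) == 0)
    stop_ppi("ppi_config_error", "empty training stream")
  if (is.null(val_data)) {
    n <- length(data)
    n_val <- max(1L, round(config$validation_split * n))
    if (n_val >= n)
      stop_ppi("ppi_config_error", "validation split leaves no training data")
    idx <- with_seed(derive_seed(config$seed, 17), sample(n, n_val))
    val_data <- data[idx]
    data <- data[-idx]
  }
  if (length(val_data) == 0)
    stop_ppi("ppi_config_error",
             "early stopping requires a non-empty validation set")
  tr <- stack_entries(data)
  va <- stack_entries(val_data)
  if (anyNA(tr$y) || anyNA(va$y))
    stop_ppi("ppi_config_error", "entries lack target values")
  if (config$task == "classification") {
    tr$y <- as.integer(tr$y); va$y <- as.integer(va$y)
    weights <- if (identical(config$class_weights, "auto"))
      class_weights(tr$y)
    else stats::setNames(as.numeric(config$class_weights),
                         c("negative", "positive"))
  } else weights <- c(negative = 1, positive = 1)
  in_shape <- dim(tr$x)[1:4]
  net <- with_seed(config$seed, nn_build(in_shape, config))
  opt <- if (config$optimizer == "sgd")
    list(name = "sgd", lr = config$lr, momentum = config$momentum,
         weight_decay = config$weight_decay)
  else
    list(name = "adam", lr = config$lr, beta1 = 0.9, beta2 = 0.999,
         eps = 1e-8)
  state <- opt_init(net)
  n_tr <- length(tr$y)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(loss = Inf, epoch = 0L, layers = net$layers)
  t_step <- 0
  xm <- matrix(tr$x, ncol = n_tr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, 1000 + epoch), sample(n_tr))
    losses <- c()
    for (start in seq(1, n_tr, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1, n_tr)]
      xb <- array(xm[, sel, drop = FALSE], dim = c(in_shape, length(sel)))
      r <- batch_loss(net, xb, tr$y[sel], config, weights, training = TRUE)
      net <- r$fw$net
      bk <- nn_backward(net, r$fw$caches, r$dz)
      t_step <- t_step + 1
      st <- opt_step(net, bk$grads, state, opt, t_step)
      net <- st$net; state <- st$state
      losses <- c(losses, r$loss)
    }
    ev <- eval_pass(net, va$x, va$y, config, weights)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_loss = ev$loss,
                                   val_accuracy = ev$accuracy))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                      epoch, mean(losses), ev$loss, ev$accuracy))
    if (ev$loss < best$loss) {
      best <- list(loss = ev$loss, epoch = epoch, layers = net$layers)
    } else if (epoch - best$epoch >= config$patience) break
  }
  net$layers <- best$layers
  model <- structure(list(net = net, config = config, history = hist,
                          best_epoch = best$epoch, weights = weights,
                          channel_names = dimnames(data[[1]]$x)[[4]]),
                     class = "ppi_trained_model")
  if (!is.null(history_path)) {
    if (file.exists(history_path)) unlink(history_path)
    rhdf5::h5createFile(history_path)
    rhdf5::h5createGroup(history_path, "history")
    rhdf5::h5write(hist$train_loss, history_path, "history/train_loss")
    rhdf5::h5write(hist$val_loss, history_path, "history/val_loss")
    rhdf5::h5write(hist$val_accuracy, history_path, "history/epoch_metrics")
    preds <- predict_model(model, val_data)
    rhdf5::h5createGroup(history_path, "predictions")
    rhdf5::h5write(preds$model_id, history_path, "predictions/model_id")
    rhdf5::h5write(preds$score, history_path, "predictions/score")
    rhdf5::h5closeAll()
  }
  model
}

#' Apply a trained model to dataset entries
#'
#' Classification returns the two log-softmax scores per entry; the
#' wrong-class score is the ranking score (lower means the model is
#' predicted to be of higher quality). Regression returns one value.
#'
#' @param model a [train_model()] result.
#' @param data list of entries with `x` tensors matching the training
#'   channel set.
#' @return data frame with `model_id`, `case_id`, `score`, and for
#'   classification `logp_wrong`, `logp_near_native`.
#' @export
predict_model <- function(model, data) {
  st <- stack_entries(data)
  in_shape <- dim(st$x)[1:4]
  if (!identical(in_shape, model$net$input_shape))
    stop_ppi("ppi_config_error",
             "input shape %s does not match training shape %s",
             paste(in_shape, collapse = "x"),
             paste(model$net$input_shape, collapse = "x"))
  out <- nn_forward(model$net, st$x, training = FALSE)$out
  if (model$config$task == "classification") {
    lp <- log_softmax(out)
    data.frame(model_id = st$ids, case_id = st$case_ids,
               logp_wrong = lp[1, ], logp_near_native = lp[2, ],
               score = lp[1, ], stringsAsFactors = FALSE)
  } else {
    data.frame(model_id = st$ids, case_id = st$case_ids,
               score = as.vector(out), stringsAsFactors = FALSE)
  }
}
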