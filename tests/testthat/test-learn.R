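# Training-engine tests use tiny tensors so the finite-difference check
# and the planted-signal runs stay fast.

tiny_entries <- function(n, n_chan = 2, grid_n = 12, snr = 0, seed = 1,
                         regression = FALSE) {
  blob <- {
    ax <- seq(-(grid_n - 1) / 2, (grid_n - 1) / 2)
    d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    exp(-d2 / (2 * (grid_n / 6)^2))
  }
  lapply(seq_len(n), function(i) {
    x <- ppirank:::with_seed(ppirank:::derive_seed(seed, i),
                             array(stats::rnorm(grid_n^3 * n_chan),
                                   dim = c(rep(grid_n, 3), n_chan)))
    if (regression) {
      amp <- ppirank:::with_seed(ppirank:::derive_seed(seed, 5000 + i),
                                 stats::runif(1, 0, 5))
      x[, , , 1] <- x[, , , 1] + amp * blob
      y <- sum(x[, , , 1])
    } else {
      y <- i %% 2
      if (y == 1) x[, , , 1] <- x[, , , 1] + snr * blob
    }
    dimnames(x) <- c(rep(list(NULL), 3),
                     list(paste0("ch", seq_len(n_chan))))
    list(model_id = sprintf("e%03d", i), case_id = sprintf("c%d", i %% 3),
         x = x, y = y)
  })
}

test_that("class weights mirror the opposite class fractions", {
  labels <- rep(c(1, 0), c(71, 929))
  expect_equal(class_weights(labels),
               c(negative = 0.071, positive = 0.929))
  expect_equal(class_weights(rep(c(1, 0), 50)),
               c(negative = 0.5, positive = 0.5))
  expect_equal(class_weights(rep(c(1, 0), c(25, 75))),
               c(negative = 0.25, positive = 0.75))
  expect_equal(sum(class_weights(rep(c(1, 0), c(3, 17)))), 1)
  expect_error(class_weights(rep(1, 10)), class = "ppi_weighting_error")
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- model_config(conv_filters = c(2, 2), fc_widths = 4,
                     max_epochs = 1, seed = 3)
  entries <- tiny_entries(4, n_chan = 2, grid_n = 12, snr = 1)
  st <- ppirank:::stack_entries(entries)
  net <- ppirank:::with_seed(3, ppirank:::nn_build(dim(st$x)[1:4], cfg))
  y <- as.integer(st$y) + 1L
  w <- c(0.4, 0.6)
  loss_at <- function(net) {
    fw <- ppirank:::nn_forward(net, st$x, training = TRUE)
    ppirank:::loss_cross_entropy(fw$out, y, w)$loss
  }
  fw <- ppirank:::nn_forward(net, st$x, training = TRUE)
  l <- ppirank:::loss_cross_entropy(fw$out, y, w)
  bk <- ppirank:::nn_backward(fw$net, fw$caches, l$dz)
  h <- 1e-5
  set.seed(8)
  for (li in seq_along(net$layers)) {
    g <- bk$grads[[li]]
    if (is.null(g)) next
    for (p in names(g)) {
      for (rep in 1:3) {
        j <- sample(length(net$layers[[li]][[p]]), 1)
        np <- net; np$layers[[li]][[p]][j] <- np$layers[[li]][[p]][j] + h
        nm <- net; nm$layers[[li]][[p]][j] <- nm$layers[[li]][[p]][j] - h
        fd <- (loss_at(np) - loss_at(nm)) / (2 * h)
        an <- g[[p]][j]
        expect_equal(an, fd, tolerance = 1e-3,
                     label = sprintf("layer %d %s[%d] analytic", li, p, j))
      }
    }
  }
})

test_that("training is deterministic given the seed", {
  entries <- tiny_entries(16, snr = 3, seed = 5)
  cfg <- model_config(conv_filters = c(2, 2), fc_widths = 8,
                     batch_size = 4, max_epochs = 3, seed = 11)
  m1 <- train_model(entries, cfg)
  m2 <- train_model(entries, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net$layers, m2$net$layers)
})

test_that("prediction scores are normalized log-probabilities", {
  entries <- tiny_entries(12, snr = 3, seed = 6)
  cfg <- model_config(conv_filters = c(2, 2), fc_widths = 8,
                     batch_size = 4, max_epochs = 2, seed = 2)
  m <- train_model(entries, cfg)
  p <- predict_model(m, entries)
  expect_equal(nrow(p), 12)
  expect_true(all(is.finite(p$score)))
  expect_equal(exp(p$logp_wrong) + exp(p$logp_near_native),
               rep(1, 12), tolerance = 1e-6)
})

test_that("zero-weight classes contribute nothing to the loss", {
  z <- matrix(stats::rnorm(10), nrow = 2)
  y <- rep(c(1L, 2L), c(3, 2))
  w <- c(0, 1)  # negatives carry zero weight
  l1 <- ppirank:::loss_cross_entropy(z, y, w)
  z2 <- z
  z2[, y == 1] <- z2[, y == 1] + matrix(stats::rnorm(6), nrow = 2)
  l2 <- ppirank:::loss_cross_entropy(z2, y, w)
  expect_equal(l1$loss, l2$loss)
  expect_true(all(l1$dz[, y == 1] == 0))
})

test_that("a planted separable signal is learned to high accuracy", {
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  make_planted_grid_dataset(path, snr = 5, seed = 4)
  data <- read_selection(path, target = "binary_class")
  cfg <- preset_adam_classifier(batch_size = 10, max_epochs = 12, seed = 3)
  m <- train_model(data, cfg)
  expect_gte(max(m$history$val_accuracy), 0.95)
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
  p <- predict_model(m, data)
  y <- vapply(data, function(e) e$y, numeric(1))
  expect_lt(mean(p$score[y == 1]), mean(p$score[y == 0]))
})

test_that("regression recovers a target linear in one channel's sum", {
  entries <- tiny_entries(50, n_chan = 2, seed = 7, regression = TRUE)
  ys <- vapply(entries, function(e) e$y, numeric(1))
  mu <- mean(ys); sd_y <- stats::sd(ys)
  entries <- lapply(entries, function(e) {
    e$y <- (e$y - mu) / sd_y
    e
  })
  test_idx <- seq(1, 50, by = 5)
  cfg <- model_config(task = "regression", conv_filters = c(4, 8),
                     fc_widths = 16, optimizer = "adam", lr = 0.01,
                     batch_size = 8, max_epochs = 40, patience = 20,
                     seed = 9)
  m <- train_model(entries[-test_idx], cfg)
  p <- predict_model(m, entries[test_idx])
  truth <- vapply(entries[test_idx], function(e) e$y, numeric(1))
  r2 <- 1 - sum((p$score - truth)^2) / sum((truth - mean(truth))^2)
  expect_gte(r2, 0.9)
})
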