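test_that("sigmoid has the expected fixed points and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(50), 1, tolerance = 1e-12)
  set.seed(20)
  x <- rnorm(50, sd = 5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 50), tolerance = 1e-12)
})

test_that("hidden widths follow the floor decrease-ratio rule", {
  expect_identical(hidden_widths(780), c(702L, 561L, 392L))
  expect_identical(hidden_widths(26, c(0.9, 0.8)), c(23L, 18L))
  expect_error(hidden_widths(100, c(1.2)), "\\(0, 1\\)")
  m <- new_sda_model(26, seed = 1)
  expect_equal(vapply(m$layers, function(l) ncol(l$W), integer(1)),
               hidden_widths(26))
  # chained shapes: layer k input equals layer k-1 output
  for (k in 2:3)
    expect_equal(nrow(m$layers[[k]]$W), ncol(m$layers[[k - 1]]$W))
  # exactly three trainable arrays per layer (tied weights)
  expect_true(all(vapply(m$layers, length, integer(1)) == 3))
})

test_that("encode and decode match hand-expanded arithmetic", {
  layer <- list(W = matrix(0, 3, 2), b = c(0, 0), b_prime = c(0, 0, 0))
  expect_equal(encode_layer(c(1, -1, 2), layer), c(0.5, 0.5))
  layer2 <- list(W = diag(2), b = c(0, 0), b_prime = c(0, 0))
  expect_equal(encode_layer(c(0, 0), layer2), c(0.5, 0.5))
  set.seed(21)
  W <- matrix(rnorm(6), 3, 2); b <- rnorm(2); bp <- rnorm(3)
  l <- list(W = W, b = b, b_prime = bp)
  x <- rnorm(3); y <- rnorm(2)
  enc_hand <- c(1 / (1 + exp(-(W[1, 1] * x[1] + W[2, 1] * x[2] + W[3, 1] * x[3] + b[1]))),
                1 / (1 + exp(-(W[1, 2] * x[1] + W[2, 2] * x[2] + W[3, 2] * x[3] + b[2]))))
  expect_equal(encode_layer(x, l), enc_hand, tolerance = 1e-12)
  dec_hand <- c(W[1, 1] * y[1] + W[1, 2] * y[2] + bp[1],
                W[2, 1] * y[1] + W[2, 2] * y[2] + bp[2],
                W[3, 1] * y[1] + W[3, 2] * y[2] + bp[3])
  expect_equal(decode_layer(y, l), dec_hand, tolerance = 1e-12)
  # y = 0 decodes to the reconstruction bias; zero W likewise
  expect_equal(decode_layer(c(0, 0), l), bp)
  expect_error(encode_layer(c(1, 2), l), "dimension mismatch")
  expect_error(decode_layer(c(1, 2, 3), l), "dimension mismatch")
})

test_that("decoding uses exactly the transpose of the encoding matrix", {
  m <- new_sda_model(12, ratios = c(0.8), seed = 2)
  x <- runif(12)
  base <- sda_forward(m, x)
  m2 <- m
  m2$layers[[1]]$W[1, 1] <- m2$layers[[1]]$W[1, 1] + 0.5
  pert <- sda_forward(m2, x)
  # perturbing W changes the encoding AND the decoding path
  y1 <- encode_layer(x, m$layers[[1]]); y2 <- encode_layer(x, m2$layers[[1]])
  expect_false(isTRUE(all.equal(y1, y2)))
  expect_false(isTRUE(all.equal(decode_layer(y1, m$layers[[1]]),
                                decode_layer(y1, m2$layers[[1]]))))
  expect_false(isTRUE(all.equal(base, pert)))
})

test_that("the forward pass preserves length and stays finite", {
  m <- new_sda_model(39, seed = 3)
  x <- runif(39)
  out <- sda_forward(m, x)
  expect_length(out, 39)
  expect_true(all(is.finite(out)))
  cl <- sda_forward(m, x, clamp01 = TRUE)
  expect_true(all(cl >= 0 & cl <= 1))
  expect_error(sda_forward(m, runif(10)), "dimension mismatch")
  expect_error(new_sda_model(2, ratios = c(0.3, 0.3)), "degenerate")
})

test_that("rmsd_loss counts atoms and matches the geometric RMSD", {
  f <- runif(26)
  expect_equal(rmsd_loss(f, f), 0)
  lab <- f
  inc <- prsda:::coord_channel_idx(1:2)
  pred <- lab
  pred[1:3] <- lab[1:3] + c(0.3, 0.4, 0)   # one atom off by 0.5
  expect_equal(rmsd_loss(pred, lab, include = 1:3), 0.5)
  # cross-module consistency: equals rmsd() on the de-interleaved triples
  set.seed(22)
  a <- runif(26); b <- runif(26)
  pa <- matrix(a[inc], ncol = 3, byrow = TRUE)
  pb <- matrix(b[inc], ncol = 3, byrow = TRUE)
  expect_equal(rmsd_loss(a, b, include = inc), rmsd(pa, pb), tolerance = 1e-12)
  expect_error(rmsd_loss(a, b[-1]), "differ in length")
  expect_error(rmsd_loss(a, b, include = integer(0)), "empty inclusion")
})

test_that("analytic gradients match central finite differences", {
  set.seed(23)
  d <- 26
  m <- new_sda_model(d, ratios = c(0.9, 0.8), seed = 31)
  X <- matrix(runif(3 * d), 3, d)
  Y <- matrix(runif(3 * d), 3, d)
  inc <- prsda:::coord_channel_idx(1:2)
  g <- prsda:::sda_gradients(m, X, Y, inc)
  loss_at <- function(mm) prsda:::sda_gradients(mm, X, Y, inc)$loss
  h <- 1e-6
  max_rel <- 0
  for (k in seq_along(m$layers)) {
    for (nm in c("W", "b", "b_prime")) {
      p <- m$layers[[k]][[nm]]
      idx <- sample(length(p), min(15, length(p)))
      for (i in idx) {
        mp <- m; mp$layers[[k]][[nm]][i] <- p[i] + h
        mn <- m; mn$layers[[k]][[nm]][i] <- p[i] - h
        fd <- (loss_at(mp) - loss_at(mn)) / (2 * h)
        an <- switch(nm, W = g$grads[[k]]$dW[i], b = g$grads[[k]]$db[i],
                     b_prime = g$grads[[k]]$db_prime[i])
        max_rel <- max(max_rel, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
      }
    }
  }
  expect_lt(max_rel, 1e-5)
})

test_that("layer-wise pretraining reduces reconstruction error deterministically", {
  m <- new_sda_model(8, ratios = c(0.8), seed = 4)
  set.seed(24)
  data <- matrix(runif(40 * 8), 40, 8)
  expect_identical(pretrain_layerwise(m, data, epochs = 0), m)
  tr <- pretrain_layerwise(m, data, epochs = 200, seed = 5)
  log <- tr$training_log
  expect_true(all(log$phase == "pretrain"))
  expect_lt(log$loss[nrow(log)], log$loss[1])
  tr2 <- pretrain_layerwise(m, data, epochs = 200, seed = 5)
  expect_identical(tr$layers, tr2$layers)
  expect_message(pretrain_layerwise(m, data[1, , drop = FALSE], epochs = 1),
                 "single data row")
})

test_that("fine-tuning descends on the RMSD objective and can overfit one sample", {
  set.seed(25)
  d <- 26
  m <- new_sda_model(d, ratios = c(0.9, 0.8), seed = 6)
  X <- matrix(runif(10 * d), 10, d)
  # identical labels and inputs, full-batch: loss decreases monotonically
  tr <- finetune(m, X, X, epochs = 60, learning_rate = 0.05, batch_size = 10,
                 seed = 7)
  loss <- tr$training_log$loss[tr$training_log$phase == "finetune"]
  expect_lt(loss[60], loss[1])
  expect_true(all(diff(loss[5:60]) <= 1e-10))
  # zero learning rate leaves parameters untouched
  frozen <- finetune(m, X, X, epochs = 3, learning_rate = 0, seed = 7)
  expect_identical(frozen$layers, m$layers)
  # a single repeated sample is reconstructed to below 1e-2 loss
  # (coarse then fine step size: the RMSD objective has a constant-magnitude
  # gradient near its minimum, so a fixed large step keeps orbiting it)
  x1 <- matrix(runif(d), 1)
  over <- finetune(m, x1[rep(1, 20), ], x1[rep(1, 20), ], epochs = 1500,
                   learning_rate = 0.2, batch_size = 20, seed = 8)
  over <- finetune(over, x1[rep(1, 20), ], x1[rep(1, 20), ], epochs = 300,
                   learning_rate = 0.02, batch_size = 20, seed = 9)
  final <- prsda:::sda_gradients(over, x1, x1,
                                 prsda:::coord_channel_idx(1:2))$loss
  expect_lt(final, 1e-2)
})

test_that("checkpoints round-trip and reject shape-inconsistent files", {
  m <- new_sda_model(26, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_sda(m, path)
  expect_identical(load_sda(path), m)
  bad <- m
  bad$layers[[2]]$W <- bad$layers[[2]]$W[, -1]
  save_sda(bad, path)
  expect_error(load_sda(path), "shape-inconsistent")
  saveRDS(list(other = 1), path)
  expect_error(load_sda(path), "not an SDA checkpoint")
})
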