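test_that("the feedforward pass matches a scalar-loop evaluation", {
  # zero network outputs the sigmoid of zero
  m0 <- structure(list(W1 = matrix(0, 3, 2), b1 = c(0, 0),
                       w2 = c(0, 0), b2 = 0), class = "fbann")
  expect_equal(fbann_forward(m0, c(1, 2, 3)), 0.5)
  # single unit, unit weights: f(f(0)) = f(0.5)
  m1 <- structure(list(W1 = matrix(1, 1, 1), b1 = 0, w2 = 1, b2 = 0),
                  class = "fbann")
  expect_equal(fbann_forward(m1, 0), 1 / (1 + exp(-0.5)),
               tolerance = 1e-12)
  # random small instances against the independent loop oracle
  set.seed(9)
  for (i in 1:20) {
    m <- sample(2:5, 1); n <- sample(1:4, 1)
    W1 <- matrix(rnorm(m * n), m, n); b1 <- rnorm(n)
    w2 <- rnorm(n); b2 <- rnorm(1); x <- rnorm(m)
    mod <- structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2),
                     class = "fbann")
    expect_equal(fbann_forward(mod, x), oracle_fbann(W1, b1, w2, b2, x),
                 tolerance = 1e-12)
  }
  expect_error(fbann_forward(m1, c(1, 2)), "features")
})

test_that("all-positive weights make the output monotone in each input", {
  set.seed(4)
  mod <- structure(list(W1 = matrix(runif(6), 2, 3), b1 = runif(3),
                        w2 = runif(3), b2 = 0.1), class = "fbann")
  x <- c(0.3, -0.2)
  base <- fbann_forward(mod, x)
  for (q in 1:2) {
    up <- x; up[q] <- up[q] + 0.5
    expect_gte(fbann_forward(mod, up), base)
  }
})

test_that("backpropagation training separates blobs and solves XOR", {
  blobs <- make_blobs()
  m <- fbann_train(blobs$x, blobs$y, seed = 1)
  expect_gte(mean((fbann_forward(m, blobs$x) >= 0.5) == blobs$y), 0.95)
  # flipped labels: the symmetric problem is learned equally well
  mf <- fbann_train(blobs$x, 1 - blobs$y, seed = 1)
  expect_gte(mean((fbann_forward(mf, blobs$x) >= 0.5) == (1 - blobs$y)),
             0.95)
  # training error is non-increasing up to tolerance
  expect_lte(m$train_error[length(m$train_error)], m$train_error[1] + 1e-9)
  # XOR needs the hidden layer
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0, 1, 1, 0)
  mx <- fbann_train(X, y, n_hidden = 4, lr = 1, max_epochs = 5000,
                    val_fraction = 0, restarts = 5, seed = 11)
  expect_equal(mean((fbann_forward(mx, X) >= 0.5) == y), 1)
  expect_error(fbann_train(X, c(1, 1, 1, 1)), "one class")
})

test_that("RBF kernel behaves at and far from a center", {
  mod <- structure(list(centers = matrix(c(1, 2), 1, 2), sigma = 1,
                        weights = c(0, 1)), class = "rbfnn")
  expect_equal(rbfnn_predict(mod, c(1, 2)), 1)
  expect_lt(rbfnn_predict(mod, c(100, 100)), 1e-10)
  blobs <- make_blobs()
  m <- rbfnn_train(blobs$x, blobs$y, seed = 2)
  expect_gte(mean((rbfnn_predict(m, blobs$x) >= 0.5) == blobs$y), 0.95)
  few <- c(1:3, 101:103)
  expect_error(rbfnn_train(blobs$x[few, ], blobs$y[few], n_centers = 20),
               "fewer samples")
})

test_that("PNN posteriors follow the Parzen/Bayes construction", {
  x <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  y <- c("a", "b")
  m <- pnn_train(x, y, sigma = 0.05)
  post <- pnn_predict(m, c(0, 0))
  expect_gt(post[, "a"], 0.999)
  # equidistant point with equal priors splits evenly
  post <- pnn_predict(m, c(0.5, 0.5))
  expect_equal(unname(post[, "a"]), 0.5, tolerance = 1e-9)
  # duplicating every pattern leaves the posterior unchanged
  m2 <- pnn_train(rbind(x, x), c(y, y), sigma = 0.05)
  expect_equal(pnn_predict(m2, c(0.2, 0.7)), pnn_predict(m, c(0.2, 0.7)))
  expect_error(pnn_train(x, y, sigma = -1), "sigma")
  blobs <- make_blobs()
  mp <- pnn_train(blobs$x, as.character(blobs$y), seed = 3)
  pred <- pnn_classify(mp, blobs$x)
  expect_gte(mean(pred == as.character(blobs$y)), 0.95)
})

test_that("the feature scaler standardizes with training statistics", {
  set.seed(6)
  x <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(unname(colMeans(xs)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  # constant columns survive with unit scale
  x[, 2] <- 7
  xs <- apply_scaler(fit_scaler(x), x)
  expect_true(all(xs[, 2] == 0))
})
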