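# The three base neural network classifiers of the ensemble: a feedforward
# backpropagation network (single sigmoid hidden layer, single sigmoid
# output, trained by steepest descent on the mean squared error), a radial
# basis function network (k-means centers, Gaussian units, closed-form
# regularized linear output layer), and a probabilistic neural network
# (Parzen Gaussian kernel density per class, Bayes decision rule). All
# predictors are deterministic given a fitted model; binary targets are
# coded 0/1 and scores live in [0, 1] for the >= 0.5 thresholding scheme.

#' Per-dimension z-scoring fitted on training data
#'
#' Distance-based classifiers (RBFNN, PNN) need commensurate feature
#' scales, so all three base classifiers see features standardized with
#' training-fold statistics. Constant dimensions get unit scale.
#'
#' @param x Training matrix (rows: samples).
#' @return Object of class `feature_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

# ---- FBANN ----------------------------------------------------------------

#' Feedforward backpropagation network: forward pass
#'
#' Evaluates \eqn{\phi = f(\sum_p w^2_p f(\sum_q W^1_{pq} x_q + b^1_p) +
#' b^2)} with \eqn{f} the logistic sigmoid; the score lies in (0, 1).
#'
#' @param model An `fbann` model.
#' @param x Numeric vector of length m, or an n x m matrix.
#' @return Score(s) in (0, 1).
#' @export
fbann_forward <- function(model, x) {
  stopifnot(inherits(model, "fbann"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(model$W1))
    stop(sprintf("input has %d features, model expects %d",
                 ncol(X), nrow(model$W1)))
  H <- sigmoid(sweep(X %*% model$W1, 2, model$b1, "+"))
  as.numeric(sigmoid(H %*% model$w2 + model$b2))
}

#' Train a feedforward backpropagation network
#'
#' Full-batch steepest descent on the mean squared error of a single
#' sigmoid output unit. Training stops at `max_epochs` or when the
#' monitored error (a held-out validation split when `val_fraction > 0`,
#' otherwise the training error) has not improved for `patience`
#' consecutive checks.
#'
#' @param x Training matrix (n x m), already scaled.
#' @param y Binary 0/1 targets.
#' @param n_hidden Hidden units (default 10).
#' @param lr Learning rate (default 0.05).
#' @param max_epochs Epoch budget (default 500).
#' @param val_fraction Fraction held out for early stopping (default 0.1).
#' @param patience Checks without improvement before stopping (default 10;
#'   checked every 10 epochs).
#' @param restarts Independent random initializations; the design with the
#'   lowest monitored error is kept (default 3).
#' @param seed Seed for weight initialization and the validation split.
#' @return Object of class `fbann` with the weight matrices, biases and
#'   the per-epoch training error trace.
#' @export
fbann_train <- function(x, y, n_hidden = 10, lr = 0.05, max_epochs = 500,
                        val_fraction = 0.1, patience = 10, restarts = 3,
                        seed = NULL) {
  if (restarts > 1) {
    fits <- lapply(seq_len(restarts), function(i)
      fbann_train(x, y, n_hidden = n_hidden, lr = lr,
                  max_epochs = max_epochs, val_fraction = val_fraction,
                  patience = patience, restarts = 1,
                  seed = if (is.null(seed)) NULL else seed + 1000 * i))
    scores <- vapply(fits, function(f) f$monitor_error, numeric(1))
    return(fits[[which.min(scores)]])
  }
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y) || nrow(x) < 2) stop("need >= 2 labelled samples")
  if (length(unique(y)) < 2)
    stop("degenerate training set: only one class present")
  m <- ncol(x)
  with_seed(seed, {
    n <- nrow(x)
    val_idx <- integer(0)
    if (val_fraction > 0 && n >= 20) {
      nv <- max(2L, floor(val_fraction * n))
      val_idx <- sample.int(n, nv)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    Xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
    W1 <- matrix(stats::runif(m * n_hidden, -0.5, 0.5) / sqrt(m), m, n_hidden)
    b1 <- numeric(n_hidden)
    w2 <- stats::runif(n_hidden, -0.5, 0.5) / sqrt(n_hidden)
    b2 <- 0
    nt <- nrow(Xt)
    trace <- numeric(0)
    best <- Inf; bad <- 0L
    monitor <- Inf
    for (epoch in seq_len(max_epochs)) {
      H <- sigmoid(sweep(Xt %*% W1, 2, b1, "+"))
      out <- as.numeric(sigmoid(H %*% w2 + b2))
      err <- out - yt
      trace[epoch] <- mean(err^2)
      # gradients of (1/n) sum (out - y)^2
      d_out <- 2 * err * out * (1 - out) / nt
      g_w2 <- as.numeric(crossprod(H, d_out))
      g_b2 <- sum(d_out)
      d_hid <- (d_out %o% w2) * H * (1 - H)
      g_W1 <- crossprod(Xt, d_hid)
      g_b1 <- colSums(d_hid)
      W1 <- W1 - lr * g_W1; b1 <- b1 - lr * g_b1
      w2 <- w2 - lr * g_w2; b2 <- b2 - lr * g_b2
      if (epoch %% 10 == 0) {
        monitor <- if (length(val_idx) > 0) {
          Hv <- sigmoid(sweep(Xv %*% W1, 2, b1, "+"))
          cv_error(yv, as.numeric(sigmoid(Hv %*% w2 + b2)))
        } else trace[epoch]
        if (monitor < best - 1e-8) { best <- monitor; bad <- 0L }
        else bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    final_monitor <- if (length(val_idx) > 0) {
      Hv <- sigmoid(sweep(Xv %*% W1, 2, b1, "+"))
      cv_error(yv, as.numeric(sigmoid(Hv %*% w2 + b2)))
    } else trace[length(trace)]
    structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                   train_error = trace, epochs = length(trace),
                   monitor_error = final_monitor),
              class = "fbann")
  })
}

# ---- RBFNN ----------------------------------------------------------------

#' Train a radial basis function network
#'
#' Hidden layer of Gaussian units centered on k-means prototypes of the
#' training set, with a common width proportional to the median
#' inter-center distance (the scale factor picked from a small grid by
#' inner cross-validation error); the linear output layer is solved in
#' closed form by regularized least squares (the global minimum of the
#' output-layer problem).
#'
#' @param x Training matrix (n x m), already scaled.
#' @param y Binary 0/1 targets.
#' @param n_centers Number of prototypes (default 20).
#' @param ridge Ridge penalty on the output weights (default 1e-6).
#' @param sigma_scales Candidate multiples of the median inter-center
#'   distance for the unit width; a single value skips the search.
#' @param inner_k Inner folds for the width search (default 5).
#' @param seed Seed for k-means initialization and the inner split.
#' @return Object of class `rbfnn`.
#' @export
rbfnn_train <- function(x, y, n_centers = 20, ridge = 1e-6,
                        sigma_scales = c(0.5, 1, 2), inner_k = 5,
                        seed = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (length(unique(y)) < 2)
    stop("degenerate training set: only one class present")
  if (nrow(x) < n_centers)
    stop(sprintf("fewer samples (%d) than centers (%d)", nrow(x), n_centers))
  with_seed(seed, {
    km <- suppressWarnings(
      stats::kmeans(x, centers = n_centers, nstart = 3, iter.max = 50))
    centers <- km$centers
    d_ref <- stats::median(stats::dist(centers))
    if (!is.finite(d_ref) || d_ref <= 0) d_ref <- 1
    fit_w <- function(xs, ys, sigma) {
      A <- cbind(1, rbf_design(xs, centers, sigma))
      solve(crossprod(A) + ridge * diag(ncol(A)), crossprod(A, ys))
    }
    sigma <- d_ref * sigma_scales[1]
    if (length(sigma_scales) > 1) {
      folds <- kfold_split(nrow(x), k = min(inner_k, nrow(x)),
                           labels = as.character(y))
      errs <- vapply(sigma_scales, function(sc) {
        s <- d_ref * sc
        e <- 0
        for (te in folds) {
          tr <- setdiff(seq_len(nrow(x)), te)
          if (length(unique(y[tr])) < 2) next
          w <- fit_w(x[tr, , drop = FALSE], y[tr], s)
          pred <- cbind(1, rbf_design(x[te, , drop = FALSE], centers, s)) %*% w
          e <- e + sum((as.integer(pred >= 0.5)) != y[te])
        }
        e
      }, numeric(1))
      sigma <- d_ref * sigma_scales[which.min(errs)]
    }
    structure(list(centers = centers, sigma = sigma,
                   weights = as.numeric(fit_w(x, y, sigma))),
              class = "rbfnn")
  })
}

rbf_design <- function(x, centers, sigma) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * x %*% t(centers)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' RBFNN score
#'
#' Linear combination of Gaussian hidden activations, clipped to `[0, 1]`.
#'
#' @param model An `rbfnn` model.
#' @param x Feature vector or matrix.
#' @return Score(s) in `[0, 1]`.
#' @export
rbfnn_predict <- function(model, x) {
  stopifnot(inherits(model, "rbfnn"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model$centers))
    stop(sprintf("input has %d features, model expects %d",
                 ncol(X), ncol(model$centers)))
  Phi <- rbf_design(X, model$centers, model$sigma)
  raw <- as.numeric(cbind(1, Phi) %*% model$weights)
  pmin(pmax(raw, 0), 1)
}

# ---- PNN ------------------------------------------------------------------

#' Train a probabilistic neural network
#'
#' Stores the training patterns per class; prediction evaluates a Parzen
#' Gaussian kernel density estimate per class and applies the Bayes
#' optimal decision rule. When `sigma` is `NULL` the smoothing parameter
#' is chosen by grid search on inner cross-validation folds (minimizing
#' the CV error of the posterior for the positive class).
#'
#' @param x Training matrix (n x m), already scaled.
#' @param y Class labels (any type; binary 0/1 for the decoding stages).
#' @param sigma Kernel width, or `NULL` for the inner-CV grid search.
#' @param priors Named class priors (default: empirical frequencies).
#' @param inner_k Inner folds for the sigma search (default 5).
#' @param seed Seed for the inner split.
#' @return Object of class `pnn`.
#' @export
pnn_train <- function(x, y, sigma = NULL, priors = NULL, inner_k = 5,
                      seed = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("degenerate training set: only one class present")
  if (is.null(priors)) priors <- table(y) / length(y)
  priors <- priors[classes]
  if (!is.null(sigma) && sigma <= 0) stop("`sigma` must be > 0")
  if (is.null(sigma)) {
    d_med <- stats::median(stats::dist(x[sample_cap(nrow(x), 200), ,
                                         drop = FALSE]))
    grid <- d_med * c(0.1, 0.2, 0.5, 1, 2)
    folds <- kfold_split(nrow(x), k = min(inner_k, min(table(y))),
                         labels = y, seed = seed)
    errs <- vapply(grid, function(s) {
      e <- 0
      for (te in folds) {
        tr <- setdiff(seq_len(nrow(x)), te)
        if (length(unique(y[tr])) < 2) next
        m <- pnn_fit_raw(x[tr, , drop = FALSE], y[tr], s, priors)
        post <- pnn_predict(m, x[te, , drop = FALSE])
        e <- e + cv_error(as.numeric(y[te] == classes[length(classes)]),
                          post[, length(classes)]) * length(te)
      }
      e / nrow(x)
    }, numeric(1))
    sigma <- grid[which.min(errs)]
  }
  pnn_fit_raw(x, y, sigma, priors)
}

sample_cap <- function(n, cap) if (n <= cap) seq_len(n) else
  round(seq(1, n, length.out = cap))

pnn_fit_raw <- function(x, y, sigma, priors) {
  classes <- sort(unique(y))
  structure(list(patterns = lapply(classes,
                                   function(cl) x[y == cl, , drop = FALSE]),
                 classes = classes, sigma = sigma,
                 priors = as.numeric(priors[classes]) /
                   sum(as.numeric(priors[classes]))),
            class = "pnn")
}

#' PNN class posteriors
#'
#' Class score proportional to `prior_j * mean_i exp(-||x - x_i^j||^2 /
#' (2 sigma^2))`, normalized across classes. Duplicating every stored
#' pattern leaves the posteriors unchanged.
#'
#' @param model A `pnn` model.
#' @param x Feature vector or matrix.
#' @return Matrix of posteriors (rows: inputs, columns: classes in
#'   `model$classes` order).
#' @export
pnn_predict <- function(model, x) {
  stopifnot(inherits(model, "pnn"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model$patterns[[1]]))
    stop(sprintf("input has %d features, model expects %d",
                 ncol(X), ncol(model$patterns[[1]])))
  s2 <- 2 * model$sigma^2
  scores <- vapply(seq_along(model$classes), function(j) {
    P <- model$patterns[[j]]
    d2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P)
    model$priors[j] * rowMeans(exp(-pmax(d2, 0) / s2))
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(NULL, model$classes))
  tot <- rowSums(scores)
  # all-zero kernel mass (x far from every pattern): fall back to priors
  zero <- tot == 0
  if (any(zero)) {
    scores[zero, ] <- matrix(model$priors, sum(zero), length(model$classes),
                             byrow = TRUE)
    tot[zero] <- 1
  }
  scores / tot
}

#' PNN class decision (Bayes rule)
#'
#' Argmax of the posteriors; exact posterior ties resolve to the first
#' class in canonical (sorted) order, with a message noting the tie.
#'
#' @param model A `pnn` model.
#' @param x Feature vector or matrix.
#' @return Character vector of predicted classes.
#' @export
pnn_classify <- function(model, x) {
  post <- pnn_predict(model, x)
  apply(post, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) message("PNN posterior tie; taking first class")
    model$classes[top[1]]
  })
}

# ---- common score interface ----------------------------------------------

# Score in [0, 1] for the positive ("1") class, used by the voting stage.
base_score <- function(model, x) UseMethod("base_score")

#' @export
base_score.fbann <- function(model, x) fbann_forward(model, x)

#' @export
base_score.rbfnn <- function(model, x) rbfnn_predict(model, x)

#' @export
base_score.pnn <- function(model, x) {
  post <- pnn_predict(model, x)
  if (!"1" %in% colnames(post))
    stop("PNN stage model must be trained with 0/1 labels")
  post[, "1"]
}
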