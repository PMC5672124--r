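#' Threshold a base-classifier score
#'
#' Binary decision from a raw score in `[0, 1]`: class 1 (event / left
#' movement) iff the score is `>= 0.5`, else class 0 (rest / right
#' movement).
#'
#' @param score Numeric score(s) in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
threshold_output <- function(score) {
  if (any(!is.finite(score))) stop("score must be finite")
  if (any(score < 0 | score > 1)) stop("score outside [0, 1]")
  as.integer(score >= 0.5)
}

#' Majority vote of three base classifiers
#'
#' Plurality fusion: the ensemble picks the class receiving the most base
#' votes; with three classifiers and two classes any two agreeing
#' classifiers decide and no tie is possible.
#'
#' @param votes Integer vector of exactly three 0/1 votes, or an n x 3
#'   matrix of votes (one row per trial).
#' @return Fused 0/1 decision(s).
#' @export
majority_vote <- function(votes) {
  if (is.matrix(votes)) {
    if (ncol(votes) != 3) stop("exactly three base classifiers are required")
    if (!all(votes %in% c(0, 1))) stop("votes must be 0 or 1")
    return(as.integer(rowSums(votes) >= 2))
  }
  if (length(votes) != 3) stop("exactly three base classifiers are required")
  if (!all(votes %in% c(0, 1))) stop("votes must be 0 or 1")
  as.integer(sum(votes) >= 2)
}

#' Train one voting stage (three base classifiers)
#'
#' Fits the feature scaler on the training fold, then the FBANN, RBFNN and
#' PNN base classifiers on the standardized features with binary 0/1
#' targets. The fitted stage thresholds each base score at 0.5 and fuses
#' the three votes by majority.
#'
#' Class balancing differs by base-classifier type: the discriminative
#' FBANN and RBFNN consume the full (bootstrap-augmented) training set,
#' whereas the generative PNN estimates its Parzen class densities from the
#' original patterns only, with equal class priors. Convex-combination
#' bootstrap samples contract systematically toward the class centroid in
#' high dimension, which biases a kernel density estimate; for a
#' density-based classifier the Bayes-correct way to balance classes is
#' through the priors, not through fabricated samples.
#'
#' @param x Training feature matrix.
#' @param y Binary 0/1 targets (1 = event / left).
#' @param hyper Named list of base-classifier hyperparameters (see
#'   [classifier_hyper()]).
#' @param provenance Optional character vector marking each row
#'   `"original"` or `"bootstrap"`; the PNN is fitted on original rows
#'   only.
#' @param seed Integer seed controlling all stochastic fitting steps.
#' @return Object of class `vote_stage`.
#' @export
train_stage <- function(x, y, hyper = classifier_hyper(),
                        provenance = NULL, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("stage targets must be 0/1")
  if (is.null(provenance)) provenance <- rep("original", length(y))
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list(seed + 1:3)
  n_centers <- min(hyper$rbf_centers, nrow(xs) - 1)
  orig <- provenance == "original"
  structure(list(
    scaler = scaler,
    models = list(
      fbann = fbann_train(xs, y, n_hidden = hyper$fbann_hidden,
                          lr = hyper$fbann_lr,
                          max_epochs = hyper$fbann_epochs,
                          seed = seeds[[1]]),
      rbfnn = rbfnn_train(xs, y, n_centers = n_centers,
                          seed = seeds[[2]]),
      pnn = pnn_train(xs[orig, , drop = FALSE], as.character(y[orig]),
                      sigma = hyper$pnn_sigma,
                      priors = c("0" = 0.5, "1" = 0.5),
                      seed = seeds[[3]])),
    threshold = 0.5), class = "vote_stage")
}

#' Base-classifier hyperparameters
#'
#' @param fbann_hidden Hidden units of the feedforward network.
#' @param fbann_lr Learning rate of the steepest-descent training.
#' @param fbann_epochs Epoch budget.
#' @param rbf_centers k-means prototypes of the RBF network.
#' @param pnn_sigma PNN kernel width (`NULL`: inner-CV grid search).
#' @return Named list.
#' @export
classifier_hyper <- function(fbann_hidden = 10, fbann_lr = 0.05,
                             fbann_epochs = 500, rbf_centers = 20,
                             pnn_sigma = NULL) {
  list(fbann_hidden = fbann_hidden, fbann_lr = fbann_lr,
       fbann_epochs = fbann_epochs, rbf_centers = rbf_centers,
       pnn_sigma = pnn_sigma)
}

#' Base votes of one stage
#'
#' @param stage A fitted `vote_stage`.
#' @param x Feature matrix.
#' @return n x 3 integer matrix of 0/1 votes (columns fbann, rbfnn, pnn).
#' @export
stage_votes <- function(stage, x) {
  stopifnot(inherits(stage, "vote_stage"))
  xs <- apply_scaler(stage$scaler, as.matrix(x))
  v <- vapply(stage$models,
              function(m) threshold_output(base_score(m, xs)),
              integer(nrow(xs)))
  matrix(v, nrow = nrow(xs), dimnames = list(NULL, names(stage$models)))
}

#' Fused stage decision
#'
#' @inheritParams stage_votes
#' @return Integer 0/1 vector of majority decisions.
#' @export
stage_predict <- function(stage, x) majority_vote(stage_votes(stage, x))

#' Train the two-stage ensemble decoder
#'
#' Stage 1 discriminates movement (1) from rest (0); stage 2, trained on
#' movement trials only, discriminates left-cued (1) from right-cued (0)
#' movements. Class imbalance within the training set is corrected by
#' nearest-neighbor weighted bootstrap augmentation of the minority class
#' up to the majority count (training data only).
#'
#' @param features Feature data frame from [session_features()] (columns
#'   `trial_id`, `label`, then the 70 features), training trials only.
#' @param hyper [classifier_hyper()] list.
#' @param bootstrap Named list with `r`, `gaussian_mu`, `gaussian_sigma`
#'   controlling the augmentation, or `NULL` to disable balancing.
#' @param seed Integer seed.
#' @return Object of class `ensemble_model` with `stage1` and `stage2`.
#' @export
train_ensemble <- function(features, hyper = classifier_hyper(),
                           bootstrap = list(r = 5, gaussian_mu = 0,
                                            gaussian_sigma = 1),
                           seed = NULL) {
  fcols <- setdiff(names(features), c("trial_id", "label", "provenance"))
  X <- as.matrix(features[, fcols])
  lab <- features$label
  s1 <- balance_binary(X, as.integer(lab != "rest"), bootstrap,
                       seed = if (is.null(seed)) NULL else seed + 11)
  mov <- lab != "rest"
  s2 <- balance_binary(X[mov, , drop = FALSE],
                       as.integer(lab[mov] == "left"), bootstrap,
                       seed = if (is.null(seed)) NULL else seed + 12)
  structure(list(
    stage1 = train_stage(s1$x, s1$y, hyper, provenance = s1$provenance,
                         seed = if (is.null(seed)) NULL else seed + 21),
    stage2 = train_stage(s2$x, s2$y, hyper, provenance = s2$provenance,
                         seed = if (is.null(seed)) NULL else seed + 22),
    feature_names = fcols), class = "ensemble_model")
}

# Balance a binary problem by bootstrap-augmenting the minority class up to
# the majority count; returns x, y and a provenance flag per row.
balance_binary <- function(x, y, bootstrap, seed = NULL) {
  if (is.null(bootstrap))
    return(list(x = x, y = y, provenance = rep("original", length(y))))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0 || min(n1, n0) < bootstrap$r + 1)
    return(list(x = x, y = y, provenance = rep("original", length(y))))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n1 - n0)
  bs <- neighbor_bootstrap(x[y == minority, , drop = FALSE], n_target = need,
                           r = bootstrap$r,
                           gaussian_mu = bootstrap$gaussian_mu,
                           gaussian_sigma = bootstrap$gaussian_sigma,
                           seed = seed)
  list(x = rbind(x, bs$samples), y = c(y, rep(minority, need)),
       provenance = c(rep("original", length(y)), rep("bootstrap", need)))
}

#' Two-stage decoding of trials
#'
#' Applies stage 1 (movement vs rest) to every trial; only trials decided
#' as movement are passed to stage 2 (left vs right). Rest decisions never
#' invoke stage 2.
#'
#' @param model A fitted `ensemble_model`.
#' @param x Feature matrix (or feature data frame) of the trials to decode.
#' @return Data frame: `decision` (rest/left/right), `stage1_vote` (0/1),
#'   the three per-base stage-1 votes, and (movement rows only) the
#'   stage-2 votes.
#' @export
decode_trials <- function(model, x) {
  stopifnot(inherits(model, "ensemble_model"))
  if (is.data.frame(x)) x <- as.matrix(x[, model$feature_names])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  v1 <- stage_votes(model$stage1, x)
  d1 <- majority_vote(v1)
  decision <- rep("rest", nrow(x))
  v2full <- matrix(NA_integer_, nrow(x), 3,
                   dimnames = list(NULL, colnames(v1)))
  mov <- which(d1 == 1L)
  if (length(mov) > 0) {
    v2 <- stage_votes(model$stage2, x[mov, , drop = FALSE])
    d2 <- majority_vote(v2)
    decision[mov] <- ifelse(d2 == 1L, "left", "right")
    v2full[mov, ] <- v2
  }
  out <- data.frame(decision = decision, stage1_vote = d1,
                    stringsAsFactors = FALSE)
  colnames(v1) <- paste0("s1_", colnames(v1))
  colnames(v2full) <- paste0("s2_", colnames(v2full))
  cbind(out, v1, v2full)
}

#' Two-stage decoding using a single base classifier
#'
#' Same state machine as [decode_trials()] but with one named base
#' classifier standing in for the ensemble in both stages; used to compare
#' the fused decoder against its components.
#'
#' @param model A fitted `ensemble_model`.
#' @param x Feature matrix.
#' @param base One of `"fbann"`, `"rbfnn"`, `"pnn"`.
#' @return Character vector of rest/left/right decisions.
#' @export
decode_trials_base <- function(model, x, base = c("fbann", "rbfnn", "pnn")) {
  base <- match.arg(base)
  stopifnot(inherits(model, "ensemble_model"))
  if (is.data.frame(x)) x <- as.matrix(x[, model$feature_names])
  x1 <- apply_scaler(model$stage1$scaler, x)
  d1 <- threshold_output(base_score(model$stage1$models[[base]], x1))
  decision <- rep("rest", nrow(x))
  mov <- which(d1 == 1L)
  if (length(mov) > 0) {
    x2 <- apply_scaler(model$stage2$scaler, x[mov, , drop = FALSE])
    d2 <- threshold_output(base_score(model$stage2$models[[base]], x2))
    decision[mov] <- ifelse(d2 == 1L, "left", "right")
  }
  decision
}
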