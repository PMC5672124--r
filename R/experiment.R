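#' Experiment configuration
#'
#' Bundles every setting of an end-to-end decoding experiment: simulator,
#' preprocessing, bootstrap augmentation, classifier hyperparameters and
#' the cross-validation design.
#'
#' @param sim A [sim_config()].
#' @param preprocess A [preprocess_params()].
#' @param bootstrap List with `r`, `gaussian_mu`, `gaussian_sigma`.
#' @param hyper A [classifier_hyper()] list.
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              preprocess = preprocess_params(),
                              bootstrap = list(r = 5, gaussian_mu = 0,
                                               gaussian_sigma = 1),
                              hyper = classifier_hyper(),
                              k_folds = 10, seed = 1) {
  if (k_folds < 2) stop("`k_folds` must be >= 2")
  structure(list(sim = sim, preprocess = preprocess, bootstrap = bootstrap,
                 hyper = hyper, k_folds = k_folds, seed = seed),
            class = "experiment_config")
}

#' Run the full decoding experiment on a synthetic session
#'
#' Executes the complete evaluation protocol: simulate a session,
#' preprocess it, extract the 70-dimensional band-power features,
#' stratified k-fold cross-validation in which each training fold is
#' bootstrap-balanced (test folds are never augmented), per-fold training
#' of the two-stage ensemble, two-stage decoding of the test fold, and
#' pooled plus per-fold evaluation statistics for stage 1 (movement vs
#' rest), stage 2 (left vs right, on true movement trials) and the
#' three-class decoding.
#'
#' @param config An [experiment_config()].
#' @param features Optional precomputed feature table (skips simulation
#'   and feature extraction).
#' @param verbose Print fold progress.
#' @return Object of class `lfp_experiment`: `stage1`, `stage2` (pooled
#'   [metrics_report()]s), `three_class` (confusion matrix, accuracy,
#'   kappa), `base_three_class_accuracy` (named, per base classifier),
#'   `per_fold` (data frame of per-fold rates), `features`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), features = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(features)) {
    session <- simulate_session(config$sim)
    session <- preprocess_session(session, config$preprocess)
    features <- session_features(session)
  }
  fcols <- setdiff(names(features), c("trial_id", "label", "provenance"))
  lab <- features$label
  n <- nrow(features)
  folds <- kfold_split(n, k = config$k_folds, labels = lab,
                       seed = config$seed + 1000)
  classes <- c("rest", "left", "right")
  cm3 <- matrix(0L, 3, 3, dimnames = list(truth = classes,
                                          predicted = classes))
  cm3_base <- lapply(c(fbann = 1, rbfnn = 2, pnn = 3), function(i) cm3)
  ct1 <- NULL; ct2 <- NULL
  per_fold <- list()
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    if (verbose) message(sprintf("fold %d/%d: %d train / %d test",
                                 f, length(folds), length(tr), length(te)))
    model <- train_ensemble(features[tr, , drop = FALSE],
                            hyper = config$hyper,
                            bootstrap = config$bootstrap,
                            seed = config$seed + 100 * f)
    Xte <- as.matrix(features[te, fcols])
    dec <- decode_trials(model, Xte)
    truth <- lab[te]
    # stage 1: movement vs rest
    f_ct1 <- tally_confusion(as.integer(truth != "rest"), dec$stage1_vote)
    ct1 <- if (is.null(ct1)) f_ct1 else add_confusion(ct1, f_ct1)
    # stage 2 evaluated on true movement trials
    mov <- truth != "rest"
    f_ct2 <- NULL
    if (sum(mov) > 0) {
      v2 <- stage_predict(model$stage2, Xte[mov, , drop = FALSE])
      f_ct2 <- tally_confusion(as.integer(truth[mov] == "left"), v2)
      ct2 <- if (is.null(ct2)) f_ct2 else add_confusion(ct2, f_ct2)
    }
    # three-class decisions
    for (i in seq_along(te))
      cm3[truth[i], dec$decision[i]] <- cm3[truth[i], dec$decision[i]] + 1L
    for (b in names(cm3_base)) {
      db <- decode_trials_base(model, Xte, base = b)
      for (i in seq_along(te))
        cm3_base[[b]][truth[i], db[i]] <- cm3_base[[b]][truth[i], db[i]] + 1L
    }
    per_fold[[f]] <- data.frame(
      fold = f,
      stage1_accuracy = basic_rates(f_ct1)$accuracy,
      stage2_accuracy = if (is.null(f_ct2)) NA_real_
                        else basic_rates(f_ct2)$accuracy,
      three_class_accuracy = mean(dec$decision == truth))
  }
  acc3 <- function(m) sum(diag(m)) / sum(m)
  structure(list(
    stage1 = metrics_report(ct1),
    stage2 = metrics_report(ct2),
    three_class = list(confusion = cm3, accuracy = acc3(cm3),
                       kappa = kappa_with_se(cm3)),
    base_three_class_accuracy = vapply(cm3_base, acc3, numeric(1)),
    per_fold = do.call(rbind, per_fold),
    features = features,
    config = config), class = "lfp_experiment")
}

#' @export
print.lfp_experiment <- function(x, ...) {
  cat("Two-stage LFP decoding experiment\n")
  cat(sprintf("  trials: %d (%s)\n", nrow(x$features),
              paste(sprintf("%s=%d", names(table(x$features$label)),
                            table(x$features$label)), collapse = ", ")))
  cat(sprintf("  stage 1 (movement vs rest): accuracy %.3f, kappa %.3f\n",
              x$stage1$accuracy, x$stage1$kappa))
  cat(sprintf("  stage 2 (left vs right):    accuracy %.3f, kappa %.3f\n",
              x$stage2$accuracy, x$stage2$kappa))
  cat(sprintf("  three-class ensemble accuracy: %.3f (kappa %.3f)\n",
              x$three_class$accuracy, x$three_class$kappa$kappa))
  cat("  base three-class accuracies:",
      paste(sprintf("%s %.3f", names(x$base_three_class_accuracy),
                    x$base_three_class_accuracy), collapse = ", "), "\n")
  invisible(x)
}
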