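# Plain-text file dialects: CSV containers for sessions and feature
# tables, key=value files for configuration scalars, JSON for trained
# models. All round-trip to full double precision.

#' Write / read an LFP session as CSV
#'
#' A session is stored as three files under a common prefix:
#' `<prefix>_signals.csv` (columns `left`, `right`),
#' `<prefix>_events.csv` (`stimulus_time_s`, `response_time_s`, `label`)
#' and `<prefix>_meta.txt` (`key=value`, currently `fs`).
#'
#' @param session An `lfp_session`.
#' @param prefix File path prefix.
#' @return `write_session` the prefix (invisibly); `read_session` the
#'   session.
#' @export
write_session <- function(session, prefix) {
  stopifnot(inherits(session, "lfp_session"))
  utils::write.csv(data.frame(left = session$signals$left,
                              right = session$signals$right),
                   paste0(prefix, "_signals.csv"), row.names = FALSE)
  utils::write.csv(session$events, paste0(prefix, "_events.csv"),
                   row.names = FALSE)
  writeLines(sprintf("fs=%.17g", session$fs), paste0(prefix, "_meta.txt"))
  invisible(prefix)
}

#' @rdname write_session
#' @export
read_session <- function(prefix) {
  sig_file <- paste0(prefix, "_signals.csv")
  ev_file <- paste0(prefix, "_events.csv")
  meta_file <- paste0(prefix, "_meta.txt")
  for (f in c(sig_file, ev_file, meta_file))
    if (!file.exists(f)) stop(sprintf("missing session file: %s", f))
  sig <- utils::read.csv(sig_file)
  if (!all(c("left", "right") %in% names(sig)))
    stop(sprintf("%s: expected columns left,right", sig_file))
  ev <- utils::read.csv(ev_file, stringsAsFactors = FALSE)
  meta <- read_keyvals(meta_file)
  if (is.null(meta$fs)) stop(sprintf("%s: missing fs", meta_file))
  new_lfp_session(list(left = sig$left, right = sig$right),
                  as.numeric(meta$fs), ev)
}

read_keyvals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad))
    stop(sprintf("%s: malformed key=value at line %d", path, which(bad)[1]))
  stats::setNames(lapply(kv, function(p) trimws(p[2])),
                  vapply(kv, function(p) trimws(p[1]), character(1)))
}

#' Write / read a feature table as CSV
#'
#' One row per trial: `trial_id`, `label`, optionally `provenance`
#' (original | bootstrap), then the 70 feature columns named
#' `side_band_window`.
#'
#' @param features Feature data frame.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("trial_id", "label") %in% names(df)))
    stop(sprintf("%s: expected trial_id and label columns", path))
  fcols <- setdiff(names(df), c("trial_id", "label", "provenance"))
  bad <- which(!vapply(df[fcols], is.numeric, logical(1)))
  if (length(bad) > 0)
    stop(sprintf("%s: non-numeric feature column %s", path,
                 fcols[bad[1]]))
  if (anyNA(df[fcols])) {
    row <- which(rowSums(is.na(df[fcols])) > 0)[1]
    stop(sprintf("%s: missing feature values in row %d", path, row))
  }
  df
}

#' Serialize / restore a trained ensemble model as JSON
#'
#' The JSON container records both stages' scaler statistics and base
#' classifier parameters (FBANN weights, RBFNN centers/width/weights, PNN
#' patterns/sigma/priors) at full precision.
#'
#' @param model An `ensemble_model`.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ensemble_model"))
  enc_stage <- function(st) list(
    scaler = list(mean = st$scaler$mean, sd = st$scaler$sd),
    fbann = list(W1 = st$models$fbann$W1, b1 = st$models$fbann$b1,
                 w2 = st$models$fbann$w2, b2 = st$models$fbann$b2),
    rbfnn = list(centers = st$models$rbfnn$centers,
                 sigma = st$models$rbfnn$sigma,
                 weights = st$models$rbfnn$weights),
    pnn = list(classes = st$models$pnn$classes,
               sigma = st$models$pnn$sigma, priors = st$models$pnn$priors,
               patterns = st$models$pnn$patterns),
    threshold = st$threshold)
  obj <- list(format = "lfpdecode-ensemble-1",
              feature_names = model$feature_names,
              stage1 = enc_stage(model$stage1),
              stage2 = enc_stage(model$stage2))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lfpdecode-ensemble-1"))
    stop(sprintf("%s: not an lfpdecode ensemble model", path))
  dec_stage <- function(st) {
    fb <- structure(list(W1 = as.matrix(st$fbann$W1),
                         b1 = as.numeric(st$fbann$b1),
                         w2 = as.numeric(st$fbann$w2),
                         b2 = as.numeric(st$fbann$b2)), class = "fbann")
    rb <- structure(list(centers = as.matrix(st$rbfnn$centers),
                         sigma = as.numeric(st$rbfnn$sigma),
                         weights = as.numeric(st$rbfnn$weights)),
                    class = "rbfnn")
    pats <- st$pnn$patterns
    # equal-sized per-class matrices come back as one 3-D array
    if (is.array(pats) && length(dim(pats)) == 3)
      pats <- lapply(seq_len(dim(pats)[1]), function(i) pats[i, , ])
    pn <- structure(list(patterns = lapply(pats, as.matrix),
                         classes = as.character(st$pnn$classes),
                         sigma = as.numeric(st$pnn$sigma),
                         priors = as.numeric(st$pnn$priors)), class = "pnn")
    structure(list(scaler = structure(list(mean = as.numeric(st$scaler$mean),
                                           sd = as.numeric(st$scaler$sd)),
                                      class = "feature_scaler"),
                   models = list(fbann = fb, rbfnn = rb, pnn = pn),
                   threshold = st$threshold), class = "vote_stage")
  }
  structure(list(stage1 = dec_stage(obj$stage1),
                 stage2 = dec_stage(obj$stage2),
                 feature_names = as.character(obj$feature_names)),
            class = "ensemble_model")
}
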