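#' EEG preprocessing, FLDA classification and selection bookkeeping
#'
#' The signal chain: zero-phase band-pass filtering (0.1-30 Hz), epoching
#' on stimulus onsets, selection of the 50-800 ms post-onset window, mean
#' removal, 50-fold decimation and head-to-tail concatenation of the 30
#' channels into 450-sample feature vectors.  A shrinkage-regularized
#' Fisher linear discriminant separates target from nontarget epochs; row
#' and column scores are combined into a cell decision per repetition, and
#' online selections vote over 3 repetitions.
#'
#' @name eeg-pipeline
NULL

EEG_RATE_HZ <- 1000L
N_CHANNELS <- 30L
EPOCH_START_MS <- 50L
EPOCH_END_MS <- 800L
DECIMATION <- 50L
N_FEATURES <- N_CHANNELS * (EPOCH_END_MS - EPOCH_START_MS) / DECIMATION  # 450

#' Construct a raw EEG recording
#'
#' @param samples Numeric `channels x time` matrix (30 channels at
#'   1000 Hz).
#' @param rate Sampling rate in Hz; fixed at 1000.
#' @param events Data frame of stimulus events with columns
#'   `sample_index` (1-based onset sample), `kind`, `index`, `trial`,
#'   `repetition`, `is_target` and `target` (the trial's true cell).
#' @param targets Character vector of true targets, one per trial.
#' @return An object of class `raw_eeg`.
#' @export
raw_eeg <- function(samples, rate = EEG_RATE_HZ, events = NULL,
                    targets = NULL) {
  samples <- as.matrix(samples)
  if (rate != EEG_RATE_HZ)
    stop_spellerseg("sampling rate is fixed at 1000 Hz", "bad_params")
  if (nrow(samples) != N_CHANNELS)
    stop_spellerseg("expected 30 recording channels", "bad_params")
  if (is.null(rownames(samples)))
    rownames(samples) <- sprintf("ch%02d", seq_len(nrow(samples)))
  structure(list(samples = samples, rate = as.integer(rate),
                 events = events, targets = targets),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("raw EEG: %d channels x %d samples (%.1f s at %d Hz), %d event(s), %d trial(s)\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$rate,
              x$rate, if (is.null(x$events)) 0L else nrow(x$events),
              length(x$targets)))
  invisible(x)
}

#' Zero-phase band-pass filter a recording
#'
#' Each channel is filtered forward-backward with a cascade of a
#' 4th-order Butterworth high-pass at `low` Hz and a 4th-order Butterworth
#' low-pass at `high` Hz (an equivalent, numerically stable realization of
#' the 0.1-30 Hz band at a 1000 Hz rate).
#'
#' @param raw A `raw_eeg` recording.
#' @param low,high Band edges in Hz.
#' @return The filtered `raw_eeg`.
#' @export
bandpass_filter <- function(raw, low = 0.1, high = 30) {
  stopifnot(inherits(raw, "raw_eeg"))
  n <- ncol(raw$samples)
  if (n < 100)
    stop_spellerseg("recording too short to filter", "too_short")
  hp <- signal::butter(4, low * 2 / raw$rate, type = "high")
  lp <- signal::butter(4, high * 2 / raw$rate, type = "low")
  raw$samples <- t(apply(raw$samples, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  raw
}

#' Feature vector of one stimulus epoch
#'
#' Per channel, the samples strictly after `onset + 50 ms` up to
#' `onset + 800 ms` (750 samples) are taken, the window mean is removed,
#' and the window is reduced 50-fold; the 30 channels are then
#' concatenated head to tail into 450 values.
#'
#' @param raw A (filtered) `raw_eeg`.
#' @param onset 1-based sample index of the stimulus onset.
#' @param decimate `"block-mean"` (default) averages non-overlapping
#'   50-sample blocks; `"subsample"` takes every 50th sample.
#' @return Numeric feature vector of length 450.
#' @export
extract_features <- function(raw, onset, decimate = c("block-mean", "subsample")) {
  stopifnot(inherits(raw, "raw_eeg"))
  decimate <- match.arg(decimate)
  lo <- onset + EPOCH_START_MS; hi <- onset + EPOCH_END_MS
  if (onset < 1 || hi > ncol(raw$samples))
    stop_spellerseg("epoch window falls outside the recording", "out_of_range")
  win <- raw$samples[, (lo + 1):hi, drop = FALSE]
  win <- win - rowMeans(win)
  nblk <- ncol(win) %/% DECIMATION
  feat <- if (decimate == "block-mean") {
    # channels x 50 x 15 -> mean over the 50-sample axis
    dim(win) <- c(nrow(win), DECIMATION, nblk)
    apply(win, c(1, 3), mean)
  } else {
    win[, seq_len(nblk) * DECIMATION, drop = FALSE]
  }
  as.numeric(t(feat))
}

#' Feature matrix over all events of a recording
#'
#' @param raw A (filtered) `raw_eeg` whose `events` are set.
#' @param decimate Passed to [extract_features()].
#' @return List with `x` (epochs x 450 matrix), `y` (+1 target /
#'   -1 nontarget) and the event log `events`.
#' @export
feature_matrix <- function(raw, decimate = "block-mean") {
  ev <- raw$events
  if (is.null(ev) || nrow(ev) == 0)
    stop_spellerseg("recording carries no events", "bad_params")
  x <- t(vapply(ev$sample_index,
                function(s) extract_features(raw, s, decimate),
                numeric(N_FEATURES)))
  list(x = x, y = ifelse(ev$is_target, 1, -1), events = ev)
}

#' Train a shrinkage-regularized Fisher linear discriminant
#'
#' The discriminant direction is
#' `w = (S_w + shrinkage * (tr(S_w)/d) * I)^{-1} (mu_+ - mu_-)` with `S_w`
#' the pooled within-class scatter; the bias places the midpoint of the
#' projected class means at 0.  Shrinkage keeps the 450-dimensional
#' scatter invertible for small sessions.
#'
#' @param x Feature matrix (epochs x features).
#' @param y Labels, `+1` target / `-1` nontarget; both classes required.
#' @param shrinkage Regularization fraction in `[0, 1)`.
#' @return An object of class `flda` with elements `weights`, `bias`,
#'   `shrinkage`.
#' @export
train_flda <- function(x, y, shrinkage = 0.05) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y))
    stop_spellerseg("x and y dimensions disagree", "dim_mismatch")
  if (!all(sort(unique(y)) %in% c(-1, 1)) || length(unique(y)) < 2)
    stop_spellerseg("need both classes labelled +1 and -1", "single_class")
  if (shrinkage < 0 || shrinkage >= 1)
    stop_spellerseg("shrinkage must be in [0, 1)", "bad_params")
  xp <- x[y > 0, , drop = FALSE]; xm <- x[y < 0, , drop = FALSE]
  mup <- colMeans(xp); mum <- colMeans(xm)
  cp <- sweep(xp, 2, mup); cm <- sweep(xm, 2, mum)
  sw <- (crossprod(cp) + crossprod(cm)) / (nrow(x) - 2)
  d <- ncol(x)
  lambda <- shrinkage * sum(diag(sw)) / d
  w <- solve(sw + diag(lambda + 1e-12, d), mup - mum)
  b <- -sum(w * (mup + mum)) / 2
  structure(list(weights = as.numeric(w), bias = b, shrinkage = shrinkage,
                 n_train = nrow(x)), class = "flda")
}

#' @export
print.flda <- function(x, ...) {
  cat(sprintf("Fisher linear discriminant: %d features, shrinkage %.3g, trained on %d epochs\n",
              length(x$weights), x$shrinkage, x$n_train))
  invisible(x)
}

#' @export
coef.flda <- function(object, ...) {
  c(bias = object$bias, object$weights)
}

#' Discriminant scores for new epochs
#'
#' @param object A trained `flda` model.
#' @param newdata Feature matrix (epochs x features) or a single feature
#'   vector.
#' @param ... Unused.
#' @return Numeric score per epoch; positive leans target.
#' @export
predict.flda <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$weights))
    stop_spellerseg("feature dimension does not match the model", "dim_mismatch")
  as.numeric(newdata %*% object$weights + object$bias)
}

#' Cell decision from one repetition's six scores
#'
#' The attended cell sits at the crossing of the highest-scoring row and
#' the highest-scoring column; ties go to the lowest index.
#'
#' @param scores Data frame with columns `kind` (`"row"`/`"column"`),
#'   `index` (0..2) and `score`; exactly 6 rows, one per stimulus.
#' @param layout The [speller_layout()].
#' @return The selected cell identifier.
#' @export
classify_repetition <- function(scores, layout = speller_layout()) {
  if (nrow(scores) != 6)
    stop_spellerseg("a repetition has exactly 6 stimulus scores", "wrong_count")
  rs <- scores[scores$kind == "row", ]
  cs <- scores[scores$kind == "column", ]
  if (nrow(rs) != 3 || nrow(cs) != 3)
    stop_spellerseg("need 3 row and 3 column scores", "wrong_count")
  ri <- rs$index[order(rs$index)][which.max(rs$score[order(rs$index)])]
  ci <- cs$index[order(cs$index)][which.max(cs$score[order(cs$index)])]
  unclass(layout)[ri + 1, ci + 1]
}

#' Cell decision for an offline trial
#'
#' Aggregates the discriminant scores over the trial's repetitions
#' (summing per row/column stimulus) before the row/column decision.
#'
#' @param scores Data frame with columns `kind`, `index`, `score` covering
#'   all repetitions of the trial.
#' @param layout The [speller_layout()].
#' @return The selected cell identifier.
#' @export
classify_trial <- function(scores, layout = speller_layout()) {
  agg <- stats::aggregate(score ~ kind + index, data = scores, FUN = sum)
  classify_repetition(agg, layout)
}

#' Online selection by voting over 3 repetitions
#'
#' The cell predicted by at least 2 of the 3 repetitions wins.  When all
#' three disagree, the cell with the greatest summed row + column
#' discriminant score across the repetitions is selected.
#'
#' @param predictions Character vector of 3 per-repetition cell decisions.
#' @param scores Data frame with `kind`, `index`, `score` pooled over the
#'   3 repetitions; only consulted when all predictions differ.
#' @param layout The [speller_layout()].
#' @return The selected cell identifier.
#' @export
vote_online <- function(predictions, scores = NULL, layout = speller_layout()) {
  if (length(predictions) != 3)
    stop_spellerseg("online voting uses exactly 3 repetitions", "wrong_count")
  tab <- table(predictions)
  if (max(tab) >= 2) return(names(tab)[which.max(tab)])
  if (is.null(scores))
    stop_spellerseg("3-way disagreement needs fallback scores", "wrong_count")
  classify_trial(scores, layout)
}

#' Percentage of correct selections
#'
#' @param predicted,truth Equal-length vectors of selected and true cell
#'   identifiers (or a 2-column data frame as `predicted`).
#' @return `100 * correct / total`, rounded half-up to 2 decimals.
#' @examples
#' session_accuracy(c(rep("O1", 17), "O2"), rep("O1", 18))  # 94.44
#' @export
session_accuracy <- function(predicted, truth = NULL) {
  if (is.data.frame(predicted)) {
    truth <- predicted[[2]]; predicted <- predicted[[1]]
  }
  if (length(predicted) == 0)
    stop_spellerseg("no selection results", "empty_results")
  if (length(predicted) != length(truth))
    stop_spellerseg("predicted and truth lengths disagree", "dim_mismatch")
  round_half_up(100 * mean(predicted == truth), 2)
}

#' Mean of session accuracies
#'
#' @param accuracies Numeric vector of per-session accuracy percentages.
#' @return Their mean, rounded half-up to 2 decimals.
#' @export
mean_accuracy <- function(accuracies) {
  round_half_up(mean(as.numeric(accuracies)), 2)
}

# per-repetition score table(s) for one trial of a recording
trial_score_tables <- function(model, feats, trial_id) {
  ev <- feats$events
  sel <- ev$trial == trial_id
  sc <- predict(model, feats$x[sel, , drop = FALSE])
  data.frame(repetition = ev$repetition[sel], kind = ev$kind[sel],
             index = ev$index[sel], score = sc, stringsAsFactors = FALSE)
}

#' Decode every trial of a recorded session
#'
#' Offline mode aggregates the scores of all of a trial's repetitions
#' before deciding; online mode decides per repetition and lets the 3
#' repetitions vote.
#'
#' @param model A trained `flda`.
#' @param raw A filtered `raw_eeg` with events and per-trial targets.
#' @param mode `"online"` (3-repetition voting) or `"offline"`
#'   (score aggregation across the trial).
#' @param layout The [speller_layout()].
#' @param decimate Passed to [extract_features()].
#' @return Data frame with one row per trial: `trial`, `predicted`,
#'   `target`.
#' @export
classify_session <- function(model, raw, mode = c("online", "offline"),
                             layout = speller_layout(),
                             decimate = "block-mean") {
  mode <- match.arg(mode)
  feats <- feature_matrix(raw, decimate)
  trials <- sort(unique(feats$events$trial))
  predicted <- vapply(trials, function(tr) {
    tab <- trial_score_tables(model, feats, tr)
    if (mode == "offline") return(classify_trial(tab, layout))
    reps <- sort(unique(tab$repetition))
    if (length(reps) != 3)
      stop_spellerseg("online voting uses exactly 3 repetitions", "wrong_count")
    preds <- vapply(reps, function(rp)
      classify_repetition(tab[tab$repetition == rp, ], layout), character(1))
    vote_online(preds, tab, layout)
  }, character(1))
  data.frame(trial = trials, predicted = predicted,
             target = raw$targets[seq_along(trials)],
             stringsAsFactors = FALSE)
}

#' Save / load an FLDA model as a flat text file
#'
#' @param model A trained `flda`.
#' @param path Output path.
#' @export
write_flda <- function(model, path) {
  writeLines(c(sprintf("# flda shrinkage=%g n_train=%d", model$shrinkage,
                       model$n_train),
               sprintf("%.17g", c(model$bias, model$weights))), path)
  invisible(path)
}

#' @rdname write_flda
#' @export
read_flda <- function(path) {
  lines <- readLines(path)
  meta <- lines[1]
  v <- as.numeric(lines[-1])
  structure(list(weights = v[-1], bias = v[1],
                 shrinkage = as.numeric(sub(".*shrinkage=([0-9.eE+-]+).*", "\\1", meta)),
                 n_train = as.integer(sub(".*n_train=([0-9]+).*", "\\1", meta))),
            class = "flda")
}
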