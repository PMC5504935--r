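#' Synthetic scenes and synthetic EEG sessions
#'
#' Stand-ins for photographed scenes and human recordings: cluttered
#' multi-blob color scenes under a controllable global multiplicative
#' illumination factor, and oddball speller EEG in which every flash that
#' covers the attended cell carries a positive half-cosine deflection
#' around 300 ms after onset on top of Gaussian channel noise.  Both
#' generators are bit-reproducible from their `rng_seed` and emit ground
#' truth (blob masks, per-trial targets) so accuracy and
#' intersection-over-union are well defined.
#'
#' @name synthetic-data
NULL

#' Specify a synthetic cluttered scene
#'
#' Blobs are placed on a fixed 2 x 4 grid of centers, alternating ellipse
#' and rectangle footprints with mildly varying sizes, each painted in its
#' object's seed color plus per-pixel Gaussian channel jitter.  Clutter
#' speckles of random color (1-2 px) are scattered at least `clutter_margin`
#' pixels away from every blob so ground truth stays unambiguous.  The
#' illumination factor scales all channels last (then rounds and clips to
#' 8 bits), emulating the same scene shot under dimmer light.
#'
#' @param canvas `c(M, N)` image size in pixels.
#' @param objects Object identifiers to place (default all dataset
#'   objects, `O1..O7`).
#' @param dataset Seed-pixel dataset supplying the blob colors.
#' @param jitter_sd Per-channel Gaussian jitter of blob pixels, intensity
#'   counts.
#' @param clutter_n Number of clutter speckles.
#' @param clutter_color_range Channel range the speckle colors are drawn
#'   from.
#' @param clutter_margin Minimum pixel distance between clutter and any
#'   blob bounding box.
#' @param background Background RGB color (chosen so it matches no
#'   object's fuzzy parameters).
#' @param illumination Positive global channel scale factor.
#' @param rng_seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(canvas = c(90L, 120L), objects = NULL,
                       dataset = read_seed_dataset(), jitter_sd = 4,
                       clutter_n = 40L, clutter_color_range = c(20L, 235L),
                       clutter_margin = 3L, background = c(20, 80, 30),
                       illumination = 1, rng_seed = 1L) {
  if (!(illumination > 0))
    stop_spellerseg("illumination factor must be positive", "bad_params")
  objects <- objects %||% names(dataset)
  stopifnot(all(objects %in% names(dataset)))
  structure(list(canvas = as.integer(canvas), objects = objects,
                 dataset = dataset, jitter_sd = jitter_sd,
                 clutter_n = as.integer(clutter_n),
                 clutter_color_range = clutter_color_range,
                 clutter_margin = as.integer(clutter_margin),
                 background = background, illumination = illumination,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# deterministic blob geometry for up to 8 objects on a 2 x 4 grid
blob_footprint <- function(i, canvas) {
  M <- canvas[1]; N <- canvas[2]
  centers_m <- round(c(0.27, 0.73) * M)
  centers_n <- round(c(0.14, 0.38, 0.62, 0.86) * N)
  cm <- centers_m[(i - 1) %/% 4 + 1]
  cn <- centers_n[(i - 1) %% 4 + 1]
  rm <- 6 + (i %% 3)        # semi-axis / half-height 6..8
  rn <- 7 + ((i * 2) %% 3)  # semi-axis / half-width  7..9
  mm <- outer(seq_len(M) - 1 - cm, rep(1, N))
  nn <- outer(rep(1, M), seq_len(N) - 1 - cn)
  if (i %% 2 == 1) (mm / rm)^2 + (nn / rn)^2 <= 1   # ellipse
  else abs(mm) <= rm & abs(nn) <= rn                # rectangle
}

#' Render a synthetic scene
#'
#' @param spec A [scene_spec()].
#' @return An object of class `scene`: the 8-bit `image`
#'   (`M x N x 3`), per-object ground-truth `masks` (0/1 matrices,
#'   recorded before jitter, clutter and illumination), and the `spec`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  M <- spec$canvas[1]; N <- spec$canvas[2]
  img <- array(rep(spec$background, each = M * N), c(M, N, 3))
  masks <- list()
  blob_any <- matrix(FALSE, M, N)
  with_seed(spec$rng_seed, {
    for (k in seq_along(spec$objects)) {
      id <- spec$objects[k]
      fp <- blob_footprint(k, spec$canvas)
      if (any(fp & blob_any))
        warning("blob footprints overlap; ground-truth masks intersect")
      masks[[id]] <- matrix(as.integer(fp), M, N)
      blob_any <- blob_any | fp
      col <- spec$dataset[[id]]$seed
      n_px <- sum(fp)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[fp] <- col[ch] + stats::rnorm(n_px, 0, spec$jitter_sd)
        img[, , ch] <- plane
      }
    }
    # keep-out zone around every blob for clutter placement
    keep_out <- blob_any
    mg <- spec$clutter_margin
    if (mg > 0) {
      idx <- which(blob_any, arr.ind = TRUE)
      for (dm in -mg:mg) for (dn in -mg:mg) {
        mm <- pmin(pmax(idx[, 1] + dm, 1L), M)
        nn <- pmin(pmax(idx[, 2] + dn, 1L), N)
        keep_out[cbind(mm, nn)] <- TRUE
      }
    }
    free <- which(!keep_out)
    if (spec$clutter_n > 0 && length(free) > 0) {
      at <- sample(free, min(spec$clutter_n, length(free)))
      lo <- spec$clutter_color_range[1]; hi <- spec$clutter_color_range[2]
      for (p in at) {
        col <- stats::runif(3, lo, hi)
        cells <- p
        if (stats::runif(1) < 0.5 && p %% M != 0) cells <- c(p, p + 1L)  # 2 px tall
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[cells] <- col[ch]
          img[, , ch] <- plane
        }
      }
    }
  })
  # quantize the reference scene to 8 bits, then apply illumination last
  img <- round(pmax(0, pmin(255, img)))
  img <- round(img * spec$illumination)
  img <- array(as.integer(pmax(0, pmin(255, img))), c(M, N, 3))
  structure(list(image = img, masks = masks, spec = spec), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("synthetic scene %d x %d, %d object blob(s) (%s), illumination %.2f\n",
              nrow(x$image), ncol(x$image), length(x$masks),
              paste(names(x$masks), collapse = ", "), x$spec$illumination))
  invisible(x)
}

#' Specify the synthetic event-related response
#'
#' Every flash covering the attended cell adds a positive half-cosine
#' deflection of the given amplitude, centered `latency_ms` after
#' stimulus onset with the given total width, scaled per channel by a
#' fixed posterior-weighted topography; all channels carry independent
#' Gaussian noise.
#'
#' @param amplitude Peak deflection in microvolts.
#' @param latency_ms Deflection center relative to stimulus onset.
#' @param width_ms Total support of the half-cosine.
#' @param noise_sd Gaussian channel noise standard deviation, microvolts.
#' @param n_channels Number of recording channels (30).
#' @param rng_seed Integer seed.
#' @return An object of class `erp_spec`.
#' @export
erp_spec <- function(amplitude = 8, latency_ms = 300, width_ms = 400,
                     noise_sd = 4, n_channels = N_CHANNELS, rng_seed = 1L) {
  if (noise_sd < 0) stop_spellerseg("noise_sd must be >= 0", "bad_params")
  if (latency_ms + width_ms / 2 > EPOCH_END_MS)
    stop_spellerseg("deflection must fit inside the 800 ms epoch", "bad_params")
  structure(list(amplitude = amplitude, latency_ms = latency_ms,
                 width_ms = width_ms, noise_sd = noise_sd,
                 n_channels = as.integer(n_channels),
                 rng_seed = as.integer(rng_seed)),
            class = "erp_spec")
}

# fixed smooth posterior-weighted channel gain profile
erp_topography <- function(n_channels) {
  0.4 + 0.6 * ((seq_len(n_channels) - 1) / (n_channels - 1))^2
}

#' Synthesize an oddball EEG session for a stimulus schedule
#'
#' Trials are laid out back to back: trial `t` occupies repetitions
#' `(t-1)*R + 1 .. t*R` of the schedule, where `R = reps_per_trial`, with
#' 200 ms lead-in and 1000 ms tail padding around the session.
#'
#' @param schedule A [build_schedule()] result with
#'   `length(targets) * reps_per_trial` repetitions.
#' @param targets Character vector of attended cells, one per trial.
#' @param spec An [erp_spec()].
#' @param reps_per_trial Repetitions per trial.
#' @param layout The [speller_layout()].
#' @return A `raw_eeg` with the full event log (absolute sample onsets,
#'   per-event `is_target`) and per-trial targets.
#' @export
make_eeg_session <- function(schedule, targets, spec,
                             reps_per_trial = 3L,
                             layout = speller_layout()) {
  stopifnot(inherits(spec, "erp_spec"))
  n_rep <- attr(schedule, "n_repetitions")
  if (n_rep != length(targets) * reps_per_trial)
    stop_spellerseg("schedule length does not cover targets x repetitions",
                    "inconsistent_length")
  pad <- 200L
  total <- pad + n_rep * REPETITION_SPAN_MS + 1000L
  ev <- as.data.frame(schedule)
  ev$trial <- (ev$repetition - 1L) %/% reps_per_trial + 1L
  ev$target <- targets[ev$trial]
  ev$sample_index <- pad + (ev$repetition - 1L) * REPETITION_SPAN_MS +
    ev$onset_ms + 1L
  pos <- vapply(targets, function(tg) target_position(layout, tg), numeric(2))
  ev$is_target <- ifelse(ev$kind == "row",
                         ev$index == pos["row", ev$trial],
                         ev$index == pos["col", ev$trial])
  nc <- spec$n_channels
  samples <- with_seed(spec$rng_seed,
    matrix(stats::rnorm(nc * total, 0, spec$noise_sd), nrow = nc))
  if (spec$amplitude != 0) {
    topo <- erp_topography(nc)
    half <- spec$width_ms / 2
    trel <- seq(-half + 1, half - 1)
    bump <- spec$amplitude * cos(pi * trel / spec$width_ms)
    for (i in which(ev$is_target)) {
      center <- ev$sample_index[i] + spec$latency_ms
      at <- center + trel
      ok <- at >= 1 & at <= total
      samples[, at[ok]] <- samples[, at[ok]] + outer(topo, bump[ok])
    }
  }
  raw_eeg(samples, events = ev, targets = targets)
}

# convenience: schedule + session in one step, seeds derived from one seed
simulate_session <- function(targets, reps_per_trial, spec, rng_seed,
                             layout = speller_layout()) {
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, 2))
  sched <- build_schedule(length(targets) * reps_per_trial, seeds[1])
  spec$rng_seed <- seeds[2]
  make_eeg_session(sched, targets, spec, reps_per_trial, layout)
}

#' Simulate, train and evaluate the whole selection-plus-extraction loop
#'
#' Trains the discriminant on a simulated offline session (18 trials of 6
#' repetitions by default), runs simulated online selections (3
#' repetitions each, majority voting), and extracts every scene object
#' whose parameters the dataset carries, reporting online selection
#' accuracy and per-object mask IoU against the scene's ground truth.
#'
#' @param scene A [scene_spec()].
#' @param erp An [erp_spec()].
#' @param n_selections Number of online selections to simulate.
#' @param rng_seed Master seed; all stage seeds derive from it.
#' @param cfg A [growth_config()] for the extraction stage.
#' @param offline_trials,offline_reps Size of the simulated training
#'   session.
#' @return An object of class `e2e_report`: `accuracy` (percent),
#'   `selections` (per-selection data frame), `iou` (named per-object
#'   vector), `masks`, the trained `model` and the `scene`.
#' @export
run_end_to_end <- function(scene = scene_spec(), erp = erp_spec(),
                           n_selections = 18L, rng_seed = 1L,
                           cfg = growth_config(),
                           offline_trials = 18L, offline_reps = 6L) {
  stopifnot(inherits(scene, "scene_spec"), inherits(erp, "erp_spec"))
  layout <- speller_layout()
  cells <- as.character(t(unclass(layout)))
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, 3))

  # offline phase: train the discriminant
  off_targets <- rep_len(cells, offline_trials)
  off_raw <- bandpass_filter(
    simulate_session(off_targets, offline_reps, erp, seeds[1]))
  off <- feature_matrix(off_raw)
  model <- train_flda(off$x, off$y)

  # online phase: batches of up to 18 selections, 3 repetitions each
  sel <- list()
  remaining <- n_selections
  batch_seed <- seeds[2]
  while (remaining > 0) {
    nb <- min(18L, remaining)
    tg <- rep_len(cells, nb)
    raw <- bandpass_filter(simulate_session(tg, 3L, erp, batch_seed))
    sel[[length(sel) + 1L]] <- classify_session(model, raw, "online", layout)
    remaining <- remaining - nb
    batch_seed <- (batch_seed + 7919L) %% .Machine$integer.max
  }
  selections <- do.call(rbind, sel)
  accuracy <- session_accuracy(selections$predicted, selections$target)

  # extraction phase on the synthetic scene
  scene$rng_seed <- seeds[3]
  sc <- make_scene(scene)
  ids <- intersect(names(sc$masks), names(scene$dataset))
  masks <- list(); iou <- stats::setNames(numeric(0), character(0))
  for (id in ids) {
    om <- extract_object(sc$image, lookup_params(scene$dataset, id), cfg)
    masks[[id]] <- om
    iou[id] <- mask_iou(om$mask, sc$masks[[id]])
  }
  structure(list(accuracy = accuracy, n_selections = n_selections,
                 selections = selections, iou = iou, masks = masks,
                 model = model, scene = sc, rng_seed = rng_seed),
            class = "e2e_report")
}

#' @export
print.e2e_report <- function(x, ...) {
  cat(sprintf("end-to-end report (seed %d)\n", x$rng_seed))
  cat(sprintf("  online selection accuracy: %.2f%% over %d selections\n",
              x$accuracy, x$n_selections))
  if (length(x$iou))
    cat(sprintf("  mask IoU vs ground truth: %s\n",
                paste(sprintf("%s=%.3f", names(x$iou), x$iou), collapse = " ")))
  invisible(x)
}
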