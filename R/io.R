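# File interchange: 8-bit RGB PNG scenes, 0/255 mask PNGs, delimited
# seed-pixel dataset configs, delimited EEG recordings and event logs.

#' Read an 8-bit RGB image from a PNG file
#'
#' Grayscale images are expanded to three equal channels; an alpha channel
#' is dropped.
#'
#' @param path PNG file path.
#' @return Integer `M x N x 3` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 2) x <- array(rep(x[, , 1], 3), c(dim(x)[1:2], 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(255 * x)), dim(x))
}

#' Write an 8-bit RGB image to a PNG file
#'
#' @param image Integer `M x N x 3` array, values in `[0, 255]`.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(as_image(image) / 255, path)
  invisible(path)
}

#' Write a binary mask as a single-channel 0/255 PNG
#'
#' @param mask 0/1 matrix or an `object_mask`.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "object_mask")) mask <- mask$mask
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG back to a 0/1 matrix
#'
#' @param path PNG file path.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(x > 0.5), nrow(x), ncol(x))
}

#' Read a seed-pixel dataset config
#'
#' A tab-separated file with one record per object and columns `object`,
#' `r`, `g`, `b` (seed channels), `alpha1`, `alpha2`, `rho_m`, `sigma`,
#' `r_gate`, `gap_threshold`.  `r_gate` may be `Inf` to disable the
#' proximity gate.
#'
#' @param path Path to the config; defaults to the dataset shipped with
#'   the package (seven objects O1..O7).
#' @return An object of class `seed_dataset`: a named list of entries,
#'   each with `object_id`, `seed` and [fuzzy_params()].
#' @export
read_seed_dataset <- function(path = system.file("extdata", "seed_dataset.tsv",
                                                 package = "spellerseg")) {
  if (!file.exists(path))
    stop_spellerseg(sprintf("dataset config not found: %s", path), "missing_file")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("object", "r", "g", "b", "alpha1", "alpha2", "rho_m", "sigma",
            "r_gate", "gap_threshold")
  if (!all(need %in% names(tab)))
    stop_spellerseg("dataset config lacks required columns", "bad_config")
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    list(object_id = row$object,
         seed = c(row$r, row$g, row$b),
         params = fuzzy_params(row$alpha1, row$alpha2, row$rho_m, row$sigma,
                               r = row$r_gate, gap_threshold = row$gap_threshold))
  })
  names(entries) <- tab$object
  structure(entries, class = "seed_dataset")
}

#' @export
print.seed_dataset <- function(x, ...) {
  cat(sprintf("seed-pixel dataset with %d object(s): %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write a stimulus schedule as a delimited event log
#'
#' @param schedule A schedule from [build_schedule()].
#' @param path Output path (TSV: repetition, onset_ms, kind, index,
#'   duration_ms).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a recorded EEG session as delimited text
#'
#' Two files are produced: `<path>` with one row per sample and one column
#' per channel (header carries the sampling rate and channel names), and
#' `<path base>_events.tsv` with the stimulus event log.
#'
#' @param raw A `raw_eeg` object.
#' @param path Output path for the sample table.
#' @export
write_eeg <- function(raw, path) {
  stopifnot(inherits(raw, "raw_eeg"))
  con <- file(path, "w")
  writeLines(sprintf("# rate_hz=%d", raw$rate), con)
  close(con)
  samp <- as.data.frame(t(raw$samples))
  names(samp) <- rownames(raw$samples)
  suppressWarnings(utils::write.table(samp, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  ev_path <- sub("\\.tsv$", "", path)
  utils::write.table(raw$events, paste0(ev_path, "_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EEG session written by [write_eeg()]
#'
#' @param path Path of the sample table; the event log is read from the
#'   matching `_events.tsv` file.
#' @return A `raw_eeg` object.
#' @export
read_eeg <- function(path) {
  header <- readLines(path, n = 1)
  rate <- as.integer(sub(".*rate_hz=", "", header))
  samp <- utils::read.delim(path, skip = 1)
  ev <- utils::read.delim(paste0(sub("\\.tsv$", "", path), "_events.tsv"),
                          stringsAsFactors = FALSE)
  samples <- t(as.matrix(samp))
  rownames(samples) <- names(samp)
  targets <- unique(ev[, c("trial", "target")])
  raw_eeg(samples, rate = rate, events = ev,
          targets = targets$target[order(targets$trial)])
}
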