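#' The 3x3 P300 speller paradigm
#'
#' A 3x3 grid of selectable objects is flashed row by row and column by
#' column.  One repetition flashes each of the 3 rows and 3 columns once in
#' random order, so every cell is covered exactly twice per repetition.  A
#' stimulus is presented for 200 ms with 300 ms onset-to-onset spacing, so
#' one repetition spans 6 x 300 ms = 1.8 s.  Attending a cell makes the
#' flashes that cover it rare, attended events - the oddball condition that
#' elicits a P300 deflection used to decode the attended cell.
#'
#' @name p300-speller
NULL

STIM_ONSET_SPACING_MS <- 300
STIM_DURATION_MS <- 200
REPETITION_SPAN_MS <- 6 * STIM_ONSET_SPACING_MS

#' The speller grid layout
#'
#' Cells are filled row-major with the seven dataset objects `O1..O7`
#' followed by two reserved slots `R8`, `R9`.
#'
#' @return A 3x3 character matrix of cell identifiers, class
#'   `speller_layout`.
#' @export
speller_layout <- function() {
  structure(matrix(c("O1", "O2", "O3", "O4", "O5", "O6", "O7", "R8", "R9"),
                   nrow = 3, byrow = TRUE),
            class = c("speller_layout", "matrix"))
}

target_position <- function(layout, target_id) {
  pos <- which(unclass(layout) == target_id, arr.ind = TRUE)
  if (nrow(pos) != 1)
    stop_spellerseg(sprintf("unknown target '%s'", target_id), "unknown_target")
  c(row = unname(pos[1, 1]) - 1L, col = unname(pos[1, 2]) - 1L)
}

#' Build a randomized stimulus schedule
#'
#' Each repetition is an independent seeded-random permutation of the six
#' stimuli (rows 0..2, columns 0..2) with onsets at 0, 300, ..., 1500 ms
#' from the repetition start and 200 ms presentation each.
#'
#' @param n_repetitions Number of repetitions (>= 1).
#' @param rng_seed Integer seed; equal seeds give identical schedules.
#' @return A data frame of class `speller_schedule` with columns
#'   `repetition` (1-based), `onset_ms` (from repetition start), `kind`
#'   (`"row"`/`"column"`), `index` (0..2) and `duration_ms`.
#' @export
build_schedule <- function(n_repetitions, rng_seed = 1L) {
  if (n_repetitions < 1) stop_spellerseg("need n_repetitions >= 1", "bad_params")
  stim <- data.frame(kind = rep(c("row", "column"), each = 3),
                     index = rep(0:2, 2), stringsAsFactors = FALSE)
  reps <- with_seed(rng_seed, {
    lapply(seq_len(n_repetitions), function(k) {
      ord <- sample.int(6L)
      data.frame(repetition = k,
                 onset_ms = (seq_len(6L) - 1L) * STIM_ONSET_SPACING_MS,
                 kind = stim$kind[ord], index = stim$index[ord],
                 duration_ms = STIM_DURATION_MS,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, reps)
  attr(out, "n_repetitions") <- as.integer(n_repetitions)
  attr(out, "rng_seed") <- as.integer(rng_seed)
  class(out) <- c("speller_schedule", "data.frame")
  out
}

#' Events of a schedule that cover one target
#'
#' A cell is covered by the flash of its row and the flash of its column:
#' exactly 2 events per repetition.
#'
#' @param schedule A [build_schedule()] result.
#' @param target_id Cell identifier (`O1..O7`, `R8`, `R9`).
#' @param layout The [speller_layout()].
#' @return The covering rows of `schedule`, ordered by repetition and
#'   onset.
#' @export
flashes_covering_target <- function(schedule, target_id,
                                    layout = speller_layout()) {
  pos <- target_position(layout, target_id)
  hit <- (schedule$kind == "row" & schedule$index == pos["row"]) |
    (schedule$kind == "column" & schedule$index == pos["col"])
  out <- schedule[hit, , drop = FALSE]
  out[order(out$repetition, out$onset_ms), , drop = FALSE]
}

#' Look up one object's seed pixel and fuzzy parameters
#'
#' @param dataset A [read_seed_dataset()] result.
#' @param object_id Object identifier, e.g. `"O1"`.
#' @return The dataset entry: `object_id`, `seed`, `params`.
#' @export
lookup_params <- function(dataset, object_id) {
  stopifnot(inherits(dataset, "seed_dataset"))
  entry <- dataset[[object_id]]
  if (is.null(entry))
    stop_spellerseg(sprintf("no dataset entry for object '%s'", object_id),
                    "unknown_object")
  entry
}
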