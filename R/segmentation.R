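#' Seeded subregion growing and object extraction
#'
#' Given a seed pixel and its fuzzy parameters, the extractor repeatedly
#' (i) picks the unassigned pixel whose vector angle to the seed is
#' minimal, (ii) grows the connected set of fuzzy-matched pixels reachable
#' from it under the configured neighborhood pattern, and (iii) moves on to
#' the next subregion, until the next candidate fails the fuzzy match or
#' the squared-RGB-distance gate `r`.  The largest subregion is taken to be
#' the object; short unextracted runs inside it are then filled row by row
#' and column by column.
#'
#' @name segmentation
NULL

CONNECTIVITIES <- list(
  "4-adjacent" = cbind(dm = c(-1, 1, 0, 0), dn = c(0, 0, -1, 1)),
  "4-diagonal" = cbind(dm = c(-1, -1, 1, 1), dn = c(-1, 1, -1, 1)),
  "8-neighbor" = cbind(dm = c(-1, -1, -1, 0, 0, 1, 1, 1),
                       dn = c(-1, 0, 1, -1, 1, -1, 0, 1)))

#' Subregion-growing configuration
#'
#' @param connectivity Neighborhood pattern used while growing:
#'   `"8-neighbor"` (default), `"4-adjacent"` (edge neighbors) or
#'   `"4-diagonal"` (corner neighbors).
#' @param r Optional override of the per-object squared-distance gate
#'   threshold; `NULL` uses the value carried by the object's
#'   [fuzzy_params()], `Inf` disables the gate.
#' @param gap_threshold Optional override of the per-object gap-filling
#'   threshold (pixels).
#' @param max_subregions Safety cap on the number of subregions grown.
#' @param gate_per_pixel If `TRUE` the distance gate is also applied to
#'   every pixel during growth, not only to each new subregion's start
#'   candidate.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(connectivity = c("8-neighbor", "4-adjacent", "4-diagonal"),
                          r = NULL, gap_threshold = NULL,
                          max_subregions = 512L, gate_per_pixel = FALSE) {
  connectivity <- match.arg(connectivity)
  if (!is.null(r) && !(r > 0)) stop_spellerseg("need r > 0", "bad_params")
  if (max_subregions < 1) stop_spellerseg("need max_subregions >= 1", "bad_params")
  structure(list(connectivity = connectivity, r = r,
                 gap_threshold = gap_threshold,
                 max_subregions = as.integer(max_subregions),
                 gate_per_pixel = isTRUE(gate_per_pixel)),
            class = "growth_config")
}

as_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3))
    stop_spellerseg("image must be an M x N x 3 array", "bad_image")
  if (anyNA(image) || any(image < 0) || any(image > 255))
    stop_spellerseg("image channels must lie in [0, 255]", "bad_image")
  image
}

# 0-based (m, n) <-> 1-based column-major linear index over an M x N matrix
coord_to_lin <- function(coords, M) coords[, 2] * M + coords[, 1] + 1L
lin_to_coord <- function(idx, M) cbind(m = (idx - 1L) %% M, n = (idx - 1L) %/% M)

# row-major scan rank of a linear index, for tie-breaking
rowmajor_rank <- function(idx, M, N) ((idx - 1L) %% M) * N + (idx - 1L) %/% M

new_subregion <- function(idx, M) {
  idx <- sort(idx)
  structure(list(coords = lin_to_coord(idx, M), size = length(idx),
                 .lin = idx, .M = M), class = "subregion")
}

#' @export
print.subregion <- function(x, ...) {
  cat(sprintf("subregion of %d pixel(s)\n", x$size))
  invisible(x)
}

#' Minimal-angle start pixel
#'
#' Among the remaining (unassigned) pixels, returns the coordinate whose
#' vector angle to the seed is smallest; ties are broken by row-major scan
#' order.  Degenerate all-zero pixels sort last.
#'
#' @param image An `M x N x 3` array with channels in `[0, 255]`.
#' @param seed The seed pixel (length-3 RGB vector).
#' @param remaining Logical `M x N` matrix marking candidate pixels;
#'   `NULL` means all pixels.
#' @return Integer vector `c(m, n)` of 0-based (row, column) coordinates.
#' @export
find_start_pixel <- function(image, seed, remaining = NULL) {
  image <- as_image(image)
  a <- angle_map(image, seed)
  k <- find_start_lin(a, remaining, nrow(a), ncol(a))
  c(m = (k - 1L) %% nrow(a), n = (k - 1L) %/% nrow(a))
}

find_start_lin <- function(angles, remaining, M, N) {
  cand <- if (is.null(remaining)) seq_along(angles) else which(remaining)
  if (length(cand) == 0)
    stop_spellerseg("no remaining pixels to start from", "empty_set")
  av <- angles[cand]
  av[is.na(av)] <- Inf
  best <- min(av)
  if (!is.finite(best))
    return(cand[which.min(rowmajor_rank(cand, M, N))])
  ties <- cand[av == best]
  ties[which.min(rowmajor_rank(ties, M, N))]
}

#' Grow one subregion from a start pixel
#'
#' Breadth-first closure of fuzzy-matched pixels reachable from `start`
#' through the configured neighborhood; growth stops when no matched pixel
#' is adjacent to the subregion.
#'
#' @inheritParams find_start_pixel
#' @param start 0-based `c(m, n)` coordinate of a matched pixel.
#' @param params The object's [fuzzy_params()].
#' @param cfg A [growth_config()].
#' @return An object of class `subregion` with fields `coords` (0-based
#'   `(m, n)` matrix) and `size`.
#' @export
grow_subregion <- function(image, start, seed, params, cfg = growth_config()) {
  image <- as_image(image)
  M <- dim(image)[1]; N <- dim(image)[2]
  matched <- match_mask(image, seed, params)
  if (isTRUE(cfg$gate_per_pixel)) {
    r <- cfg$r %||% params$r
    matched <- matched & (dist_sq_map(image, seed) < r)
  }
  s <- coord_to_lin(matrix(as.integer(start), 1), M)
  if (!matched[s])
    stop_spellerseg("start pixel does not match the seed", "unmatched_start")
  new_subregion(flood_fill(matched, s, cfg$connectivity), M)
}

dist_sq_map <- function(image, seed) {
  seed <- as_pixel(seed)
  (image[, , 1] - seed[1])^2 + (image[, , 2] - seed[2])^2 +
    (image[, , 3] - seed[3])^2
}

# BFS over TRUE cells of `open` starting at linear index s
flood_fill <- function(open, s, connectivity) {
  M <- nrow(open); N <- ncol(open)
  off <- CONNECTIVITIES[[connectivity]]
  visited <- matrix(FALSE, M, N)
  queue <- integer(length(open)); head <- 1L; tail <- 1L
  queue[tail] <- s; tail <- tail + 1L; visited[s] <- TRUE
  while (head < tail) {
    k <- queue[head]; head <- head + 1L
    m <- (k - 1L) %% M; n <- (k - 1L) %/% M
    for (j in seq_len(nrow(off))) {
      mm <- m + off[j, 1L]; nn <- n + off[j, 2L]
      if (mm < 0L || mm >= M || nn < 0L || nn >= N) next
      kk <- nn * M + mm + 1L
      if (!visited[kk] && open[kk]) {
        visited[kk] <- TRUE
        queue[tail] <- kk; tail <- tail + 1L
      }
    }
  }
  queue[seq_len(tail - 1L)]
}

#' Extract all subregions of an image for one seed
#'
#' Repeatedly selects the minimal-angle unassigned pixel and grows a
#' subregion from it.  Extraction stops when the next candidate fails the
#' fuzzy match, fails the squared-distance gate `r`, or the subregion cap
#' is reached.  An empty list means no pixel of the image matches.
#'
#' @inheritParams grow_subregion
#' @return List of `subregion` objects in extraction order.
#' @export
extract_subregions <- function(image, seed, params, cfg = growth_config()) {
  image <- as_image(image)
  M <- dim(image)[1]; N <- dim(image)[2]
  angles <- angle_map(image, seed)
  matched <- match_mask(image, seed, params)
  r <- cfg$r %||% params$r
  if (isTRUE(cfg$gate_per_pixel))
    matched <- matched & (dist_sq_map(image, seed) < r)
  dsq <- dist_sq_map(image, seed)
  remaining <- matrix(TRUE, M, N)
  out <- list()
  while (any(remaining) && length(out) < cfg$max_subregions) {
    s <- find_start_lin(angles, remaining, M, N)
    if (!matched[s]) break
    if (!(dsq[s] < r)) break
    idx <- flood_fill(matched & remaining, s, cfg$connectivity)
    remaining[idx] <- FALSE
    out[[length(out) + 1L]] <- new_subregion(idx, M)
  }
  out
}

#' Pick the object among extracted subregions
#'
#' The subregion with the largest pixel count is taken to be the object;
#' ties go to the earliest-extracted one.
#'
#' @param subregions Nonempty list of `subregion` objects.
#' @return The selected `subregion`.
#' @export
select_object <- function(subregions) {
  if (length(subregions) == 0)
    stop_spellerseg("no subregions: no object found", "no_object")
  sizes <- vapply(subregions, function(s) as.numeric(s$size), numeric(1))
  subregions[[which.max(sizes)]]
}

#' Rasterize a subregion to a binary mask
#'
#' @param subregion A `subregion` object.
#' @param dim Integer `c(M, N)` image size.
#' @return Integer `M x N` matrix of 0/1 values.
#' @export
rasterize <- function(subregion, dim) {
  mask <- matrix(0L, dim[1], dim[2])
  mask[coord_to_lin(subregion$coords, dim[1])] <- 1L
  mask
}

#' Fill short gaps inside a binary mask
#'
#' Any maximal run of 0s strictly shorter than `gap_threshold` that is
#' bounded by 1s on both sides within a row is set to 1; the same pass is
#' then applied to the columns of the row-filled result.  The output mask
#' always contains the input mask.
#'
#' @param mask Integer or logical `M x N` matrix (0/1).
#' @param gap_threshold Strict upper bound, in pixels, on the length of a
#'   run that gets filled.
#' @return Integer `M x N` matrix of 0/1 values.
#' @export
fill_gaps <- function(mask, gap_threshold) {
  if (gap_threshold < 0)
    stop_spellerseg("need gap_threshold >= 0", "bad_params")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  fill_line <- function(v) {
    r <- rle(v)
    if (length(r$lengths) >= 3) {
      inner <- seq(2L, length(r$lengths) - 1L)
      fix <- inner[r$values[inner] == 0L & r$lengths[inner] < gap_threshold]
      r$values[fix] <- 1L
    }
    inverse.rle(r)
  }
  for (i in seq_len(nrow(m))) m[i, ] <- fill_line(m[i, ])
  for (j in seq_len(ncol(m))) m[, j] <- fill_line(m[, j])
  m
}

#' End-to-end object extraction
#'
#' Runs the full chain: subregion extraction, largest-subregion selection
#' and row/column gap filling, using one object's seed pixel and fuzzy
#' parameters.
#'
#' @inheritParams find_start_pixel
#' @param entry A seed-dataset entry (see [lookup_params()]) or any list
#'   with elements `seed`, `params` and optionally `object_id`.
#' @param cfg A [growth_config()]; its `r` / `gap_threshold`, when
#'   non-`NULL`, override the entry's values.
#' @return An object of class `object_mask`: the 0/1 `mask`, the
#'   `object_id`, and the sizes of all extracted subregions.
#' @export
extract_object <- function(image, entry, cfg = growth_config()) {
  image <- as_image(image)
  stopifnot(!is.null(entry$seed), inherits(entry$params, "fuzzy_params"))
  subs <- extract_subregions(image, entry$seed, entry$params, cfg)
  if (length(subs) == 0)
    stop_spellerseg(sprintf("no pixel of the image matches the seed of %s",
                            entry$object_id %||% "object"), "no_object")
  obj <- select_object(subs)
  gap <- cfg$gap_threshold %||% entry$params$gap_threshold
  mask <- fill_gaps(rasterize(obj, dim(image)[1:2]), gap)
  structure(list(mask = mask, object_id = entry$object_id %||% NA_character_,
                 subregion_sizes = vapply(subs, function(s) s$size, integer(1)),
                 object_size = obj$size),
            class = "object_mask")
}

#' @export
print.object_mask <- function(x, ...) {
  cat(sprintf("object mask%s: %d x %d, object %d px (mask %d px after gap fill), %d subregion(s): %s\n",
              if (is.na(x$object_id)) "" else paste0(" [", x$object_id, "]"),
              nrow(x$mask), ncol(x$mask), x$object_size, sum(x$mask),
              length(x$subregion_sizes),
              paste(x$subregion_sizes, collapse = ", ")))
  invisible(x)
}

#' @export
plot.object_mask <- function(x, ...) {
  graphics::image(t(x$mask[nrow(x$mask):1, , drop = FALSE]),
                  col = c("black", "white"), axes = FALSE,
                  main = x$object_id, ...)
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param mask,truth 0/1 matrices of equal size.
#' @return IoU in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(mask, truth) {
  a <- mask != 0; b <- truth != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
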