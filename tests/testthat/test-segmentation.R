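test_that("the minimal-angle pixel starts the growth, row-major on ties", {
  seed <- TAB1_SEEDS$O1
  img <- solid_image(3, 3, c(20, 80, 30))
  img[2, 3, ] <- seed
  expect_equal(find_start_pixel(img, seed), c(m = 1L, n = 2L))
  # 2 x 2 image: brute-force the four angles
  cols <- list(c(10, 200, 40), c(200, 80, 40), c(40, 40, 200), c(150, 60, 10))
  img2 <- array(0, c(2, 2, 3))
  img2[1, 1, ] <- cols[[1]]; img2[1, 2, ] <- cols[[2]]
  img2[2, 1, ] <- cols[[3]]; img2[2, 2, ] <- cols[[4]]
  angles <- vapply(cols, vector_angle, numeric(1), q = seed)
  best <- which.min(angles)  # row-major listing order
  expect_equal(unname(find_start_pixel(img2, seed)),
               c((best - 1) %/% 2, (best - 1) %% 2))
  # tie between two identical pixels: first in row-major order wins
  img3 <- solid_image(2, 2, c(20, 80, 30))
  img3[2, 1, ] <- seed; img3[1, 2, ] <- seed
  expect_equal(find_start_pixel(img3, seed), c(m = 0L, n = 1L))
  expect_error(find_start_pixel(img, seed, matrix(FALSE, 3, 3)),
               class = "empty_set")
})

test_that("growth follows the configured neighborhood pattern", {
  seed <- TAB1_SEEDS$O1; p <- o1_params()
  img <- paint_block(solid_image(5, 5, c(0, 0, 0)), 1, 2, 1, 2, seed)
  s <- grow_subregion(img, c(1, 1), seed, p, growth_config("8-neighbor"))
  expect_equal(s$size, 4L)
  # two 2x2 blocks touching only at a corner
  img2 <- paint_block(solid_image(6, 6, c(0, 0, 0)), 0, 1, 0, 1, seed)
  img2 <- paint_block(img2, 2, 3, 2, 3, seed)
  s4 <- grow_subregion(img2, c(0, 0), seed, p, growth_config("4-adjacent"))
  expect_equal(s4$size, 4L)
  s8 <- grow_subregion(img2, c(0, 0), seed, p, growth_config("8-neighbor"))
  expect_equal(s8$size, 8L)
  # diagonal-only connectivity walks a checkerboard
  img3 <- solid_image(3, 3, c(0, 0, 0))
  for (mn in list(c(0, 0), c(1, 1), c(0, 2), c(2, 0), c(2, 2)))
    img3[mn[1] + 1, mn[2] + 1, ] <- seed
  sd4 <- grow_subregion(img3, c(0, 0), seed, p, growth_config("4-diagonal"))
  expect_equal(sd4$size, 5L)
  expect_error(grow_subregion(img, c(0, 0), seed, p),
               class = "unmatched_start")
})

test_that("growth equals the brute-force fixed-point closure", {
  seed <- TAB1_SEEDS$O1; p <- o1_params()
  for (rs in 1:4) {
    img <- random_test_image(16, 16, rs)
    start <- unname(find_start_pixel(img, seed))
    for (conn in c("4-adjacent", "4-diagonal", "8-neighbor")) {
      got <- coords_key(grow_subregion(img, start, seed, p,
                                       growth_config(conn)))
      want <- oracle_closure(img, start, seed, p, conn)
      expect_identical(got, want)
    }
  }
})

test_that("iterated extraction returns disjoint subregions largest-first-agnostic", {
  seed <- TAB1_SEEDS$O1; p <- o1_params()
  # nothing matching
  expect_length(extract_subregions(solid_image(4, 4, c(20, 80, 30)), seed, p),
                0)
  # two disjoint blocks of 9 and 4 matched pixels
  img <- paint_block(solid_image(10, 10, c(20, 80, 30)), 0, 2, 0, 2, seed)
  img <- paint_block(img, 6, 7, 6, 7, c(190, 72, 35))
  subs <- extract_subregions(img, seed, p)
  expect_length(subs, 2)
  expect_setequal(vapply(subs, function(s) s$size, integer(1)), c(9L, 4L))
  expect_length(intersect(coords_key(subs[[1]]), coords_key(subs[[2]])), 0)
  # a uniform matching image is one subregion covering everything
  uni <- extract_subregions(solid_image(6, 7, seed), seed, p)
  expect_length(uni, 1)
  expect_equal(uni[[1]]$size, 42L)
})

test_that("the distance gate stops extraction before far-off subregions", {
  seed <- TAB1_SEEDS$O1
  # same hue direction, double intensity: angle 0 but squared distance
  # (186^2+69^2+34^2) = 40513 from the seed
  p <- o1_params(r = 1200)
  img <- paint_block(solid_image(8, 8, c(20, 80, 30)), 0, 1, 0, 1, seed)
  img <- paint_block(img, 5, 7, 5, 7, pmin(255, 2 * seed))
  subs <- extract_subregions(img, seed, p, growth_config())
  expect_length(subs, 1)
  expect_equal(subs[[1]]$size, 4L)
  # disabling the gate lets the far block in as its own subregion
  subs_inf <- extract_subregions(img, seed, p, growth_config(r = Inf))
  expect_length(subs_inf, 2)
})

test_that("the largest subregion is the object, ties to earliest", {
  mk <- function(size) structure(list(coords = cbind(m = seq_len(size) - 1,
                                                     n = rep(0, size)),
                                      size = size), class = "subregion")
  expect_equal(select_object(list(mk(9), mk(4)))$size, 9)
  expect_equal(select_object(list(mk(5)))$size, 5)
  a <- mk(7); b <- mk(7); b$coords[, 2] <- 1
  expect_identical(select_object(list(a, b)), a)
  expect_error(select_object(list()), class = "no_object")
})

test_that("gap filling closes short interior runs, rows before columns", {
  expect_equal(fill_gaps(matrix(c(1, 0, 1), 1), 2), matrix(c(1, 1, 1), 1))
  # run of length 2 is not strictly below the threshold 2
  expect_equal(fill_gaps(matrix(c(1, 0, 0, 1), 1), 2),
               matrix(c(1, 0, 0, 1), 1))
  expect_equal(fill_gaps(matrix(c(1, 0, 0, 1), 1), 3),
               matrix(c(1, 1, 1, 1), 1))
  # unbounded runs never fill
  expect_equal(fill_gaps(matrix(c(0, 0, 1), 1), 5), matrix(c(0, 0, 1), 1))
  # a column gap that only becomes bounded after the row pass still fills
  m <- rbind(c(1, 0, 1),
             c(0, 0, 0),
             c(1, 0, 1))
  got <- fill_gaps(m, 2)
  expect_equal(got, matrix(1, 3, 3))
})

test_that("gap filling is monotone and stable along single lines", {
  set.seed(99)
  for (k in 1:20) {
    m <- matrix(rbinom(15 * 12, 1, 0.45), 15, 12)
    for (t in c(0, 2, 4)) {
      f1 <- fill_gaps(m, t)
      expect_true(all(f1 >= m))  # never clears a set pixel
    }
    # along a single line the pass is idempotent: every surviving run is
    # unbounded or at least threshold long
    v <- matrix(rbinom(40, 1, 0.4), 1)
    for (t in c(2, 3, 5)) {
      f1 <- fill_gaps(v, t)
      expect_identical(fill_gaps(f1, t), f1)
    }
  }
})

test_that("end-to-end extraction recovers a dominant blob amid speckles", {
  seed <- TAB1_SEEDS$O1; p <- o1_params()
  ds_entry <- list(object_id = "O1", seed = seed, params = p)
  img <- paint_block(solid_image(20, 24, c(20, 80, 30)), 4, 11, 5, 14, seed)
  truth <- matrix(0L, 20, 24); truth[5:12, 6:15] <- 1L
  # pinholes inside the blob and speckles elsewhere
  img[7, 8, ] <- c(20, 80, 30); img[9, 12, ] <- c(20, 80, 30)
  img[2, 2, ] <- seed; img[17, 20, ] <- seed
  om <- extract_object(img, ds_entry, growth_config())
  expect_s3_class(om, "object_mask")
  expect_gte(mask_iou(om$mask, truth), 0.95)
  # the pinholes were filled back in
  expect_equal(om$mask[7, 8], 1L)
  expect_equal(om$mask[9, 12], 1L)
  # speckles did not make it into the object mask
  expect_equal(om$mask[2, 2], 0L)
  expect_error(extract_object(solid_image(5, 5, c(20, 80, 30)), ds_entry),
               class = "no_object")
})

test_that("masks are unchanged under global channel scaling with the gate off", {
  ds <- read_seed_dataset()
  cfg <- growth_config(r = Inf)
  ref <- make_scene(scene_spec(objects = c("O1", "O2", "O7"), rng_seed = 5))
  dim_ <- make_scene(scene_spec(objects = c("O1", "O2", "O7"), rng_seed = 5,
                                illumination = 0.6))
  for (id in c("O1", "O2", "O7")) {
    m_ref <- extract_object(ref$image, lookup_params(ds, id), cfg)
    m_dim <- extract_object(dim_$image, lookup_params(ds, id), cfg)
    expect_identical(m_ref$mask, m_dim$mask)
    expect_gte(mask_iou(m_ref$mask, ref$masks[[id]]), 0.95)
  }
})
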