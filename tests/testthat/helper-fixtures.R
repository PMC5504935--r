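# fixtures and independent oracles, built in code

TAB1_SEEDS <- list(
  O1 = c(186, 69, 34), O2 = c(104, 140, 53), O3 = c(130, 100, 142),
  O4 = c(141, 47, 48), O5 = c(87, 133, 166), O6 = c(134, 147, 181),
  O7 = c(176, 134, 36))

o1_params <- function(...) fuzzy_params(0.2, 0.3, 0.2, 0.5, ...)

solid_image <- function(M, N, col) {
  array(rep(col, each = M * N), c(M, N, 3))
}

# paint an inclusive 0-based block [m0..m1] x [n0..n1]
paint_block <- function(img, m0, m1, n0, n1, col) {
  for (ch in 1:3) img[(m0 + 1):(m1 + 1), (n0 + 1):(n1 + 1), ch] <- col[ch]
  img
}

# independent trapezoid-rule centroid of the clipped output envelope
oracle_centroid <- function(wm, wu, rho_m, panels = 8192) {
  U <- pi / 2 - rho_m
  x <- seq(0, pi / 2, length.out = panels + 1)
  muM <- ifelse(x < U, (U - x) / U, 0)
  muU <- ifelse(x < rho_m, 0, (x - rho_m) / U)
  f <- pmax(pmin(wm, muM), pmin(wu, muU))
  h <- x[2] - x[1]
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * h
  trap(f * x) / trap(f)
}

# brute-force fixed-point region closure: repeatedly add any matched pixel
# adjacent to the set, until stable; start is a 0-based (m, n) pair
oracle_closure <- function(image, start, seed, params, connectivity) {
  M <- dim(image)[1]; N <- dim(image)[2]
  off <- list(
    "4-adjacent" = cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)),
    "4-diagonal" = cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)),
    "8-neighbor" = cbind(c(-1, -1, -1, 0, 0, 1, 1, 1),
                         c(-1, 0, 1, -1, 1, -1, 0, 1)))[[connectivity]]
  matched <- matrix(FALSE, M, N)
  for (m in 1:M) for (n in 1:N) {
    px <- image[m, n, ]
    matched[m, n] <- any(px > 0) && match_decision(px, seed, params)
  }
  inset <- matrix(FALSE, M, N)
  inset[start[1] + 1, start[2] + 1] <- TRUE
  repeat {
    added <- FALSE
    for (m in 1:M) for (n in 1:N) {
      if (inset[m, n] || !matched[m, n]) next
      for (j in seq_len(nrow(off))) {
        mm <- m + off[j, 1]; nn <- n + off[j, 2]
        if (mm >= 1 && mm <= M && nn >= 1 && nn <= N && inset[mm, nn]) {
          inset[m, n] <- TRUE; added <- TRUE; break
        }
      }
    }
    if (!added) break
  }
  w <- which(inset, arr.ind = TRUE)
  sort(paste(w[, 1] - 1, w[, 2] - 1, sep = ","))
}

coords_key <- function(subregion) {
  sort(paste(subregion$coords[, 1], subregion$coords[, 2], sep = ","))
}

# random cluttered test image dominated by background, with a guaranteed
# O1-colored pixel block and assorted noise pixels
random_test_image <- function(M, N, rng_seed) {
  set.seed(rng_seed)
  img <- solid_image(M, N, c(20, 80, 30))
  n_noise <- round(0.3 * M * N)
  for (k in seq_len(n_noise)) {
    m <- sample.int(M, 1); n <- sample.int(N, 1)
    col <- if (runif(1) < 0.5)
      pmin(255, pmax(0, TAB1_SEEDS$O1 + rnorm(3, 0, 30)))
    else runif(3, 0, 255)
    img[m, n, ] <- col
  }
  img <- paint_block(img, 2, 4, 2, 4, TAB1_SEEDS$O1)
  img
}

table4 <- function() {
  read.delim(system.file("extdata", "illumination_variation.tsv",
                         package = "spellerseg"))
}
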