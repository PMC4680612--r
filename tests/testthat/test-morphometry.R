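# Brute-force perimeter oracle: count unit edges between white pixels and
# black pixels or the image border, pixel by pixel.
perimeter_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  tot <- 0
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (!m[r, cc]) next
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nr <- r + dd[1]; nc <- cc + dd[2]
      if (nr < 1 || nr > H || nc < 1 || nc > W || !m[nr, nc]) tot <- tot + 1
    }
  }
  tot
}

test_that("rectilinear shapes measure exactly", {
  m <- matrix(FALSE, 30, 40)
  m[11:20, 16:25] <- TRUE              # 10x10 square in the interior
  res <- measure_pattern(m)
  expect_equal(res$area, 100)
  expect_equal(res$perimeter_total, 40)
  expect_equal(res$perimeter_edge, 0)
  expect_equal(res$perimeter_away, 40)

  strip <- matrix(FALSE, 30, 40)
  strip[30, 11:30] <- TRUE             # 1x20 strip flush on the bottom border
  res <- measure_pattern(strip)
  expect_equal(res$area, 20)
  expect_equal(res$perimeter_total, 42)
  expect_equal(res$perimeter_edge, res$perimeter_total)  # all inside the band
  expect_equal(res$perimeter_away, 0)

  empty <- matrix(FALSE, 10, 10)
  res <- measure_pattern(empty)
  expect_equal(res$area, 0)
  expect_equal(res$perimeter_total, 0)
})

test_that("perimeter agrees with the exhaustive edge-count oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(FALSE, 40, 50)
    # grow a random blob of ~200 px
    r <- 20; cc <- 25; m[r, cc] <- TRUE
    while (sum(m) < 200) {
      white <- which(m, arr.ind = TRUE)
      w <- white[sample.int(nrow(white), 1), ]
      dd <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample.int(4, 1), ]
      nr <- min(max(w[1] + dd[1], 1), 40)
      nc <- min(max(w[2] + dd[2], 1), 50)
      m[nr, nc] <- TRUE
    }
    res <- measure_pattern(m)
    expect_equal(res$perimeter_total, perimeter_oracle(m))
    expect_equal(res$area, sum(m))
    expect_equal(res$perimeter_edge + res$perimeter_away, res$perimeter_total)
  }
})

test_that("measurement is invariant under the arena's mirror symmetries", {
  set.seed(5)
  m <- matrix(runif(40 * 30) < 0.3, 30, 40)
  r0 <- measure_pattern(m)
  expect_equal(measure_pattern(m[30:1, ]), r0)
  expect_equal(measure_pattern(m[, 40:1]), r0)
})

test_that("cleaning removes small objects and fills small holes at the stated bounds", {
  m <- matrix(FALSE, 60, 80)
  m[5:11, 5:11] <- TRUE                  # 49-px object: removed
  m[20:26, 5:11] <- TRUE
  m[20, 4] <- TRUE                       # 49 + 1 = 50-px object: kept
  big <- matrix(TRUE, 20, 20)
  big[8:10, 8:10] <- FALSE               # 9-px hole: filled
  m[30:49, 30:49] <- big
  big2 <- matrix(TRUE, 20, 20)
  big2[8:12, 8:9] <- FALSE               # 10-px hole: kept
  m[30:49, 55:74] <- big2

  cl <- clean_pattern(m)
  expect_equal(sum(cl[5:11, 4:11]), 0)             # 49 px gone
  expect_equal(sum(cl[20:26, 4:11]), 50)           # 50 px (8-connected) kept
  expect_true(all(cl[30:49, 30:49]))               # hole filled
  expect_equal(sum(!cl[30:49, 55:74]), 10)         # hole kept
  # idempotence
  expect_identical(clean_pattern(cl), cl)
  # empty image passes through
  expect_equal(sum(clean_pattern(matrix(FALSE, 10, 10))), 0)
})

test_that("labelling respects the requested connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE       # diagonal pair
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  expect_error(label_components(m, 6), "connectivity")
})

test_that("quasi-square minimizes and the snake maximizes perimeter at fixed area", {
  sq <- pattern_fixture("square", side = 14)       # 196 px
  sn <- pattern_fixture("snake", snake_length = 196)
  blob <- pattern_fixture("disc", radius = 8)      # ~197 px irregular disc
  p_sq <- measure_pattern(sq$mask)$perimeter_total
  p_sn <- measure_pattern(sn$mask)$perimeter_total
  p_bl <- measure_pattern(blob$mask)$perimeter_total
  expect_lte(p_sq, p_bl)
  expect_gte(p_sn, p_bl)
  expect_gt(p_sn, p_sq)
})

test_that("binarize thresholds single-channel images and recovers a clean disc", {
  img <- matrix(0, 50, 60)
  expect_equal(sum(binarize(img, threshold = 0.5)), 0)
  img[20:30, 20:40] <- 200 / 255
  b <- binarize(img, threshold = 0.5)
  expect_equal(sum(b), 11 * 21)
  # Otsu separates a noisy bright disc from a dark background pixel-exactly
  set.seed(3)
  disc <- pattern_fixture("disc", width = 60, height = 50, radius = 10)$mask
  noisy <- ifelse(disc, 0.8, 0.15) + matrix(rnorm(50 * 60, 0, 0.03), 50, 60)
  b2 <- binarize(noisy)
  expect_identical(unclass(b2), disc)
  expect_error(binarize(array(0, c(4, 4, 3))), "single-channel")
})

test_that("simulated mats have smaller perimeter than tube patterns at matched area", {
  mat <- pattern_fixture("mat", radius = 20)
  tubes <- pattern_fixture("radial_tubes", n_tubes = 6, tube_length = 55,
                           tube_width = 3)
  m_mat <- measure_pattern(mat$mask)
  m_tub <- measure_pattern(tubes$mask)
  expect_lt(abs(m_mat$area - m_tub$area) / m_mat$area, 0.35)
  expect_lt(m_mat$perimeter_total, m_tub$perimeter_total)
})

test_that("grid morphometry counts nest and built cells as structure", {
  p <- small_params(stop_count = 40L)
  tr <- sim_run(p, seed = 5)
  res <- measure_grid(tr$final_grid)
  expect_equal(res$area, 40 + 13)   # built + nest cells
  mask <- tr$final_grid > 0
  expect_equal(res$perimeter_total, perimeter_oracle(mask))
})
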