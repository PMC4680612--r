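rc_idx <- function(st, r, c) sheltertube:::rc_to_idx(st, r, c)

test_that("candidate set matches an exhaustive grid scan", {
  st <- small_state()
  got <- candidate_set(st)
  want <- scan_candidates(st)
  expect_identical(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                   unname(want[order(want[, 1], want[, 2]), , drop = FALSE]))
  # still in agreement after some construction
  set.seed(5)
  for (k in 1:12) {
    cand <- candidate_set(st, crowd_filter = FALSE)
    build_cell(st, cand[sample.int(nrow(cand), 1), ])
  }
  got <- candidate_set(st, crowd_filter = FALSE)
  want <- scan_candidates(st)
  expect_identical(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                   unname(want[order(want[, 1], want[, 2]), , drop = FALSE]))
})

test_that("crowded and blocked cells leave the candidate set", {
  st <- small_state()
  tube <- build_tube_east(st, 1)
  i <- rc_idx(st, tube$row, tube$col0)
  st$crowd[i] <- 0.9
  cand <- candidate_set(st)
  # every vacant neighbour whose only built neighbour is the crowded cell
  # is excluded
  expect_false(any(cand[, 1] == tube$row & cand[, 2] == tube$col0 + 1))
  st$crowd[i] <- 0.89
  cand <- candidate_set(st)
  expect_true(any(cand[, 1] == tube$row & cand[, 2] == tube$col0 + 1))
})

test_that("direction factor follows the cosine of the construction angle", {
  st <- small_state()
  tube <- build_tube_east(st, 2)
  r <- tube$row; c0 <- tube$col0
  via <- c(r, c0 + 1)   # its beginning point is the first tube cell
  expect_equal(direction_factor(st, c(r, c0 + 2), via), 1)    # straight on
  expect_equal(direction_factor(st, c(r, c0), via), 0)        # back to origin
  expect_equal(direction_factor(st, c(r - 1, c0 + 1), via), 0.5)  # perpendicular
  expect_equal(direction_factor(st, c(r + 1, c0 + 1), via), 0.5)
  # via that is its own beginning point: direction measured from the nest centre
  ax <- c0 - (st$cx - 1); ay <- r - (st$cy - 1)
  want <- 0.5 + 0.5 * ax / sqrt(ax^2 + ay^2)
  expect_equal(direction_factor(st, c(r, c0 + 1), c(r, c0)), want)
  expect_error(direction_factor(st, c(r, c0 + 2), c(r, c0 + 5)), "not built")
})

test_that("leaving the edge band costs the edge-exit constant", {
  st <- small_state(nest_position = "edge")   # band = 4 for 50 workers
  ring <- candidate_set(st)
  at4 <- ring[ring[, 1] == 4, , drop = FALSE]
  expect_gt(nrow(at4), 0)
  via <- at4[1, ]
  build_cell(st, via)
  out <- c(5, via[2])   # one row below: outside the band
  expect_equal(direction_factor(st, out, via), 0.0007274)
  # a step staying inside the band keeps the cosine value
  stay <- c(4, via[2] + 1)
  expect_gt(direction_factor(st, stay, via), 0.0007274)
})

test_that("attraction reproduces hand-computed values", {
  st <- small_state(x = 2)
  tube <- build_tube_east(st, 2)
  r <- tube$row; via <- c(r, tube$col0 + 1)
  candidate <- c(r, tube$col0 + 2)
  iv <- rc_idx(st, via[1], via[2])
  ic <- rc_idx(st, candidate[1], candidate[2])
  st$phero[] <- 0
  st$phero[iv] <- 0.3
  st$kf[ic] <- 2
  st$dist[iv] <- 35        # candidate distance becomes 36
  # v = 1 (collinear via only), base = 0.3 + 2 - 36/360 = 2.2
  expect_equal(attraction(st, candidate), 2.2^2)
  # trivial case: nest-adjacent candidate with no pheromone
  g <- state_grid(st)
  west <- c(r, min(which(g[r, ] == 1L)) - 1L)
  expect_equal(attraction(st, west), 1)
  # nonpositive base clamps to zero
  st$kf[ic] <- 1
  st$phero[iv] <- 0
  st$dist[iv] <- 1000
  expect_equal(attraction(st, candidate), 0)
})

test_that("attraction agrees with a from-scratch scalar oracle", {
  st <- small_state(x = 2.5)
  set.seed(9)
  for (k in 1:10) {
    cand <- candidate_set(st, crowd_filter = FALSE)
    build_cell(st, cand[sample.int(nrow(cand), 1), ])
  }
  sim_step(st)   # sprinkle pheromone and evaporate once
  p <- st$params
  cand <- candidate_set(st, crowd_filter = FALSE)
  d <- distance_field(st)
  g <- state_grid(st)
  H <- nrow(g); W <- ncol(g)
  for (j in seq_len(nrow(cand))) {
    rc <- cand[j, ]
    # scalar recomputation of every term
    c_i <- candidate_pheromone(st, rc)
    k_i <- st$kf[rc_idx(st, rc[1], rc[2])]
    nb4 <- rbind(rc + c(-1, 0), rc + c(1, 0), rc + c(0, -1), rc + c(0, 1))
    ok <- nb4[, 1] >= 1 & nb4[, 1] <= H & nb4[, 2] >= 1 & nb4[, 2] <= W
    nb4 <- nb4[ok, , drop = FALSE]
    dvals <- c()
    v <- 0
    nest_any <- FALSE
    for (m in seq_len(nrow(nb4))) {
      s <- g[nb4[m, 1], nb4[m, 2]]
      if (s == 1L) { dvals <- c(dvals, -1); nest_any <- TRUE }
      if (s == 2L) {
        dvals <- c(dvals, d[nb4[m, 1], nb4[m, 2]])
        v <- v + direction_factor(st, rc, nb4[m, ])
      }
    }
    v <- v + nest_any   # founding next to the nest carries no direction
    base <- c_i + k_i - p$b * (1 + min(dvals))
    want <- v * max(0, base)^p$x
    expect_equal(attraction(st, rc), want)
  }
})

test_that("attraction is monotone in pheromone and preference, antitone in distance", {
  st <- small_state(x = 2)
  tube <- build_tube_east(st, 2)
  candidate <- c(tube$row, tube$col0 + 2)
  iv <- rc_idx(st, tube$row, tube$col0 + 1)
  ic <- rc_idx(st, candidate[1], candidate[2])
  set.seed(21)
  for (k in 1:25) {
    c1 <- runif(1, 0, 2); c2 <- c1 + runif(1, 0, 2)
    k1 <- runif(1, 0.5, 2); k2 <- k1 + runif(1, 0, 1)
    d1 <- sample(1:200, 1); d2 <- d1 + sample(1:100, 1)
    st$phero[iv] <- c1; st$kf[ic] <- k1; st$dist[iv] <- d1
    a_base <- attraction(st, candidate)
    st$phero[iv] <- c2
    expect_gte(attraction(st, candidate), a_base)
    st$phero[iv] <- c1; st$kf[ic] <- k2
    expect_gte(attraction(st, candidate), a_base)
    st$kf[ic] <- k1; st$dist[iv] <- d2
    expect_lte(attraction(st, candidate), a_base)
    st$dist[iv] <- d1
  }
})

test_that("choice distribution normalizes and falls back to uniform", {
  expect_equal(choice_distribution(c(1, 1)), c(0.5, 0.5))
  expect_equal(choice_distribution(c(1, 3)), c(0.25, 0.75))
  expect_equal(choice_distribution(c(0, 0, 0)), rep(1 / 3, 3))
  expect_error(choice_distribution(numeric(0)), "empty")
  expect_error(choice_distribution(c(1, -1)), "negative")
  set.seed(13)
  for (k in 1:20) {
    a <- runif(sample(2:50, 1), 0, 10)
    expect_equal(sum(choice_distribution(a)), 1, tolerance = 1e-12)
  }
})

test_that("at x = 0 the choice is uniform over the founding ring", {
  st <- small_state(x = 0)
  cand <- candidate_set(st)
  A <- attraction(st, cand)
  expect_true(all(abs(A - A[1]) < 1e-12))
  expect_equal(choice_distribution(A), rep(1 / nrow(cand), nrow(cand)))
})

test_that("beginning points start at the nest, are inherited and merge at midpoints", {
  st <- small_state(nest_area = 1L, nest_radius = 0)
  g <- state_grid(st)
  nest <- which(g == 1L, arr.ind = TRUE)[1, ]
  r <- nest[1]; cc <- nest[2]
  E <- c(r, cc + 1); E2 <- c(r, cc + 2)
  N <- c(r - 1, cc)
  build_cell(st, E); build_cell(st, E2); build_cell(st, N)
  iE <- rc_idx(st, E[1], E[2]); iE2 <- rc_idx(st, E2[1], E2[2])
  iN <- rc_idx(st, N[1], N[2])
  # first builds own their beginning point; extension inherits it
  expect_equal(c(st$ox[iE], st$oy[iE]), c(st$colp[iE], st$rowp[iE]))
  expect_equal(c(st$ox[iE2], st$oy[iE2]), c(st$colp[iE], st$rowp[iE]))
  # the diagonal cell joins two fronts: midpoint of their beginning points
  M <- c(r - 1, cc + 1)
  build_cell(st, M)
  iM <- rc_idx(st, M[1], M[2])
  expect_equal(st$ox[iM], (st$colp[iE] + st$colp[iN]) / 2)
  expect_equal(st$oy[iM], (st$rowp[iE] + st$rowp[iN]) / 2)
  expect_error(build_cell(st, E), "non-empty")
})

test_that("tube collisions are detected from distance gaps and block an 8x8 window", {
  st <- small_state(width = 40L, height = 30L)
  tube <- build_tube_east(st, 12)    # distances 0..11 along the row
  r <- tube$row; c0 <- tube$col0
  # a single tube turning a corner never flags contact
  for (k in 1:4) build_cell(st, c(r - k, c0 + 11))
  expect_false(any(st$contact))

  # fabricate a second tube running diagonally above the first with far
  # larger route distances, as after a long detour
  fake <- cbind(r - 6, (c0 + 1):(c0 + 9))
  for (m in seq_len(nrow(fake))) {
    i <- rc_idx(st, fake[m, 1], fake[m, 2])
    st$state[i] <- 2L
    st$dist[i] <- 45 + m
    st$ox[i] <- st$colp[i]; st$oy[i] <- st$rowp[i]
  }
  # cells of a connecting row are "built" one by one between the tubes;
  # each touches the far tube via its 8-neighbourhood with |delta d| >= 10
  bridge <- cbind(r - 5, (c0 + 1):(c0 + 8))
  blocked_before <- sum(st$blocked)
  for (m in 1:7) {
    i <- rc_idx(st, bridge[m, 1], bridge[m, 2])
    st$state[i] <- 2L
    st$dist[i] <- 5 + m
    detect_collision(st, bridge[m, ])
    expect_true(st$contact[i])   # classified as touching a different tube
  }
  expect_equal(sum(st$blocked), blocked_before)   # 7 contact cells: no block
  i8 <- rc_idx(st, bridge[8, 1], bridge[8, 2])
  st$state[i8] <- 2L
  st$dist[i8] <- 13
  expect_true(detect_collision(st, bridge[8, ]))  # 8th closes the interface
  expect_gt(sum(st$blocked), blocked_before)
  # the window is permanently out of the candidate set
  cand <- candidate_set(st, crowd_filter = FALSE)
  win_r <- (bridge[8, 1] - 4):(bridge[8, 1] + 3)
  win_c <- (bridge[8, 2] - 4):(bridge[8, 2] + 3)
  expect_false(any(cand[, 1] %in% win_r & cand[, 2] %in% win_c))
})

test_that("sampled build sites follow the enumerated choice probabilities", {
  st <- small_state(x = 2)
  set.seed(17)
  for (k in 1:8) {
    cand <- candidate_set(st, crowd_filter = FALSE)
    build_cell(st, cand[sample.int(nrow(cand), 1), ])
  }
  cand <- candidate_set(st)
  P <- choice_distribution(attraction(st, cand))
  idx <- sheltertube:::rc_to_idx(st, cand[, 1], cand[, 2])
  n <- 20000
  draws <- replicate(n, sheltertube:::draw_site(st))
  counts <- tabulate(match(draws, idx), nbins = length(idx))
  expect_equal(sum(counts), n)   # every draw lands in the candidate set
  # lump rare categories so the chi-squared approximation is valid
  keep <- n * P >= 5
  obs <- counts[keep]; pp <- P[keep]
  if (any(!keep)) { obs <- c(obs, sum(counts[!keep])); pp <- c(pp, sum(P[!keep])) }
  chi <- chisq.test(obs, p = pp / sum(pp))
  expect_gt(chi$p.value, 0.01)
})
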