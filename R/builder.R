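# Per-build-event construction logic: candidate enumeration, direction
# factor, attraction A_i = v_i * (c_i + k_i - b * d_i)^x, probability
# normalization, origin bookkeeping and collision handling.
#
# Every built cell records the beginning point of its construction (the
# first-constructed lattice of its tube: a cell touching the nest or the
# container edge; merging construction fronts average their beginning
# points). A candidate's direction factor sums the cosine rule over its
# built 4-neighbours, each acting as the last-constructed lattice of the
# growth that reached it.
#
# Field values are read differently for vacant and constructed lattices:
# a vacant candidate has no pheromone or crowdedness of its own, so it
# reads the largest pheromone and the mean crowdedness of its constructed
# 8-neighbours; a lattice filled earlier in the current time step (still a
# valid work site for later agents, see sim_step) carries its own
# accumulated values. This asymmetry is what lets cement pheromone pile
# up at an attractive site within a step and ignite positive feedback at
# high sensitivity x.
#
# Hot-path functions are vectorized over candidate vectors of padded
# linear indices; the exported wrappers accept (row, col) pairs.

# Vectorized direction factor for candidate/via index pairs.
#
# theta is the angle between the vector from the via cell's beginning
# point to the via cell ("direction of construction so far") and the
# vector from the via cell to the candidate. Factor = (1 + cos theta)/2:
# 1 when growth continues straight away from the beginning point, 0 when
# it points back. When the via cell IS its own beginning point the
# nest-centre -> via direction is used (growth starts outward). A step
# leaving the edge band from inside it gets the constant edge-exit factor.
dir_factor_vec <- function(st, cand, via, edge_exit_v) {
  ax <- st$colp[via] - st$ox[via]
  ay <- st$rowp[via] - st$oy[via]
  deg <- is.na(ax) | (ax == 0 & ay == 0)
  if (any(deg)) {
    ax[deg] <- st$colp[via][deg] - st$cx
    ay[deg] <- st$rowp[via][deg] - st$cy
  }
  bx <- st$colp[cand] - st$colp[via]
  by <- st$rowp[cand] - st$rowp[via]
  denom <- sqrt((ax * ax + ay * ay) * (bx * bx + by * by))
  ct <- (ax * bx + ay * by) / denom
  ct[!is.finite(ct)] <- 1   # via at the exact nest centre: treat as forward
  v <- 0.5 + 0.5 * ct
  ee <- st$in_band[via] & !st$in_band[cand]
  v[ee] <- edge_exit_v
  v
}

# Attraction components for a vector of candidate padded indices (vacant
# cells, or cells filled earlier in the current step, which use their own
# stored pheromone/crowdedness and their fill-time v and d).
# Returns list(crowd, phero, d, v, A). Crowd filtering is NOT applied here.
attraction_components <- function(st, ci, params = st$params) {
  nc <- length(ci)
  csum <- numeric(nc); cnt <- numeric(nc); cmax <- numeric(nc)
  for (off in st$off8) {
    nb <- ci + off
    b <- st$state[nb] == CELL_BUILT
    if (any(b)) {
      bi <- nb[b]
      csum[b] <- csum[b] + st$crowd[bi]
      cnt[b] <- cnt[b] + 1
      cmax[b] <- pmax(cmax[b], st$phero[bi])
    }
  }
  crowd <- ifelse(cnt > 0, csum / cnt, 0)
  dmin <- rep(Inf, nc); vsum <- numeric(nc)
  nest_adj <- logical(nc)
  for (off in st$off4) {
    nb <- ci + off
    s <- st$state[nb]
    isn <- s == CELL_NEST
    isb <- s == CELL_BUILT
    if (any(isn)) {
      dmin[isn] <- pmin(dmin[isn], -1)
      nest_adj[isn] <- TRUE
    }
    if (any(isb)) {
      bi <- nb[isb]
      dmin[isb] <- pmin(dmin[isb], st$dist[bi])
      vsum[isb] <- vsum[isb] +
        dir_factor_vec(st, ci[isb], bi, params$edge_exit_v)
    }
  }
  vsum <- vsum + nest_adj   # founding next to the nest has no direction: v = 1
  d <- 1 + dmin
  # constructed work sites carry their own field values and keep the
  # geometry they had when filled
  w <- st$state[ci] == CELL_BUILT
  if (any(w)) {
    wi <- ci[w]
    cmax[w] <- st$phero[wi]
    crowd[w] <- st$crowd[wi]
    vsum[w] <- st$site_v[wi]
    d[w] <- st$site_d[wi]
  }
  base <- cmax + st$kf[ci] - params$b * d
  A <- vsum * pmax(0, base)^params$x
  A[!is.finite(A)] <- 0   # d undefined (no structural neighbour): skip
  list(crowd = crowd, phero = cmax, d = d, v = vsum, A = A)
}

#' Candidate build sites
#'
#' All empty, non-blocked cells 4-adjacent to the existing structure (nest
#' or built cells), excluding cells whose mean neighbour crowdedness has
#' reached the crowdedness threshold.
#'
#' @param state A `tube_state`.
#' @param crowd_filter Apply the crowdedness exclusion (default `TRUE`).
#' @return A two-column integer matrix of (row, col) coordinates, one row
#'   per candidate; zero rows when no cell is available.
#' @export
candidate_set <- function(state, crowd_filter = TRUE) {
  ci <- which(state$cand)
  if (length(ci) && crowd_filter) {
    comp <- attraction_components(state, ci)
    ci <- ci[comp$crowd < state$params$crowd_threshold]
  }
  idx_to_rc(state, ci)
}

#' Direction factor of a candidate step
#'
#' Evaluates `(1 + cos(theta)) / 2` for building `candidate` via the built
#' cell `via`, where `theta` is the angle between the vector from the via
#' cell's recorded beginning point to the via cell (the direction of
#' construction so far) and the vector from the via cell to the candidate:
#' 1 for growth continuing straight away from the beginning point, 0 for a
#' step pointing back toward it, 1/2 for a perpendicular step. A step from
#' inside the edge band to outside it returns the edge-exit constant
#' instead. The factor is evaluated geometrically for any cell pair;
#' vacancy of the candidate is enforced by [candidate_set()], not here.
#'
#' @param state A `tube_state`.
#' @param candidate,via `c(row, col)` coordinates; `via` must be built.
#' @return A single number in \[0, 1\].
#' @export
direction_factor <- function(state, candidate, via) {
  vi <- rc_to_idx(state, via[1], via[2])
  if (state$state[vi] != CELL_BUILT)
    stop("logic error: via cell is not built")
  ci <- rc_to_idx(state, candidate[1], candidate[2])
  dir_factor_vec(state, ci, vi, state$params$edge_exit_v)
}

#' Attraction of candidate cells
#'
#' `A_i = v_i * max(0, c_i + k_i - b * d_i)^x`, where `c_i` is the largest
#' pheromone value among built 8-neighbours, `k_i` the edge preference,
#' `d_i` the shortest-route distance from the nest and `v_i` the sum of
#' direction factors over the built 4-neighbours (plus 1 if the cell
#' touches the nest). A nonpositive base or zero direction sum gives 0.
#' Cells filled earlier in the current time step remain work sites and are
#' evaluated with their own accumulated pheromone and crowdedness.
#'
#' @param state A `tube_state`.
#' @param cells Two-column matrix (or single `c(row, col)`) of candidate
#'   coordinates.
#' @return Numeric vector of attractions.
#' @export
attraction <- function(state, cells) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2)
  ci <- rc_to_idx(state, cells[, 1], cells[, 2])
  attraction_components(state, ci)$A
}

#' Choice probabilities from attractions
#'
#' Normalizes attractions to a probability vector `P_i = A_i / sum(A)`.
#' When every attraction is 0 (possible far from the nest where the
#' distance discount exhausts the base) the choice falls back to uniform.
#'
#' @param attractions Nonnegative numeric vector.
#' @return Probability vector of the same length, summing to 1.
#' @export
choice_distribution <- function(attractions) {
  if (!length(attractions)) stop("logic error: empty candidate set")
  if (any(attractions < 0)) stop("logic error: negative attraction")
  tot <- sum(attractions)
  if (tot <= 0) return(rep(1 / length(attractions), length(attractions)))
  attractions / tot
}

#' Build a cell
#'
#' Fills a vacant cell with material: marks it built, deposits cement
#' pheromone and crowdedness on it, assigns its beginning point (its own
#' centre when it touches the nest or the container border; otherwise
#' inherited from its built neighbours, averaging distinct beginning
#' points when construction fronts merge), updates the shortest-route
#' distance field incrementally, and runs collision detection.
#'
#' @param state A `tube_state`.
#' @param cell `c(row, col)` of a vacant candidate cell.
#' @return The state, invisibly (updated in place).
#' @export
build_cell <- function(state, cell) {
  i <- if (length(cell) == 1L) as.integer(cell)
       else rc_to_idx(state, cell[1], cell[2])
  build_at(state, i)
  invisible(state)
}

# Internal build on a padded index.
build_at <- function(st, i) {
  if (st$state[i] != CELL_EMPTY || st$blocked[i])
    stop("logic error: building on a non-empty or blocked cell")
  p <- st$params
  # remember the geometry the site had as a candidate: it stays a work
  # site for the rest of the step
  comp <- attraction_components(st, i, p)
  nb4 <- i + st$off4
  s4 <- st$state[nb4]
  touches_nest <- any(s4 == CELL_NEST)
  built_nb <- nb4[s4 == CELL_BUILT]
  dn <- c(st$dist[built_nb], if (touches_nest) -1)
  dn <- dn[is.finite(dn)]
  if (!length(dn))
    stop("logic error: cell is not adjacent to the structure")
  di <- 1 + min(dn)
  st$dist[i] <- di
  st$site_v[i] <- comp$v
  st$site_d[i] <- comp$d
  # beginning point: own centre when the cell touches the nest or the
  # container edge; otherwise inherited, with merging construction fronts
  # contributing the centre of their distinct beginning points
  if (touches_nest || st$on_border[i]) {
    st$ox[i] <- st$colp[i]; st$oy[i] <- st$rowp[i]
  } else {
    os <- unique(cbind(st$ox[built_nb], st$oy[built_nb]))
    st$ox[i] <- mean(os[, 1]); st$oy[i] <- mean(os[, 2])
  }
  st$state[i] <- CELL_BUILT
  st$phero[i] <- st$phero[i] + p$q
  st$crowd[i] <- st$crowd[i] + p$crowd_increment
  st$built_count <- st$built_count + 1L
  st$cand[i] <- FALSE
  emp <- nb4[st$state[nb4] == CELL_EMPTY & !st$blocked[nb4]]
  if (length(emp)) st$cand[emp] <- TRUE
  # collision check sees the pre-merge distance field
  detect_collision(st, i)
  relax_distance(st, i)
  i
}

# Propagate shortcuts through the distance field after a build (bounded
# BFS relaxation from the new cell).
relax_distance <- function(st, i) {
  q <- i; head <- 1L
  while (head <= length(q)) {
    u <- q[head]; head <- head + 1L
    du <- st$dist[u]
    nb <- u + st$off4
    nb <- nb[st$state[nb] == CELL_BUILT]
    nb <- nb[st$dist[nb] > du + 1]
    if (length(nb)) {
      st$dist[nb] <- du + 1
      q <- c(q, nb)
    }
  }
  invisible(NULL)
}

#' Collision detection after a build event
#'
#' Adjacent built cells whose shortest-route distances differ by at least
#' the collision d-gap (default 10) belong to different shelter tubes; a
#' freshly built cell with such an 8-neighbour is a contact cell. When the
#' 8-connected cluster of contact cells containing the new cell reaches
#' the contact threshold (default 8 cells), the two tubes have merged over
#' a long enough interface that construction there ends: the blocking
#' window (default 8 x 8) centred on the last-built cell is permanently
#' excluded from future candidate sets. Distances are compared before the
#' merge shortcut is propagated.
#'
#' @param state A `tube_state`.
#' @param last_built Padded index or `c(row, col)` of the cell just built.
#' @return `TRUE` (invisibly) when a blocking window was placed.
#' @export
detect_collision <- function(state, last_built) {
  st <- state
  i <- if (length(last_built) == 1L) as.integer(last_built)
       else rc_to_idx(st, last_built[1], last_built[2])
  p <- st$params
  nb8 <- i + st$off8
  b <- st$state[nb8] == CELL_BUILT
  gap <- b & abs(st$dist[nb8] - st$dist[i]) >= p$collision_d_gap
  if (!any(gap)) return(invisible(FALSE))
  st$contact[i] <- TRUE
  # size of the 8-connected contact cluster containing i
  q <- i; seen <- i; head <- 1L
  while (head <= length(q)) {
    u <- q[head]; head <- head + 1L
    nb <- u + st$off8
    nb <- nb[st$contact[nb]]
    nb <- nb[!(nb %in% seen)]
    if (length(nb)) { seen <- c(seen, nb); q <- c(q, nb) }
  }
  if (length(seen) < p$collision_contact) return(invisible(FALSE))
  block_window(st, i, p$collision_block_window)
  invisible(TRUE)
}

# Permanently block the w x w window centred on padded index i.
block_window <- function(st, i, w) {
  r0 <- st$rowp[i] - w %/% 2L
  r1 <- r0 + w - 1L
  c0 <- st$colp[i] - w %/% 2L
  c1 <- c0 + w - 1L
  rows <- max(2L, r0):min(st$Hp - 1L, r1)
  cols <- max(2L, c0):min(st$Wp - 1L, c1)
  win <- as.vector(outer(rows, (cols - 1L) * st$Hp, `+`))
  st$blocked[win] <- TRUE
  st$cand[win] <- FALSE
  invisible(NULL)
}
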