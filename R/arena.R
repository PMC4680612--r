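# Cell state codes used throughout the padded grid representation.
# The grid is stored as a vector in column-major order with a one-cell
# sentinel ring (CELL_OUT) so that neighbour lookups never need bounds checks.
CELL_EMPTY <- 0L
CELL_NEST  <- 1L
CELL_BUILT <- 2L
CELL_OUT   <- 3L

#' Initialize a construction arena
#'
#' Creates the lattice world in which worker agents build: a rectangular grid
#' of square cells (1 cell = 1 mm) holding a central nest disc (the sawdust
#' block that supplies building material) and the edge-preference field. The
#' nest is defined as the `nest_area` cells whose centres are nearest to the
#' arena centre (Euclidean distance, ties broken by angle then linear index),
#' which makes the nest cell count exact and deterministic for any requested
#' area. The nominal disc radius is kept as metadata.
#'
#' @param width,height Arena dimensions in cells. Defaults 220 x 140, i.e. a
#'   220 x 140 mm container floor.
#' @param nest_area Number of cells in the central nest disc (default 1020,
#'   a disc of nominal radius 18).
#' @param group_size Number of workers the arena is set up for (50 or 400);
#'   only used to pick the default edge-band width.
#' @param k_edge Edge preference value given to cells in the border band
#'   (default 2; all other cells get 1). Edging tubes need roughly half the
#'   material of free-standing tubes, hence the doubled preference.
#' @param band Width of the border band in cells. If `NULL`, 5 for 400-worker
#'   arenas and 4 for 50-worker arenas (the mean measured widths of edging
#'   tubes in the two set-ups).
#' @param nest_radius Nominal nest disc radius in cells; also sets the
#'   wall offset of the disc centre under `nest_position = "edge"`.
#' @param nest_position `"edge"` (default): disc centre on the midline of
#'   the long side, `nest_radius` cells from the wall, so the disc is
#'   tangent to it; `"centre"`: disc at the arena centre.
#' @return An object of class `tube_arena`: a list with the grid geometry,
#'   per-cell state vector (padded), edge-preference field `kf`, border-band
#'   mask and index helpers.
#' @examples
#' a <- init_arena(40, 30, nest_area = 21, group_size = 50)
#' sum(a$state == 1L)  # 21 nest cells
#' @export
init_arena <- function(width = 220L, height = 140L, nest_area = 1020L,
                       group_size = 400L, k_edge = 2, band = NULL,
                       nest_radius = 18, nest_position = c("edge", "centre")) {
  nest_position <- match.arg(nest_position)
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("config error: arena dimensions must be positive integers")
  nest_area <- as.integer(nest_area)
  if (nest_area < 0L || nest_area > width * height)
    stop("config error: nest_area must be between 0 and width*height")
  if (is.null(band)) band <- if (group_size >= 400L) 5L else 4L
  band <- as.integer(band)
  if (band < 0L) stop("config error: band must be >= 0")
  if (k_edge <= 0) stop("config error: k_edge must be > 0")

  Hp <- height + 2L; Wp <- width + 2L
  n  <- Hp * Wp
  idx    <- seq_len(n)
  rowp   <- ((idx - 1L) %% Hp) + 1L        # padded row (1..Hp)
  colp   <- ((idx - 1L) %/% Hp) + 1L       # padded col (1..Wp)
  inside <- rowp >= 2L & rowp <= Hp - 1L & colp >= 2L & colp <= Wp - 1L

  state <- rep(CELL_OUT, n)
  state[inside] <- CELL_EMPTY

  # Nest centre in padded cell-centre coordinates (x = col, y = row)
  cx <- (Wp + 1) / 2
  cy <- if (nest_position == "centre") (Hp + 1) / 2 else 1.5 + nest_radius

  # Nest = distance-ranked nearest cells; ties by angle, then index.
  if (nest_area > 0L) {
    ii <- idx[inside]
    dx <- colp[ii] - cx; dy <- rowp[ii] - cy
    d2 <- dx * dx + dy * dy
    ang <- atan2(dy, dx) %% (2 * pi)
    ord <- order(d2, ang, ii)
    state[ii[ord[seq_len(nest_area)]]] <- CELL_NEST
  }

  # Distance of each interior cell to the nearest container border
  # (border cells have distance 0).
  db <- pmin(rowp - 2L, Hp - 1L - rowp, colp - 2L, Wp - 1L - colp)
  in_band <- inside & db <= band - 1L
  on_border <- inside & db == 0L

  kf <- rep(1, n)
  kf[in_band] <- k_edge

  structure(list(
    width = width, height = height, Hp = Hp, Wp = Wp,
    nest_area = nest_area, nest_radius = nest_radius,
    nest_position = nest_position,
    group_size = as.integer(group_size), k_edge = k_edge, band = band,
    cx = cx, cy = cy,
    state = state, kf = kf, in_band = in_band, on_border = on_border,
    rowp = rowp, colp = colp
  ), class = "tube_arena")
}

#' @export
print.tube_arena <- function(x, ...) {
  cat(sprintf("<tube_arena> %d x %d cells, nest %d cells (radius %g), band %d (k_edge = %g)\n",
              x$width, x$height, x$nest_area, x$nest_radius, x$band, x$k_edge))
  invisible(x)
}

#' Edge-preference field
#'
#' Computes the per-cell preference field: cells within `band` cells of the
#' container border get `k_edge`, all others get 1. Used as the
#' pheromone-independent attraction term of the choice rule.
#'
#' @param arena A `tube_arena`.
#' @param group_size Worker group size, used for the default band width when
#'   `band` is `NULL` (5 for 400 workers, 4 for 50).
#' @param k_edge Preference value inside the band (default 2).
#' @param band Band width in cells, or `NULL` for the group-size default.
#' @return A `height x width` numeric matrix.
#' @export
compute_k_field <- function(arena, group_size = arena$group_size,
                            k_edge = 2, band = NULL) {
  if (is.null(band)) band <- if (group_size >= 400L) 5L else 4L
  if (band < 0L) stop("config error: band must be >= 0")
  if (k_edge <= 0) stop("config error: k_edge must be > 0")
  H <- arena$height; W <- arena$width
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  db <- pmin(r - 1L, H - r, cc - 1L, W - cc)
  k <- matrix(1, H, W)
  k[db <= band - 1L] <- k_edge
  k
}

# Convert (row, col) arena coordinates (1-based, unpadded) to padded linear
# indices and back.
rc_to_idx <- function(obj, row, col) {
  (row + 1L) + col * obj$Hp
}
idx_to_rc <- function(obj, idx) {
  cbind(row = ((idx - 1L) %% obj$Hp), col = (idx - 1L) %/% obj$Hp)
}

# Extract the unpadded height x width matrix of a padded per-cell vector.
unpad <- function(obj, v) {
  matrix(v, obj$Hp, obj$Wp)[2:(obj$Hp - 1L), 2:(obj$Wp - 1L), drop = FALSE]
}

#' Shortest-route distance field over the structure
#'
#' Breadth-first shortest path distance from the nest boundary, walking only
#' on nest and built cells with 4-connectivity. Built cells adjacent to the
#' nest have distance 0; distance grows by 1 per structural step. Cells that
#' are not part of the structure (or unreachable) are `NA`. For a vacant
#' candidate cell the distance is 1 + the minimum over its constructed
#' 4-neighbours (0 if it touches the nest directly); see
#' [candidate_distance()].
#'
#' @param x A `tube_arena` or a simulation state created by [sim_state()].
#' @return A `height x width` numeric matrix: distances on built cells,
#'   `NA` on nest, empty and unreachable cells.
#' @export
distance_field <- function(x) {
  st <- if (inherits(x, "tube_arena")) sim_state_from_arena(x) else x
  n <- length(st$state)
  d <- rep(NA_real_, n)
  off4 <- st$off4
  # seeds: built cells 4-adjacent to the nest
  built <- which(st$state == CELL_BUILT)
  if (length(built)) {
    touches_nest <- vapply(built, function(i)
      any(st$state[i + off4] == CELL_NEST), logical(1))
    q <- built[touches_nest]
    d[q] <- 0
    head <- 1L
    while (head <= length(q)) {
      u <- q[head]; head <- head + 1L
      nb <- u + off4
      nb <- nb[st$state[nb] == CELL_BUILT & is.na(d[nb])]
      if (length(nb)) { d[nb] <- d[u] + 1; q <- c(q, nb) }
    }
  }
  unpad(st, d)
}

#' Candidate-cell distance
#'
#' Distance value `d_i` used in the attraction rule for a vacant candidate
#' cell: 1 + the minimum distance over its constructed 4-neighbours, or 0 if
#' the cell is 4-adjacent to the nest. `NA` if the cell touches no structure.
#'
#' @param state A simulation state (see [sim_state()]).
#' @param cell `c(row, col)` of the vacant cell (1-based).
#' @return A single number or `NA`.
#' @export
candidate_distance <- function(state, cell) {
  i <- rc_to_idx(state, cell[1], cell[2])
  nb <- i + state$off4
  s <- state$state[nb]
  dn <- c(state$dist[nb[s == CELL_BUILT]], if (any(s == CELL_NEST)) -1)
  dn <- dn[is.finite(dn)]
  if (!length(dn)) return(NA_real_)
  1 + min(dn)
}
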