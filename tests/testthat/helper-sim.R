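# Small worlds used across tests. The default test arena is 30 x 24 with a
# 13-cell nest disc placed centrally so that geometric expectations are easy
# to write down; edge-specific tests build their own arenas.

small_params <- function(...) {
  defaults <- list(group_size = 50L, alpha = 0.1, x = 2,
                   width = 30L, height = 24L,
                   nest_area = 13L, nest_radius = 2,
                   nest_position = "centre",
                   stop_count = 50L, snapshot_interval = 1000L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

small_state <- function(...) {
  sim_state(small_params(...))
}

# Build a straight horizontal tube of `len` cells east from the first empty
# cell to the right of the nest, returning the state and the row used.
build_tube_east <- function(st, len) {
  row <- round(st$cy) - 1L   # unpadded row through the nest centre
  grid <- state_grid(st)
  col0 <- max(which(grid[row, ] == 1L)) + 1L   # first vacant cell east
  for (k in seq_len(len)) build_cell(st, c(row, col0 + k - 1L))
  list(st = st, row = row, col0 = col0)
}

# Exhaustive scan: empty cells 4-adjacent to nest or built cells.
scan_candidates <- function(st) {
  g <- state_grid(st)
  H <- nrow(g); W <- ncol(g)
  out <- NULL
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (g[r, cc] != 0L) next
    nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W, , drop = FALSE]
    if (any(g[nb] %in% c(1L, 2L))) out <- rbind(out, c(r, cc))
  }
  out
}
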