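#' Simulation parameters
#'
#' Bundles every model constant with its default. Defaults are the study
#' conditions: deposit q = 0.3, evaporation r = 0.7, distance discount
#' b = 1/360 (chosen so that the preference minus the discount vanishes once
#' the whole container edge is constructed), crowdedness threshold 0.9,
#' edge-exit direction factor 0.0007274, collision constants (d-gap 10,
#' contact 8, 8 x 8 blocking window), and stop counts of 5700 constructed
#' cells for 400 workers and 1350 for 50 workers (the mean areas built in
#' 30-day experiments).
#'
#' @param group_size Number of workers in the group (50 or 400; other values
#'   allowed for scaled-down runs).
#' @param alpha Active-worker fraction in (0, 1]; `round(alpha * group_size)`
#'   agents (half-up, minimum 1) build per time step.
#' @param x Pheromone sensitivity exponent (>= 0); governs the nonlinearity
#'   of site choice and hence positive-feedback strength.
#' @param q Cement pheromone deposited on a cell when it is built.
#' @param r Fraction of pheromone lost to evaporation at the end of each
#'   time step (field is multiplied by `1 - r`).
#' @param b Distance discount per cell of shortest-route distance from the
#'   nest.
#' @param crowd_increment Crowdedness added to a cell when it is built
#'   (defaults to `q`, accumulating "in the same way" as pheromone).
#' @param crowd_threshold Candidates whose mean neighbour crowdedness reaches
#'   this value are excluded from the choice set (default 0.9).
#' @param k_edge,band Edge-preference field parameters, see [init_arena()].
#' @param edge_exit_v Direction factor assigned to a step leaving the edge
#'   band from a cell inside it (default 0.0007274, an empirical constant).
#' @param collision_d_gap Two adjacent built cells whose distances differ by
#'   at least this many cells belong to different tubes (default 10).
#' @param collision_contact Number of contact-interface cells between
#'   different tubes that triggers blocking (default 8).
#' @param collision_block_window Side length of the square window, centred
#'   on the last-built cell, that is permanently blocked when a collision
#'   completes (default 8).
#' @param stop_count Total constructed cells at which the run ends. If
#'   `NULL`, 5700 for `group_size >= 400`, otherwise 1350.
#' @param snapshot_interval Record the grid every this many constructed
#'   cells (default 1000).
#' @param width,height,nest_area,nest_radius,nest_position Arena geometry,
#'   see [init_arena()].
#' @param seed Optional RNG seed stored with the parameters; [sim_run()]
#'   uses it when no explicit seed is passed.
#' @param max_stalled_steps Abort the run after this many consecutive time
#'   steps in which no agent could build (default 100).
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(group_size = 400, alpha = 0.05, x = 3)
#' p$stop_count  # 5700
#' @export
sim_params <- function(group_size = 400L, alpha = 0.05, x = 3,
                       q = 0.3, r = 0.7, b = 1 / 360,
                       crowd_increment = q, crowd_threshold = 0.9,
                       k_edge = 2, band = NULL,
                       edge_exit_v = 0.0007274,
                       collision_d_gap = 10L, collision_contact = 8L,
                       collision_block_window = 8L,
                       stop_count = NULL, snapshot_interval = 1000L,
                       width = 220L, height = 140L,
                       nest_area = 1020L, nest_radius = 18,
                       nest_position = "edge",
                       seed = NULL, max_stalled_steps = 100L) {
  if (alpha <= 0 || alpha > 1) stop("config error: alpha must be in (0, 1]")
  if (x < 0) stop("config error: x must be >= 0")
  if (r < 0 || r > 1) stop("config error: r must be in [0, 1]")
  if (q < 0) stop("config error: q must be >= 0")
  if (b <= 0) stop("config error: b must be > 0")
  if (crowd_threshold <= 0) stop("config error: crowd_threshold must be > 0")
  if (collision_d_gap <= 0 || collision_contact <= 0 || collision_block_window <= 0)
    stop("config error: collision thresholds must be positive")
  if (is.null(stop_count))
    stop_count <- if (group_size >= 400L) 5700L else 1350L
  stop_count <- as.integer(stop_count)
  if (stop_count < 1L) stop("config error: stop_count must be >= 1")
  p <- list(group_size = as.integer(group_size), alpha = alpha, x = x,
            q = q, r = r, b = b,
            crowd_increment = crowd_increment,
            crowd_threshold = crowd_threshold,
            k_edge = k_edge, band = band,
            edge_exit_v = edge_exit_v,
            collision_d_gap = collision_d_gap,
            collision_contact = as.integer(collision_contact),
            collision_block_window = as.integer(collision_block_window),
            stop_count = stop_count,
            snapshot_interval = as.integer(snapshot_interval),
            width = as.integer(width), height = as.integer(height),
            nest_area = as.integer(nest_area), nest_radius = nest_radius,
            nest_position = nest_position,
            seed = seed, max_stalled_steps = as.integer(max_stalled_steps))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_params> N = %d, alpha = %g, x = %g | q = %g, r = %g, b = 1/%g\n",
    "  arena %d x %d, nest %d cells, band %s | stop at %d built cells\n"),
    x$group_size, x$alpha, x$x, x$q, x$r, round(1 / x$b),
    x$width, x$height, x$nest_area,
    if (is.null(x$band)) "auto" else x$band, x$stop_count))
  invisible(x)
}

#' Number of active agents per time step
#'
#' `round(alpha * group_size)` with half-up rounding and a minimum of 1.
#'
#' @param params A `sim_params` object.
#' @return Integer count of agents that build each step.
#' @export
active_agents <- function(params) {
  max(1L, as.integer(floor(params$alpha * params$group_size + 0.5)))
}

#' Create a simulation state
#'
#' Builds the mutable world state for a run: arena grid, pheromone and
#' crowdedness fields (all zero at the start), shortest-route distance
#' field, tube-origin bookkeeping and the candidate mask. The state is an
#' environment; builder and engine functions update it in place.
#'
#' @param params A `sim_params` object.
#' @return An environment of class `tube_state`.
#' @export
sim_state <- function(params) {
  arena <- init_arena(params$width, params$height, params$nest_area,
                      params$group_size, k_edge = params$k_edge,
                      band = params$band, nest_radius = params$nest_radius,
                      nest_position = params$nest_position)
  st <- sim_state_from_arena(arena)
  st$params <- params
  st
}

# Internal: state skeleton from an arena (params may be attached afterwards).
sim_state_from_arena <- function(arena) {
  st <- new.env(parent = emptyenv())
  n <- length(arena$state)
  Hp <- arena$Hp
  st$arena <- arena
  st$Hp <- Hp; st$Wp <- arena$Wp
  st$state <- arena$state
  st$kf <- arena$kf
  st$in_band <- arena$in_band
  st$on_border <- arena$on_border
  st$rowp <- arena$rowp; st$colp <- arena$colp
  st$cx <- arena$cx; st$cy <- arena$cy
  st$off4 <- c(-1L, 1L, -Hp, Hp)
  st$off8 <- c(st$off4, -1L - Hp, 1L - Hp, -1L + Hp, 1L + Hp)
  st$blocked <- arena$state == CELL_OUT
  st$phero <- numeric(n)
  st$crowd <- numeric(n)
  st$dist <- rep(Inf, n)
  st$dist[arena$state == CELL_NEST] <- -1   # so candidates next to nest get 0
  st$contact <- logical(n)
  # beginning point of construction recorded per built cell, plus the
  # direction sum and distance each cell had when it was filled (it stays
  # a work site for the rest of that time step)
  st$ox <- rep(NA_real_, n)
  st$oy <- rep(NA_real_, n)
  st$site_v <- rep(NA_real_, n)
  st$site_d <- rep(NA_real_, n)
  # initial candidates: empty cells 4-adjacent to the nest
  cand <- logical(n)
  nest <- which(arena$state == CELL_NEST)
  for (off in st$off4) {
    nb <- nest + off
    cand[nb[st$state[nb] == CELL_EMPTY]] <- TRUE
  }
  st$cand <- cand
  st$built_count <- 0L
  st$stalled_steps <- 0L
  st$status <- "running"
  st$snapshots <- list()
  st$params <- NULL
  class(st) <- "tube_state"
  st
}

#' Extract the cell-state grid from a state
#'
#' @param state A `tube_state`.
#' @return A `height x width` integer matrix with 0 = empty, 1 = nest,
#'   2 = built.
#' @export
state_grid <- function(state) {
  unpad(state, state$state)
}
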