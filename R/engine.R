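# Time stepping, stopping, snapshots, replication and the parameter sweep.

#' Advance the simulation by one time step
#'
#' Each of the `round(alpha * group_size)` active agents (half-up, minimum
#' 1) chooses one work site in turn, seeing all deposits made earlier in
#' the same step. The choice set holds every vacant lattice adjacent to
#' the structure plus the lattices filled earlier in the current step
#' (workers keep carrying material to an attractive site: choosing such a
#' site deposits another `q` of pheromone and crowdedness on it, which is
#' how cement pheromone accumulates beyond a single deposit). Sites whose
#' crowdedness reaches the threshold — their own value for fresh material,
#' the mean over constructed neighbours for vacant cells — are excluded
#' for the rest of the step, sending later agents to other locations. The
#' step ends early when the stop count is reached. At the end of the step
#' the pheromone field evaporates and crowdedness is reset (workers return
#' to the nest for material).
#'
#' @param state A `tube_state` with `state$params` set.
#' @return The state, invisibly (updated in place); `state$status` becomes
#'   `"done"` when the stop count is reached.
#' @export
sim_step <- function(state) {
  st <- state
  p <- st$params
  n_active <- active_agents(p)
  worked <- integer(0)   # lattices filled earlier in this step
  built_this_step <- FALSE
  for (a in seq_len(n_active)) {
    j <- draw_site(st, worked)
    if (is.na(j)) next   # everything crowded out: the agent skips
    if (st$state[j] == CELL_EMPTY) {
      build_at(st, j)   # deposits q pheromone and crowdedness on j
      built_this_step <- TRUE
      if (!st$blocked[j]) worked <- c(worked, j)
      if (st$built_count %% p$snapshot_interval == 0L)
        record_snapshot(st)
      if (st$built_count >= p$stop_count) {
        st$status <- "done"
        break
      }
    } else {
      # site filled earlier this step: the agent adds material there
      st$phero[j] <- st$phero[j] + p$q
      st$crowd[j] <- st$crowd[j] + p$crowd_increment
    }
  }
  pheromone_evaporate(st)
  crowd_reset(st)
  if (built_this_step) {
    st$stalled_steps <- 0L
  } else {
    st$stalled_steps <- st$stalled_steps + 1L
    if (st$status == "running" && st$stalled_steps >= p$max_stalled_steps)
      st$status <- "stalled"
  }
  invisible(st)
}

# Draw one work site for an agent: vacant candidates plus lattices filled
# earlier in the current step, minus crowded-out sites; sampled with
# probability proportional to attraction (uniform when all attractions
# vanish). Returns a padded index, or NA when no site is admissible.
draw_site <- function(st, worked = integer(0)) {
  p <- st$params
  ci <- c(which(st$cand), worked)
  if (!length(ci)) return(NA_integer_)
  comp <- attraction_components(st, ci, p)
  keep <- comp$crowd < p$crowd_threshold
  if (!any(keep)) return(NA_integer_)
  ci <- ci[keep]
  A <- comp$A[keep]
  if (sum(A) <= 0 || length(ci) == 1L) ci[sample.int(length(ci), 1L)]
  else ci[sample.int(length(ci), 1L, prob = A)]
}

# Append the current grid (and its morphometry) to the snapshot list.
record_snapshot <- function(st) {
  g <- state_grid(st)
  st$snapshots[[length(st$snapshots) + 1L]] <- list(
    count = st$built_count,
    grid = g,
    morphometry = measure_grid(g))
  invisible(NULL)
}

#' Run a single construction simulation
#'
#' Steps the model until the stop count of constructed cells is reached
#' (5700 for 400 workers, 1350 for 50 workers, by default), recording the
#' grid and its morphometry every `snapshot_interval` constructed cells and
#' at the final state. Deterministic given the seed.
#'
#' @param params A `sim_params` object.
#' @param seed RNG seed; defaults to `params$seed`. `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `tube_trajectory`: list with `params`,
#'   `seed`, `status` (`"done"` or `"stalled"`), `built_count`,
#'   `snapshots` (list of `count`/`grid`/`morphometry`), `final_grid` and
#'   `final_morphometry`.
#' @examples
#' p <- sim_params(group_size = 50, alpha = 0.2, x = 2, width = 40,
#'                 height = 30, nest_area = 30, nest_radius = 3,
#'                 stop_count = 60, snapshot_interval = 25)
#' tr <- sim_run(p, seed = 1)
#' tr$built_count  # 60
#' @export
sim_run <- function(params, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  st <- sim_state(params)
  while (st$status == "running") sim_step(st)
  g <- state_grid(st)
  ns <- length(st$snapshots)
  if (ns == 0L || st$snapshots[[ns]]$count != st$built_count)
    st$snapshots[[ns + 1L]] <- list(
      count = st$built_count, grid = g, morphometry = measure_grid(g))
  structure(list(
    params = params, seed = seed, status = st$status,
    built_count = st$built_count,
    snapshots = st$snapshots,
    final_grid = g,
    final_morphometry = measure_grid(g),
    state = st
  ), class = "tube_trajectory")
}

#' @export
print.tube_trajectory <- function(x, ...) {
  m <- x$final_morphometry
  cat(sprintf(paste0(
    "<tube_trajectory> %s: %d cells built (N = %d, alpha = %g, x = %g)\n",
    "  area %g mm^2, perimeter %g mm (%g edge + %g away), %d snapshots\n"),
    x$status, x$built_count, x$params$group_size, x$params$alpha,
    x$params$x, m$area, m$perimeter_total, m$perimeter_edge,
    m$perimeter_away, length(x$snapshots)))
  invisible(x)
}

# Reproducible per-run seed, unique over (alpha index, x index, rep)
# within a sweep; strides keep distinct tuples distinct for grids of up to
# 100 values and up to 100000 replicates.
sweep_seed <- function(base_seed, ia, ix, rep) {
  as.integer((as.double(base_seed) * 7919 + ia * 100000003 +
                ix * 1000003 + rep) %% 2147483647)
}

#' Parameter sweep over active fraction and pheromone sensitivity
#'
#' Runs `reps` replicate simulations for every combination of `alpha` and
#' `x` (defaults: alpha 0.05-0.25 by 0.05, x 1-3 by 0.5, i.e. the 25
#' parameter sets of the study design) and returns tidy morphometry rows,
#' one per run and snapshot. Each run's seed is derived reproducibly from
#' the base seed and the grid position, so any single run can be repeated
#' in isolation with [sim_run()].
#'
#' @param alpha,x Numeric grids of parameter values.
#' @param reps Replicates per parameter combination (the study used 100).
#' @param params Base `sim_params`; `alpha` and `x` are overridden per run.
#' @param base_seed Integer seed from which all per-run seeds are derived.
#' @param final_only Keep only each run's final snapshot row (default
#'   `FALSE`).
#' @return A data frame with columns `alpha`, `x`, `rep`, `seed`, `status`,
#'   `count`, `is_final`, `area`, `perimeter_total`, `perimeter_edge`,
#'   `perimeter_away`.
#' @export
sim_sweep <- function(alpha = seq(0.05, 0.25, by = 0.05),
                      x = seq(1, 3, by = 0.5),
                      reps = 100L, params = sim_params(),
                      base_seed = 1L, final_only = FALSE) {
  if (!length(alpha) || !length(x)) stop("config error: empty parameter grid")
  rows <- vector("list", length(alpha) * length(x) * reps)
  k <- 0L
  for (ia in seq_along(alpha)) for (ix in seq_along(x)) {
    for (rep in seq_len(reps)) {
      p <- params
      p$alpha <- alpha[ia]; p$x <- x[ix]
      sd <- sweep_seed(base_seed, ia, ix, rep)
      tr <- sim_run(p, seed = sd)
      snaps <- tr$snapshots
      if (final_only) snaps <- snaps[length(snaps)]
      m <- lapply(snaps, function(s) {
        data.frame(alpha = alpha[ia], x = x[ix], rep = rep, seed = sd,
                   status = tr$status, count = s$count,
                   is_final = s$count == tr$built_count,
                   area = s$morphometry$area,
                   perimeter_total = s$morphometry$perimeter_total,
                   perimeter_edge = s$morphometry$perimeter_edge,
                   perimeter_away = s$morphometry$perimeter_away)
      })
      k <- k + 1L
      rows[[k]] <- do.call(rbind, m)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}
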