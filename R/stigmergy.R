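# Cement-pheromone and crowdedness field dynamics.
#
# Pheromone lives only on built cells: a piece of material carries its
# cement pheromone, which evaporates over time. A vacant candidate cell
# reads the field through its neighbours (max for pheromone, mean for
# crowdedness). Crowdedness accumulates with construction exactly like
# pheromone but is reset at the end of every time step, when workers return
# to the nest for more material.

#' Deposit cement pheromone on a built cell
#'
#' Adds `q` to the pheromone value of `cell`. Deposits happen at
#' construction time, so the cell must already be built.
#'
#' @param state A `tube_state`.
#' @param cell `c(row, col)` of a built cell.
#' @param q Amount of pheromone to add (default: the state's `q`).
#' @return The state, invisibly (updated in place).
#' @export
pheromone_deposit <- function(state, cell, q = state$params$q) {
  i <- rc_to_idx(state, cell[1], cell[2])
  if (state$state[i] != CELL_BUILT)
    stop("logic error: pheromone deposit on a non-built cell")
  state$phero[i] <- state$phero[i] + q
  invisible(state)
}

#' Evaporate the pheromone field
#'
#' Multiplies every pheromone value by `1 - r`: a rate-`r` evaporation
#' loses the fraction `r` of the field per time step. Called once at the
#' end of each step.
#'
#' @param state A `tube_state`.
#' @param r Evaporation rate in \[0, 1\] (default: the state's `r`).
#' @return The state, invisibly (updated in place).
#' @export
pheromone_evaporate <- function(state, r = state$params$r) {
  if (r < 0 || r > 1) stop("config error: r must be in [0, 1]")
  state$phero <- state$phero * (1 - r)
  invisible(state)
}

#' Pheromone value seen by a vacant candidate cell
#'
#' The largest cement-pheromone value among the built 8-neighbours of
#' `cell`; nest neighbours contribute 0, and a cell with no built neighbour
#' reads 0.
#'
#' @param state A `tube_state`.
#' @param cell `c(row, col)` of the vacant cell.
#' @return A single nonnegative number.
#' @export
candidate_pheromone <- function(state, cell) {
  i <- rc_to_idx(state, cell[1], cell[2])
  nb <- i + state$off8
  b <- nb[state$state[nb] == CELL_BUILT]
  if (!length(b)) return(0)
  max(state$phero[b])
}

#' Crowdedness seen by a vacant candidate cell
#'
#' The arithmetic mean of crowdedness over the built 8-neighbours of
#' `cell`; 0 if there are none. Candidates whose value reaches the
#' crowdedness threshold are excluded from the choice set.
#'
#' @param state A `tube_state`.
#' @param cell `c(row, col)` of the vacant cell.
#' @return A single nonnegative number.
#' @export
candidate_crowdedness <- function(state, cell) {
  i <- rc_to_idx(state, cell[1], cell[2])
  nb <- i + state$off8
  b <- nb[state$state[nb] == CELL_BUILT]
  if (!length(b)) return(0)
  mean(state$crowd[b])
}

#' Reset the crowdedness field
#'
#' Sets every crowdedness value to 0; called at the end of each time step
#' (workers return to the nest to restock material).
#'
#' @param state A `tube_state`.
#' @return The state, invisibly (updated in place).
#' @export
crowd_reset <- function(state) {
  state$crowd[] <- 0
  invisible(state)
}
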