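# Synthetic fixtures: programmatic construction patterns with analytic
# ground truth (for exercising the morphometry) and group-record tables
# with planted effect sizes (for exercising the statistics).

#' Generate a synthetic construction pattern
#'
#' Draws a lattice-native binary pattern of a given class on a blank
#' canvas, together with analytic ground truth where the shape permits.
#' Pattern classes mirror the phenotypes seen in construction arenas:
#' `mat` (filled disc around the centre), `radial_tubes` (straight
#' 4-connected arms leaving a central disc), `edging_tubes` (strips along
#' the container wall), `intermediate` (disc plus arms), and the geometric
#' test shapes `square`, `disc` and `snake` (1-pixel serpentine). No
#' anti-aliasing is applied, so measurements are bit-exact.
#'
#' @param kind One of `"mat"`, `"radial_tubes"`, `"edging_tubes"`,
#'   `"intermediate"`, `"square"`, `"snake"`, `"disc"`.
#' @param width,height Canvas size in pixels (default 220 x 140).
#' @param radius Disc radius for `mat`/`disc`/`intermediate` (pixels).
#' @param side Side length for `square`.
#' @param n_tubes,tube_length,tube_width Arm parameters for
#'   `radial_tubes`/`intermediate`.
#' @param band_width Strip width for `edging_tubes`.
#' @param snake_length Total pixel count for `snake`.
#' @param noise Number of isolated single noise pixels to sprinkle on free
#'   background (default 0); requires `seed`.
#' @param seed RNG seed for noise placement; `NULL` leaves the RNG alone.
#' @return List with `mask` (logical matrix), `kind`, and `truth`: a list
#'   with `area` always, and `perimeter` (plus `perimeter_edge` /
#'   `perimeter_away`) for rectilinear shapes where it is known in closed
#'   form (`NULL` entries otherwise).
#' @examples
#' fx <- pattern_fixture("square", side = 10)
#' fx$truth$perimeter  # 40
#' @export
pattern_fixture <- function(kind = c("mat", "radial_tubes", "edging_tubes",
                                     "intermediate", "square", "snake",
                                     "disc"),
                            width = 220L, height = 140L,
                            radius = 18L, side = 10L,
                            n_tubes = 4L, tube_length = 40L, tube_width = 3L,
                            band_width = 4L, snake_length = 200L,
                            noise = 0L, seed = NULL) {
  kind <- match.arg(kind)
  m <- matrix(FALSE, height, width)
  cr <- (height + 1) / 2; cc <- (width + 1) / 2
  truth <- list(area = NULL, perimeter = NULL,
                perimeter_edge = NULL, perimeter_away = NULL)

  disc_mask <- function(rad) {
    r <- matrix(seq_len(height), height, width)
    cl <- matrix(seq_len(width), height, width, byrow = TRUE)
    (r - cr)^2 + (cl - cc)^2 <= rad^2
  }

  if (kind %in% c("mat", "disc")) {
    m <- disc_mask(radius)
    truth$area <- sum(m)
  } else if (kind == "square") {
    r0 <- floor(cr - side / 2) + 1L; c0 <- floor(cc - side / 2) + 1L
    m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- TRUE
    truth$area <- side^2
    truth$perimeter <- 4 * side
    truth$perimeter_edge <- 0
    truth$perimeter_away <- 4 * side
  } else if (kind == "snake") {
    # serpentine 1-px path in the interior: maximal perimeter 2L + 2
    rows <- seq(5L, height - 5L, by = 2L)
    len <- 0L
    span <- width - 10L
    for (k in seq_along(rows)) {
      if (len >= snake_length) break
      take <- min(span, snake_length - len - (if (len > 0L) 1L else 0L))
      cols <- if (k %% 2L == 1L) 6L:(5L + take) else (4L + span):(5L + span - take)
      m[rows[k], cols] <- TRUE
      len <- len + take
      if (len < snake_length && k < length(rows)) {
        # vertical connector
        m[rows[k] + 1L, cols[length(cols)]] <- TRUE
        len <- len + 1L
      }
    }
    truth$area <- sum(m)
  } else if (kind == "radial_tubes" || kind == "intermediate") {
    core <- if (kind == "intermediate") disc_mask(radius) else disc_mask(max(4L, radius %/% 2L))
    m <- m | core
    dirs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                 c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
    half <- tube_width %/% 2L
    for (t in seq_len(min(n_tubes, 8L))) {
      d <- dirs[[t]]
      for (s in seq_len(tube_length)) {
        r <- round(cr + d[1] * s); cl <- round(cc + d[2] * s)
        rr <- max(1L, r - half):min(height, r + half)
        ccl <- max(1L, cl - half):min(width, cl + half)
        m[rr, ccl] <- TRUE
      }
    }
    truth$area <- sum(m)  # generator's own cell ledger
  } else if (kind == "edging_tubes") {
    m[1:band_width, ] <- TRUE
    m[(height - band_width + 1L):height, ] <- TRUE
    m[, 1:band_width] <- TRUE
    m[, (width - band_width + 1L):width] <- TRUE
    truth$area <- sum(m)
    # full border ring of width w: inner boundary only (outer lies on the
    # image border and contributes the outer edge count as well)
    truth$perimeter <- 2 * (width + height) + 2 * (width - 2 * band_width) +
      2 * (height - 2 * band_width)
  }

  if (noise > 0L) {
    if (!is.null(seed)) set.seed(seed)
    # place isolated single pixels on background, away from the structure
    free <- which(!m)
    # keep only pixels whose 8-neighbourhood is empty and off the border
    H <- height; W <- width
    rr <- ((free - 1L) %% H) + 1L; cc2 <- ((free - 1L) %/% H) + 1L
    ok <- rr > 2L & rr < H - 1L & cc2 > 2L & cc2 < W - 1L
    free <- free[ok]
    pick <- integer(0)
    cand <- sample(free)
    for (i in cand) {
      if (length(pick) >= noise) break
      r <- ((i - 1L) %% H) + 1L; cl <- ((i - 1L) %/% H) + 1L
      if (!any(m[(r - 1L):(r + 1L), (cl - 1L):(cl + 1L)])) {
        m[r, cl] <- TRUE
        pick <- c(pick, i)
      }
    }
    truth$noise_pixels <- length(pick)
  }

  list(kind = kind, mask = m, truth = truth)
}

#' Generate a synthetic group-records table
#'
#' Simulates container-group records for `n_colonies` colonies with `reps`
#' replicate groups each: measurements are normal within colony, and
#' colony means are spaced by `effect_size` within-colony standard
#' deviations, giving a known effect for power and type-I-error testing of
#' the ANOVA pipeline. Optionally plants rows with survival at or below
#' 0.5 that the survival filter must remove.
#'
#' @param n_colonies Number of colonies (labelled A, B, ...; default 5).
#' @param reps Replicate groups per colony (default 5).
#' @param effect_size Spacing of consecutive colony means in units of the
#'   within-colony standard deviation (0 = null).
#' @param sd Within-colony standard deviation of each measure.
#' @param baseline Grand mean of each measure.
#' @param group_size Worker count recorded for every row (default 400).
#' @param n_low_survival Number of rows given survival drawn in \[0.2, 0.5\]
#'   (the rest draw from \[0.8, 1\]).
#' @param seed RNG seed; `NULL` leaves the RNG alone.
#' @return Data frame with columns `colony`, `group_size`, `replicate`,
#'   `survival_rate`, `area`, `perimeter_total`, `perimeter_edge`,
#'   `perimeter_away`.
#' @export
group_table_fixture <- function(n_colonies = 5L, reps = 5L,
                                effect_size = 0, sd = 1, baseline = 100,
                                group_size = 400L, n_low_survival = 0L,
                                seed = NULL) {
  if (n_colonies < 2L) stop("need at least 2 colonies")
  if (!is.null(seed)) set.seed(seed)
  n <- n_colonies * reps
  colony <- rep(LETTERS[seq_len(n_colonies)], each = reps)
  shift <- (match(colony, LETTERS) - (n_colonies + 1) / 2) * effect_size * sd
  gen <- function() baseline + shift + stats::rnorm(n, 0, sd)
  df <- data.frame(
    colony = colony,
    group_size = group_size,
    replicate = rep(seq_len(reps), times = n_colonies),
    survival_rate = stats::runif(n, 0.8, 1),
    area = gen(),
    perimeter_total = gen(),
    perimeter_edge = gen(),
    perimeter_away = gen())
  if (n_low_survival > 0L) {
    low <- sample.int(n, min(n_low_survival, n))
    df$survival_rate[low] <- stats::runif(length(low), 0.2, 0.5)
  }
  df
}
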