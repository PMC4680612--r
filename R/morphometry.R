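# Pattern morphometry: binarization, cleaning and lattice-exact area and
# perimeter measurement of construction patterns, with the perimeter split
# into an along-edge component (white pixels within the 3 mm border band)
# and an away-from-edge component. 1 pixel = 1 mm.

#' Binarize a grayscale pattern image
#'
#' Thresholds a single-channel image: pixels at or above the threshold
#' become white (construction), the rest black (background). The default
#' threshold is Otsu's, computed on the image histogram.
#'
#' @param img Numeric matrix of intensities. Values above 1 are assumed to
#'   be on a 0-255 scale and rescaled.
#' @param threshold Threshold in \[0, 1\], or `NULL` for Otsu.
#' @return A logical matrix of class `pattern_mask` (TRUE = white).
#' @export
binarize <- function(img, threshold = NULL) {
  if (length(dim(img)) != 2L)
    stop("binarize expects a single-channel image; reduce multi-channel input first (see read_pattern_image)")
  img <- as.matrix(img)
  if (!is.numeric(img)) stop("binarize expects numeric intensities")
  mx <- max(img)
  if (is.finite(mx) && mx > 1) img <- img / 255
  if (is.null(threshold)) {
    if (length(unique(as.vector(img))) < 2L) {
      threshold <- 0.5  # flat image: Otsu undefined, split at mid-grey
    } else {
      threshold <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1))
    }
  }
  structure(img >= threshold, class = "pattern_mask")
}

#' Connected-component labelling
#'
#' Labels connected sets of TRUE pixels with increasing integers
#' (0 = background), under 8- or 4-connectivity. Used with 8-connectivity
#' for white objects and 4-connectivity for holes (the standard duality).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, same dimensions as `mask`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  Hp <- H + 2L
  m <- matrix(FALSE, Hp, W + 2L)
  m[2:(H + 1L), 2:(W + 1L)] <- mask > 0
  v <- as.vector(m)
  off <- c(-1L, 1L, -Hp, Hp)
  if (connectivity == 8L) off <- c(off, -1L - Hp, 1L - Hp, -1L + Hp, 1L + Hp)
  lab <- integer(length(v))
  cur <- 0L
  q <- integer(sum(v))
  for (s in which(v)) {
    if (lab[s]) next
    cur <- cur + 1L
    lab[s] <- cur
    q[1L] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      u <- q[head]; head <- head + 1L
      nb <- u + off
      nb <- nb[v[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        q[(tail + 1L):(tail + length(nb))] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  matrix(lab, Hp, W + 2L)[2:(H + 1L), 2:(W + 1L), drop = FALSE]
}

#' Clean a binary pattern
#'
#' Removes debris and noise before measurement: white connected components
#' (8-connectivity) smaller than `min_object` pixels are deleted (loose
#' sawdust, faeces, stray individuals) and interior black holes
#' (4-connectivity, not touching the image border) smaller than `max_hole`
#' pixels are filled. Idempotent.
#'
#' @param mask Logical (or 0/1) matrix, TRUE = white.
#' @param min_object Smallest white object kept, in pixels (default 50).
#' @param max_hole Holes strictly smaller than this are filled (default 10).
#' @return A cleaned logical matrix of class `pattern_mask`.
#' @export
clean_pattern <- function(mask, min_object = 50L, max_hole = 10L) {
  m <- mask > 0
  lab <- label_components(m, 8L)
  if (max(lab) > 0L) {
    sz <- tabulate(lab)
    keep <- sz >= min_object
    drop <- lab > 0L & !keep[pmax(lab, 1L)]
    m[drop] <- FALSE
  }
  # holes: black 4-components not connected to the border background
  H <- nrow(m); W <- ncol(m)
  bg <- matrix(TRUE, H + 2L, W + 2L)
  bg[2:(H + 1L), 2:(W + 1L)] <- !m
  labb <- label_components(bg, 4L)
  outside <- labb[1L, 1L]
  if (max(labb) > 0L) {
    szb <- tabulate(labb)
    holes <- which(szb < max_hole)
    holes <- setdiff(holes, outside)
    if (length(holes)) {
      fill <- matrix(labb %in% holes, H + 2L, W + 2L)
      m[fill[2:(H + 1L), 2:(W + 1L)]] <- TRUE
    }
  }
  structure(m, class = "pattern_mask")
}

#' Measure area and perimeter of a binary pattern
#'
#' Lattice-exact morphometry: area is the white pixel count (mm^2 at
#' 1 px = 1 mm) and the perimeter is the number of unit edges between a
#' white pixel and a black pixel or the image border (mm). Each perimeter
#' edge is classified by its owning white pixel: within `edge_band` pixels
#' of the border it counts as along-edge, otherwise as away-from-edge.
#' Boundaries of holes that survive cleaning are included.
#'
#' @param mask Logical (or 0/1) matrix, TRUE = white.
#' @param edge_band Width of the border band in pixels (default 3).
#' @param cell_size Side length of one pixel in mm (default 1).
#' @return An object of class `morphometry`: list with `area`,
#'   `perimeter_total`, `perimeter_edge`, `perimeter_away`.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
#' measure_pattern(m)  # area 100, perimeter 40, all away from the edge
#' @export
measure_pattern <- function(mask, edge_band = 3L, cell_size = 1) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L), drop = FALSE]
  up    <- pad[1:H, 2:(W + 1L), drop = FALSE]
  down  <- pad[3:(H + 2L), 2:(W + 1L), drop = FALSE]
  left  <- pad[2:(H + 1L), 1:W, drop = FALSE]
  right <- pad[2:(H + 1L), 3:(W + 2L), drop = FALSE]
  edges <- core * ((!up) + (!down) + (!left) + (!right))
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  db <- pmin(r - 1L, H - r, cc - 1L, W - cc)
  in_band <- db <= edge_band - 1L
  pe <- sum(edges[in_band]) * cell_size
  pa <- sum(edges[!in_band]) * cell_size
  structure(list(area = sum(core) * cell_size^2,
                 perimeter_total = pe + pa,
                 perimeter_edge = pe,
                 perimeter_away = pa),
            class = "morphometry")
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf("<morphometry> area %g mm^2, perimeter %g mm (edge %g + away %g)\n",
              x$area, x$perimeter_total, x$perimeter_edge, x$perimeter_away))
  invisible(x)
}

#' Morphometry of a simulation grid
#'
#' Treats nest and built cells as white (the sawdust block is part of the
#' photographed structure) and measures the pattern. Cleaning is skipped by
#' default: simulated grids carry no debris.
#'
#' @param grid Integer matrix of cell states (0 empty, 1 nest, 2 built), as
#'   returned by [state_grid()] or stored in trajectory snapshots.
#' @param edge_band Border band width in cells (default 3).
#' @param clean Apply [clean_pattern()] first (default `FALSE`).
#' @return A `morphometry` object.
#' @export
measure_grid <- function(grid, edge_band = 3L, clean = FALSE) {
  m <- grid == CELL_NEST | grid == CELL_BUILT
  if (clean) m <- clean_pattern(m)
  measure_pattern(m, edge_band = edge_band)
}

#' Measure a set of pattern images
#'
#' Reads each image, binarizes (Otsu unless `threshold` given), cleans and
#' measures it, returning one tidy row per image.
#'
#' @param paths Character vector of image files (PGM, PNG or TIFF).
#' @param threshold Fixed binarization threshold, or `NULL` for Otsu.
#' @param min_object,max_hole Cleaning parameters, see [clean_pattern()].
#' @param edge_band Border band width in pixels.
#' @return Data frame with columns `id`, `area`, `perimeter_total`,
#'   `perimeter_edge`, `perimeter_away`.
#' @export
measure_images <- function(paths, threshold = NULL, min_object = 50L,
                           max_hole = 10L, edge_band = 3L) {
  rows <- lapply(paths, function(p) {
    img <- read_pattern_image(p)
    m <- clean_pattern(binarize(img, threshold), min_object, max_hole)
    res <- measure_pattern(m, edge_band = edge_band)
    data.frame(id = basename(p), area = res$area,
               perimeter_total = res$perimeter_total,
               perimeter_edge = res$perimeter_edge,
               perimeter_away = res$perimeter_away)
  })
  do.call(rbind, rows)
}
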