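# Configuration, manifests and grid/image I/O.

#' Write a grid or mask as PGM
#'
#' Writes a binary (P5) portable graymap. Cell-state grids are encoded
#' 0 = empty, 128 = nest, 255 = built; logical masks as 0/255.
#'
#' @param grid Integer cell-state matrix, logical mask, or numeric matrix
#'   of gray values in \[0, 255\].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(grid, path) {
  g <- grid
  if (is.logical(g)) {
    g <- ifelse(g, 255L, 0L)
  } else if (all(g %in% c(CELL_EMPTY, CELL_NEST, CELL_BUILT))) {
    g <- matrix(c(0L, 128L, 255L)[g + 1L], nrow(g), ncol(g))
  }
  g <- round(g)
  if (any(g < 0 | g > 255)) stop("PGM values must be in [0, 255]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(g), nrow(g)), "255"), con, sep = "\n")
  writeBin(as.integer(t(g)), con, size = 1L)
  invisible(path)
}

#' Read a PGM image
#'
#' Supports binary (P5) and ASCII (P2) graymaps with comment lines.
#'
#' @param path Input file.
#' @return Numeric matrix of gray values in \[0, maxval\].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokens(con, 4L)
  magic <- tok[1]
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE,
                 comment.char = "#")
  }
  matrix(vals, h, w, byrow = TRUE)
}

# Read whitespace-separated header tokens, skipping '#' comments. After the
# last token exactly one whitespace byte is consumed (P5 data follows).
pgm_tokens <- function(con, n) {
  tok <- character(0)
  cur <- ""
  while (length(tok) < n || nchar(cur)) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || !nchar(ch)) break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nchar(cur)) { tok <- c(tok, cur); cur <- "" }
      if (length(tok) >= n) break
    } else {
      cur <- paste0(cur, ch)
    }
  }
  tok
}

#' Read a pattern image file
#'
#' Reads PGM, PNG or TIFF into a grayscale intensity matrix. Multi-channel
#' images are reduced to luminance when `as_gray = TRUE` (the default);
#' with `as_gray = FALSE` the raw array is returned.
#'
#' @param path Image file; format chosen by extension.
#' @param as_gray Reduce RGB to luminance (0.2126 R + 0.7152 G + 0.0722 B).
#' @return Numeric matrix (rows = image rows), values in \[0, 1\] for
#'   PNG/TIFF and \[0, 255\] for PGM.
#' @export
read_pattern_image <- function(path, as_gray = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (as_gray && length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img[, , 1]
  }
  img
}

#' Write a grid or mask as PNG
#'
#' @param grid As in [write_pgm()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grid_png <- function(grid, path) {
  g <- grid
  if (is.logical(g)) {
    g <- ifelse(g, 1, 0)
  } else if (all(g %in% c(CELL_EMPTY, CELL_NEST, CELL_BUILT))) {
    g <- matrix(c(0, 128, 255)[g + 1L] / 255, nrow(g), ncol(g))
  } else {
    g <- g / max(1, max(g))
  }
  png::writePNG(g, path)
  invisible(path)
}

# Configuration keys settable from a YAML file or CLI overrides.
config_keys <- function() {
  names(formals(sim_params))
}

#' Load a simulation configuration
#'
#' Resolves simulation parameters from (in increasing precedence) the
#' built-in defaults, an optional YAML file and a list of overrides.
#' Unknown keys are rejected.
#'
#' @param path YAML config file, or `NULL` for defaults only.
#' @param overrides Named list of parameter overrides (e.g. from CLI
#'   flags).
#' @return A `sim_params` object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    vals <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("config error: ", conditionMessage(e)))
    if (is.null(vals)) vals <- list()
    if (!is.list(vals) || (length(vals) && is.null(names(vals))))
      stop("config error: config must be a mapping of parameter keys")
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), config_keys())
  if (length(unknown))
    stop("config error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  do.call(sim_params, vals)
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run bit-identically: the full
#' resolved parameter set, the seed, the package version and the MD5
#' checksums of the output files.
#'
#' @param params A `sim_params` object.
#' @param path Manifest file to write (JSON).
#' @param seed Seed actually used for the run.
#' @param outputs Character vector of produced files to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path, seed = params$seed,
                           outputs = character(0)) {
  man <- list(
    package = "sheltertube",
    version = as.character(utils::packageVersion("sheltertube")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = unclass(params),
    outputs = lapply(outputs, function(f)
      list(file = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Re-load parameters from a manifest
#'
#' @param path Manifest JSON written by [write_manifest()].
#' @return A `sim_params` object identical to the one recorded.
#' @export
read_manifest_params <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- man$params
  p <- p[!vapply(p, is.null, logical(1))]
  do.call(sim_params, p)
}
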