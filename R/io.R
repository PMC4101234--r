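## File I/O for images, sinograms and run configurations.
##
## Images: PNG and TIFF (linear grayscale, via the png/tiff packages) or
## plain CSV grids. Sinograms: CSV, one row per view. Configurations:
## YAML or JSON.

format_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff", "csv", "yaml", "yml", "json")) ext
  else stop_invalid("unsupported file extension: '", ext, "'")
}

#' Read an image from PNG, TIFF or CSV
#'
#' PNG/TIFF files are read as linear grayscale in `[0, 1]` (multi-channel
#' files are averaged); CSV files are read as a bare numeric grid.
#'
#' @param path file path; the format is taken from the extension.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  fmt <- format_of(path)
  x <- switch(fmt,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    stop_invalid("'", fmt, "' is not an image format")
  )
  if (length(dim(x)) == 3) x <- apply(x, c(1, 2), mean)
  unname(as.matrix(x))
}

#' Write an image to PNG, TIFF or CSV
#'
#' For PNG/TIFF the image is linearly rescaled to `[0, 1]` unless it
#' already lies there; CSV keeps raw values.
#'
#' @param f numeric matrix.
#' @param path output path; format from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(f, path) {
  fmt <- format_of(path)
  if (fmt %in% c("png", "tif", "tiff")) {
    lo <- min(f); hi <- max(f)
    g <- if (lo >= 0 && hi <= 1) f else if (hi > lo) (f - lo) / (hi - lo) else f * 0
    if (fmt == "png") png::writePNG(g, path) else tiff::writeTIFF(g, path)
  } else if (fmt == "csv") {
    write.table(f, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    stop_invalid("'", fmt, "' is not an image format")
  }
  invisible(path)
}

#' Read/write a sinogram as CSV (one row per view)
#'
#' @param path file path.
#' @param geometry optional [projection_geometry()] to attach on read.
#' @return `read_sinogram`: a sinogram matrix; `write_sinogram`: the path.
#' @export
read_sinogram <- function(path, geometry = NULL) {
  p <- unname(as.matrix(read.csv(path, header = FALSE)))
  if (!is.null(geometry)) {
    if (!all(dim(p) == c(geometry$n_views, geometry$n_detectors))) {
      stop_invalid("sinogram shape does not match the geometry")
    }
    p <- structure(p, class = c("sinogram", "matrix"), geometry = geometry)
  }
  p
}

#' @rdname read_sinogram
#' @param p sinogram matrix.
#' @export
write_sinogram <- function(p, path) {
  write.table(unclass(p), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read/write an experiment configuration (YAML or JSON)
#'
#' The on-disk representation is a plain mapping of the
#' [experiment_config()] fields; the round trip config -> file -> config is
#' lossless.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_config`: an `experiment_config`; `write_config`: the path.
#' @export
read_config <- function(path) {
  fmt <- format_of(path)
  x <- switch(fmt,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_invalid("'", fmt, "' is not a config format")
  )
  x$snr_db <- if (is.null(x$snr_db)) Inf else as.numeric(x$snr_db)
  do.call(experiment_config, x)
}

#' @rdname read_config
#' @param config an [experiment_config()].
#' @export
write_config <- function(config, path) {
  fmt <- format_of(path)
  x <- unclass(config)
  x$params <- unclass(x$params)
  ## Inf does not survive YAML/JSON portably; absence means "no noise"
  if (is.infinite(x$snr_db)) x$snr_db <- NULL
  if (fmt %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (fmt == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop_invalid("'", fmt, "' is not a config format")
  }
  invisible(path)
}
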