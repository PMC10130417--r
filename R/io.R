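# File interchange: multi-page TIFF image stacks (one file per channel,
# frame-major), spot tables as CSV with a JSON settings sidecar, and
# calibration serialization.

#' Write an image stack to multi-page TIFF files
#'
#' One 32-bit float TIFF per channel, frame-major pages. Counts are stored
#' divided by `scale` to fit the [0, 1] float convention of baseline TIFF
#' writers; the scale is returned (and recorded by
#' [generateFixtureDataset()] manifests) for exact restoration.
#'
#' @param stack an [ImageStack-class].
#' @param prefix path prefix; files are written as
#'   `<prefix>_<channel>.tif`.
#' @param scale intensity scale divisor (default 65536).
#' @return invisibly, a named character vector of file paths with
#'   attribute `scale`.
#' @export
writeImageStack <- function(stack, prefix, scale = 65536) {
  stopifnot(is(stack, "ImageStack"))
  paths <- character(0)
  for (ch in names(stack@channels)) {
    arr <- stack@channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[1]), function(f) arr[f, , ] / scale)
    path <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    paths[ch] <- path
  }
  attr(paths, "scale") <- scale
  invisible(paths)
}

#' Read an image stack from multi-page TIFF files
#'
#' @param paths named character vector (names = channel names) of TIFF
#'   files written by [writeImageStack()].
#' @param pixelSize um/px.
#' @param frameInterval s.
#' @param scale intensity scale used at write time.
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(paths, pixelSize, frameInterval = 0.1,
                           scale = 65536) {
  chans <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * scale
    arr
  })
  names(chans) <- if (!is.null(names(paths))) names(paths)
    else paste0("ch", seq_along(paths))
  new("ImageStack", channels = chans, pixelSize = pixelSize,
      frameInterval = frameInterval)
}

#' Write a spot list to CSV with a JSON sidecar
#'
#' The CSV has columns channel, x_um, y_um, amplitude, integrated_intensity,
#' sigma_um (origin at the centre of pixel (0,0), x rightward, y downward);
#' detection settings go to `<path>.json`.
#'
#' @param spotlist a [SpotList-class].
#' @param path CSV path.
#' @return invisibly, the CSV path.
#' @export
writeSpotList <- function(spotlist, path) {
  stopifnot(is(spotlist, "SpotList"))
  df <- spotlist@spots
  names(df) <- c("channel", "x_um", "y_um", "amplitude",
                 "integrated_intensity", "sigma_um")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(spotlist@metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spot list written by [writeSpotList()]
#' @param path CSV path.
#' @return a [SpotList-class].
#' @export
readSpotList <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- c("channel", "x", "y", "amplitude", "integrated", "sigma")
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  new("SpotList", spots = df, metadata = as.list(meta))
}

#' Serialize a calibration to JSON
#'
#' Stores slope, intercept, range and diagnostics together with an md5
#' provenance hash of the input table when one is given.
#'
#' @param cal a [DensityCalibration-class].
#' @param path JSON path.
#' @param inputTable optional path of the measurement table to hash.
#' @return invisibly, the path.
#' @export
writeCalibration <- function(cal, path, inputTable = NULL) {
  stopifnot(is(cal, "DensityCalibration"))
  obj <- list(slope = cal@slope, intercept = cal@intercept,
              range = cal@range, diagnostics = cal@diagnostics)
  if (!is.null(inputTable))
    obj$provenance <- unname(tools::md5sum(inputTable))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration written by [writeCalibration()]
#' @param path JSON path.
#' @return a [DensityCalibration-class].
#' @export
readCalibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DensityCalibration", slope = obj$slope, intercept = obj$intercept,
      range = obj$range, diagnostics = as.list(obj$diagnostics))
}
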