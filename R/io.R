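## Portable container and exchange-table I/O.
##
## The container is a directory holding `manifest.json` plus one raw
## little-endian float64 file per channel x direction (row-major) and a
## uint8 validity mask. The layout is deliberately trivial to read from any
## language (e.g. numpy.fromfile + reshape) and round-trips bit-identically.
## Proprietary instrument formats are not parsed; TIFF/CSV import is the
## documented conversion path.

.CONTAINER_SCHEMA <- "afmirib-container-1"

.writeArray <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
}

.readArray <- function(path, h, w) {
  if (!file.exists(path))
    stop("missing channel data file: ", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = h * w, size = 8, endian = "little")
  if (length(v) != h * w) stop("truncated array file: ", basename(path))
  t(matrix(v, w, h))
}

.writeMask <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(m)), con, size = 1)
}

.readMask <- function(path, h, w) {
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = h * w, size = 1, signed = FALSE)
  t(matrix(v != 0, w, h))
}

.datasetManifest <- function(ds, prefix) {
  chans <- lapply(ds@channels, function(cm) {
    base <- paste(prefix, cm@channel, cm@direction, sep = "_")
    list(channel = cm@channel, direction = cm@direction, units = cm@units,
         shape = dim(cm@data), data_file = paste0(base, ".f64"),
         mask_file = paste0(base, ".mask.u8"))
  })
  list(wavenumber = ds@wavenumber, pixel_size_nm = ds@pixelSizeNm,
       field_of_view_um = ds@fieldOfViewUm, sample_id = ds@sampleId,
       session_id = ds@sessionId, channels = chans)
}

.writeDatasetArrays <- function(ds, prefix, path) {
  for (cm in ds@channels) {
    base <- file.path(path, paste(prefix, cm@channel, cm@direction,
                                  sep = "_"))
    .writeArray(cm@data, paste0(base, ".f64"))
    .writeMask(cm@valid, paste0(base, ".mask.u8"))
  }
}

.readDatasetFromManifest <- function(man, path) {
  chans <- lapply(man$channels, function(ch) {
    sh <- as.integer(unlist(ch$shape))
    h <- sh[1]; w <- sh[2]
    f <- file.path(path, ch$data_file)
    if (!file.exists(f))
      stop("container is missing channel ", ch$channel, "/", ch$direction)
    data <- .readArray(f, h, w)
    valid <- .readMask(file.path(path, ch$mask_file), h, w)
    data[!valid] <- 0
    ChannelMap(ch$channel, data, ch$direction, ch$units, valid = valid)
  })
  AFMIRDataset(man$wavenumber, chans, unlist(man$field_of_view_um),
               pixelSizeNm = man$pixel_size_nm, sampleId = man$sample_id,
               sessionId = man$session_id)
}

#' Write / read the portable map container
#'
#' Serialises an [AFMIRDataset-class] or [DatasetPair-class] to a directory
#' container (JSON manifest + raw float64 arrays + uint8 validity masks);
#' the round trip is bit-identical for all arrays, masks and metadata,
#' including the registration transform of a pair.
#'
#' @param x An [AFMIRDataset-class] or [DatasetPair-class].
#' @param path Container directory (created, overwriting an existing
#'   container).
#' @return \code{writeContainer}: the path, invisibly.
#'   \code{readContainer}: the stored object.
#' @export
writeContainer <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (is(x, "DatasetPair")) {
    man <- list(schema = .CONTAINER_SCHEMA, type = "pair",
                ds1650 = .datasetManifest(x@ds1650, "ds1650"),
                ds1625 = .datasetManifest(x@ds1625, "ds1625"),
                transform = if (isRegistered(x)) x@transform else NULL)
    .writeDatasetArrays(x@ds1650, "ds1650", path)
    .writeDatasetArrays(x@ds1625, "ds1625", path)
  } else if (is(x, "AFMIRDataset")) {
    man <- list(schema = .CONTAINER_SCHEMA, type = "dataset",
                dataset = .datasetManifest(x, "ds"))
    .writeDatasetArrays(x, "ds", path)
  } else stop("cannot write object of class ", class(x)[1])
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeContainer
#' @export
readContainer <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a container: no manifest at ", path)
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(man$schema, .CONTAINER_SCHEMA))
    stop("unsupported container schema: ", man$schema)
  if (identical(man$type, "pair")) {
    tr <- if (!is.null(man$transform))
      matrix(unlist(man$transform), 3, 3, byrow = TRUE)
    ds1650 <- .readDatasetFromManifest(man$ds1650, path)
    ds1625 <- .readDatasetFromManifest(man$ds1625, path)
    DatasetPair(ds1650, ds1625, transform = tr)
  } else {
    .readDatasetFromManifest(man$dataset, path)
  }
}

#' Export channel maps as 32-bit float TIFF
#'
#' One TIFF per channel x direction, for interoperability with image tools.
#' Values are written as 32-bit floats without rescaling.
#'
#' @param dataset An [AFMIRDataset-class].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
exportChannelTiff <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(dataset@channels, function(cm) {
    f <- file.path(dir, sprintf("%.0f_%s_%s.tif", dataset@wavenumber,
                                cm@channel, cm@direction))
    ## float samples legitimately exceed [0, 1]; writeTIFF warns regardless
    suppressWarnings(
      tiff::writeTIFF(cm@data, f, bits.per.sample = 32, reduce = FALSE))
    f
  }, character(1))
  invisible(paths)
}

## ---------------------------------------------------------------------------
## spectra exchange tables
## ---------------------------------------------------------------------------

.fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Export / import spectra as a long-format CSV
#'
#' One row per (spectrum, wavenumber): columns spectrum_id, wavenumber,
#' amplitude, pll, valid, sample_id, session_id, category, x, y. Numbers are
#' written with 17 significant digits so the numeric round trip is lossless.
#' All spectra must share one wavenumber grid. An empty collection produces
#' a header-only file.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path CSV file path.
#' @return \code{exportSpectraTable}: the path, invisibly;
#'   \code{importSpectraTable}: a list of [Spectrum-class] objects.
#' @export
exportSpectraTable <- function(spectra, path) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  cols <- c("spectrum_id", "wavenumber", "amplitude", "pll", "valid",
            "sample_id", "session_id", "category", "x", "y")
  if (!length(spectra)) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  g <- wavenumber(spectra[[1]])
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (!.sameGrid(g, wavenumber(s)))
      stop("mixed grids in spectra collection")
    n <- length(g)
    data.frame(
      spectrum_id = i,
      wavenumber = .fmtNum(wavenumber(s)),
      amplitude = .fmtNum(irAmplitude(s)),
      pll = if (length(s@pllFrequency)) .fmtNum(s@pllFrequency)
            else rep("NA", n),
      valid = as.integer(validMask(s)),
      sample_id = rep(sampleId(s), n),
      session_id = rep(sessionId(s), n),
      category = rep(category(s), n),
      x = if (length(s@position)) rep(.fmtNum(s@position[1]), n)
          else rep("NA", n),
      y = if (length(s@position)) rep(.fmtNum(s@position[2]), n)
          else rep("NA", n))
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exportSpectraTable
#' @export
importSpectraTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  lapply(split(df, df$spectrum_id), function(d) {
    d <- d[order(d$wavenumber), ]
    pos <- if (all(is.na(d$x))) numeric() else c(d$x[1], d$y[1])
    Spectrum(d$wavenumber, d$amplitude,
             pllFrequency = if (all(is.na(d$pll))) numeric() else d$pll,
             valid = d$valid > 0, sampleId = as.character(d$sample_id[1]),
             sessionId = as.character(d$session_id[1]),
             category = d$category[1], position = pos)
  })
}

#' Write IB/cell feature tables to CSV
#'
#' Plain CSV with full-precision numerics and a sidecar column dictionary.
#'
#' @param features Output of [extractIbFeatures()].
#' @param ibsPath,cellsPath Output CSV paths.
#' @return Invisibly, the paths.
#' @export
writeFeatureTables <- function(features, ibsPath, cellsPath) {
  utils::write.csv(features$ibs, ibsPath, row.names = FALSE)
  utils::write.csv(features$cells, cellsPath, row.names = FALSE)
  invisible(c(ibsPath, cellsPath))
}
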