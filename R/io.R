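#' Read a localization table
#'
#' Reads per-emitter localizations (one detected single-molecule position
#' per frame) from CSV. Two header dialects are supported: the
#' ThunderSTORM export convention (columns such as `"frame"`, `"x [nm]"`,
#' `"y [nm]"`, `"uncertainty [nm]"`, `"intensity [photon]"`) and a
#' generic dialect with exact names `frame,x_nm,y_nm[,precision_nm][,intensity]`.
#' Coordinates are in nanometres throughout; frames are 1-based.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect `"thunderstorm"` or `"generic"`.
#' @return A `data.frame` of class `localizations` with columns `frame`
#'   (integer), `x`, `y` (nm), and optionally `intensity` and `precision`
#'   (nm). Unknown input columns are carried through untouched.
#' @export
read_localizations <- function(path, dialect = c("thunderstorm", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(raw)
  if (dialect == "thunderstorm") {
    map <- c(frame = "^frame$", x = "^x \\[nm\\]$", y = "^y \\[nm\\]$",
             precision = "^uncertainty(_xy)? \\[nm\\]$",
             intensity = "^intensity( \\[(photon|a\\.?u\\.?)\\])?$")
  } else {
    map <- c(frame = "^frame$", x = "^x_nm$", y = "^y_nm$",
             precision = "^precision_nm$", intensity = "^intensity$")
  }
  required <- c("frame", "x", "y")
  out <- raw
  for (target in names(map)) {
    hit <- grep(map[[target]], nm)
    if (length(hit) == 1L) {
      names(out)[hit] <- target
    } else if (target %in% required) {
      abort_format(sprintf("missing required column '%s' in %s dialect header",
                           target, dialect))
    }
  }
  for (col in intersect(c("frame", "x", "y", "precision", "intensity"),
                        names(out))) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        abort_format(sprintf("non-numeric value in column '%s' at data row %d",
                             col, bad[1]))
      v <- vn
    }
    out[[col]] <- v
  }
  as_localizations(out)
}

#' Construct / validate a localization table
#'
#' @param df data.frame with columns `frame`, `x`, `y` and optionally
#'   `precision`, `intensity` (nm units for lengths).
#' @return The validated `localizations` data.frame.
#' @export
as_localizations <- function(df) {
  for (col in c("frame", "x", "y"))
    if (!col %in% names(df)) abort_format(sprintf("missing column '%s'", col))
  if (nrow(df)) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      abort_format("non-finite coordinates in localization table")
    if (any(df$frame < 1)) abort_format("frames must be >= 1")
    if ("precision" %in% names(df) &&
        any(!is.na(df$precision) & df$precision <= 0))
      abort_format("localization precision must be > 0 where present")
  }
  df$frame <- as.integer(df$frame)
  class(df) <- c("localizations", "data.frame")
  df
}

#' Write a localization table (generic dialect)
#'
#' @param locs A `localizations` table.
#' @param path Output CSV path.
#' @export
write_localizations <- function(locs, path) {
  out <- data.frame(frame = locs$frame, x_nm = locs$x, y_nm = locs$y)
  if ("precision" %in% names(locs)) out$precision_nm <- locs$precision
  if ("intensity" %in% names(locs)) out$intensity <- locs$intensity
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trajectory tables
#'
#' A track table holds linked trajectories: columns `track_id`, `frame`,
#' `x`, `y` (nm) and optionally `precision` (nm). Within a track frames
#' are strictly increasing.
#'
#' @param tracks A track table `data.frame`.
#' @param path CSV path.
#' @return `read_tracks` returns the validated track table.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- validate_tracks(tracks)
  out <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    x_nm = tracks$x, y_nm = tracks$y)
  out$precision_nm <- if ("precision" %in% names(tracks)) tracks$precision
                      else rep(NA_real_, nrow(out))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_nm", "y_nm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_format(sprintf("track table missing columns: %s",
                         paste(miss, collapse = ", ")))
  df <- data.frame(track_id = as.integer(raw$track_id),
                   frame = as.integer(raw$frame),
                   x = raw$x_nm, y = raw$y_nm)
  if ("precision_nm" %in% names(raw)) df$precision <- raw$precision_nm
  validate_tracks(df)
}

validate_tracks <- function(df) {
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(sprintf("track table missing columns: %s",
                         paste(miss, collapse = ", ")))
  if (nrow(df)) {
    ord <- order(df$track_id, df$frame)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    d <- split(df$frame, df$track_id)
    bad <- names(d)[vapply(d, function(f) any(diff(f) <= 0), logical(1))]
    if (length(bad))
      abort_format(sprintf(
        "frames not strictly increasing within track_id %s", bad[1]))
  }
  class(df) <- c("tracks", "data.frame")
  df
}

#' Read an integer label mask
#'
#' Reads a segmentation mask (background 0, one positive integer label
#' per cell) from a TIFF or PNG raster and attaches the physical pixel
#' size. Labels need not be contiguous integers.
#'
#' @param path Raster path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size Pixel edge length in nm.
#' @return A `label_mask`: integer matrix with attribute `pixel_size`.
#' @export
read_label_mask <- function(path, pixel_size) {
  check_number(pixel_size, "pixel_size", lower = 0, allow_equal = FALSE)
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- x[, , 1]
      # png stores [0,1]; recover stored integers for 8- or 16-bit depth
      if (all(abs(x * 255 - round(x * 255)) < 1e-6)) x * 255 else x * 65535
    },
    abort_format(sprintf("unsupported raster format '.%s'", ext)))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  label_mask(matrix(img, nrow(img), ncol(img)), pixel_size)
}

#' Construct a label mask from a matrix
#'
#' @param m Integer matrix, background 0.
#' @param pixel_size Pixel edge length, nm.
#' @return A `label_mask` object.
#' @export
label_mask <- function(m, pixel_size) {
  check_number(pixel_size, "pixel_size", lower = 0, allow_equal = FALSE)
  if (!is.matrix(m)) abort_format("mask must be a matrix")
  if (any(!is.finite(m))) abort_format("mask values must be finite")
  if (any(abs(m - round(m)) > 1e-6))
    abort_format("raster contains non-integral values; not a label mask")
  if (any(m < 0)) abort_format("labels must be non-negative")
  structure(matrix(as.integer(round(m)), nrow(m), ncol(m)),
            pixel_size = pixel_size, class = c("label_mask", "matrix"))
}

#' Write a label mask to TIFF
#'
#' @param mask A `label_mask`.
#' @param path Output path (`.tif`).
#' @export
write_label_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.integer(mask), nrow(mask), ncol(mask)) / 65535,
                  path, bits.per.sample = 16)
  invisible(path)
}

#' Number of cells in a label mask
#' @param mask A `label_mask`.
#' @return Count of distinct positive labels.
#' @export
n_cells <- function(mask) length(setdiff(unique(as.integer(mask)), 0L))

#' Read a generic long-format series table
#'
#' Validates a CSV against a required column set and returns it with
#' extra columns retained. Used for plate-reader, isotherm, FTIR and
#' gel band-intensity inputs.
#'
#' @param path CSV path with header.
#' @param schema Character vector of required column names.
#' @return A `data.frame`.
#' @export
read_series <- function(path, schema) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(schema, names(df))
  if (length(miss))
    abort_format(sprintf("series missing required columns: %s",
                         paste(miss, collapse = ", ")))
  df
}
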