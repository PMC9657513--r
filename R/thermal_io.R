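# Frame I/O. Three interchange formats:
#   * CSV numeric matrix, degrees C, NA/empty = invalid pixel;
#   * 16-bit grayscale TIFF at 0.01 degC per unit (radiometric-camera style
#     centi-degC convention; count 0 is reserved as the no-data value);
#   * native binary array (doubles, lossless) for exact round-trips.
# Geometry/session metadata travels in a JSON sidecar `<path>.json` with keys
# distance_cm, focal_cm, pixel_w_cm, pixel_l_cm, session_id, timestamp.

.thermo_io_error <- function(msg) {
  stop(structure(class = c("thermo_io_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.sidecar_path <- function(path) paste0(path, ".json")

.metadata_to_sidecar <- function(frame) {
  list(distance_cm = frame$distance_d, focal_cm = frame$focal_f,
       pixel_w_cm = frame$pixel_width_W, pixel_l_cm = frame$pixel_length_L,
       session_id = frame$session_id,
       timestamp = if (inherits(frame$timestamp, "Date"))
         format(frame$timestamp) else frame$timestamp)
}

.metadata_from_list <- function(md) {
  get0 <- function(k) if (!is.null(md[[k]])) md[[k]] else NA
  list(distance_d = as.numeric(get0("distance_cm")),
       focal_f = as.numeric(get0("focal_cm")),
       pixel_width_W = as.numeric(get0("pixel_w_cm")),
       pixel_length_L = as.numeric(get0("pixel_l_cm")),
       session_id = if (is.na(get0("session_id")[1L])) NA_character_
                    else as.character(get0("session_id")),
       timestamp = if (is.na(get0("timestamp")[1L])) NA
                   else as.Date(get0("timestamp")))
}

.frame_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tif = , tiff = "tiff", bin = "bin",
         .thermo_io_error(paste0("unknown thermal frame extension: '",
                                 tools::file_ext(path), "'")))
}

#' Read a thermal frame from disk
#'
#' Supported formats (chosen by extension): `.csv` (numeric matrix of
#' degrees C; empty cells or `NA` mark invalid pixels), `.tif`/`.tiff`
#' (16-bit grayscale, temperature = pixel value x 0.01 degC, value 0 =
#' no-data) and `.bin` (native lossless binary array). If a JSON metadata
#' sidecar `<path>.json` exists it is read; entries in `metadata` override
#' it (keys `distance_cm`, `focal_cm`, `pixel_w_cm`, `pixel_l_cm`,
#' `session_id`, `timestamp`).
#'
#' @param path file to read.
#' @param metadata named list of acquisition metadata overriding the sidecar.
#' @return A [thermal_frame()] with non-finite cells marked invalid.
#' @export
read_frame <- function(path, metadata = list()) {
  if (!file.exists(path))
    .thermo_io_error(paste0("no such file: ", path))
  fmt <- .frame_format(path)
  grid <- switch(fmt,
    csv = .read_csv_grid(path),
    tiff = .read_tiff_grid(path),
    bin = .read_bin_grid(path))
  md <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc))
    md <- jsonlite::read_json(sc, simplifyVector = TRUE)
  md[names(metadata)] <- metadata
  md <- .metadata_from_list(md)
  thermal_frame(grid,
                distance_d = md$distance_d, focal_f = md$focal_f,
                pixel_width_W = md$pixel_width_W,
                pixel_length_L = md$pixel_length_L,
                session_id = md$session_id, timestamp = md$timestamp)
}

.read_csv_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .thermo_io_error(paste0("empty CSV frame: ", path))
  cells <- strsplit(lines, ",", fixed = TRUE)
  w <- unique(lengths(cells))
  if (length(w) != 1L)
    .thermo_io_error(paste0("non-rectangular CSV frame: ", path))
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  matrix(vals, nrow = length(lines), ncol = w, byrow = TRUE)
}

.read_tiff_grid <- function(path) {
  r <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) .thermo_io_error(
                  paste0("unreadable TIFF: ", path, " (", conditionMessage(e), ")")))
  if (length(dim(r)) == 3L) r <- r[, , 1L]
  g <- r * 0.01
  g[r == 0L] <- NA_real_  # 0 counts reserved as no-data
  g
}

.read_bin_grid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "THFR"))
    .thermo_io_error(paste0("not a thermolesion binary frame: ", path))
  ver <- readBin(con, "integer", 1L, size = 4L)
  if (ver != 1L) .thermo_io_error(paste0("unsupported binary frame version ", ver))
  hw <- readBin(con, "integer", 2L, size = 4L)
  vals <- readBin(con, "double", hw[1L] * hw[2L])
  if (length(vals) != hw[1L] * hw[2L])
    .thermo_io_error(paste0("truncated binary frame: ", path))
  matrix(vals, nrow = hw[1L], ncol = hw[2L])
}

#' Write a thermal frame to disk
#'
#' The binary format is lossless (`read_frame(write_frame(x))` is the
#' identity on valid pixels); TIFF quantizes to 0.01 degC and cannot
#' represent temperatures outside (0, 655.35] degC; CSV keeps full printed
#' precision. A JSON metadata sidecar `<path>.json` is always written so
#' acquisition metadata survives the round trip.
#'
#' @param frame a [thermal_frame()].
#' @param path destination file.
#' @param format `"auto"` (from extension), `"csv"`, `"tiff"` or `"bin"`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, format = c("auto", "csv", "tiff", "bin")) {
  stopifnot(inherits(frame, "thermal_frame"))
  format <- match.arg(format)
  if (format == "auto") format <- .frame_format(path)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    .thermo_io_error(paste0("unwritable path: ", path))
  switch(format,
    csv = {
      g <- frame$grid
      txt <- apply(g, 1L, function(row)
        paste(ifelse(is.na(row), "", format(row, trim = TRUE, digits = 15)),
              collapse = ","))
      writeLines(txt, path)
    },
    tiff = {
      g <- frame$grid
      counts <- round(g * 100)
      bad <- frame$mask & (counts < 1 | counts > 65535)
      if (any(bad))
        .thermo_io_error(
          "TIFF format cannot represent temperatures outside (0, 655.35] degC")
      counts[!frame$mask] <- 0
      tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
    },
    bin = {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(charToRaw("THFR"), con)
      writeBin(c(1L, nrow(frame$grid), ncol(frame$grid)), con, size = 4L)
      writeBin(as.vector(frame$grid), con)
    })
  jsonlite::write_json(.metadata_to_sidecar(frame), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
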