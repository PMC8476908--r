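# Map and cohort IO. Maps travel as 16-bit grayscale TIFF with a JSON
# sidecar carrying dose scale and geometry (stored integer = cGy * 100),
# or as DICOM RT Image (read-only). Cohorts are a directory of TIFFs plus a
# CSV manifest.

DOSE_PER_INT <- 1 / 100 # cGy per stored 16-bit unit

#' Write a fluence map as 16-bit TIFF
#'
#' Pixel doses are stored as `round(cGy * 100)` in a 16-bit grayscale TIFF;
#' pitch, dose scale and the error vector go to a `<path>.json` sidecar so
#' the round trip is lossless to the 0.01 cGy quantisation.
#'
#' @param map a [fluence_map()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  m <- map_pixels(as_fluence_map(map))
  ints <- pmin(pmax(round(m / DOSE_PER_INT), 0), 65535)
  tiff::writeTIFF(ints / 65535, path, bits.per.sample = 16,
                  compression = "none")
  e <- map_error(map)
  sidecar <- list(pitch_mm = map_pitch(map),
                  dose_per_int_cgy = DOSE_PER_INT,
                  patient_id = attr(map, "patient_id"),
                  lr_mm = e[["lr"]], si_mm = e[["si"]], ap_mm = e[["ap"]])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a fluence map (TIFF or DICOM RT Image)
#'
#' TIFF files are rescaled to cGy via the JSON sidecar written by
#' [write_map()] (or `pitch_mm`/`dose_per_int` overrides); DICOM RT Image
#' files (explicit-VR little-endian) are rescaled through their
#' RescaleSlope/Intercept and take the pitch from ImagePlanePixelSpacing.
#' An explicit `pitch_mm` always wins over metadata.
#'
#' @param path file to read.
#' @param pitch_mm pixel pitch override in mm.
#' @param dose_per_int dose per stored integer unit for TIFFs without a
#'   sidecar.
#' @return A [fluence_map()].
#' @export
read_map <- function(path, pitch_mm = NULL, dose_per_int = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is_dicom(path)) return(read_dicom_rtimage(path, pitch_mm))
  vals <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(vals)) != 2)
    stop("expected a single-channel grayscale TIFF", call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  pitch <- pitch_mm %||% sidecar$pitch_mm
  if (is.null(pitch))
    stop("no pixel pitch: supply `pitch_mm` or a JSON sidecar", call. = FALSE)
  scale <- dose_per_int %||% sidecar$dose_per_int_cgy %||% DOSE_PER_INT
  err <- if (!is.null(sidecar))
    error_vector(sidecar$lr_mm %||% 0, sidecar$si_mm %||% 0,
                 sidecar$ap_mm %||% 0) else error_vector()
  fluence_map(vals * scale, pitch_mm = pitch,
              patient_id = sidecar$patient_id %||% NA_character_,
              error = err)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && identical(hdr[129:132], charToRaw("DICM"))
}

# Minimal explicit-VR little-endian DICOM walker; returns the handful of
# attributes an RT Image needs. Not a general DICOM implementation.
read_dicom_rtimage <- function(path, pitch_mm = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(raw[129:132], charToRaw("DICM")))
    stop("not a DICOM file: ", path, call. = FALSE)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1]) +
    65536 * as.integer(raw[i + 2]) + 16777216 * as.integer(raw[i + 3])
  pos <- 133
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8)
      data_at <- pos + 12
    } else {
      len <- u16(pos + 6)
      data_at <- pos + 8
    }
    tag <- sprintf("%04x%04x", group, elem)
    if (tag == "00020010") # transfer syntax
      elems[[tag]] <- sub("\\s+$", "", rawToChar(raw[data_at:(data_at + len - 1)]))
    else if (tag %in% c("00280010", "00280011")) # rows / columns
      elems[[tag]] <- u16(data_at)
    else if (tag %in% c("30020011", "00280030", "00281052", "00281053")) {
      elems[[tag]] <- as.numeric(strsplit(
        rawToChar(raw[data_at:(data_at + len - 1)]), "\\\\")[[1]])
    } else if (tag == "00280100") { # bits allocated
      elems[[tag]] <- u16(data_at)
    } else if (tag == "7fe00010") {
      elems[["pixel_at"]] <- data_at
      elems[["pixel_len"]] <- len
      break
    }
    pos <- data_at + len
  }
  ts <- elems[["00020010"]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("only explicit-VR little-endian DICOM is supported", call. = FALSE)
  rows <- elems[["00280010"]]; cols <- elems[["00280011"]]
  if (is.null(rows) || is.null(cols) || is.null(elems$pixel_at))
    stop("DICOM file lacks image dimensions or pixel data", call. = FALSE)
  bits <- elems[["00280100"]] %||% 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported",
                        call. = FALSE)
  n <- rows * cols
  pix <- readBin(raw[elems$pixel_at:(elems$pixel_at + 2 * n - 1)],
                 "integer", n = n, size = 2, signed = FALSE,
                 endian = "little")
  slope <- (elems[["00281053"]] %||% 1)[1]
  intercept <- (elems[["00281052"]] %||% 0)[1]
  # DICOM pixel order is row-major
  m <- matrix(pix * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)
  spacing <- elems[["30020011"]] %||% elems[["00280030"]]
  pitch <- pitch_mm %||% (if (!is.null(spacing)) spacing[1] else NULL)
  if (is.null(pitch))
    stop("DICOM file lacks pixel spacing; supply `pitch_mm`", call. = FALSE)
  fluence_map(pmax(m, 0), pitch_mm = pitch)
}

#' Write / read a cohort as TIFF maps plus a CSV manifest
#'
#' `write_cohort()` writes one 16-bit TIFF per map and a UTF-8 CSV manifest
#' with the patient id, error vector, all labels, seeds and relative file
#' paths. `read_manifest()` loads the manifest back (optionally with the
#' pixel data), validating that every patient has exactly one baseline.
#'
#' @param cohort a [generate_cohort()] tibble with its `map` column.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns the manifest path;
#'   `read_manifest()` returns the cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot("map" %in% names(cohort))
  check_one_baseline(cohort)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_s%02d.tif", cohort$patient_id, cohort$serial)
  for (i in seq_len(nrow(cohort)))
    write_map(cohort$map[[i]], file.path(dir, files[i]))
  manifest <- dplyr::mutate(
    dplyr::select(cohort, -"map"),
    pitch_mm = vapply(cohort$map, map_pitch, numeric(1)),
    file = files)
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_cohort
#' @param path manifest CSV path.
#' @param load_maps read the pixel data as well (default `TRUE`).
#' @export
read_manifest <- function(path, load_maps = TRUE) {
  manifest <- readr::read_csv(path, show_col_types = FALSE)
  check_one_baseline(manifest)
  if (load_maps) {
    dir <- dirname(path)
    manifest$map <- lapply(seq_len(nrow(manifest)), function(i) {
      m <- read_map(file.path(dir, manifest$file[i]))
      attr(m, "patient_id") <- manifest$patient_id[i]
      attr(m, "error") <- error_vector(manifest$lr_mm[i], manifest$si_mm[i],
                                       manifest$ap_mm[i])
      m
    })
  }
  manifest
}

check_one_baseline <- function(records) {
  counts <- table(records$patient_id[records$role == "baseline"])
  pats <- unique(records$patient_id)
  bad <- setdiff(pats, names(counts)[counts == 1])
  if (length(bad))
    stop("each patient needs exactly one baseline record; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
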