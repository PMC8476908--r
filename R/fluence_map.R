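#' Transmission fluence maps
#'
#' A fluence map is the 2D dose image recorded by an EPID panel of the beam
#' transmitted through the patient (here, a synthetic head phantom) during an
#' arc delivery. Pixel values are doses in cGy on the fraction-dose scale
#' (about 200 cGy fully open); rows run along the superior-inferior (SI)
#' imager axis and columns along the in-plane axis, origin top-left.
#'
#' @param pixels numeric matrix of doses in cGy; all values must be >= 0.
#' @param pitch_mm pixel pitch in mm (detector default 0.336).
#' @param patient_id identifier of the (synthetic) patient the map belongs to.
#' @param error the injected [error_vector()] (the baseline carries zeros).
#' @param meta named list of free-form acquisition metadata.
#' @return A `fluence_map`: the pixel matrix with pitch/patient/error
#'   attributes attached.
#' @export
fluence_map <- function(pixels, pitch_mm = 0.336, patient_id = NA_character_,
                        error = error_vector(), meta = list()) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < 0)) stop("fluence map pixels must be >= 0", call. = FALSE)
  stopifnot(is.numeric(pitch_mm), length(pitch_mm) == 1, pitch_mm > 0)
  structure(pixels,
            pitch_mm = as.numeric(pitch_mm),
            patient_id = as.character(patient_id),
            error = as_error_vector(error),
            meta = meta,
            class = c("fluence_map", "matrix", "array"))
}

#' @rdname fluence_map
#' @param x object to coerce / query.
#' @export
as_fluence_map <- function(x, pitch_mm = 0.336) {
  if (inherits(x, "fluence_map")) return(x)
  fluence_map(as.matrix(x), pitch_mm = pitch_mm)
}

#' @rdname fluence_map
#' @export
map_pixels <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

#' @rdname fluence_map
#' @export
map_pitch <- function(x) {
  p <- attr(x, "pitch_mm")
  if (is.null(p)) 0.336 else p
}

#' @rdname fluence_map
#' @export
map_error <- function(x) {
  e <- attr(x, "error")
  if (is.null(e)) error_vector() else e
}

#' @export
print.fluence_map <- function(x, ...) {
  e <- map_error(x)
  cat(sprintf(
    "<fluence_map %dx%d px, pitch %.3f mm, patient %s, error LR=%g SI=%g AP=%g mm>\n",
    nrow(x), ncol(x), map_pitch(x), attr(x, "patient_id"),
    e[["lr"]], e[["si"]], e[["ap"]]))
  cat(sprintf("  dose range [%.3f, %.3f] cGy\n", min(x), max(x)))
  invisible(x)
}
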