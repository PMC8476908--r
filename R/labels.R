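#' Couch-shift error vectors
#'
#' An error vector is the 3D translational set-up error of the patient,
#' expressed in millimetres along the three patient axes: left-right (LR),
#' superior-inferior (SI) and anterior-posterior (AP).
#'
#' @param lr_mm,si_mm,ap_mm shift along the LR / SI / AP patient axis, in mm.
#' @return An object of class `error_vector`: a named numeric vector with
#'   elements `lr`, `si`, `ap`.
#' @examples
#' error_vector(4, 0, 2)
#' @export
error_vector <- function(lr_mm = 0, si_mm = 0, ap_mm = 0) {
  stopifnot(is.numeric(lr_mm), is.numeric(si_mm), is.numeric(ap_mm),
            length(lr_mm) == 1, length(si_mm) == 1, length(ap_mm) == 1,
            is.finite(lr_mm), is.finite(si_mm), is.finite(ap_mm))
  structure(c(lr = as.numeric(lr_mm), si = as.numeric(si_mm),
              ap = as.numeric(ap_mm)),
            class = "error_vector")
}

#' @export
format.error_vector <- function(x, ...) {
  sprintf("<error_vector LR=%g SI=%g AP=%g mm; isocenter=%.2f mm>",
          x[["lr"]], x[["si"]], x[["ap"]], isocenter_error(x))
}

#' @export
print.error_vector <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Isocenter error magnitude
#'
#' The isocenter error is the Euclidean norm of the 3D translational set-up
#' error, `sqrt(LR^2 + SI^2 + AP^2)`.
#'
#' @param e an [error_vector()], or a numeric vector of length 3 (LR, SI, AP).
#' @return Isocenter error in mm.
#' @examples
#' isocenter_error(error_vector(4, 0, 4)) # 5.66 mm
#' @export
isocenter_error <- function(e) {
  e <- as_error_vector(e)
  sqrt(sum(e^2))
}

as_error_vector <- function(e) {
  if (inherits(e, "error_vector")) return(e)
  if (is.numeric(e) && length(e) == 3) return(error_vector(e[[1]], e[[2]], e[[3]]))
  stop("`e` must be an error_vector or a numeric vector (lr, si, ap)",
       call. = FALSE)
}

#' Classification labels for a position error
#'
#' Maps a 3D couch-shift error vector to the three label families used for
#' shift classification:
#' \describe{
#'   \item{type 1}{binary: class 2 if the isocenter error exceeds 3 mm,
#'     class 1 otherwise.}
#'   \item{type 2}{three binary labels (LR, SI, AP): class 2 if that axis'
#'     shift exceeds 3 mm.}
#'   \item{type 3}{eight-way joint label encoding *which* axes exceed 3 mm:
#'     1 = none, 2 = LR only, 3 = AP only, 4 = SI only, 5 = LR+AP,
#'     6 = LR+SI, 7 = SI+AP, 8 = all three.}
#' }
#' The 3 mm boundary is exclusive: an isocenter error of exactly 3.00 mm is
#' class 1 (a (2,2,2) mm shift, isocenter 3.46 mm, is the smallest class-2
#' combination on the 0/2/4 mm design grid).
#'
#' @param e an [error_vector()] or numeric length-3 vector (LR, SI, AP) in mm.
#' @param threshold_mm decision boundary in mm (default 3, exclusive).
#' @return A one-row tibble with columns `lr_mm`, `si_mm`, `ap_mm`,
#'   `isocenter_mm`, `type1`, `type2_lr`, `type2_si`, `type2_ap`, `type3`.
#' @examples
#' assign_labels(error_vector(2, 2, 2)) # isocenter 3.46 -> type1 = 2, type3 = 1
#' @export
assign_labels <- function(e, threshold_mm = 3) {
  e <- as_error_vector(e)
  iso <- isocenter_error(e)
  over <- abs(e) > threshold_mm # lr, si, ap
  tibble::tibble(
    lr_mm = e[["lr"]], si_mm = e[["si"]], ap_mm = e[["ap"]],
    isocenter_mm = iso,
    type1 = if (iso > threshold_mm) 2L else 1L,
    type2_lr = if (over[["lr"]]) 2L else 1L,
    type2_si = if (over[["si"]]) 2L else 1L,
    type2_ap = if (over[["ap"]]) 2L else 1L,
    type3 = type3_class(over[["lr"]], over[["si"]], over[["ap"]])
  )
}

# 8-way encoding of which axes exceed the boundary; numbering follows the
# study design table: 1 none, 2 LR, 3 AP, 4 SI, 5 LR+AP, 6 LR+SI, 7 SI+AP,
# 8 LR+SI+AP.
type3_class <- function(lr_over, si_over, ap_over) {
  key <- paste0(as.integer(lr_over), as.integer(si_over), as.integer(ap_over))
  code <- c(`000` = 1L, `100` = 2L, `001` = 3L, `010` = 4L,
            `101` = 5L, `110` = 6L, `011` = 7L, `111` = 8L)
  unname(code[[key]])
}

# Inverse of type3_class: per-axis over-threshold flags for a type-3 class.
type3_flags <- function(class3) {
  stopifnot(class3 %in% 1:8)
  flags <- rbind(`1` = c(FALSE, FALSE, FALSE), `2` = c(TRUE, FALSE, FALSE),
                 `3` = c(FALSE, FALSE, TRUE),  `4` = c(FALSE, TRUE, FALSE),
                 `5` = c(TRUE, FALSE, TRUE),   `6` = c(TRUE, TRUE, FALSE),
                 `7` = c(FALSE, TRUE, TRUE),   `8` = c(TRUE, TRUE, TRUE))
  stats::setNames(flags[as.character(class3), ], c("lr", "si", "ap"))
}

# The 27 error positions of the 0/2/4 mm design, in study serial order
# (serials 2..28): the no-error re-measurement, single-axis shifts, paired
# shifts, then triple shifts.
design_error_grid <- function() {
  m <- matrix(c(
    0, 0, 0,
    2, 0, 0,  4, 0, 0,  0, 2, 0,  0, 4, 0,  0, 0, 2,  0, 0, 4,
    2, 0, 4,  4, 0, 4,  4, 0, 2,  2, 0, 2,
    2, 2, 0,  2, 4, 0,  4, 4, 0,  4, 2, 0,
    0, 2, 2,  0, 2, 4,  0, 4, 4,  0, 4, 2,
    2, 2, 2,  2, 2, 4,  2, 4, 4,  2, 4, 2,
    4, 4, 2,  4, 2, 2,  4, 2, 4,  4, 4, 4
  ), ncol = 3, byrow = TRUE)
  colnames(m) <- c("lr", "si", "ap")
  m
}

#' The 27-position error-design label table
#'
#' Enumerates every combination of 0/2/4 mm shifts along LR, SI and AP (the
#' 27 simulated error positions) together with the isocenter error and all
#' classification labels. Serial numbers start at 2; serial 1 is reserved for
#' the baseline acquisition, which carries no labels.
#'
#' @return A 27-row tibble with columns `serial`, `lr_mm`, `si_mm`, `ap_mm`,
#'   `isocenter_mm` (rounded to 2 decimals), `type1`, `type2_lr`, `type2_si`,
#'   `type2_ap`, `type3`.
#' @examples
#' build_label_table()
#' @export
build_label_table <- function() {
  grid <- design_error_grid()
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    assign_labels(error_vector(grid[i, "lr"], grid[i, "si"], grid[i, "ap"]))
  })
  out <- dplyr::bind_rows(rows)
  out$isocenter_mm <- round(out$isocenter_mm, 2)
  dplyr::bind_cols(tibble::tibble(serial = seq_len(nrow(out)) + 1L), out)
}
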