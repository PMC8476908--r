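#' SSIM configuration
#'
#' Parameters of the local structural-similarity decomposition. Local moments
#' are computed over a uniform (unweighted) square sliding window. The
#' stabilising constants follow the standard SSIM parameterisation
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, `C3 = C2 / 2`, with the dynamic range
#' `L` set to the fraction dose so that the dose images need no rescaling.
#'
#' @param window odd window side length in pixels (default 11).
#' @param K1,K2 small stabilising fractions (defaults 0.01 and 0.03).
#' @param L dynamic range of the images; defaults to 200, the fraction dose
#'   in cGy.
#' @param alpha,beta,gamma exponents weighting the luminance, contrast and
#'   structure terms in the combined SSIM product (default 1 each).
#' @param padding `"reflect"` (default) mirrors the image at its borders so
#'   every pixel has a full window; `"valid"` restricts the output to pixels
#'   whose window lies fully inside and fills the border with `NA`.
#' @return An object of class `ssim_config` with derived constants
#'   `C1`, `C2`, `C3`.
#' @export
ssim_config <- function(window = 11L, K1 = 0.01, K2 = 0.03, L = 200,
                        alpha = 1, beta = 1, gamma = 1,
                        padding = c("reflect", "valid")) {
  window <- as.integer(window)
  padding <- match.arg(padding)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3", call. = FALSE)
  stopifnot(K1 > 0, K2 > 0, L > 0)
  C2 <- (K2 * L)^2
  structure(list(window = window, K1 = K1, K2 = K2, L = L,
                 alpha = alpha, beta = beta, gamma = gamma,
                 C1 = (K1 * L)^2, C2 = C2, C3 = C2 / 2,
                 padding = padding),
            class = "ssim_config")
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop(sprintf("map shapes differ: %s vs %s",
                 paste(dim(x), collapse = "x"),
                 paste(dim(y), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Dose-difference map
#'
#' Pointwise absolute dose difference `|V_x - V_y|` between a baseline
#' fluence map and a perturbed one. Symmetric in its arguments.
#'
#' @param baseline,errored fluence maps (or plain matrices) of equal shape.
#' @return A numeric matrix of absolute dose differences (same units as the
#'   inputs, cGy for dose maps).
#' @examples
#' dd_map(matrix(100, 2, 2), matrix(98, 2, 2))
#' @export
dd_map <- function(baseline, errored) {
  x <- map_pixels(as_fluence_map(baseline))
  y <- map_pixels(as_fluence_map(errored))
  check_same_shape(x, y)
  abs(x - y)
}

# Mirror the matrix at its borders by k pixels (half-sample symmetric
# reflection: the edge row/column is repeated).
pad_reflect <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(k < h, k < w)
  ri <- c(k:1, 1:h, h:(h - k + 1))
  ci <- c(k:1, 1:w, w:(w - k + 1))
  m[ri, ci]
}

# Uniform box-window local mean via an integral image on the padded matrix.
box_mean <- function(m, window) {
  k <- (window - 1L) %/% 2L
  p <- pad_reflect(m, k)
  # summed-area table with a zero first row/column
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  h <- nrow(m); w <- ncol(m)
  i1 <- 1L:h; i2 <- i1 + window - 1L
  j1 <- 1L:w; j2 <- j1 + window - 1L
  (s[i2 + 1L, j2 + 1L] - s[i1, j2 + 1L] - s[i2 + 1L, j1] + s[i1, j1]) /
    (window * window)
}

#' Local window moments of an image pair
#'
#' Sliding-window means, standard deviations and covariance of two images
#' over a uniform square window, with mirror padding at the borders (the
#' population form: variances are divided by the window pixel count).
#'
#' @param x,y fluence maps or matrices of equal shape.
#' @param cfg an [ssim_config()].
#' @return A list of matrices `mu_x`, `mu_y`, `sd_x`, `sd_y`, `cov_xy`.
#' @export
local_moments <- function(x, y, cfg = ssim_config()) {
  x <- map_pixels(as_fluence_map(x)); y <- map_pixels(as_fluence_map(y))
  check_same_shape(x, y)
  if (cfg$window > min(dim(x)))
    stop("SSIM window larger than the image", call. = FALSE)
  mu_x <- box_mean(x, cfg$window)
  mu_y <- box_mean(y, cfg$window)
  var_x <- pmax(box_mean(x * x, cfg$window) - mu_x^2, 0)
  var_y <- pmax(box_mean(y * y, cfg$window) - mu_y^2, 0)
  cov_xy <- box_mean(x * y, cfg$window) - mu_x * mu_y
  out <- list(mu_x = mu_x, mu_y = mu_y,
              sd_x = sqrt(var_x), sd_y = sqrt(var_y), cov_xy = cov_xy)
  if (cfg$padding == "valid") {
    k <- (cfg$window - 1L) %/% 2L
    mask_border <- function(m) {
      m[c(seq_len(k), nrow(m) - seq_len(k) + 1L), ] <- NA_real_
      m[, c(seq_len(k), ncol(m) - seq_len(k) + 1L)] <- NA_real_
      m
    }
    out <- lapply(out, mask_border)
  }
  out
}

#' DD and SSIM component maps for a baseline / error pair
#'
#' Computes the five comparison maps quantifying how a perturbed fluence map
#' deviates from its baseline: the absolute dose-difference (DD) map and the
#' luminance, contrast, structure and combined SSIM maps,
#' \deqn{l = \frac{2\mu_x\mu_y + C_1}{\mu_x^2+\mu_y^2+C_1},\quad
#'       c = \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2+\sigma_y^2+C_2},\quad
#'       s = \frac{\sigma_{xy} + C_3}{\sigma_x\sigma_y + C_3},}
#' with the combined map \eqn{SSIM = l^\alpha c^\beta s^\gamma}. A map
#' compared with itself gives SSIM = 1 everywhere.
#'
#' @param x,y baseline and errored fluence maps (equal shape).
#' @param cfg an [ssim_config()].
#' @return An object of class `comparison_maps`: a list with matrices `dd`,
#'   `luminance`, `contrast`, `structure`, `ssim` and the `config` used.
#' @examples
#' m <- matrix(runif(64, 0, 200), 8, 8)
#' cm <- ssim_components(m, m, ssim_config(window = 3))
#' range(cm$ssim) # 1 1
#' @export
ssim_components <- function(x, y, cfg = ssim_config()) {
  xm <- map_pixels(as_fluence_map(x)); ym <- map_pixels(as_fluence_map(y))
  check_same_shape(xm, ym)
  mo <- local_moments(xm, ym, cfg)
  l <- (2 * mo$mu_x * mo$mu_y + cfg$C1) / (mo$mu_x^2 + mo$mu_y^2 + cfg$C1)
  cc <- (2 * mo$sd_x * mo$sd_y + cfg$C2) / (mo$sd_x^2 + mo$sd_y^2 + cfg$C2)
  s <- (mo$cov_xy + cfg$C3) / (mo$sd_x * mo$sd_y + cfg$C3)
  ssim <- l^cfg$alpha * cc^cfg$beta * s^cfg$gamma
  structure(list(dd = abs(xm - ym), luminance = l, contrast = cc,
                 structure = s, ssim = ssim, config = cfg),
            class = "comparison_maps")
}

#' @export
print.comparison_maps <- function(x, ...) {
  cat(sprintf("<comparison_maps %dx%d px>\n", nrow(x$dd), ncol(x$dd)))
  cat(sprintf("  mean DD %.4f cGy, max DD %.4f cGy, mean SSIM %.6f\n",
              mean(x$dd), max(x$dd), mean(x$ssim, na.rm = TRUE)))
  invisible(x)
}

#' Summaries of a comparison-map set
#'
#' @param x a `comparison_maps` object.
#' @param ... unused.
#' @return A one-row tibble with mean/max DD and the mean of each SSIM
#'   component map.
#' @export
glance.comparison_maps <- function(x, ...) {
  tibble::tibble(
    mean_dd = mean(x$dd), max_dd = max(x$dd),
    mean_luminance = mean(x$luminance, na.rm = TRUE),
    mean_contrast = mean(x$contrast, na.rm = TRUE),
    mean_structure = mean(x$structure, na.rm = TRUE),
    mean_ssim = mean(x$ssim, na.rm = TRUE)
  )
}
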