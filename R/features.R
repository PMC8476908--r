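# Radiomics feature extraction: 94 features per map (19 first-order plus
# five gray-level texture families), IBSI-aligned formulas. Texture matrices
# are built in compiled code; the feature formulas live here.

#' Gray-level discretization configuration
#'
#' Texture families operate on a discretized image. Two schemes are
#' supported: a fixed bin width anchored at the map minimum (level =
#' `floor((x - min) / width) + 1`), which preserves absolute contrast, and a
#' fixed bin count spanning the observed range, which is scale-free.
#'
#' @param method `"width"` or `"count"`.
#' @param bin_width bin width in map units (used for `"width"`; default 25).
#' @param bin_count number of bins (used for `"count"`; default 32).
#' @return A `disc_config` object.
#' @export
disc_config <- function(method = c("width", "count"), bin_width = 25,
                        bin_count = 32L) {
  method <- match.arg(method)
  stopifnot(bin_width > 0, bin_count >= 2)
  structure(list(method = method, bin_width = bin_width,
                 bin_count = as.integer(bin_count)),
            class = "disc_config")
}

# Discretize a numeric matrix to integer levels 1..ng.
discretize_map <- function(m, cfg = disc_config()) {
  if (!all(is.finite(m))) stop("map contains non-finite values", call. = FALSE)
  rng <- range(m)
  if (rng[1] == rng[2]) {
    lv <- matrix(1L, nrow(m), ncol(m))
  } else if (cfg$method == "width") {
    lv <- matrix(as.integer(floor((m - rng[1]) / cfg$bin_width)) + 1L,
                 nrow(m), ncol(m))
  } else {
    wdt <- (rng[2] - rng[1]) / cfg$bin_count
    lv <- matrix(pmin(as.integer(floor((m - rng[1]) / wdt)) + 1L,
                      cfg$bin_count), nrow(m), ncol(m))
  }
  lv
}

#' Centered square crop of a map
#'
#' Extracts the centered `side` x `side` submatrix; when the residual margin
#' is odd the extra row/column is left at the bottom/right (the crop starts
#' at offset `floor((H - side) / 2)`).
#'
#' @param map a matrix (or fluence map) at least `side` pixels in each
#'   dimension.
#' @param side crop side length in pixels (default 512).
#' @return The cropped matrix.
#' @examples
#' dim(center_crop(matrix(0, 600, 600), 512)) # 512 512
#' @export
center_crop <- function(map, side = 512L) {
  h <- nrow(map); w <- ncol(map)
  side <- as.integer(side)
  if (h < side || w < side)
    stop(sprintf("map (%dx%d) smaller than crop side %d", h, w, side),
         call. = FALSE)
  ro <- (h - side) %/% 2L
  co <- (w - side) %/% 2L
  map[ro + seq_len(side), co + seq_len(side), drop = FALSE]
}

log2p <- function(p) ifelse(p > 0, log2(p), 0)

firstorder_features <- function(x, levels, pixel_mm2 = 1) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  robust <- x[x >= q[1] & x <= q[5]]
  p <- tabulate(levels) / n
  c(Energy = sum(x^2),
    TotalEnergy = pixel_mm2 * sum(x^2),
    Entropy = -sum(p * log2p(p)),
    Minimum = min(x),
    P10 = q[1], P90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Features of one normalized symmetric co-occurrence matrix.
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  autoc <- sum(i * j * P)
  diff_avg <- sum(k_diff * p_diff)
  hxy <- -sum(P * log2p(P))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2p(pxy))
  hxy2 <- -sum(pxy * log2p(pxy))
  hx <- -sum(px * log2p(px)); hy <- -sum(py * log2p(py))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sd_x * sd_y > 0) (autoc - mu_x * mu_y) / (sd_x * sd_y) else 1
  # maximal correlation coefficient: sqrt of the 2nd largest eigenvalue of Q
  mcc <- if (ng > 1) {
    Q <- matrix(0, ng, ng)
    for (ii in which(px > 0))
      for (jj in which(px > 0))
        Q[ii, jj] <- sum(P[ii, py > 0] * P[jj, py > 0] /
                           (px[ii] * py[py > 0]))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) > 1) sqrt(pmax(ev[2], 0)) else 1
  } else 1
  c(Autocorrelation = autoc,
    JointAverage = mu_x,
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * P),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * P),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = diff_avg,
    DifferenceEntropy = -sum(p_diff * log2p(p_diff)),
    DifferenceVariance = sum((k_diff - diff_avg)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1, Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum * log2p(p_sum)),
    SumSquares = sum((i - mu_x)^2 * P),
    MCC = mcc)
}

glcm_features <- function(levels, ng) {
  mats <- cpp_glcm(levels, ng)
  per_angle <- lapply(1:4, function(a) {
    P <- matrix(mats[, , a], ng, ng)
    glcm_features_one(P / sum(P))
  })
  Reduce(`+`, per_angle) / 4
}

# Run-length / size-zone style features share their functional forms; `mat`
# has gray level rows and size/length columns.
size_dist_features <- function(mat, n_pixels) {
  gl <- seq_len(nrow(mat)); sz <- seq_len(ncol(mat))
  ns <- sum(mat)
  i <- row(mat); r <- col(mat)
  pn <- mat / ns
  mu_g <- sum(i * pn); mu_s <- sum(r * pn)
  out <- c(
    small = sum(mat / outer(gl^0, sz^2)) / ns,
    large = sum(mat * outer(gl^0, sz^2)) / ns,
    GrayLevelNonUniformity = sum(rowSums(mat)^2) / ns,
    GrayLevelNonUniformityNormalized = sum(rowSums(mat)^2) / ns^2,
    SizeNonUniformity = sum(colSums(mat)^2) / ns,
    SizeNonUniformityNormalized = sum(colSums(mat)^2) / ns^2,
    Percentage = ns / n_pixels,
    GrayLevelVariance = sum((i - mu_g)^2 * pn),
    SizeVariance = sum((r - mu_s)^2 * pn),
    Entropy = -sum(pn * log2p(pn)),
    LowGrayLevelEmphasis = sum(mat / outer(gl^2, sz^0)) / ns,
    HighGrayLevelEmphasis = sum(mat * outer(gl^2, sz^0)) / ns,
    SmallLow = sum(mat / outer(gl^2, sz^2)) / ns,
    SmallHigh = sum(mat * outer(gl^2, 1 / sz^2)) / ns,
    LargeLow = sum(mat * outer(1 / gl^2, sz^2)) / ns,
    LargeHigh = sum(mat * outer(gl^2, sz^2)) / ns)
  out
}

glrlm_features <- function(levels, ng) {
  mats <- cpp_glrlm(levels, ng)
  np <- length(levels)
  per_dir <- lapply(1:4, function(a) {
    m <- matrix(mats[, , a], dim(mats)[1], dim(mats)[2])
    f <- size_dist_features(m, np)
    names(f) <- c("ShortRunEmphasis", "LongRunEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                  "RunPercentage", "GrayLevelVariance", "RunVariance",
                  "RunEntropy", "LowGrayLevelRunEmphasis",
                  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                  "ShortRunHighGrayLevelEmphasis",
                  "LongRunLowGrayLevelEmphasis",
                  "LongRunHighGrayLevelEmphasis")
    f
  })
  Reduce(`+`, per_dir) / 4
}

glszm_features <- function(levels, ng) {
  m <- cpp_glszm(levels, ng)$matrix
  f <- size_dist_features(m, length(levels))
  names(f) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                "SmallAreaHighGrayLevelEmphasis",
                "LargeAreaLowGrayLevelEmphasis",
                "LargeAreaHighGrayLevelEmphasis")
  f
}

gldm_features <- function(levels, ng, alpha = 0L) {
  mat <- cpp_gldm(levels, ng, alpha)
  gl <- seq_len(nrow(mat)); dp <- seq_len(ncol(mat))
  nz <- sum(mat)
  i <- row(mat); j <- col(mat)
  pn <- mat / nz
  mu_g <- sum(i * pn); mu_d <- sum(j * pn)
  c(SmallDependenceEmphasis = sum(mat / outer(gl^0, dp^2)) / nz,
    LargeDependenceEmphasis = sum(mat * outer(gl^0, dp^2)) / nz,
    GrayLevelNonUniformity = sum(rowSums(mat)^2) / nz,
    DependenceNonUniformity = sum(colSums(mat)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(mat)^2) / nz^2,
    GrayLevelVariance = sum((i - mu_g)^2 * pn),
    DependenceVariance = sum((j - mu_d)^2 * pn),
    DependenceEntropy = -sum(pn * log2p(pn)),
    LowGrayLevelEmphasis = sum(mat / outer(gl^2, dp^0)) / nz,
    HighGrayLevelEmphasis = sum(mat * outer(gl^2, dp^0)) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(mat / outer(gl^2, dp^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(mat * outer(gl^2, 1 / dp^2)) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(mat * outer(1 / gl^2, dp^2)) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(mat * outer(gl^2, dp^2)) / nz)
}

ngtdm_features <- function(levels, ng) {
  m <- cpp_ngtdm(levels, ng)
  np <- sum(m[, 1])
  p <- m[, 1] / np
  s <- m[, 2]
  act <- p > 0
  gl <- seq_len(ng)
  ngp <- sum(act)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(gl[act], gl[act], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / np
  } else 0
  ipi <- gl[act] * p[act]
  busy_den <- sum(abs(outer(ipi, ipi, `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  pa <- p[act]; sa <- s[act]; ga <- gl[act]
  complexity <- sum(abs(outer(ga, ga, `-`)) *
                      (outer(pa * sa, pa * sa, `+`) /
                         outer(pa, pa, `+`))) / np
  strength <- if (sum(s) > 0)
    sum(outer(pa, pa, `+`) * outer(ga, ga, `-`)^2) / sum(s) else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Extract the 94-feature radiomics vector of a map
#'
#' Computes 19 first-order features on the raw map values plus five texture
#' families on the discretized map: gray level co-occurrence (GLCM, 24
#' features; 4 in-plane directions at distance 1, features averaged over
#' directions), gray level dependence (GLDM, 14), gray level run length
#' (GLRLM, 16; direction-averaged), gray level size zone (GLSZM, 16;
#' 8-connected zones) and neighbouring gray tone difference (NGTDM, 5) —
#' 94 features in total. Shape features are omitted by construction (the
#' map support never changes). Constant maps yield the defined degenerate
#' values (zero variance/contrast), never `NaN`.
#'
#' @param map numeric matrix (typically a cropped comparison map).
#' @param cfg a [disc_config()].
#' @param pixel_mm2 pixel area in mm^2 used by the TotalEnergy feature
#'   (default 1).
#' @return Named numeric vector of length 94; names are
#'   `<family>_<Feature>`.
#' @export
extract_features <- function(map, cfg = disc_config(), pixel_mm2 = 1) {
  m <- map_pixels(as_fluence_map_any(map))
  if (!all(is.finite(m))) stop("map contains non-finite values", call. = FALSE)
  lv <- discretize_map(m, cfg)
  ng <- max(lv)
  out <- c(
    prefix_names(firstorder_features(as.vector(m), as.vector(lv), pixel_mm2),
                 "firstorder"),
    prefix_names(glcm_features(lv, ng), "glcm"),
    prefix_names(gldm_features(lv, ng), "gldm"),
    prefix_names(glrlm_features(lv, ng), "glrlm"),
    prefix_names(glszm_features(lv, ng), "glszm"),
    prefix_names(ngtdm_features(lv, ng), "ngtdm"))
  stopifnot(length(out) == 94, !anyNA(out), all(is.finite(out)))
  out
}

prefix_names <- function(x, prefix) {
  names(x) <- paste0(prefix, "_", names(x))
  x
}

# comparison-map matrices may be plain matrices that can contain values < 0
# (structure maps), so bypass the fluence-map non-negativity check
as_fluence_map_any <- function(x) {
  if (is.matrix(x)) structure(x, class = c("fluence_map", "matrix", "array"))
  else as_fluence_map(x)
}

#' Assemble per-sample feature matrices for the ML configurations
#'
#' Computes comparison maps for every error record of a cohort against its
#' patient's baseline, extracts the 94 radiomics features from the centre
#' crop of each requested source map, and concatenates them per sample:
#' `"ml1"` uses the DD map (94 columns), `"ml2"` the luminance, contrast and
#' structure maps (282 columns), `"ml3"` all four (376 columns). DD-map
#' features use the fixed-bin-width discretization; SSIM component maps,
#' whose native range is \[-1, 1\], use the fixed-bin-count scheme.
#'
#' @param cohort a [generate_cohort()] tibble (with the `map` list-column).
#' @param ml_config `"ml1"`, `"ml2"` or `"ml3"`.
#' @param crop_side centre-crop side in pixels; defaults to 512 or to the
#'   largest available size for smaller simulated maps.
#' @param ssim_cfg an [ssim_config()].
#' @param dd_disc,ssim_disc [disc_config()]s for DD and SSIM-component maps.
#' @return A tibble: `patient_id`, `serial`, label columns, then one column
#'   per namespaced feature (`dd_`, `luminance_`, `contrast_`, `structure_`
#'   prefixes).
#' @export
build_feature_matrix <- function(cohort, ml_config = c("ml3", "ml1", "ml2"),
                                 crop_side = NULL,
                                 ssim_cfg = ssim_config(),
                                 dd_disc = disc_config("width", bin_width = 25),
                                 ssim_disc = disc_config("count", bin_count = 32)) {
  ml_config <- match.arg(ml_config)
  if (!"map" %in% names(cohort))
    stop("cohort must carry its `map` list-column", call. = FALSE)
  sources <- switch(ml_config,
                    ml1 = "dd",
                    ml2 = c("luminance", "contrast", "structure"),
                    ml3 = c("dd", "luminance", "contrast", "structure"))
  label_cols <- c("isocenter_mm", "type1", "type2_lr", "type2_si",
                  "type2_ap", "type3")

  rows <- lapply(split(seq_len(nrow(cohort)), cohort$patient_id), function(idx) {
    sub <- cohort[idx, ]
    base_i <- which(sub$role == "baseline")
    if (length(base_i) != 1)
      stop(sprintf("patient %s: expected exactly one baseline",
                   sub$patient_id[1]), call. = FALSE)
    base <- sub$map[[base_i]]
    err_i <- which(sub$role == "error")
    side <- if (is.null(crop_side)) min(512L, nrow(base)) else crop_side
    purrr::map(err_i, function(i) {
      if (is.null(sub$map[[i]]))
        stop(sprintf("missing map for patient %s serial %d",
                     sub$patient_id[1], sub$serial[i]), call. = FALSE)
      cm <- ssim_components(base, sub$map[[i]], ssim_cfg)
      feats <- unlist(lapply(sources, function(s) {
        dcfg <- if (s == "dd") dd_disc else ssim_disc
        prefix_names(extract_features(center_crop(cm[[s]], side), dcfg), s)
      }))
      dplyr::bind_cols(sub[i, c("patient_id", "serial", label_cols)],
                       tibble::as_tibble(as.list(feats)))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
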