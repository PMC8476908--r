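# DD and SSIM component maps.

test_that("dd_map is the pointwise absolute difference", {
  expect_equal(dd_map(matrix(5, 3, 3), matrix(5, 3, 3)), matrix(0, 3, 3))
  expect_equal(dd_map(matrix(100, 1, 1), matrix(98, 1, 1)),
               matrix(2, 1, 1))
  a <- matrix(1:9, 3, 3, byrow = TRUE)
  b <- matrix(9:1, 3, 3, byrow = TRUE)
  expect_equal(dd_map(a, b),
               matrix(c(8, 6, 4, 2, 0, 2, 4, 6, 8), 3, 3, byrow = TRUE))
  expect_equal(dd_map(a, b), dd_map(b, a))
})

test_that("shape mismatches are rejected", {
  expect_error(dd_map(matrix(0, 3, 3), matrix(0, 4, 4)), "shapes differ")
  expect_error(ssim_components(matrix(0, 12, 12), matrix(0, 13, 13)),
               "shapes differ")
  expect_error(local_moments(dose_matrix(8), dose_matrix(8),
                             ssim_config(window = 11)),
               "window larger")
})

test_that("ssim_config derives the stabilising constants", {
  cfg <- ssim_config()
  expect_equal(cfg$window, 11L)
  expect_equal(cfg$C1, (0.01 * 200)^2)
  expect_equal(cfg$C2, (0.03 * 200)^2)
  expect_identical(cfg$C3, cfg$C2 / 2)
  expect_error(ssim_config(window = 4), "odd")
})

test_that("local moments match direct summation", {
  # constant image: mean c, zero spread
  mo <- local_moments(matrix(7, 15, 15), matrix(7, 15, 15))
  expect_equal(mo$mu_x, matrix(7, 15, 15))
  expect_equal(mo$sd_x, matrix(0, 15, 15))

  # y = x: covariance equals the variance
  x <- dose_matrix(20, seed = 3)
  mo <- local_moments(x, x)
  expect_equal(mo$cov_xy, mo$sd_x^2, tolerance = 1e-12)
  expect_true(all(mo$sd_x >= 0))

  # 11x11 patch, window 11: the centre window is exactly the patch
  p <- dose_matrix(11, seed = 4)
  q <- dose_matrix(11, seed = 5)
  mo <- local_moments(p, q, ssim_config(window = 11))
  expect_equal(mo$mu_x[6, 6], mean(p))
  expect_equal(mo$mu_y[6, 6], mean(q))
  expect_equal(mo$sd_x[6, 6], sqrt(mean((p - mean(p))^2)))
  expect_equal(mo$cov_xy[6, 6], mean((p - mean(p)) * (q - mean(q))))
})

test_that("a map compared with itself has SSIM 1 everywhere", {
  x <- dose_matrix(32, seed = 7)
  cm <- ssim_components(x, x)
  expect_equal(cm$ssim, matrix(1, 32, 32), tolerance = 1e-12)
  expect_equal(cm$dd, matrix(0, 32, 32))
})

test_that("luminance of constant regions matches the closed form", {
  # mu_x = 100, mu_y = 50, C1 = 4: l = 10004/12504
  cm <- ssim_components(matrix(100, 15, 15), matrix(50, 15, 15))
  expect_equal(cm$luminance, matrix(10004 / 12504, 15, 15))
  expect_equal(cm$luminance[1, 1], 0.80006, tolerance = 1e-5)
})

test_that("equal local spread gives a contrast map of ones", {
  x <- dose_matrix(16, seed = 8)
  cm <- ssim_components(x, x + 5) # shift preserves all spreads
  expect_equal(cm$contrast, matrix(1, 16, 16), tolerance = 1e-12)
  expect_true(all(cm$luminance < 1))
})

test_that("components are symmetric and bounded", {
  x <- dose_matrix(24, seed = 10)
  y <- dose_matrix(24, seed = 11)
  a <- ssim_components(x, y)
  b <- ssim_components(y, x)
  expect_equal(a$dd, b$dd)
  expect_equal(a$luminance, b$luminance, tolerance = 1e-12)
  expect_equal(a$contrast, b$contrast, tolerance = 1e-12)
  expect_equal(a$structure, b$structure, tolerance = 1e-12)
  expect_true(all(a$luminance > 0 & a$luminance <= 1 + 1e-12))
  expect_true(all(a$contrast > 0 & a$contrast <= 1 + 1e-12))
  expect_true(all(abs(a$structure) <= 1 + 1e-9))
  expect_true(all(abs(a$ssim) <= 1 + 1e-9))
})

test_that("maps agree with the naive double-loop oracle", {
  for (case in list(list(n = 16, window = 5, seed = 1),
                    list(n = 32, window = 11, seed = 2),
                    list(n = 21, window = 7, seed = 3))) {
    cfg <- ssim_config(window = case$window)
    x <- dose_matrix(case$n, seed = case$seed)
    y <- pmax(x + dose_matrix(case$n, seed = case$seed + 100) / 10 - 10, 0)
    got <- ssim_components(x, y, cfg)
    want <- naive_ssim(x, y, cfg)
    for (nm in c("dd", "luminance", "contrast", "structure", "ssim"))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                   info = sprintf("%s n=%d w=%d", nm, case$n, case$window))
  }
})

test_that("valid-only padding masks the border", {
  x <- dose_matrix(16, seed = 12)
  mo <- local_moments(x, x, ssim_config(window = 5, padding = "valid"))
  expect_true(all(is.na(mo$mu_x[1:2, ])))
  expect_true(all(is.na(mo$mu_x[, 15:16])))
  expect_false(anyNA(mo$mu_x[3:14, 3:14]))
})
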