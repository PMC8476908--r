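# Synthetic fluence-map generator.

test_that("phantoms are deterministic in the seed and vary across seeds", {
  cfg <- reduced_config(size = 48)
  p1 <- generate_phantom(11, cfg)
  p2 <- generate_phantom(11, cfg)
  expect_identical(p1, p2)
  p3 <- generate_phantom(12, cfg)
  h1 <- p1$objects[p1$objects$kind == "het", c("cx", "cy", "cz")]
  h3 <- p3$objects[p3$objects$kind == "het", c("cx", "cy", "cz")]
  expect_false(isTRUE(all.equal(h1, h3)))
  expect_gte(nrow(h1), 3)
})

test_that("the rasterised attenuation grid is non-negative", {
  g <- phantom_grid(generate_phantom(5, reduced_config(size = 48)),
                    voxel_mm = 4)
  expect_true(min(g) >= 0)
  expect_true(max(g) > 0)
})

test_that("the plan is two partial arcs between 240 and 120 degrees", {
  pl <- plan_model(3, simulation_config())
  expect_equal(nrow(pl$arcs), 2)
  expect_equal(pl$arcs$start_deg, c(240, 120))
  expect_equal(pl$arcs$stop_deg, c(120, 240))
  expect_equal(pl$arcs$sense, c("cw", "ccw"))
  ang <- epidshift:::arc_angles(240, 120, "cw", 5)
  expect_equal(ang[1], 240)
  expect_equal(ang[length(ang)], 120)
  # the arc passes through 0, never through the 120..240 dead sector
  expect_false(any(ang > 120 & ang < 240))
})

test_that("zero shift with identical seeds reproduces the baseline exactly", {
  cfg <- reduced_config(size = 48, noise_sigma_frac = 0.005)
  ph <- generate_phantom(21, cfg)
  pl <- plan_model(21, cfg)
  base <- simulate_fluence(ph, pl, error_vector(), cfg, noise_seed = 9)
  again <- simulate_fluence(ph, pl, error_vector(0, 0, 0), cfg,
                            noise_seed = 9)
  expect_identical(map_pixels(base), map_pixels(again))
  expect_true(min(base) >= 0)
})

test_that("an SI shift displaces the integrated image coherently", {
  cfg <- simulation_config(image_size = 600L, noise_sigma_frac = 0)
  ph <- generate_phantom(42, cfg)
  pl <- plan_model(42, cfg)
  base <- map_pixels(simulate_fluence(ph, pl, error_vector(), cfg, 1))
  si4 <- map_pixels(simulate_fluence(ph, pl, error_vector(0, 4, 0), cfg, 1))
  lags <- -20:20
  # brute-force normalised cross-correlation over integer row (SI) lags
  xc <- vapply(lags, function(lag) {
    i <- seq_len(600)
    j <- i + lag
    ok <- j >= 1 & j <= 600
    stats::cor(as.vector(base[i[ok], ]), as.vector(si4[j[ok], ]))
  }, numeric(1))
  peak <- lags[which.max(xc)]
  expect_lt(abs(peak - 4 / 0.336), 1) # 11.90 px: peak at 11 or 12
  # no coherent displacement along the in-plane (column) axis
  xc_col <- vapply(lags, function(lag) {
    j <- seq_len(600)
    k <- j + lag
    ok <- k >= 1 & k <= 600
    stats::cor(as.vector(base[, j[ok]]), as.vector(si4[, k[ok]]))
  }, numeric(1))
  expect_equal(lags[which.max(xc_col)], 0)
})

test_that("mean absolute DD grows with shift size and SI dominates LR", {
  cfg <- reduced_config(size = 96, noise_sigma_frac = 0)
  mean_dd <- function(seed, e) {
    ph <- generate_phantom(seed, cfg)
    pl <- plan_model(seed, cfg)
    b <- map_pixels(simulate_fluence(ph, pl, error_vector(), cfg, 1))
    m <- map_pixels(simulate_fluence(ph, pl, e, cfg, 1))
    mean(abs(b - m))
  }
  # monotone in the shift magnitude, zero noise
  si <- vapply(c(0, 2, 4), function(s) mean_dd(31, error_vector(0, s, 0)),
               numeric(1))
  expect_true(all(diff(si) >= 0))
  lr <- vapply(c(0, 2, 4), function(s) mean_dd(31, error_vector(s, 0, 0)),
               numeric(1))
  expect_true(all(diff(lr) >= 0))

  # directional asymmetry averaged over 5 patients
  seeds <- 101:105
  si4 <- vapply(seeds, function(s) mean_dd(s, error_vector(0, 4, 0)),
                numeric(1))
  lr4 <- vapply(seeds, function(s) mean_dd(s, error_vector(4, 0, 0)),
                numeric(1))
  expect_gt(mean(si4), mean(lr4))
})

test_that("shifts that push the phantom out of view are rejected", {
  cfg <- reduced_config(size = 64, noise_sigma_frac = 0)
  ph <- generate_phantom(2, cfg)
  pl <- plan_model(2, cfg)
  expect_error(simulate_fluence(ph, pl, error_vector(0, 500, 0), cfg, 1),
               "field of view")
})

test_that("cohorts have 28 labelled maps per patient and are reproducible", {
  co <- tiny_cohort(n_patients = 2, size = 48)
  expect_equal(nrow(co), 56)
  expect_equal(as.integer(table(co$patient_id)), c(28L, 28L))
  per_pat <- dplyr::count(co[co$role == "error", ], patient_id)
  expect_equal(per_pat$n, c(27L, 27L))
  expect_equal(sum(co$role == "baseline"), 2)

  # labels on the error records match the design table
  tbl <- build_label_table()
  err <- co[co$role == "error" & co$patient_id == co$patient_id[1], ]
  expect_equal(err$type3, tbl$type3)
  expect_equal(err$isocenter_mm, tbl$isocenter_mm)
  # baseline carries no labels
  expect_true(all(is.na(co$type1[co$role == "baseline"])))

  # bit-exact reproducibility from the master seed
  cfg <- reduced_config(size = 48, n_patients = 1, master_seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(lapply(c1$map, map_pixels), lapply(c2$map, map_pixels))

  # the repeat no-error acquisition differs from the baseline only by noise
  noisy <- tiny_cohort(n_patients = 2, size = 48) # default noise
  b <- map_pixels(noisy$map[[1]])
  r <- map_pixels(noisy$map[[2]])
  expect_false(identical(b, r))
  expect_lt(mean(abs(b - r)), 5 * 0.005 * 200)
})
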