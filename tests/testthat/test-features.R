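# Radiomics feature extraction.

test_that("center_crop uses the floor-offset convention", {
  m <- matrix(seq_len(1190 * 1190), 1190, 1190)
  cr <- center_crop(m, 512)
  expect_equal(dim(cr), c(512, 512))
  expect_equal(cr[1, 1], m[340, 340]) # offset floor((1190-512)/2) = 339
  expect_equal(cr[512, 512], m[851, 851])

  expect_identical(center_crop(m[1:512, 1:512], 512), m[1:512, 1:512])

  m600 <- matrix(seq_len(600 * 600), 600, 600)
  expect_equal(center_crop(m600, 512)[1, 1], m600[45, 45]) # offset 44

  expect_error(center_crop(matrix(0, 100, 100), 512), "smaller")
})

test_that("the feature vector has the published census", {
  f <- extract_features(dose_matrix(32, seed = 1))
  expect_length(f, 94)
  expect_false(any(duplicated(names(f))))
  expect_true(all(is.finite(f)))
  fam <- table(sub("_.*", "", names(f)))
  expect_equal(fam[["firstorder"]], 19)
  expect_equal(fam[["glcm"]], 24)
  expect_equal(fam[["gldm"]], 14)
  expect_equal(fam[["glrlm"]], 16)
  expect_equal(fam[["glszm"]], 16)
  expect_equal(fam[["ngtdm"]], 5)
  expect_false(any(grepl("shape", names(f), ignore.case = TRUE)))
})

test_that("constant maps take defined degenerate values, never NaN", {
  f <- extract_features(matrix(42, 16, 16))
  expect_true(all(is.finite(f)))
  expect_equal(f[["firstorder_Variance"]], 0)
  expect_equal(f[["glcm_Contrast"]], 0)
  expect_equal(f[["firstorder_Entropy"]], 0)
  expect_equal(f[["firstorder_Uniformity"]], 1)
})

test_that("checkerboard features match brute-force enumeration", {
  # 4x4 two-level checkerboard, values 0 / 30 (bin width 25 -> levels 1, 2)
  m <- 30 * (outer(1:4, 1:4, `+`) %% 2)
  f <- extract_features(m)

  # first-order entropy by direct value counting: two equiprobable levels
  expect_equal(f[["firstorder_Entropy"]], 1)

  # GLCM contrast by exhaustive pair counting: every horizontal and
  # vertical neighbour pair differs by one level, every diagonal and
  # anti-diagonal pair is equal
  lv <- (m > 15) + 1
  contrasts <- vapply(1:4, function(a) {
    P <- oracle_glcm(lv, 2)[, , a]
    P <- P / sum(P)
    sum((row(P) - col(P))^2 * P)
  }, numeric(1))
  expect_equal(f[["glcm_Contrast"]], mean(contrasts))
  expect_equal(f[["glcm_Contrast"]], 0.5) # (1 + 0 + 1 + 0) / 4
})

test_that("texture matrices equal the nested-loop oracles", {
  for (seed in 1:4) {
    lv <- withr::with_seed(seed, matrix(sample(1:4, 64, replace = TRUE), 8, 8))
    ng <- 4L
    expect_equal(as.vector(epidshift:::cpp_glcm(lv, ng)),
                 as.vector(oracle_glcm(lv, ng)))
    expect_equal(as.vector(epidshift:::cpp_glrlm(lv, ng)),
                 as.vector(oracle_glrlm(lv, ng)))
    expect_equal(unname(epidshift:::cpp_glszm(lv, ng)$matrix),
                 unname(oracle_glszm(lv, ng)))
    expect_equal(unname(epidshift:::cpp_gldm(lv, ng, 0L)),
                 unname(oracle_gldm(lv, ng, 0)))
    expect_equal(unname(epidshift:::cpp_ngtdm(lv, ng)),
                 unname(oracle_ngtdm(lv, ng)), tolerance = 1e-12)
  }
})

test_that("texture features agree with formulas evaluated on oracle matrices", {
  lv <- withr::with_seed(9, matrix(sample(1:3, 49, replace = TRUE), 7, 7))
  m <- (lv - 1) * 25 # bin width 25 maps back to these levels
  f <- extract_features(m)

  # short-run emphasis from the oracle run-length matrices
  sre <- mean(vapply(1:4, function(a) {
    P <- oracle_glrlm(lv, 3)[, , a]
    sum(P / (col(P)^2)) / sum(P)
  }, numeric(1)))
  expect_equal(f[["glrlm_ShortRunEmphasis"]], sre, tolerance = 1e-9)

  # zone percentage from the oracle zone matrix
  zm <- oracle_glszm(lv, 3)
  expect_equal(f[["glszm_ZonePercentage"]], sum(zm) / 49, tolerance = 1e-9)

  # dependence entropy from the oracle dependence matrix
  dm <- oracle_gldm(lv, 3)
  pn <- dm / sum(dm)
  de <- -sum(pn[pn > 0] * log2(pn[pn > 0]))
  expect_equal(f[["gldm_DependenceEntropy"]], de, tolerance = 1e-9)

  # NGTDM coarseness straight from the n_i / s_i table
  nt <- oracle_ngtdm(lv, 3)
  coarse <- 1 / sum((nt[, 1] / 49) * nt[, 2])
  expect_equal(f[["ngtdm_Coarseness"]], coarse, tolerance = 1e-9)

  # GLCM joint entropy from the oracle co-occurrence matrices
  je <- mean(vapply(1:4, function(a) {
    P <- oracle_glcm(lv, 3)[, , a]
    P <- P / sum(P)
    -sum(P[P > 0] * log2(P[P > 0]))
  }, numeric(1)))
  expect_equal(f[["glcm_JointEntropy"]], je, tolerance = 1e-9)
})

test_that("difference-based GLCM features are shift invariant under
           min-anchored fixed-width binning", {
  m <- dose_matrix(16, seed = 21)
  f0 <- extract_features(m, disc_config("width", bin_width = 25))
  f1 <- extract_features(m + 300, disc_config("width", bin_width = 25))
  expect_equal(f1[["glcm_Contrast"]], f0[["glcm_Contrast"]])
  expect_equal(f1[["glcm_DifferenceEntropy"]], f0[["glcm_DifferenceEntropy"]])
})

test_that("feature matrices have the configuration-dependent shapes", {
  co <- tiny_cohort(n_patients = 2, size = 48)
  fm1 <- build_feature_matrix(co, "ml1")
  expect_equal(nrow(fm1), 2 * 27)
  expect_equal(sum(grepl("^dd_", names(fm1))), 94)
  expect_equal(ncol(fm1) - 8, 94) # 8 metadata columns

  fm2 <- build_feature_matrix(co, "ml2")
  expect_equal(ncol(fm2) - 8, 282)
  expect_true(all(grepl("^(luminance|contrast|structure)_",
                        setdiff(names(fm2), names(fm2)[1:8]))))

  fm3 <- build_feature_matrix(co, "ml3")
  expect_equal(ncol(fm3) - 8, 376)
  expect_false(any(grepl("shape", names(fm3), ignore.case = TRUE)))
})

test_that("a cohort record without its map is rejected with its identity", {
  co <- tiny_cohort(n_patients = 2, size = 48)
  co$map[5] <- list(NULL)
  expect_error(build_feature_matrix(co, "ml1"), co$patient_id[5])
})
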