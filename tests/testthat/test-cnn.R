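# Four-branch CNN architecture and training behaviour.

# Small synthetic comparison-map stacks whose class is encoded in the DD
# level, for engine-level tests without simulation.
fake_comparisons <- function(n, side = 16, seed = 1) {
  lapply(seq_len(n), function(i) {
    cls <- i %% 2
    withr::with_seed(seed + i, {
      structure(list(
        dd = matrix(runif(side^2, 0, 30) + cls * 80, side, side),
        luminance = matrix(runif(side^2, 0.7, 1), side, side),
        contrast = matrix(runif(side^2, 0.7, 1), side, side),
        structure = matrix(runif(side^2, -0.3, 1), side, side)),
        class = "comparison_maps")
    })
  })
}

test_that("the architecture census matches the design", {
  spec <- network_spec(8)
  expect_equal(spec$n_conv, 13)   # 13 convolutional layers per branch
  expect_equal(spec$n_pool, 4)    # 4 max-pooling layers per branch
  expect_equal(spec$input_size, 512)
  expect_equal(spec$final_size, 32) # 512 / 2^4 before the average pool
  expect_equal(unique(spec$cout), c(8L, 16L, 32L, 64L, 128L)) # doubling
  expect_equal(sum(spec$pool_after), 4)
  expect_equal(spec$concat_dim, 4 * 128) # four branches concatenated

  model <- build_network(8, spec)
  expect_length(model$weights$branches, 4)
  expect_length(model$weights$branches[[1]], 13)
  expect_equal(dim(model$weights$fc2_W), c(8L, spec$fc_hidden))
  expect_equal(nrow(model$weights$branches[[1]][[1]]$W), 8) # cout x 9*cin
  expect_equal(ncol(model$weights$branches[[1]][[1]]$W), 9)

  # reduced mode keeps the 13 convolutions, drops the last two pools
  red <- network_spec(2, input_size = 128, base_width = 4, reduced = TRUE)
  expect_equal(red$n_conv, 13)
  expect_equal(red$n_pool, 2)
  expect_equal(red$final_size, 32)

  expect_error(network_spec(2, input_size = 100), "divisible")
})

test_that("predictions are normalised scores with arg-max classes", {
  cmp <- fake_comparisons(6)
  lab <- (seq_len(6)) %% 2 + 1
  spec <- network_spec(2, input_size = 16, base_width = 2, reduced = TRUE)
  m <- train_cnn(cmp, lab, 2, spec = spec,
                 cfg = train_config(epochs = 3, batch_size = 2, seed = 2))
  p <- predict_cnn(m, cmp)
  expect_equal(rowSums(as.matrix(p[, c("score_1", "score_2")])),
               rep(1, 6), tolerance = 1e-6)
  expect_equal(p$pred, max.col(as.matrix(p[, c("score_1", "score_2")])))
  # single comparison object accepted too
  p1 <- predict_cnn(m, cmp[[1]])
  expect_equal(nrow(p1), 1)

  small <- fake_comparisons(1, side = 8)
  expect_error(predict_cnn(m, small), "smaller")
})

test_that("training is deterministic given the seed", {
  cmp <- fake_comparisons(6)
  lab <- (seq_len(6)) %% 2 + 1
  spec <- network_spec(2, input_size = 16, base_width = 2, reduced = TRUE)
  cfg <- train_config(epochs = 4, batch_size = 3, seed = 5)
  m1 <- train_cnn(cmp, lab, 2, spec = spec, cfg = cfg)
  m2 <- train_cnn(cmp, lab, 2, spec = spec, cfg = cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss, m2$loss)
  expect_identical(predict_cnn(m1, cmp), predict_cnn(m2, cmp))
  # a different seed gives a different optimisation path
  m3 <- train_cnn(cmp, lab, 2, spec = spec,
                  cfg = train_config(epochs = 4, batch_size = 3, seed = 6))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("the network has the capacity to memorise a small set", {
  cmp <- fake_comparisons(10, side = 16, seed = 30)
  lab <- (seq_len(10)) %% 2 + 1
  spec <- network_spec(2, input_size = 16, base_width = 2, reduced = TRUE)
  m <- train_cnn(cmp, lab, 2, spec = spec,
                 cfg = train_config(epochs = 200, batch_size = 5, seed = 3,
                                    stop_at_train_acc = 1,
                                    check_every = 10))
  p <- predict_cnn(m, cmp)
  expect_equal(mean(p$pred == lab), 1)
  expect_true(all(is.finite(m$loss)))
  # smoothed loss trend decreases on this easy set
  half <- floor(length(m$loss) / 2)
  expect_lt(mean(utils::tail(m$loss, half)), mean(utils::head(m$loss, half)))
})
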