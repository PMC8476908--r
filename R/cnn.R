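# Four-branch CNN classifier: DD, luminance, contrast and structure maps are
# fed to four parallel feature extractors whose pooled features are
# concatenated and integrated by two fully connected layers.

#' Network architecture specification
#'
#' Each of the four branch extractors stacks 13 size-preserving 3x3
#' convolutional layers (ReLU) in VGG-style blocks of 2, 2, 3, 3 and 3
#' layers, with a 2x2 max-pooling layer after each of the first four blocks
#' that halves the spatial size and doubles the channel count, followed by a
#' global average-pooling layer that reduces every channel to its mean. The
#' four pooled vectors are concatenated and passed through two fully
#' connected layers emitting one score per class; the predicted class is the
#' arg-max (softmax probabilities are reported).
#'
#' `reduced = TRUE` keeps the 13 convolutional layers but drops the last two
#' pooling layers (and their channel doublings), matching smaller inputs
#' such as 128x128 while preserving the final 32x32 pooled resolution of the
#' full 512x512 network.
#'
#' @param n_classes number of output classes (2 for binary tasks, 8 for the
#'   joint task).
#' @param input_size input map side length in pixels (default 512).
#' @param base_width channel width of the first block (default 8).
#' @param fc_hidden width of the first fully connected layer (default 64).
#' @param reduced drop the last two pooling stages for reduced-size inputs.
#' @return A `network_spec` object describing the per-layer channel plan.
#' @export
network_spec <- function(n_classes, input_size = 512L, base_width = 8L,
                         fc_hidden = 64L, reduced = FALSE) {
  stopifnot(n_classes >= 2, input_size >= 8, base_width >= 1)
  blocks <- c(2L, 2L, 3L, 3L, 3L)
  pooled_blocks <- if (reduced) 1:2 else 1:4
  n_pool <- length(pooled_blocks)
  if (input_size %% 2^n_pool != 0)
    stop("input_size must be divisible by 2^(number of pooling layers)",
         call. = FALSE)
  width <- base_width
  cin <- integer(0); cout <- integer(0); pool_after <- logical(0)
  prev <- 1L
  for (bl in seq_along(blocks)) {
    for (l in seq_len(blocks[bl])) {
      cin <- c(cin, prev)
      cout <- c(cout, width)
      pool_after <- c(pool_after, FALSE)
      prev <- width
    }
    if (bl %in% pooled_blocks) {
      pool_after[length(pool_after)] <- TRUE
      width <- 2L * width
    }
  }
  final_size <- input_size / 2^n_pool
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 base_width = as.integer(base_width),
                 fc_hidden = as.integer(fc_hidden),
                 reduced = reduced,
                 cin = cin, cout = cout, pool_after = pool_after,
                 n_conv = length(cin), n_pool = n_pool,
                 final_size = as.integer(final_size),
                 concat_dim = 4L * cout[length(cout)]),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<network_spec: 4 branches x (%d conv + %d max-pool + 1 avg-pool)",
           ", 2 FC layers, %d classes>\n"),
    x$n_conv, x$n_pool, x$n_classes))
  cat(sprintf("  input %dx%d -> pooled %dx%d, channels %s, concat %d\n",
              x$input_size, x$input_size, x$final_size, x$final_size,
              paste(unique(x$cout), collapse = "->"), x$concat_dim))
  invisible(x)
}

#' Build (initialise) the four-branch network
#'
#' Allocates He-initialised weights for the architecture described by a
#' [network_spec()]. The returned model is untrained; [train_cnn()] fits it.
#'
#' @param n_classes number of classes (2 or 8 in the study design).
#' @param spec a [network_spec()]; defaults to the full 512x512 layout for
#'   `n_classes`.
#' @param seed RNG seed for the weight initialisation.
#' @return An object of class `cnn_model` holding the spec and weights.
#' @export
build_network <- function(n_classes, spec = network_spec(n_classes),
                          seed = 1L) {
  stopifnot(spec$n_classes == n_classes)
  local_seed(seed, {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)),
                                  nr, nc)
    branches <- lapply(1:4, function(b) {
      lapply(seq_len(spec$n_conv), function(l) {
        fan_in <- 9L * spec$cin[l]
        list(W = he(spec$cout[l], fan_in), b = rep(0, spec$cout[l]))
      })
    })
    weights <- list(branches = branches,
                    fc1_W = he(spec$fc_hidden, spec$concat_dim),
                    fc1_b = rep(0, spec$fc_hidden),
                    fc2_W = he(n_classes, spec$fc_hidden),
                    fc2_b = rep(0, n_classes))
    structure(list(spec = spec, weights = weights, trained = FALSE,
                   loss = numeric(0), classes = NULL, task = NULL),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  print(x$spec)
  cat(if (x$trained)
    sprintf("  trained (%d epochs, final loss %.4f)\n",
            length(x$loss), utils::tail(x$loss, 1))
    else "  untrained\n")
  invisible(x)
}

#' CNN training configuration
#'
#' Optimisation settings for [train_cnn()]: Adam with cross-entropy loss.
#' Inputs are normalised to \[0, 1\] with fixed per-map-type ranges (DD by
#' the fraction dose `L`; SSIM components from \[-1, 1\]), so the scheme is
#' independent of the data batch.
#'
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 8).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed seed for weight initialisation and epoch shuffles.
#' @param dose_scale L used to scale DD maps (default 200 cGy).
#' @param stop_at_train_acc optionally stop early once training accuracy
#'   reaches this level (e.g. 1.0); `NULL` disables.
#' @param check_every epochs between early-stop accuracy checks (default 5).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, lr = 1e-3,
                         seed = 1L, dose_scale = 200,
                         stop_at_train_acc = NULL, check_every = 5L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), dose_scale = dose_scale,
                 stop_at_train_acc = stop_at_train_acc,
                 check_every = as.integer(check_every)),
            class = "train_config")
}

# Stack comparison maps into the (h, w, 4, n) input array, normalised to
# [0,1]: DD / L, SSIM components (x+1)/2.
cnn_input_array <- function(comparisons, crop_side, dose_scale = 200) {
  n <- length(comparisons)
  x <- array(0, dim = c(crop_side, crop_side, 4L, n))
  for (s in seq_len(n)) {
    cm <- comparisons[[s]]
    x[, , 1, s] <- pmin(center_crop(cm$dd, crop_side) / dose_scale, 1)
    x[, , 2, s] <- (center_crop(cm$luminance, crop_side) + 1) / 2
    x[, , 3, s] <- (center_crop(cm$contrast, crop_side) + 1) / 2
    x[, , 4, s] <- (center_crop(cm$structure, crop_side) + 1) / 2
  }
  x
}

#' Train the four-branch CNN
#'
#' Minimises multiclass cross-entropy over the comparison-map stacks of the
#' training samples with Adam. Deterministic given the configuration seed
#' (weight initialisation and minibatch shuffling both derive from it).
#'
#' @param comparisons list of `comparison_maps` objects (one per training
#'   sample).
#' @param labels integer class labels (values `1..n_classes`).
#' @param n_classes number of classes; defaults to `max(labels)`.
#' @param spec a [network_spec()]; defaults to a spec sized to the maps
#'   (reduced if smaller than 512).
#' @param cfg a [train_config()].
#' @return A trained `cnn_model` with the per-epoch mean loss in `$loss`.
#' @export
train_cnn <- function(comparisons, labels, n_classes = max(labels),
                      spec = NULL, cfg = train_config()) {
  labels <- as.integer(labels)
  stopifnot(length(comparisons) == length(labels), all(labels >= 1),
            all(labels <= n_classes))
  side <- min(dim(comparisons[[1]]$dd))
  if (is.null(spec)) {
    side <- min(side, 512L)
    side <- 2^floor(log2(side / 4)) * 4L # largest pool-compatible crop
    spec <- network_spec(n_classes, input_size = side,
                         base_width = if (side < 512) 4L else 8L,
                         reduced = side < 512)
  }
  x <- cnn_input_array(comparisons, spec$input_size, cfg$dose_scale)
  model <- build_network(n_classes, spec, seed = cfg$seed)
  n <- length(labels)
  order_mat <- local_seed(cfg$seed + 1L, {
    t(vapply(seq_len(cfg$epochs), function(e) sample.int(n), integer(n)))
  })
  if (n == 1L) order_mat <- matrix(1L, nrow = cfg$epochs, ncol = 1L)

  weights <- model$weights
  loss <- numeric(0)
  done <- 0L
  while (done < cfg$epochs) {
    chunk <- if (is.null(cfg$stop_at_train_acc)) cfg$epochs - done
             else min(cfg$check_every, cfg$epochs - done)
    fit <- cpp_cnn_train(weights, as.numeric(x), labels,
                         spec$input_size, spec$input_size, n,
                         spec$cin, spec$cout, spec$pool_after,
                         order_mat[done + seq_len(chunk), , drop = FALSE],
                         cfg$batch_size, cfg$lr, 0.9, 0.999, 1e-8)
    weights <- fit$weights
    loss <- c(loss, fit$loss)
    done <- done + chunk
    if (!is.null(cfg$stop_at_train_acc)) {
      p <- cpp_cnn_predict(weights, as.numeric(x), spec$input_size,
                           spec$input_size, n, spec$cin, spec$cout,
                           spec$pool_after)
      acc <- mean(max.col(p) == labels)
      if (acc >= cfg$stop_at_train_acc) break
    }
  }
  model$weights <- weights
  model$trained <- TRUE
  model$loss <- loss
  model$classes <- seq_len(n_classes)
  model$dose_scale <- cfg$dose_scale
  model
}

#' Predict with a trained CNN
#'
#' @param model a trained `cnn_model`.
#' @param comparisons a single `comparison_maps` object or a list of them.
#' @return A tibble with the predicted class (`pred`, the arg-max) and one
#'   `score_k` column per class; softmax scores sum to 1 per sample.
#' @export
predict_cnn <- function(model, comparisons) {
  stopifnot(inherits(model, "cnn_model"), model$trained)
  if (inherits(comparisons, "comparison_maps"))
    comparisons <- list(comparisons)
  spec <- model$spec
  side <- min(dim(comparisons[[1]]$dd))
  if (side < spec$input_size)
    stop(sprintf("maps (%d px) smaller than the network input (%d px)",
                 side, spec$input_size), call. = FALSE)
  x <- cnn_input_array(comparisons, spec$input_size,
                       if (is.null(model$dose_scale)) 200 else model$dose_scale)
  p <- cpp_cnn_predict(model$weights, as.numeric(x), spec$input_size,
                       spec$input_size, length(comparisons),
                       spec$cin, spec$cout, spec$pool_after)
  colnames(p) <- paste0("score_", seq_len(spec$n_classes))
  dplyr::bind_cols(tibble::tibble(pred = max.col(p)), tibble::as_tibble(p))
}

#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(n_conv = x$spec$n_conv, n_pool = x$spec$n_pool,
                 n_classes = x$spec$n_classes,
                 input_size = x$spec$input_size,
                 trained = x$trained, epochs = length(x$loss),
                 final_loss = if (length(x$loss)) utils::tail(x$loss, 1)
                              else NA_real_)
}
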