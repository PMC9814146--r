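test_that("quadratic cost and gradient-descent update are exact", {
  expect_equal(cnn_cost(c(1, 2), c(1, 2)), 0)
  expect_equal(cnn_cost(1.3, 1.1), 0.5 * 0.2^2, tolerance = 1e-12)
  expect_equal(cnn_cost(0, 2), 2.0)
  expect_error(cnn_cost(1:3, 1:2), "length")

  expect_equal(weight_update(1.0, 0.5, 0.1), 0.95)
  expect_equal(weight_update(2.3, 0, 0.1), 2.3)  # stationary point
  w <- weight_update(weight_update(1.0, 0.5, 0.1), 0.5, 0.1)
  expect_equal(w, 1.0 - 2 * 0.1 * 0.5)
  expect_error(weight_update(1, 1, -0.1), "positive")

  # one descent step on a scalar quadratic cost reduces the cost for any
  # learning rate below 1
  for (alpha in c(1e-3, 0.1, 0.9)) {
    w0 <- 3; target <- 1
    g <- (w0 - target)                    # d/dw of 0.5 (w - target)^2
    w1 <- weight_update(w0, g, alpha)
    expect_lt(cnn_cost(w1, target), cnn_cost(w0, target))
  }
})

test_that("build_model realizes the configured architecture reproducibly", {
  cfg <- cnn_config(seed = 5)
  m <- build_model(cfg, c(64, 64), 6)
  last <- m$layers[[length(m$layers)]]
  expect_equal(last$out_dim, 6L)
  first <- m$layers[[1]]
  expect_equal(first$type, "conv_block")
  expect_equal(nrow(first$params$W), 32L)      # 32 filters
  expect_equal(first$kernel, 5L)               # kernel size 5 x 5
  expect_equal(dim(first$params$W), c(32L, 25L))
  expect_true(first$use_bn)

  m2 <- build_model(cfg, c(64, 64), 6)
  expect_identical(m$layers, m2$layers)        # seeded initialization
  cfg2 <- cnn_config(seed = 6)
  m3 <- build_model(cfg2, c(64, 64), 6)
  expect_false(identical(m$layers[[1]]$params$W, m3$layers[[1]]$params$W))

  expect_error(build_model(cnn_config(conv_layers = list(c(4, 9))),
                           c(8, 8), 2), "kernel larger")
})

test_that("backpropagation matches finite-difference gradients", {
  ns <- asNamespace("dcsnet")
  for (bn in c(TRUE, FALSE)) {
    cfg <- cnn_config(conv_layers = list(c(3, 3), c(2, 3)), fc_depth = 2,
                      fc_width = 5, batch_size = 4, epochs = 1, seed = 42,
                      batch_norm = bn)
    mod <- build_model(cfg, c(8, 8), 2)
    set.seed(7)
    X <- matrix(rnorm(64 * 4), 64, 4)
    Yt <- matrix(rnorm(2 * 4), 2, 4)
    loss_of <- function(layers) {
      mean(0.5 * (ns$nn_forward(layers, X, TRUE)$out - Yt)^2)
    }
    fw <- ns$nn_forward(mod$layers, X, TRUE)
    bw <- ns$nn_backward(fw$layers, fw$caches, (fw$out - Yt) / length(Yt))
    worst <- 0
    for (l in seq_along(mod$layers)) {
      for (nm in names(bw$grads[[l]])) {
        g_an <- bw$grads[[l]][[nm]]
        p <- mod$layers[[l]]$params[[nm]]
        set.seed(l)
        for (k in sample(length(p), min(6, length(p)))) {
          eps <- 1e-5
          lp <- mod$layers; lp[[l]]$params[[nm]][k] <- p[k] + eps
          lm <- mod$layers; lm[[l]]$params[[nm]][k] <- p[k] - eps
          g_num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
          if (abs(g_an[k]) > 1e-10 || abs(g_num) > 1e-10) {
            worst <- max(worst, abs(g_an[k] - g_num) /
                                  (abs(g_an[k]) + abs(g_num)))
          }
        }
      }
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("the network memorizes a single training sample", {
  set.seed(31)
  x <- rnorm(64)
  ds <- structure(list(
    inputs = matrix(x, 64, 4),
    labels = matrix(rep(c(1.2, 1.0), each = 4), 4, 2),
    scheme = scheme_c2h2(),
    grid = tiny_grid(8, 8),
    splits = list(train = 1:2, validation = 3L, test = 4L),
    label_stats = list(min = c(0.9, 0.8), max = c(1.5, 1.3)),
    reference_name = "eq"), class = "dcs_dataset")
  cfg <- cnn_config(conv_layers = list(c(4, 3)), fc_depth = 1, fc_width = 8,
                    batch_size = 2, learning_rate = 5e-3, epochs = 200,
                    optimizer = "adam", seed = 1)
  fit <- train_cnn(build_model(cfg, c(8, 8), 2), ds, cfg)
  final_mae <- tail(fit$report$history$train_mae, 1)
  expect_lt(final_mae, 1e-2)
  scaled_cost <- cnn_cost(predict(fit$model, x), c(1.2, 1.0))
  expect_lt(scaled_cost, 1e-4)
})

test_that("training is deterministic and divergence is reported", {
  tc <- tiny_c2h2_fit()
  cfg <- cnn_config(conv_layers = list(c(4, 3)), fc_depth = 1, fc_width = 8,
                    batch_size = 64, learning_rate = 1e-3, epochs = 3,
                    optimizer = "adam", seed = 17)
  f1 <- train_cnn(build_model(cfg, c(16, 16), 2), tc$dataset, cfg)
  f2 <- train_cnn(build_model(cfg, c(16, 16), 2), tc$dataset, cfg)
  expect_identical(f1$report$history, f2$report$history)
  expect_identical(f1$report$test_mae, f2$report$test_mae)

  blow <- cnn_config(conv_layers = list(c(4, 3)), fc_depth = 1, fc_width = 8,
                     batch_size = 64, learning_rate = 1e12, epochs = 5,
                     batch_norm = FALSE, optimizer = "sgd", seed = 1)
  expect_error(train_cnn(build_model(blow, c(16, 16), 2), tc$dataset, blow),
               "diverged at epoch")
})

test_that("predictions are deterministic, unit-correct and shape-checked", {
  tc <- tiny_c2h2_fit()
  fit <- tc$fit
  ds <- tc$dataset
  i <- ds$splits$train[1]
  p1 <- predict(fit$model, ds$inputs[, i])
  p2 <- predict(fit$model, ds$inputs[, i])
  expect_identical(p1, p2)
  # a training input predicts near its label (consistency with the report)
  expect_lt(mean(abs(p1 - ds$labels[i, ])),
            10 * tail(fit$report$history$train_mae, 1) + 0.02)
  # matrix input: one row per sample
  pm <- predict(fit$model, ds$inputs[, ds$splits$test])
  expect_equal(dim(pm), c(length(ds$splits$test), 2L))
  expect_error(predict(fit$model, rnorm(10)), "pixels")
})

test_that("held-out off-grid structures are recovered by interpolation", {
  tc <- tiny_c2h2_fit()
  truth <- c(1.137, 1.071)  # off any sampled point, inside the ranges
  m <- dcs_map(structure_from_params(scheme_c2h2(), truth), tc$model, tc$grid)
  input <- difference_map(m, dcs_map(tc$ref, tc$model, tc$grid))
  pred <- predict(tc$fit$model, input)
  expect_lt(mean(abs(pred - truth)), 0.02)
})

test_that("model serialization round-trips bit-identically", {
  tc <- tiny_c2h2_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(tc$fit$model, path)
  back <- load_model(path)
  x <- tc$dataset$inputs[, 5]
  expect_identical(predict(back, x), predict(tc$fit$model, x))
})

test_that("ensemble retrieval composes member models transparently", {
  tc <- tiny_c2h2_fit()
  grid <- tc$grid; am <- tc$model; ref <- tc$ref
  builder <- function(seed) {
    spec <- deformation_spec("parameter-grid", scheme_c2h2(),
      parameters = list(R_CC = list(min = 1.0, max = 1.4),
                        R_CH = list(min = 0.86, max = 1.26)),
      sampling = "uniform", count = 150, seed = 100 + seed)
    assemble_dataset(generate_database(spec), ref, grid, am, seed = seed)
  }
  cfg <- cnn_config(conv_layers = list(c(6, 3)), fc_depth = 1, fc_width = 16,
                    batch_size = 40, learning_rate = 2e-3, epochs = 15,
                    optimizer = "adam", seed = 0)
  truth_map <- dcs_map(structure_from_params(scheme_c2h2(), c(1.22, 1.05)),
                       am, grid)
  input <- difference_map(truth_map, dcs_map(ref, am, grid))

  expect_error(ensemble_retrieve(builder, cfg, 1L, input), "at least two")

  # identical member seeds: zero spread across members
  same <- ensemble_retrieve(builder, cfg, c(4L, 4L), input)
  expect_equal(same$member_labels[1, ], same$member_labels[2, ],
               tolerance = 1e-12)

  # members equal running train + predict separately per seed
  ens <- ensemble_retrieve(builder, cfg, c(1L, 2L), input)
  cfg1 <- cfg; cfg1$seed <- 1L
  solo <- train_cnn(build_model(cfg1, c(16, 16), 2), builder(1L), cfg1)
  expect_equal(unname(ens$member_labels[1, ]),
               unname(predict(solo$model, input)), tolerance = 1e-12)
  expect_equal(ens$labels, colMeans(ens$member_labels))
  expect_equal(ens$total_error, ens$model_error + ens$experimental_error)
  expect_equal(ens$experimental_error, c(0, 0))  # no counts map supplied
})
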