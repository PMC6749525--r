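conv_filters <- function(spec)
  vapply(Filter(function(l) l$type == "conv", spec$layers), `[[`, integer(1),
         "filters")
layer_types <- function(spec) vapply(spec$layers, `[[`, character(1), "type")

test_that("architecture layer sequences match the published table", {
  f3 <- build_spec("FCN-III")
  expect_equal(conv_filters(f3), c(32L, 32L, 64L, 64L, 6L))
  expect_equal(layer_types(f3),
               c("conv", "conv", "maxpool", "conv", "conv", "maxpool",
                 "dropout", "conv", "gap"))
  expect_equal(conv_filters(build_spec("FCN-I")), c(16L, 16L, 32L, 6L))
  expect_equal(conv_filters(build_spec("FCN-II")), c(32L, 32L, 64L, 6L))
  expect_equal(conv_filters(build_spec("FCN-IV")),
               c(32L, 32L, 32L, 64L, 64L, 6L))
  cnn <- build_spec("CNN")
  expect_equal(conv_filters(cnn), c(32L, 32L, 64L, 64L))
  dense_units <- vapply(Filter(function(l) l$type == "dense", cnn$layers),
                        `[[`, integer(1), "units")
  expect_equal(dense_units, c(256L, 256L, 6L))
  expect_error(build_spec("FCN-V"), "FCN-I")
})

test_that("closed-form parameter counts match hand arithmetic per variant", {
  single <- structure(list(variant = "custom", n_classes = 6L,
                           input_shape = c(30L, 24L),
                           layers = list(list(type = "conv", filters = 16L,
                                              kernel = c(3L, 3L)))),
                      class = "fcn_spec")
  expect_equal(count_parameters(single), 160L)  # 16 * (9 + 1)
  expect_equal(count_parameters(build_spec("FCN-I")), 8854L)
  expect_equal(count_parameters(build_spec("FCN-II")), 31526L)
  # 320 + 9248 + 18496 + 36928 + 3462
  expect_equal(count_parameters(build_spec("FCN-III")), 68454L)
  expect_equal(count_parameters(build_spec("FCN-IV")), 77702L)
  # 64992 (conv front) + 688384 + 65792 + 1542
  expect_equal(count_parameters(build_spec("CNN")), 820710L)
})

test_that("closed-form counts agree with the built models' actual weights", {
  set.seed(41)
  imgs <- array(rnorm(30 * 24 * 12), dim = c(30, 24, 12))
  labs <- rep(ACTIVITY_LABELS, 2)
  cfg <- training_config(max_epochs = 0L, seed = 1L)
  for (v in c("FCN-I", "FCN-II", "FCN-III", "FCN-IV", "CNN")) {
    m <- train_model(build_spec(v), imgs, labs, cfg)
    n_actual <- sum(vapply(m$weights, function(wl)
      length(wl$W) + length(wl$b), numeric(1)))
    expect_equal(n_actual, count_parameters(build_spec(v)))
  }
})

test_that("softmax outputs are proper distributions over the six classes", {
  set.seed(43)
  imgs <- array(rnorm(30 * 24 * 20, sd = 3), dim = c(30, 24, 20))
  m <- train_model(build_spec("FCN-I"), imgs,
                   rep(ACTIVITY_LABELS, length.out = 20),
                   training_config(max_epochs = 0L, seed = 2L))
  P <- predict(m, imgs, type = "prob")
  expect_equal(dim(P), c(20L, 6L))
  expect_equal(colnames(P), ACTIVITY_LABELS)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))
  cls <- predict(m, imgs)
  expect_true(all(cls %in% ACTIVITY_LABELS))
})

test_that("training separable synthetic windows reaches high accuracy", {
  m <- tiny_model()
  expect_gte(tail(m$history$train_acc, 1L), 0.95)
  expect_lte(m$epochs_run, m$config$max_epochs)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(47)
  imgs <- array(rnorm(30 * 24 * 36), dim = c(30, 24, 36))
  labs <- rep(ACTIVITY_LABELS, 6)
  cfg <- training_config(max_epochs = 2L, seed = 9L)
  a <- train_model(build_spec("FCN-I"), imgs, labs, cfg)
  b <- train_model(build_spec("FCN-I"), imgs, labs, cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
})

test_that("early stopping halts before the epoch budget on unlearnable data", {
  set.seed(53)
  imgs <- array(rnorm(30 * 24 * 60), dim = c(30, 24, 60))
  labs <- sample(ACTIVITY_LABELS, 60, replace = TRUE)
  cfg <- training_config(max_epochs = 40L, patience = 2L,
                         validation_fraction = 0.2, seed = 10L)
  m <- train_model(build_spec("FCN-I"), imgs, labs, cfg)
  expect_lt(m$epochs_run, 40L)
})

test_that("degenerate training inputs raise explicit errors", {
  imgs <- array(0, dim = c(30, 24, 4))
  expect_error(train_model(build_spec("FCN-I"),
                           array(0, dim = c(30, 24, 0)), character(0)),
               "empty")
  expect_error(train_model(build_spec("FCN-I"), imgs, rep("walking", 4)),
               "2 classes")
  expect_error(train_model(build_spec("FCN-I"), array(0, dim = c(20, 24, 4)),
                           rep(c("a", "b"), 2)), "30")
})

test_that("fold assignment is a balanced deterministic partition", {
  f <- make_folds(100, 10, seed = 5L)
  expect_length(f, 100L)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10L))
  expect_identical(f, make_folds(100, 10, seed = 5L))
  expect_false(identical(f, make_folds(100, 10, seed = 6L)))
  # fold sizes within one of each other when k does not divide n
  expect_true(diff(range(table(make_folds(103, 10, seed = 1L)))) <= 1)
  expect_error(make_folds(100, 1), ">= 2")
})

test_that("cross-validation tests every sample exactly once", {
  set.seed(59)
  imgs <- array(rnorm(30 * 24 * 36, sd = 2), dim = c(30, 24, 36))
  labs <- rep(ACTIVITY_LABELS, 6)
  cv <- cross_validate(build_spec("FCN-I"), imgs, labs, k = 3L,
                       config = training_config(max_epochs = 1L, seed = 4L))
  expect_length(cv$fold_accuracy, 3L)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_equal(cv$mean, mean(cv$fold_accuracy))
  expect_equal(sort(unique(cv$folds)), 1:3)
  expect_equal(length(cv$folds), 36L)
})
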