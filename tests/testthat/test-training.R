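test_that("the multilabel loss matches its closed forms", {
  expect_equal(multilabel_loss(c(1, 0), c(0, 0)), 2 * log(2),
               tolerance = 1e-10)
  # sigma(logit) = 0.8 on a single positive label -> -log(0.8)
  expect_equal(multilabel_loss(1, stats::qlogis(0.8)), -log(0.8),
               tolerance = 1e-10)
  # perfect-prediction limit
  expect_lt(multilabel_loss(1, 40), 1e-10)
  expect_gte(multilabel_loss(c(1, 0, 1), c(-3, 2, 0.5)), 0)
  expect_error(multilabel_loss(c(1, 0.5), c(0, 0)), "0/1")
  expect_error(multilabel_loss(c(1, 0), c(0, 0, 0)), "same shape")
})

test_that("the loss is additive over labels and averages over the batch", {
  y <- c(1, 0, 1, 1)
  x <- c(0.3, -1.2, 2.0, -0.4)
  per_label <- vapply(1:4, function(l) multilabel_loss(y[l], x[l]),
                      numeric(1))
  expect_equal(multilabel_loss(y, x), sum(per_label), tolerance = 1e-12)
  Y <- rbind(y, c(0, 1, 0, 0))
  X <- rbind(x, c(0.5, 0.5, -2, 1))
  expect_equal(multilabel_loss(Y, X),
               (multilabel_loss(y, x) +
                  multilabel_loss(Y[2, ], X[2, ])) / 2,
               tolerance = 1e-12)
  # C = 1 reduces to scalar binary cross-entropy
  expect_equal(multilabel_loss(matrix(c(1, 0)), matrix(c(0.7, -0.2))),
               mean(-log(c(sigmoid_ <- 1 / (1 + exp(-0.7)),
                           1 - 1 / (1 + exp(0.2))))),
               tolerance = 1e-10)
})

test_that("the stage plan freezes modules as specified", {
  plan <- make_stage_plan()
  expect_length(plan, 4)
  expect_false("backbone" %in% plan[[2]]$trainable)
  expect_identical(plan[[3]]$trainable, "arl")
  expect_setequal(plan[[4]]$trainable,
                  c("backbone", "head", "lfa", "ada", "arl"))
  expect_identical(plan[[1]]$forward, "baseline")
  expect_identical(plan[[2]]$forward, "full")
  expect_message(make_stage_plan(warn_random_init = TRUE), "random")
})

test_that("the exponential policy decays the learning rate geometrically", {
  cfg <- train_config(base_lr = 0.02, gamma = 0.9)
  expect_equal(learning_rate(cfg, 0), 0.02)
  expect_equal(learning_rate(cfg, 3), 0.02 * 0.9^3)
})

make_toy_data <- function(n_per = 6, size = 16, seed = 5) {
  spec <- mini_spec(per = n_per, image_size = size, seed = seed)
  ds <- generate_dataset(spec)
  ds$index <- split_dataset(ds$index, seed = seed)
  ds
}

test_that("frozen modules are bit-identical across a stage", {
  ds <- make_toy_data()
  m <- tiny_model(labels = jujube_labels(), seed = 2)
  cfg <- train_config(batch_size = 8, iters = c(3, 3, 3, 3),
                      select_best = FALSE, seed = 4)
  before <- vapply(c("backbone", "head", "lfa", "ada", "arl"),
                   function(mod) param_checksum(m, mod), numeric(1))
  fit <- train_farnet(m, ds, cfg, stages = 2)
  after <- vapply(c("backbone", "head", "lfa", "ada", "arl"),
                  function(mod) param_checksum(fit$model, mod), numeric(1))
  expect_identical(before[["backbone"]], after[["backbone"]])
  expect_identical(before[["head"]], after[["head"]])
  expect_identical(before[["arl"]], after[["arl"]])
  expect_false(before[["lfa"]] == after[["lfa"]])
  expect_false(before[["ada"]] == after[["ada"]])

  fit3 <- train_farnet(m, ds, cfg, stages = 3)
  after3 <- vapply(c("backbone", "head", "lfa", "ada", "arl"),
                   function(mod) param_checksum(fit3$model, mod),
                   numeric(1))
  expect_identical(before[["lfa"]], after3[["lfa"]])
  expect_false(before[["arl"]] == after3[["arl"]])
})

test_that("training descends and is deterministic given the seed", {
  ds <- make_toy_data()
  m <- tiny_model(labels = jujube_labels(), ablate = c("lfa", "ada", "arl"),
                  seed = 3)
  cfg <- train_config(batch_size = 8, iters = c(60, 1, 1, 1),
                      base_lr = 0.01, select_best = FALSE, seed = 11)
  fit <- train_farnet(m, ds, cfg, stages = 1)
  expect_lt(mean(tail(fit$history$loss, 10)),
            mean(head(fit$history$loss, 10)))
  fit2 <- train_farnet(m, ds, cfg, stages = 1)
  expect_identical(tail(fit$history$loss, 1), tail(fit2$history$loss, 1))
  cfg3 <- cfg; cfg3$seed <- 12L
  fit3 <- train_farnet(m, ds, cfg3, stages = 1)
  expect_false(identical(tail(fit$history$loss, 1),
                         tail(fit3$history$loss, 1)))
})

test_that("stages whose modules are all ablated are skipped", {
  ds <- make_toy_data()
  m <- tiny_model(labels = jujube_labels(), ablate = "arl", seed = 2)
  cfg <- train_config(batch_size = 8, iters = c(2, 2, 2, 2),
                      select_best = FALSE, seed = 4)
  fit <- train_farnet(m, ds, cfg, stages = 3)
  expect_null(fit$history)
  expect_identical(param_checksum(m, "arl"),
                   param_checksum(fit$model, "arl"))
})

test_that("divergence aborts with a diagnostic", {
  ds <- make_toy_data()
  m <- tiny_model(labels = jujube_labels(), ablate = c("lfa", "ada", "arl"),
                  seed = 2)
  cfg <- train_config(batch_size = 8, iters = c(60, 1, 1, 1),
                      base_lr = 1e12, select_best = FALSE, seed = 4)
  expect_error(train_farnet(m, ds, cfg, stages = 1), "diverged")
})

test_that("checkpoints round-trip a trained model", {
  ds <- make_toy_data()
  m <- tiny_model(labels = jujube_labels(), seed = 6)
  cfg <- train_config(batch_size = 8, iters = c(2, 2, 2, 2),
                      select_best = FALSE, seed = 4)
  m <- train_farnet(m, ds, cfg, stages = 1)$model
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- random_image_batch(2, size = 16, seed = 9)
  expect_equal(farnet_forward(m, x)$confidence,
               farnet_forward(m2, x)$confidence, tolerance = 1e-12)
})
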