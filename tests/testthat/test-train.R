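# A shared 16x16 two-class dataset and matching miniature model keep these
# loop-level tests fast; the deeper overfitting run lives with the
# end-to-end checks.
tiny_setup <- function(seed = 31) {
  dir <- file.path(tempdir(), paste0("tinytrain", seed))
  if (!dir.exists(dir)) make_smoke_dataset(dir, seed = seed, size = 32)
  cfg <- swin_config(image_size = 16L, patch_size = 4L, embed_dim = 8L,
                     window_size = 4L, depths = c(2L), heads = c(2L),
                     num_classes = 2L)
  list(dir = file.path(dir, "train"), cfg = cfg)
}

test_that("a zero learning rate leaves every parameter untouched", {
  ts <- tiny_setup()
  model <- dual_model(ts$cfg, seed = 1)
  before <- flatten_params(model$params)
  fit <- train(model, ts$dir,
               train_config(batch_size = 8, learning_rate = 0, epochs = 1,
                            seed = 2))
  expect_equal(flatten_params(fit$model$params), before, tolerance = 0)
})

test_that("identical seeds give bit-identical loss trajectories", {
  ts <- tiny_setup()
  cfgt <- train_config(batch_size = 8, learning_rate = 1e-3, epochs = 2,
                       seed = 5, policy = aug_policy())
  f1 <- train(dual_model(ts$cfg, seed = 3), ts$dir, cfgt)
  f2 <- train(dual_model(ts$cfg, seed = 3), ts$dir, cfgt)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(flatten_params(f1$model$params),
                   flatten_params(f2$model$params))
  f3 <- train(dual_model(ts$cfg, seed = 3), ts$dir,
              train_config(batch_size = 8, learning_rate = 1e-3,
                           epochs = 2, seed = 6, policy = aug_policy()))
  expect_false(identical(f1$log$loss, f3$log$loss))
})

test_that("training logs losses and accuracies per epoch", {
  ts <- tiny_setup()
  fit <- train(dual_model(ts$cfg, seed = 4), ts$dir,
               train_config(batch_size = 8, learning_rate = 1e-3,
                            epochs = 3, seed = 7))
  expect_equal(fit$log$epoch, 1:3)
  expect_true(all(is.finite(fit$log$loss)))
  expect_true(all(fit$log$train_accuracy >= 0 &
                    fit$log$train_accuracy <= 1))
})

test_that("evaluation accumulates a conserving confusion matrix", {
  ts <- tiny_setup()
  model <- dual_model(ts$cfg, seed = 5)
  man <- read_image_folder(ts$dir)
  cm <- evaluate(model, man)
  expect_equal(sum(cm), nrow(man))
  expect_equal(unname(rowSums(unclass(cm))),
               unname(as.vector(table(man$label))))
  # constant predictor: a zero head always predicts class 1 (tie -> lowest)
  modelc <- model
  modelc$params$head$W[] <- 0; modelc$params$head$b[] <- 0
  cmc <- evaluate(modelc, man)
  expect_equal(unname(unclass(cmc)[, 1]),
               unname(as.vector(table(man$label))))
  expect_equal(sum(unclass(cmc)[, -1]), 0)
})

test_that("feature export writes one fused row per image", {
  ts <- tiny_setup()
  model <- dual_model(ts$cfg, seed = 6)
  man <- read_image_folder(ts$dir)[1:4, ]
  out <- export_features(model, man)
  expect_equal(nrow(out), 4)
  expect_equal(ncol(out) - 2L, 2L * ts$cfg$feature_dim)
  # identical images yield identical rows
  man2 <- man[c(1, 1), ]
  out2 <- export_features(model, man2)
  expect_equal(unlist(out2[1, -1]), unlist(out2[2, -1]))
  # features change under different weights
  out3 <- export_features(dual_model(ts$cfg, seed = 7), man)
  expect_false(isTRUE(all.equal(out$f1, out3$f1)))
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  export_features(model, man, file = f)
  expect_equal(nrow(read.csv(f)), 4)
  unlink(f)
})

test_that("validation checkpointing keeps the best epoch", {
  ts <- tiny_setup()
  ck <- tempfile(fileext = ".rds")
  fit <- train(dual_model(ts$cfg, seed = 8), ts$dir,
               train_config(batch_size = 8, learning_rate = 1e-3,
                            epochs = 2, seed = 9, checkpoint_path = ck),
               val_data = ts$dir)
  expect_true(file.exists(ck))
  best <- load_checkpoint(ck)
  expect_equal(attr(best, "epoch"), fit$best_epoch)
  expect_false(is.na(attr(best, "val_accuracy")))
  unlink(ck)
})
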