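test_that("predictions live on the class-probability simplex", {
  cfg <- micro_config(num_classes = 5L)
  m <- dual_model(cfg, seed = 1)
  pred <- dual_forward(rand_image(8, seed = 2), m)
  expect_length(pred$probabilities, 5)
  expect_true(all(pred$probabilities >= 0))
  expect_equal(sum(pred$probabilities), 1, tolerance = 1e-6)
  expect_length(pred$features, 2 * cfg$feature_dim)
  # deterministic in eval mode
  expect_identical(dual_forward(rand_image(8, seed = 2), m)$probabilities,
                   pred$probabilities)
})

test_that("a zero head yields uniform class probabilities", {
  m <- dual_model(micro_config(num_classes = 5L), seed = 3)
  m$params$head$W[] <- 0; m$params$head$b[] <- 0
  pred <- dual_forward(rand_image(8, seed = 4), m)
  expect_equal(pred$probabilities, rep(0.2, 5), tolerance = 1e-12)
})

test_that("permuting head outputs permutes class probabilities", {
  m <- dual_model(micro_config(num_classes = 5L), seed = 5)
  img <- rand_image(8, seed = 6)
  p1 <- dual_forward(img, m)$probabilities
  perm <- c(3, 1, 5, 2, 4)
  m$params$head$W <- m$params$head$W[, perm]
  m$params$head$b <- m$params$head$b[perm]
  expect_equal(dual_forward(img, m)$probabilities, p1[perm],
               tolerance = 1e-12)
})

test_that("cross-entropy handles hard and soft targets", {
  # certain, correct prediction -> zero loss
  expect_equal(classification_loss(list(logits = c(1e4, 0, 0)), 1), 0)
  # uniform prediction over 22 classes -> ln 22
  expect_equal(classification_loss(list(logits = rep(0, 22)), 7), log(22),
               tolerance = 1e-12)
  # linear in the target
  lg <- list(logits = c(1.3, -0.2))
  mixed <- classification_loss(lg, c(0.6, 0.4))
  expect_equal(mixed, 0.6 * classification_loss(lg, 1) +
                 0.4 * classification_loss(lg, 2), tolerance = 1e-12)
  expect_gte(mixed, 0)
  expect_error(classification_loss(lg, 3), "outside")
  expect_error(classification_loss(lg, c(0.9, 0.9)), "simplex")
})

test_that("gradients flow into the Sobel kernels unless frozen", {
  cfg <- micro_config()
  m <- dual_model(cfg, seed = 7)
  res <- swinleaf:::dual_loss_backward(rand_image(8, seed = 8), m, 2L)
  expect_gt(max(abs(res$grads$sobel$gx)), 0)
  expect_gt(max(abs(res$grads$sobel$gy)), 0)
  mf <- dual_model(cfg, seed = 7, sobel_trainable = FALSE)
  resf <- swinleaf:::dual_loss_backward(rand_image(8, seed = 8), mf, 2L)
  expect_equal(resf$grads$sobel$gx, matrix(0, 3, 3))
})

test_that("channels share no parameters and diverge under training", {
  cfg <- micro_config()
  m <- dual_model(cfg, seed = 9)
  up <- flatten_params(m$params$upper)
  lo <- flatten_params(m$params$lower)
  # independently initialized
  expect_false(isTRUE(all.equal(up, lo)))
  # force identical starting channels, then take one gradient step
  m$params$lower <- m$params$upper
  res <- swinleaf:::dual_loss_backward(rand_image(8, seed = 10), m, 1L)
  flat <- flatten_params(m$params)
  g <- flatten_params(res$grads)
  stepped <- flat
  for (nm in names(flat)) stepped[[nm]] <- flat[[nm]] - 0.01 * g[[nm]]
  p2 <- unflatten_params(stepped)
  expect_false(isTRUE(all.equal(flatten_params(p2$upper),
                                flatten_params(p2$lower))))
})

test_that("zeroing the lower head contribution recovers a single channel", {
  cfg <- micro_config(num_classes = 4L)
  m <- dual_model(cfg, seed = 11)
  img <- rand_image(8, seed = 12)
  Fd <- cfg$feature_dim
  m$params$head$W[Fd + seq_len(Fd), ] <- 0
  pred <- dual_forward(img, m)
  up <- channel_forward(img, cfg, m$params$upper)
  logits <- as.vector(up$feature %*%
                        m$params$head$W[seq_len(Fd), ]) + m$params$head$b
  expect_equal(pred$logits, logits, tolerance = 1e-12)
})

test_that("pretrained import fills backbones, skips head and kernels", {
  cfg <- micro_config()
  donor <- dual_model(cfg, seed = 13)
  target <- dual_model(cfg, seed = 14)
  map <- swin_name_map(cfg)
  # build an archive in public checkpoint naming/layout from the donor
  donor_flat <- flatten_params(donor$params$upper)
  archive <- list()
  for (r in seq_len(nrow(map))) {
    v <- donor_flat[[map$ours[r]]]
    archive[[map$theirs[r]]] <- switch(map$kind[r],
      vector = v, matrix = v, linear = t(v),
      conv = {
        P <- cfg$patch_size; C <- cfg$embed_dim
        a <- array(0, c(C, 3, P, P))
        for (o in seq_len(C))
          a[o, , , ] <- aperm(array(v[, o], c(P, P, 3)), c(3, 2, 1))
        a
      })
  }
  archive$extraneous_entry <- 1:3
  loaded <- load_pretrained(target, archive, channel = "both")
  expect_equal(flatten_params(loaded$params$upper), donor_flat)
  expect_equal(flatten_params(loaded$params$lower), donor_flat)
  # head and sobel untouched by the archive
  expect_identical(loaded$params$head, target$params$head)
  expect_identical(loaded$params$sobel, target$params$sobel)
  rep <- attr(loaded, "report")
  expect_true("extraneous_entry" %in% rep$skipped)
  # shape mismatch is a hard error naming the parameter
  bad <- archive
  bad[["norm.weight"]] <- c(bad[["norm.weight"]], 0)
  expect_error(load_pretrained(target, bad), "norm.weight")
})

test_that("checkpoints round-trip through save and load", {
  cfg <- micro_config()
  m <- dual_model(cfg, seed = 15)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, class_names = c("a", "b", "c"), epoch = 4,
                  val_accuracy = 0.5)
  m2 <- load_checkpoint(path)
  expect_equal(flatten_params(m2$params), flatten_params(m$params))
  expect_equal(attr(m2, "class_names"), c("a", "b", "c"))
  img <- rand_image(8, seed = 16)
  expect_equal(dual_forward(img, m2)$logits, dual_forward(img, m)$logits)
  unlink(path)
})
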