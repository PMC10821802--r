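test_that("the encoded class distribution matches the benchmark totals", {
  man <- table2_manifest()
  expect_equal(nrow(man), 22)
  expect_equal(sum(man$train_count), 11603)
  expect_equal(sum(man$test_count), 1668)
  expect_equal(anyDuplicated(man$label_name), 0)
  expect_true(all(man$train_count > 0 & man$test_count > 0))
  # severity pairs: every "general" class has a "serious" partner
  gen <- sub(" general$", "", grep(" general$", man$label_name,
                                   value = TRUE))
  ser <- sub(" serious$", "", grep(" serious$", man$label_name,
                                   value = TRUE))
  expect_setequal(gen, ser)
})

test_that("default specs are distinct and severity-graded", {
  specs <- default_class_specs()
  expect_length(specs, 22)
  tuples <- vapply(specs, function(s)
    paste(s$hue, s$lesion_rate, s$lesion_hue), character(1))
  expect_equal(anyDuplicated(tuples), 0)
  for (s in specs) {
    if (s$severity == "healthy") expect_equal(s$lesion_rate, 0)
    else expect_gt(s$lesion_rate, 0)
  }
})

test_that("leaf rendering is deterministic and respects the spec", {
  spec <- default_class_specs()[["Apple_Scab general"]]
  img1 <- generate_leaf_image(spec, size = 64, seed = 5)
  img2 <- generate_leaf_image(spec, size = 64, seed = 5)
  expect_identical(img1, img2)
  expect_false(identical(
    img1, generate_leaf_image(spec, size = 64, seed = 6)))
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_equal(dim(img1), c(64, 64, 3))
  healthy <- generate_leaf_image(default_class_specs()[["Apple healthy"]],
                                 size = 64, seed = 5)
  expect_equal(sum(attr(healthy, "lesion_mask")), 0)
  expect_error(generate_leaf_image(spec, size = 16), "at least 32")
})

test_that("serious classes carry more lesion area than general ones", {
  specs <- default_class_specs()
  gen <- specs[["Peach_Bacterial Spot general"]]
  ser <- specs[["Peach_Bacterial Spot serious"]]
  frac <- function(spec, seed)
    mean(attr(generate_leaf_image(spec, size = 64, seed = seed),
              "lesion_mask"))
  seeds <- 1:20
  g <- vapply(seeds, function(s) frac(gen, s), numeric(1))
  s <- vapply(seeds, function(s) frac(ser, s), numeric(1))
  expect_gt(mean(s), mean(g))
  expect_gt(mean(s > g), 0.8)  # dominates at matched seeds too
})

test_that("lesions disperse across the blade, not a single cluster", {
  spec <- default_class_specs()[["Grape Black Rot Fungus serious"]]
  spreads <- baselines <- numeric(15)
  for (i in seq_along(spreads)) {
    mask <- attr(generate_leaf_image(spec, size = 64, seed = 100 + i),
                 "lesion_mask")
    px <- which(mask, arr.ind = TRUE) / 64
    spreads[i] <- sqrt(mean((px[, 1] - mean(px[, 1]))^2 +
                              (px[, 2] - mean(px[, 2]))^2))
    # single-cluster null: a solid disc holding the same total lesion
    # area has rms radius r_eq / sqrt(2); dispersed lesions must spread
    # wider than that on every draw
    r_eq <- sqrt(sum(mask) / pi) / 64
    baselines[i] <- r_eq / sqrt(2)
  }
  expect_true(all(spreads > baselines))
})

test_that("dataset generation writes exact counts deterministically", {
  man <- table2_manifest()[c(1, 2, 6), ]
  man$label_index <- 1:3
  class(man) <- c("class_manifest", "data.frame")
  dir1 <- file.path(tempdir(), "synth1")
  dir2 <- file.path(tempdir(), "synth2")
  unlink(c(dir1, dir2), recursive = TRUE)
  w1 <- generate_dataset(man, scale = 0.01, out_dir = dir1, seed = 9,
                         size = 32)
  w2 <- generate_dataset(man, scale = 0.01, out_dir = dir2, seed = 9,
                         size = 32)
  # ceil(scale * count): train 12, 3, 1; test 2, 1, 1
  expect_equal(w1$count[w1$split == "train"],
               ceiling(0.01 * man$train_count))
  expect_equal(w1$count[w1$split == "test"],
               ceiling(0.01 * man$test_count))
  expect_true(all(w1$count >= 1))
  files1 <- list.files(dir1, recursive = TRUE, pattern = "\\.png$")
  files2 <- list.files(dir2, recursive = TRUE, pattern = "\\.png$")
  expect_equal(files1, files2)
  expect_equal(length(files1), sum(w1$count))
  # identical bytes under the same seed
  h1 <- vapply(file.path(dir1, files1), function(f)
    digest_file(f), character(1))
  h2 <- vapply(file.path(dir2, files2), function(f)
    digest_file(f), character(1))
  expect_identical(unname(h1), unname(h2))
  # train and test trees are disjoint
  expect_length(intersect(list.files(file.path(dir1, "train"),
                                     recursive = TRUE),
                          list.files(file.path(dir1, "test"),
                                     recursive = TRUE)), 0)
  man_csv <- read.csv(file.path(dir1, "manifest.csv"))
  expect_equal(nrow(man_csv), 6)
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("generated classes are separable by a trivial classifier", {
  # nearest-centroid on mean color plus the lesion-colored pixel
  # fraction must solve a 2-class, 16-image set: the fixtures carry
  # learnable signal
  dir <- file.path(tempdir(), "sep")
  unlink(dir, recursive = TRUE)
  make_smoke_dataset(dir, seed = 21)
  man <- read_image_folder(file.path(dir, "train"))
  feats <- t(vapply(man$path, function(p) {
    img <- load_image(p)
    c(apply(img, 3, mean), mean(img[, , 1] - img[, , 2] > 0.12))
  }, numeric(4)))
  cents <- rbind(colMeans(feats[man$label == 1, ]),
                 colMeans(feats[man$label == 2, ]))
  pred <- apply(feats, 1, function(f)
    which.min(c(sum((f - cents[1, ])^2), sum((f - cents[2, ])^2))))
  expect_gte(mean(pred == man$label), 0.95)
  unlink(dir, recursive = TRUE)
})
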