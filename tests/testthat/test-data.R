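test_that("annotation files round-trip and validate", {
  tmp <- tempfile(fileext = ".json")
  writeLines('[{"image_path":"a.ppm","disease_class":0},
               {"image_path":"b.ppm","disease_class":60}]', tmp)
  rec <- read_annotations(tmp)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$disease_class, c(0L, 60L))

  writeLines("[]", tmp)
  expect_equal(nrow(read_annotations(tmp)), 0)

  # 10-entry fixture: histogram equals an independent tally
  set.seed(81)
  cls <- sample(0:4, 10, TRUE)
  df <- data.frame(image_path = sprintf("img%02d.ppm", 1:10),
                   disease_class = cls)
  write_annotations(df, tmp)
  back <- read_annotations(tmp, num_classes = 5)
  expect_equal(back$image_path, df$image_path)
  expect_equal(back$disease_class, df$disease_class)
  expect_equal(attr(back, "class_histogram"),
               vapply(0:4, function(k) sum(cls == k), integer(1)))

  writeLines('[{"image_path":"a.ppm"}]', tmp)
  expect_error(read_annotations(tmp), "disease_class")
  writeLines('[{"image_path":"a.ppm","disease_class":61}]', tmp)
  expect_error(read_annotations(tmp), "out of range")
  unlink(tmp)
})

test_that("the synthetic generator is deterministic and correctly sized", {
  empty <- generate_synthetic_dataset(
    synthetic_dataset_spec(samples_per_class = 0))
  expect_equal(length(empty$y), 0)

  spec <- synthetic_dataset_spec(num_classes = 5, samples_per_class = 40,
                                 image_size = 32, seed = 2022)
  d1 <- generate_synthetic_dataset(spec)
  expect_equal(dim(d1$x), c(200, 3, 32, 32))
  expect_equal(as.vector(table(d1$y)), rep(40L, 5))
  expect_true(all(d1$x >= 0 & d1$x <= 1))
  d2 <- generate_synthetic_dataset(spec)
  expect_identical(d1$x, d2$x)
  d3 <- generate_synthetic_dataset(
    synthetic_dataset_spec(num_classes = 5, samples_per_class = 40,
                           image_size = 32, seed = 2023))
  expect_false(identical(d1$x, d3$x))
  # distinct classes have distinct lesion parameters
  cols <- t(vapply(spec$blob_params, function(b) b$rgb, numeric(3)))
  expect_equal(nrow(unique(cols)), 5)
})

test_that("written datasets carry both layouts, checksums, and re-read identically", {
  spec <- synthetic_dataset_spec(num_classes = 3, samples_per_class = 4,
                                 image_size = 16, seed = 7)
  dir1 <- file.path(tempdir(), "synth1")
  dir2 <- file.path(tempdir(), "synth2")
  unlink(c(dir1, dir2), recursive = TRUE)
  generate_synthetic_dataset(spec, dir = dir1)
  generate_synthetic_dataset(spec, dir = dir2)
  man1 <- jsonlite::fromJSON(file.path(dir1, "manifest.json"))
  man2 <- jsonlite::fromJSON(file.path(dir2, "manifest.json"))
  expect_equal(man1$files$md5, man2$files$md5)  # byte-identical regeneration
  expect_equal(nrow(man1$files), 12)

  via_ann <- load_image_dataset(file.path(dir1, "annotations.json"),
                                num_classes = 3)
  unlink(file.path(dir1, "annotations.json"))
  via_dirs <- load_image_dataset(dir1, num_classes = 3)
  expect_equal(sort(via_ann$y), sort(via_dirs$y))
  expect_equal(dim(via_ann$x), c(12, 3, 16, 16))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("ASCII PPM images survive a write/read cycle to 8-bit precision", {
  set.seed(82)
  img <- array(runif(10 * 7 * 3), c(10, 7, 3))
  tmp <- tempfile(fileext = ".ppm")
  write_ppm(img, tmp)
  back <- read_ppm(tmp)
  expect_equal(dim(back), c(10, 7, 3))
  expect_lt(max(abs(back - img)), 0.5 / 255 + 1e-9)
  unlink(tmp)
})

test_that("transforms produce normalized 3x224x224 tensors from any aspect ratio", {
  set.seed(83)
  for (d in list(c(256, 256), c(320, 260), c(260, 320), c(400, 640))) {
    img <- array(runif(prod(d) * 3), c(d, 3))
    t1 <- eval_transform(img)
    expect_equal(dim(t1), c(3, 224, 224))
    expect_identical(t1, eval_transform(img))  # no randomness
  }
  # constant gray maps to the per-channel constant (0.5 - mean) / sd
  gray <- array(0.5, c(256, 256, 3))
  tg <- eval_transform(gray)
  for (ch in 1:3)
    expect_equal(unique(as.vector(tg[ch, , ])),
                 (0.5 - c(0.485, 0.456, 0.406)[ch]) /
                   c(0.229, 0.224, 0.225)[ch], tolerance = 1e-12)
  expect_warning(eval_transform(array(0.2, c(100, 100, 3))), "upscal")
  expect_warning(eval_transform(matrix(0.3, 256, 256)), "non-RGB")
})

test_that("horizontal flips match column reversal and are seed-deterministic", {
  set.seed(84)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  img[, 1:128, 1] <- 1  # left-right asymmetric pattern
  flipped <- esaresnet:::hflip(img)
  expect_equal(flipped, img[, 256:1, , drop = FALSE])
  expect_equal(esaresnet:::hflip(flipped), img)

  set.seed(99)
  a <- train_transform(img)
  set.seed(99)
  b <- train_transform(img)
  expect_identical(a, b)
  # over many draws both orientations occur
  set.seed(100)
  outs <- replicate(20, sum(train_transform(img)[1, 1, 1:10]))
  expect_gt(length(unique(round(outs, 6))), 1)
})

test_that("denormalizing recovers the cropped pixels", {
  set.seed(85)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  t1 <- eval_transform(img)
  rec <- denormalize(t1)
  expect_equal(rec, esaresnet:::center_crop(img, 224), tolerance = 1e-8)
})

test_that("synthetic classes are separable by a nearest-mean-color rule", {
  ds <- tiny_synthetic(samples_per_class = 20)
  feats <- t(apply(ds$x, 1, function(a) c(mean(a[1, , ]), mean(a[2, , ]),
                                          mean(a[3, , ]))))
  train_ix <- seq(1, 100, by = 2)
  centroids <- sapply(0:4, function(k) {
    colMeans(feats[intersect(train_ix, which(ds$y == k)), , drop = FALSE])
  })
  test_ix <- setdiff(1:100, train_ix)
  pred <- apply(feats[test_ix, ], 1, function(f) {
    which.min(colSums((centroids - f)^2)) - 1L
  })
  expect_gt(mean(pred == ds$y[test_ix]), 0.5)  # chance is 0.2
})
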