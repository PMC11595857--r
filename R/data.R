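#' Specification of a synthetic lesion-image dataset
#'
#' A parametric stand-in for real crop pest/disease photographs used to
#' test the full pipeline without downloads: every class is a distinct
#' "lesion" pattern — a class-specific number of soft-edged colored blobs
#' on a noisy leaf-green background.  Generation is fully deterministic
#' given `seed`.
#'
#' @param num_classes number of disease classes.
#' @param samples_per_class images generated per class (0 gives an empty,
#'   still valid, dataset).
#' @param image_size side length of the square images, pixels.
#' @param noise_sd pixel noise standard deviation (intensity units,
#'   images live in `[0, 1]`).
#' @param seed integer seed; equal specs regenerate byte-identical data.
#' @param blob_params optional list (length `num_classes`) of per-class
#'   lesion parameters, each a list with `count`, `radius_range` (pixels)
#'   and `rgb` (length-3 mean color).  Defaults place the classes at
#'   distinct hues with distinct blob counts.
#' @return a `synthetic_dataset_spec` list.
#' @export
synthetic_dataset_spec <- function(num_classes = 5L,
                                   samples_per_class = 40L,
                                   image_size = 32L,
                                   noise_sd = 0.05,
                                   seed = 2022L,
                                   blob_params = NULL) {
  assert_positive_int(num_classes, "num_classes")
  assert_positive_int(image_size, "image_size")
  if (samples_per_class < 0 || samples_per_class != floor(samples_per_class))
    stop("`samples_per_class` must be a non-negative integer", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (is.null(blob_params)) {
    blob_params <- lapply(seq_len(num_classes) - 1L, function(k) {
      rgb <- grDevices::col2rgb(grDevices::hsv(k / num_classes, 0.85,
                                               0.9))[, 1] / 255
      list(count = 2L + (k %% 4L),
           radius_range = image_size * c(0.10, 0.20),
           rgb = unname(rgb))
    })
  }
  if (length(blob_params) != num_classes)
    stop("`blob_params` must have one entry per class", call. = FALSE)
  structure(list(num_classes = as.integer(num_classes),
                 samples_per_class = as.integer(samples_per_class),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 blob_params = blob_params),
            class = "synthetic_dataset_spec")
}

synth_one_image <- function(size, bp, noise_sd) {
  base <- c(0.32, 0.48, 0.28)  # leaf green
  img <- array(rep(base, each = size * size), c(size, size, 3)) +
    array(rnorm(size * size * 3, sd = noise_sd), c(size, size, 3))
  xs <- matrix(rep(seq_len(size), size), size)
  ys <- t(xs)
  for (b in seq_len(bp$count)) {
    cx <- runif(1, 0.15 * size, 0.85 * size)
    cy <- runif(1, 0.15 * size, 0.85 * size)
    r <- runif(1, bp$radius_range[1], bp$radius_range[2])
    w <- exp(-((xs - cx)^2 + (ys - cy)^2) / (0.5 * r^2))
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - w) + w * bp$rgb[ch]
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labeled image set
#'
#' Produces `num_classes * samples_per_class` images.  When `dir` is
#' given, the dataset is also written to disk in both supported layouts:
#' a directory per class of plain-text PPM images, a JSON annotation file
#' (`annotations.json`), and a manifest (`manifest.json`) recording the
#' generating spec and per-file MD5 checksums.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param dir optional output directory.
#' @return list with `x` (array `N x 3 x H x W`, values in `[0, 1]`), `y`
#'   (integer labels in `[0, num_classes)`), `spec`, and `dir` (when
#'   written).
#' @export
generate_synthetic_dataset <- function(spec, dir = NULL) {
  if (!inherits(spec, "synthetic_dataset_spec"))
    stop("`spec` must be a synthetic_dataset_spec()", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set_global_seed(spec$seed)

  n <- spec$num_classes * spec$samples_per_class
  sz <- spec$image_size
  x <- array(0, c(n, 3, sz, sz))
  y <- integer(n)
  i <- 0L
  for (k in seq_len(spec$num_classes) - 1L) {
    for (s in seq_len(spec$samples_per_class)) {
      i <- i + 1L
      img <- synth_one_image(sz, spec$blob_params[[k + 1L]], spec$noise_sd)
      x[i, , , ] <- aperm(img, c(3, 1, 2))
      y[i] <- k
    }
  }
  ds <- list(x = x, y = y, spec = spec)
  if (!is.null(dir)) {
    write_synthetic_dataset(ds, dir)
    ds$dir <- dir
  }
  ds
}

write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$y)
  paths <- character(n)
  for (i in seq_len(n)) {
    cls_dir <- file.path(dir, sprintf("class_%02d", ds$y[i]))
    dir.create(cls_dir, showWarnings = FALSE)
    paths[i] <- file.path(sprintf("class_%02d", ds$y[i]),
                          sprintf("img_%04d.ppm", i))
    write_ppm(aperm(ds$x[i, , , ], c(2, 3, 1)), file.path(dir, paths[i]))
  }
  ann <- data.frame(image_path = paths, disease_class = ds$y,
                    stringsAsFactors = FALSE)
  write_annotations(ann, file.path(dir, "annotations.json"))
  sums <- tools::md5sum(file.path(dir, paths))
  manifest <- list(spec = unclass(ds$spec),
                   files = data.frame(path = paths,
                                      md5 = unname(sums),
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---- annotations -----------------------------------------------------------

#' Read a JSON annotation file
#'
#' The annotation dialect is a JSON array of objects, each holding an
#' image path/identifier and an integer disease class in
#' `[0, num_classes)`.  The class histogram is attached as an attribute
#' (the real dataset is known to be imbalanced).
#'
#' @param path annotation file.
#' @param num_classes label-space size used for range validation.
#' @return data.frame with columns `image_path` and `disease_class`, with
#'   attribute `class_histogram`.
#' @export
read_annotations <- function(path, num_classes = 61L) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(raw) == 0)
    return(structure(data.frame(image_path = character(0),
                                disease_class = integer(0)),
                     class_histogram = integer(num_classes)))
  if (is.null(raw$image_path) && !is.null(raw$image_id))
    raw$image_path <- raw$image_id
  for (field in c("image_path", "disease_class")) {
    if (is.null(raw[[field]]))
      stop(sprintf("annotation entries lack the `%s` field", field),
           call. = FALSE)
    missing_at <- which(is.na(raw[[field]]))
    if (length(missing_at))
      stop(sprintf("annotation entry %d is missing `%s`", missing_at[1],
                   field), call. = FALSE)
  }
  cls <- raw$disease_class
  check_labels(cls, num_classes)
  out <- data.frame(image_path = as.character(raw$image_path),
                    disease_class = as.integer(cls),
                    stringsAsFactors = FALSE)
  attr(out, "class_histogram") <-
    as.integer(table(factor(cls, levels = 0:(num_classes - 1))))
  out
}

#' Write a JSON annotation file
#'
#' @param records data.frame with `image_path` and `disease_class`.
#' @param path output file.
#' @export
write_annotations <- function(records, path) {
  jsonlite::write_json(records[, c("image_path", "disease_class")], path,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an image dataset from disk
#'
#' Accepts either a JSON annotation file (paths resolved relative to its
#' directory) or a directory-per-class layout (subdirectories named
#' `class_<k>` or `<k>`).
#'
#' @param path annotation file or dataset directory.
#' @param num_classes label-space size.
#' @return dataset list with `x` (`N x 3 x H x W`) and `y`; all images
#'   must share one size.
#' @export
load_image_dataset <- function(path, num_classes = 61L) {
  if (dir.exists(path) && !file.exists(file.path(path, "annotations.json"))) {
    dirs <- list.dirs(path, recursive = FALSE)
    records <- do.call(rbind, lapply(dirs, function(d) {
      cls <- suppressWarnings(as.integer(sub("^class_", "", basename(d))))
      if (is.na(cls)) return(NULL)
      files <- list.files(d, pattern = "\\.ppm$", full.names = FALSE)
      if (!length(files)) return(NULL)
      data.frame(image_path = file.path(basename(d), files),
                 disease_class = cls, stringsAsFactors = FALSE)
    }))
    base <- path
  } else {
    ann_path <- if (dir.exists(path)) file.path(path, "annotations.json")
                else path
    records <- read_annotations(ann_path, num_classes)
    base <- dirname(ann_path)
  }
  if (is.null(records) || nrow(records) == 0)
    return(list(x = array(0, c(0, 3, 0, 0)), y = integer(0)))
  imgs <- lapply(file.path(base, records$image_path), read_ppm)
  d <- dim(imgs[[1]])
  x <- array(0, c(length(imgs), 3, d[1], d[2]))
  for (i in seq_along(imgs)) x[i, , , ] <- aperm(imgs[[i]], c(3, 1, 2))
  list(x = x, y = records$disease_class)
}

# ---- plain-text image format ----------------------------------------------
# ASCII PPM (P3) keeps every fixture in a text format; no image-IO package
# is available in the target environment, and the format is trivial.

#' Read / write ASCII PPM images
#'
#' @param img array `(H, W, 3)` with values in `[0, 1]`.
#' @param path file path.
#' @param maxval sample depth (255).
#' @return `read_ppm()` returns an `(H, W, 3)` array in `[0, 1]`.
#' @export
write_ppm <- function(img, path, maxval = 255L) {
  d <- dim(img)
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  # pixel order: rows top to bottom, R G B per pixel
  px <- aperm(vals, c(3, 2, 1))  # (channel, col, row) -> row-major stream
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), as.character(maxval)), con)
  writeLines(paste(as.integer(px), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P3") stop("only ASCII (P3) PPM is supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)]) / maxval
  if (length(vals) != w * h * 3)
    stop("truncated PPM payload", call. = FALSE)
  aperm(array(vals, c(3, w, h)), c(3, 2, 1))
}

# ---- transforms ------------------------------------------------------------

imagenet_mean <- c(0.485, 0.456, 0.406)
imagenet_sd <- c(0.229, 0.224, 0.225)

resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  interp_axis <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    frac <- src - lo
    list(lo = as.integer(lo) + 1L,
         hi = pmin(as.integer(lo) + 2L, n_in), frac = frac)
  }
  ay <- interp_axis(d[1], out_h)
  ax <- interp_axis(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    rows <- m[ay$lo, , drop = FALSE] * (1 - ay$frac) +
      m[ay$hi, , drop = FALSE] * ay$frac
    out[, , ch] <- rows[, ax$lo, drop = FALSE] %*% diag(1 - ax$frac, out_w) +
      rows[, ax$hi, drop = FALSE] %*% diag(ax$frac, out_w)
  }
  out
}

center_crop <- function(img, size) {
  d <- dim(img)
  oy <- (d[1] - size) %/% 2L
  ox <- (d[2] - size) %/% 2L
  img[oy + seq_len(size), ox + seq_len(size), , drop = FALSE]
}

hflip <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

prepare_rgb <- function(image, output_size) {
  d <- dim(image)
  if (length(d) == 2) {
    warning("non-RGB input converted to 3 channels", call. = FALSE)
    image <- array(rep(image, 3), c(d, 3))
    d <- dim(image)
  }
  if (min(d[1:2]) < output_size)
    warning(sprintf("image (%dx%d) smaller than the %d crop; upscaling",
                    d[1], d[2], output_size), call. = FALSE)
  image
}

transform_core <- function(image, output_size, resize_shorter, flip,
                           mean, sd) {
  image <- prepare_rgb(image, output_size)
  d <- dim(image)
  scale <- resize_shorter / min(d[1:2])
  image <- resize_bilinear(image, round(d[1] * scale), round(d[2] * scale))
  image <- center_crop(image, output_size)
  if (flip) image <- hflip(image)
  chw <- aperm(image, c(3, 1, 2))
  (chw - array(mean, dim(chw))) / array(sd, dim(chw))
}

#' Image transforms for training and evaluation
#'
#' Both resize the shorter image side to `resize_shorter`, take the
#' central `output_size` crop, and channel-normalize.  The training
#' variant additionally flips horizontally with probability 1/2 (drawn
#' from the global RNG, hence seed-controlled).
#'
#' @param image `(H, W, 3)` array with values in `[0, 1]` (a 2-d matrix is
#'   converted to grayscale RGB with a warning).
#' @param output_size crop size (default 224).
#' @param resize_shorter resize target for the shorter side (default 256).
#' @param mean,sd per-channel normalization constants (ImageNet defaults).
#' @return normalized `(3, output_size, output_size)` array.
#' @export
train_transform <- function(image, output_size = 224L,
                            resize_shorter = 256L,
                            mean = imagenet_mean, sd = imagenet_sd) {
  transform_core(image, output_size, resize_shorter,
                 flip = runif(1) < 0.5, mean = mean, sd = sd)
}

#' @rdname train_transform
#' @export
eval_transform <- function(image, output_size = 224L,
                           resize_shorter = 256L,
                           mean = imagenet_mean, sd = imagenet_sd) {
  transform_core(image, output_size, resize_shorter, flip = FALSE,
                 mean = mean, sd = sd)
}

#' Invert the normalization of a transformed tensor
#'
#' @param tensor `(3, H, W)` array from [train_transform()] or
#'   [eval_transform()].
#' @param mean,sd the constants used in the forward transform.
#' @return `(H, W, 3)` array of pixel intensities.
#' @export
denormalize <- function(tensor, mean = imagenet_mean, sd = imagenet_sd) {
  aperm(tensor * array(sd, dim(tensor)) + array(mean, dim(tensor)),
        c(2, 3, 1))
}
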