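#' Declarative architecture specification for the ESA residual classifier
#'
#' Describes the 34-layer residual backbone and the two lightweight
#' modifications studied here: per-block effective spatial attention (ESA)
#' gates and the replacement of every stage 3x3 convolution by a
#' depthwise + pointwise pair.  With both flags off and `dropout_rate = 0`
#' the spec denotes a standard ResNet34.
#'
#' @param stage_block_counts integer vector of length 4, residual blocks
#'   per stage (default `c(3, 4, 6, 3)`).
#' @param stage_widths integer vector of length 4, channel widths per
#'   stage; must double from stage to stage (default `c(64, 128, 256, 512)`).
#' @param num_classes number of output classes (default 61, the crop
#'   pest/disease label space).
#' @param use_esa insert ESA gates (per [esa_config()]'s placement).
#' @param use_depthwise replace the stage 3x3 convolutions by depthwise +
#'   pointwise pairs.  The 7x7 stem and the 1x1 downsample projections are
#'   never replaced.
#' @param dropout_rate dropout probability between the global pooling and
#'   the linear head, in `[0, 1)`.
#' @param esa an [esa_config()].
#' @param norm_after_depthwise also place a batch norm + ReLU between the
#'   depthwise and pointwise convolutions (MobileNet style).  The shipped
#'   default (`FALSE`, a single norm after the pointwise convolution) is
#'   the variant frozen against the published complexity audit.
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(stage_block_counts = c(3L, 4L, 6L, 3L),
                              stage_widths = c(64L, 128L, 256L, 512L),
                              num_classes = 61L,
                              use_esa = TRUE,
                              use_depthwise = TRUE,
                              dropout_rate = 0.5,
                              esa = esa_config(),
                              norm_after_depthwise = FALSE) {
  if (length(stage_block_counts) != 4 || any(stage_block_counts < 1))
    stop("`stage_block_counts` must be 4 integers >= 1", call. = FALSE)
  if (length(stage_widths) != 4)
    stop("`stage_widths` must have length 4", call. = FALSE)
  if (any(diff(stage_widths) <= 0) ||
      !all(stage_widths[-1] == 2L * stage_widths[-4]))
    stop("`stage_widths` must be strictly increasing and doubling",
         call. = FALSE)
  assert_positive_int(num_classes, "num_classes")
  if (num_classes < 2)
    stop("`num_classes` must be >= 2", call. = FALSE)
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  if (!inherits(esa, "esa_config"))
    stop("`esa` must be an esa_config()", call. = FALSE)
  structure(list(stage_block_counts = as.integer(stage_block_counts),
                 stage_widths = as.integer(stage_widths),
                 num_classes = as.integer(num_classes),
                 use_esa = isTRUE(use_esa),
                 use_depthwise = isTRUE(use_depthwise),
                 dropout_rate = dropout_rate,
                 esa = esa,
                 norm_after_depthwise = isTRUE(norm_after_depthwise)),
            class = "architecture_spec")
}

add_conv <- function(b, name, input, in_ch, out_ch, kernel, stride = 1L,
                     pad = 0L, groups = 1L, bias = FALSE) {
  b$add("conv", name, input, in_ch = as.integer(in_ch),
        out_ch = as.integer(out_ch), kernel = as.integer(kernel),
        stride = as.integer(stride), pad = as.integer(pad),
        groups = as.integer(groups), bias = bias)
}

add_bn <- function(b, name, input, channels) {
  b$add("bn", name, input, channels = as.integer(channels))
}

# One 3x3 "convolution slot" of a residual block: a standard convolution,
# or (use_depthwise) a 3x3 depthwise convolution carrying the stride
# followed by a 1x1 pointwise convolution.
add_conv3x3_slot <- function(b, prefix, input, in_ch, out_ch, stride,
                             use_depthwise, norm_after_depthwise) {
  if (!use_depthwise) {
    return(add_conv(b, paste0(prefix, ".conv"), input, in_ch, out_ch, 3L,
                    stride = stride, pad = 1L))
  }
  cur <- add_conv(b, paste0(prefix, ".dw"), input, in_ch, in_ch, 3L,
                  stride = stride, pad = 1L, groups = in_ch)
  if (norm_after_depthwise) {
    cur <- add_bn(b, paste0(prefix, ".dwbn"), cur, in_ch)
    cur <- b$add("relu", paste0(prefix, ".dwrelu"), cur)
  }
  add_conv(b, paste0(prefix, ".pw"), cur, in_ch, out_ch, 1L)
}

add_basic_block <- function(b, prefix, input, in_ch, out_ch, stride, spec) {
  cur <- add_conv3x3_slot(b, paste0(prefix, ".c1"), input, in_ch, out_ch,
                          stride, spec$use_depthwise,
                          spec$norm_after_depthwise)
  cur <- add_bn(b, paste0(prefix, ".bn1"), cur, out_ch)
  cur <- b$add("relu", paste0(prefix, ".relu1"), cur)
  cur <- add_conv3x3_slot(b, paste0(prefix, ".c2"), cur, out_ch, out_ch, 1L,
                          spec$use_depthwise, spec$norm_after_depthwise)
  cur <- add_bn(b, paste0(prefix, ".bn2"), cur, out_ch)
  if (spec$use_esa && spec$esa$placement == "per_block_pre_add") {
    cur <- b$add("esa", paste0(prefix, ".esa"), cur,
                 channels = as.integer(out_ch),
                 kernel = spec$esa$kernel_size,
                 pool = spec$esa$pool_kind, bias = spec$esa$bias)
  }
  skip <- input
  if (stride != 1L || in_ch != out_ch) {
    skip <- add_conv(b, paste0(prefix, ".down"), input, in_ch, out_ch, 1L,
                     stride = stride)
    skip <- add_bn(b, paste0(prefix, ".downbn"), skip, out_ch)
  }
  cur <- b$add("add", paste0(prefix, ".add"), c(cur, skip))
  b$add("relu", paste0(prefix, ".relu2"), cur)
}

#' Build a standalone residual block
#'
#' Mainly a testing and inspection convenience: returns the block described
#' by `spec`'s toggles as a small layer graph of its own (with its own
#' input node), so that shapes and parameter counts of a single block can
#' be examined.
#'
#' @param in_ch,out_ch input/output channel counts.
#' @param stride 1 or 2; a stride of 2 halves the spatial dimensions and is
#'   carried by the depthwise convolution when `spec$use_depthwise`.
#' @param spec an [architecture_spec()].
#' @return an `nn_model` (uninitialized) wrapping the block graph.
#' @export
make_ds_block <- function(in_ch, out_ch, stride = 1L,
                          spec = architecture_spec()) {
  if (!stride %in% c(1L, 2L)) stop("`stride` must be 1 or 2", call. = FALSE)
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  add_basic_block(b, "block", cur, in_ch, out_ch, stride, spec)
  new_nn_model(b$graph(), name = "ds_block", spec = spec)
}

#' Assemble the ESA residual classifier
#'
#' Builds the 34-layer residual classifier described by `spec`: a 7x7
#' stride-2 stem, a 3x3 stride-2 max pool, four stages of residual blocks,
#' global average pooling, dropout and a linear head.  With
#' `use_esa = FALSE`, `use_depthwise = FALSE` and `dropout_rate = 0` the
#' result is a standard ResNet34.
#'
#' @param spec an [architecture_spec()].
#' @param initialize instantiate trainable parameters (seeded from the
#'   current RNG state); set `FALSE` when the model is only profiled.
#' @return an `nn_model`.
#' @export
#' @examples
#' set.seed(1)
#' tiny <- architecture_spec(stage_block_counts = c(1, 1, 1, 1),
#'                           stage_widths = c(8, 16, 32, 64),
#'                           num_classes = 5, dropout_rate = 0)
#' m <- build_esa_resnet34(tiny)
#' logits <- predict(m, array(rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32)))
#' dim(logits)  # 2 x 5
build_esa_resnet34 <- function(spec = architecture_spec(),
                               initialize = TRUE) {
  if (!inherits(spec, "architecture_spec"))
    stop("`spec` must be an architecture_spec()", call. = FALSE)
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  w <- spec$stage_widths
  cur <- add_conv(b, "stem.conv", cur, 3L, w[1], 7L, stride = 2L, pad = 3L)
  cur <- add_bn(b, "stem.bn", cur, w[1])
  cur <- b$add("relu", "stem.relu", cur)
  cur <- b$add("maxpool", "stem.pool", cur, kernel = 3L, stride = 2L,
               pad = 1L)
  in_ch <- w[1]
  for (s in 1:4) {
    for (blk in seq_len(spec$stage_block_counts[s])) {
      stride <- if (s > 1 && blk == 1) 2L else 1L
      cur <- add_basic_block(b, sprintf("stage%d.block%d", s, blk), cur,
                             in_ch, w[s], stride, spec)
      in_ch <- w[s]
    }
    if (spec$use_esa && spec$esa$placement == "per_stage_exit") {
      cur <- b$add("esa", sprintf("stage%d.esa", s), cur,
                   channels = in_ch, kernel = spec$esa$kernel_size,
                   pool = spec$esa$pool_kind, bias = spec$esa$bias)
    }
  }
  cur <- b$add("gap", "head.gap", cur)
  if (spec$dropout_rate > 0)
    cur <- b$add("dropout", "head.dropout", cur, rate = spec$dropout_rate)
  b$add("linear", "head.fc", cur, in_features = in_ch,
        out_features = spec$num_classes, bias = TRUE)
  model <- new_nn_model(b$graph(), name = "esa_resnet34", spec = spec)
  if (initialize) model <- init_model_params(model)
  model
}

reference_model_names <- function() {
  c("alexnet", "vgg16", "densenet121", "resnet18", "resnet34", "resnet50",
    "resnet101", "resnet152", "mobilenet")
}

#' Build a reference classification architecture
#'
#' Standard published architectures (as shipped by the usual vision model
#' zoo) with the final classification layer resized to `num_classes`.
#' These serve as baselines for the complexity audit; they are returned
#' uninitialized (description only) unless `initialize = TRUE`.
#'
#' @param name one of `"alexnet"`, `"vgg16"`, `"densenet121"`,
#'   `"resnet18"`, `"resnet34"`, `"resnet50"`, `"resnet101"`,
#'   `"resnet152"`, `"mobilenet"` (MobileNetV2).
#' @param num_classes size of the classification head (default 61).
#' @param initialize instantiate parameters (only supported for
#'   architectures the runtime engine can execute).
#' @return an `nn_model`.
#' @export
build_reference_model <- function(name, num_classes = 61L,
                                  initialize = FALSE) {
  valid <- reference_model_names()
  if (length(name) != 1 || !name %in% valid)
    stop("unknown model name ", deparse(name), "; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  assert_positive_int(num_classes, "num_classes")
  graph <- switch(name,
    alexnet = build_alexnet_graph(num_classes),
    vgg16 = build_vgg16_graph(num_classes),
    densenet121 = build_densenet121_graph(num_classes),
    resnet18 = build_resnet_graph(c(2L, 2L, 2L, 2L), FALSE, num_classes),
    resnet34 = build_resnet_graph(c(3L, 4L, 6L, 3L), FALSE, num_classes),
    resnet50 = build_resnet_graph(c(3L, 4L, 6L, 3L), TRUE, num_classes),
    resnet101 = build_resnet_graph(c(3L, 4L, 23L, 3L), TRUE, num_classes),
    resnet152 = build_resnet_graph(c(3L, 8L, 36L, 3L), TRUE, num_classes),
    mobilenet = build_mobilenet_v2_graph(num_classes))
  model <- new_nn_model(graph, name = name, spec = NULL)
  if (initialize) model <- init_model_params(model)
  model
}

build_resnet_graph <- function(depths, bottleneck, num_classes) {
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  widths <- c(64L, 128L, 256L, 512L)
  expansion <- if (bottleneck) 4L else 1L
  cur <- add_conv(b, "stem.conv", cur, 3L, 64L, 7L, stride = 2L, pad = 3L)
  cur <- add_bn(b, "stem.bn", cur, 64L)
  cur <- b$add("relu", "stem.relu", cur)
  cur <- b$add("maxpool", "stem.pool", cur, kernel = 3L, stride = 2L,
               pad = 1L)
  in_ch <- 64L
  plain_spec <- architecture_spec(num_classes = num_classes,
                                  use_esa = FALSE, use_depthwise = FALSE,
                                  dropout_rate = 0)
  for (s in 1:4) {
    for (blk in seq_len(depths[s])) {
      stride <- if (s > 1 && blk == 1) 2L else 1L
      prefix <- sprintf("stage%d.block%d", s, blk)
      if (!bottleneck) {
        cur <- add_basic_block(b, prefix, cur, in_ch, widths[s], stride,
                               plain_spec)
        in_ch <- widths[s]
      } else {
        width <- widths[s]
        out_ch <- width * expansion
        x1 <- add_conv(b, paste0(prefix, ".conv1"), cur, in_ch, width, 1L)
        x1 <- add_bn(b, paste0(prefix, ".bn1"), x1, width)
        x1 <- b$add("relu", paste0(prefix, ".relu1"), x1)
        x1 <- add_conv(b, paste0(prefix, ".conv2"), x1, width, width, 3L,
                       stride = stride, pad = 1L)
        x1 <- add_bn(b, paste0(prefix, ".bn2"), x1, width)
        x1 <- b$add("relu", paste0(prefix, ".relu2"), x1)
        x1 <- add_conv(b, paste0(prefix, ".conv3"), x1, width, out_ch, 1L)
        x1 <- add_bn(b, paste0(prefix, ".bn3"), x1, out_ch)
        skip <- cur
        if (stride != 1L || in_ch != out_ch) {
          skip <- add_conv(b, paste0(prefix, ".down"), cur, in_ch, out_ch,
                           1L, stride = stride)
          skip <- add_bn(b, paste0(prefix, ".downbn"), skip, out_ch)
        }
        x1 <- b$add("add", paste0(prefix, ".add"), c(x1, skip))
        cur <- b$add("relu", paste0(prefix, ".relu3"), x1)
        in_ch <- out_ch
      }
    }
  }
  cur <- b$add("gap", "head.gap", cur)
  b$add("linear", "head.fc", cur, in_features = in_ch,
        out_features = as.integer(num_classes), bias = TRUE)
  b$graph()
}

build_vgg16_graph <- function(num_classes) {
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  cfg <- list(64L, 64L, "M", 128L, 128L, "M", 256L, 256L, 256L, "M",
              512L, 512L, 512L, "M", 512L, 512L, 512L, "M")
  in_ch <- 3L
  ci <- 0L
  mi <- 0L
  for (v in cfg) {
    if (identical(v, "M")) {
      mi <- mi + 1L
      cur <- b$add("maxpool", sprintf("pool%d", mi), cur, kernel = 2L,
                   stride = 2L, pad = 0L)
    } else {
      ci <- ci + 1L
      cur <- add_conv(b, sprintf("conv%d", ci), cur, in_ch, v, 3L, pad = 1L,
                      bias = TRUE)
      cur <- b$add("relu", sprintf("relu%d", ci), cur)
      in_ch <- v
    }
  }
  cur <- b$add("adaptive_avgpool", "avgpool", cur, out_size = 7L)
  cur <- b$add("flatten", "flatten", cur)
  cur <- b$add("linear", "fc1", cur, in_features = 512L * 49L,
               out_features = 4096L, bias = TRUE)
  cur <- b$add("relu", "fc1.relu", cur)
  cur <- b$add("dropout", "fc1.dropout", cur, rate = 0.5)
  cur <- b$add("linear", "fc2", cur, in_features = 4096L,
               out_features = 4096L, bias = TRUE)
  cur <- b$add("relu", "fc2.relu", cur)
  cur <- b$add("dropout", "fc2.dropout", cur, rate = 0.5)
  b$add("linear", "fc3", cur, in_features = 4096L,
        out_features = as.integer(num_classes), bias = TRUE)
  b$graph()
}

build_alexnet_graph <- function(num_classes) {
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  cur <- add_conv(b, "conv1", cur, 3L, 64L, 11L, stride = 4L, pad = 2L,
                  bias = TRUE)
  cur <- b$add("relu", "relu1", cur)
  cur <- b$add("maxpool", "pool1", cur, kernel = 3L, stride = 2L, pad = 0L)
  cur <- add_conv(b, "conv2", cur, 64L, 192L, 5L, pad = 2L, bias = TRUE)
  cur <- b$add("relu", "relu2", cur)
  cur <- b$add("maxpool", "pool2", cur, kernel = 3L, stride = 2L, pad = 0L)
  cur <- add_conv(b, "conv3", cur, 192L, 384L, 3L, pad = 1L, bias = TRUE)
  cur <- b$add("relu", "relu3", cur)
  cur <- add_conv(b, "conv4", cur, 384L, 256L, 3L, pad = 1L, bias = TRUE)
  cur <- b$add("relu", "relu4", cur)
  cur <- add_conv(b, "conv5", cur, 256L, 256L, 3L, pad = 1L, bias = TRUE)
  cur <- b$add("relu", "relu5", cur)
  cur <- b$add("maxpool", "pool3", cur, kernel = 3L, stride = 2L, pad = 0L)
  cur <- b$add("adaptive_avgpool", "avgpool", cur, out_size = 6L)
  cur <- b$add("flatten", "flatten", cur)
  cur <- b$add("dropout", "drop1", cur, rate = 0.5)
  cur <- b$add("linear", "fc1", cur, in_features = 256L * 36L,
               out_features = 4096L, bias = TRUE)
  cur <- b$add("relu", "fc1.relu", cur)
  cur <- b$add("dropout", "drop2", cur, rate = 0.5)
  cur <- b$add("linear", "fc2", cur, in_features = 4096L,
               out_features = 4096L, bias = TRUE)
  cur <- b$add("relu", "fc2.relu", cur)
  b$add("linear", "fc3", cur, in_features = 4096L,
        out_features = as.integer(num_classes), bias = TRUE)
  b$graph()
}

build_densenet121_graph <- function(num_classes, growth = 32L,
                                    init_features = 64L, bn_size = 4L,
                                    block_config = c(6L, 12L, 24L, 16L)) {
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  cur <- add_conv(b, "stem.conv", cur, 3L, init_features, 7L, stride = 2L,
                  pad = 3L)
  cur <- add_bn(b, "stem.bn", cur, init_features)
  cur <- b$add("relu", "stem.relu", cur)
  cur <- b$add("maxpool", "stem.pool", cur, kernel = 3L, stride = 2L,
               pad = 1L)
  ch <- init_features
  for (blk in seq_along(block_config)) {
    for (lyr in seq_len(block_config[blk])) {
      prefix <- sprintf("dense%d.layer%d", blk, lyr)
      x <- add_bn(b, paste0(prefix, ".bn1"), cur, ch)
      x <- b$add("relu", paste0(prefix, ".relu1"), x)
      x <- add_conv(b, paste0(prefix, ".conv1"), x, ch, bn_size * growth,
                    1L)
      x <- add_bn(b, paste0(prefix, ".bn2"), x, bn_size * growth)
      x <- b$add("relu", paste0(prefix, ".relu2"), x)
      x <- add_conv(b, paste0(prefix, ".conv2"), x, bn_size * growth,
                    growth, 3L, pad = 1L)
      cur <- b$add("concat", paste0(prefix, ".cat"), c(cur, x))
      ch <- ch + growth
    }
    if (blk < length(block_config)) {
      prefix <- sprintf("trans%d", blk)
      cur <- add_bn(b, paste0(prefix, ".bn"), cur, ch)
      cur <- b$add("relu", paste0(prefix, ".relu"), cur)
      cur <- add_conv(b, paste0(prefix, ".conv"), cur, ch, ch %/% 2L, 1L)
      cur <- b$add("avgpool", paste0(prefix, ".pool"), cur, kernel = 2L,
                   stride = 2L, pad = 0L)
      ch <- ch %/% 2L
    }
  }
  cur <- add_bn(b, "final.bn", cur, ch)
  cur <- b$add("relu", "final.relu", cur)
  cur <- b$add("gap", "head.gap", cur)
  b$add("linear", "head.fc", cur, in_features = ch,
        out_features = as.integer(num_classes), bias = TRUE)
  b$graph()
}

build_mobilenet_v2_graph <- function(num_classes) {
  b <- new_graph_builder()
  cur <- b$add("input", "input", character(0))
  cur <- add_conv(b, "stem.conv", cur, 3L, 32L, 3L, stride = 2L, pad = 1L)
  cur <- add_bn(b, "stem.bn", cur, 32L)
  cur <- b$add("relu", "stem.relu", cur)
  settings <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2),
                   c(6, 64, 4, 2), c(6, 96, 3, 1), c(6, 160, 3, 2),
                   c(6, 320, 1, 1))
  in_ch <- 32L
  bi <- 0L
  for (s in settings) {
    t <- s[1]; out_ch <- as.integer(s[2]); n <- s[3]; first_stride <- s[4]
    for (i in seq_len(n)) {
      bi <- bi + 1L
      stride <- if (i == 1) as.integer(first_stride) else 1L
      prefix <- sprintf("ir%d", bi)
      hidden <- as.integer(in_ch * t)
      x <- cur
      if (t != 1) {
        x <- add_conv(b, paste0(prefix, ".expand"), x, in_ch, hidden, 1L)
        x <- add_bn(b, paste0(prefix, ".expand.bn"), x, hidden)
        x <- b$add("relu", paste0(prefix, ".expand.relu"), x)
      }
      x <- add_conv(b, paste0(prefix, ".dw"), x, hidden, hidden, 3L,
                    stride = stride, pad = 1L, groups = hidden)
      x <- add_bn(b, paste0(prefix, ".dw.bn"), x, hidden)
      x <- b$add("relu", paste0(prefix, ".dw.relu"), x)
      x <- add_conv(b, paste0(prefix, ".project"), x, hidden, out_ch, 1L)
      x <- add_bn(b, paste0(prefix, ".project.bn"), x, out_ch)
      if (stride == 1L && in_ch == out_ch)
        x <- b$add("add", paste0(prefix, ".add"), c(x, cur))
      cur <- x
      in_ch <- out_ch
    }
  }
  cur <- add_conv(b, "last.conv", cur, in_ch, 1280L, 1L)
  cur <- add_bn(b, "last.bn", cur, 1280L)
  cur <- b$add("relu", "last.relu", cur)
  cur <- b$add("gap", "head.gap", cur)
  cur <- b$add("dropout", "head.dropout", cur, rate = 0.2)
  b$add("linear", "head.fc", cur, in_features = 1280L,
        out_features = as.integer(num_classes), bias = TRUE)
  b$graph()
}
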