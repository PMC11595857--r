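# Runtime engine: instantiates a layer graph and runs forward/backward
# passes with hand-derived gradients.  Only the node kinds used by the
# trainable classifier need gradients (conv, bn, relu, maxpool, gap,
# dropout, linear, add, esa); the remaining kinds exist for profiling.

new_nn_model <- function(graph, name, spec = NULL) {
  structure(list(graph = graph, name = name, spec = spec,
                 params = NULL, state = NULL),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  np <- length(x$graph$nodes)
  cat(sprintf("<nn_model '%s'>: %d nodes, %s\n", x$name, np,
              if (is.null(x$params)) "uninitialized"
              else sprintf("%s parameters",
                           format(count_parameters(x), big.mark = ","))))
  invisible(x)
}

#' Instantiate trainable parameters for a model
#'
#' Convolutions use fan-out scaled normal initialization, normalization
#' layers start at identity (unit scale, zero shift), linear layers use
#' fan-in scaling, and the ESA cross-channel kernel starts near zero so
#' that the initial gates sit close to 0.5.  All draws come from the
#' current R random number generator, so the result is reproducible under
#' [set_global_seed()].
#'
#' @param model an `nn_model`.
#' @return the model with `params` and `state` filled in.
#' @export
init_model_params <- function(model) {
  params <- list()
  state <- list()
  for (node in model$graph$nodes) {
    p <- switch(node$kind,
      conv = {
        cg <- node$in_ch %/% node$groups
        fan_out <- node$kernel^2 * node$out_ch %/% node$groups
        w <- array(rnorm(node$out_ch * cg * node$kernel^2,
                         sd = sqrt(2 / fan_out)),
                   c(node$out_ch, cg, node$kernel, node$kernel))
        if (node$bias) list(w = w, b = numeric(node$out_ch)) else list(w = w)
      },
      bn = {
        state[[node$name]] <- list(mean = numeric(node$channels),
                                   var = rep(1, node$channels))
        list(gamma = rep(1, node$channels), beta = numeric(node$channels))
      },
      linear = {
        # classic zoo convention: small normal init keeps the initial
        # logits near zero, so a fresh model starts at loss ~ log(M)
        w <- matrix(rnorm(node$out_features * node$in_features, sd = 0.01),
                    node$out_features, node$in_features)
        if (node$bias) list(w = w, b = numeric(node$out_features))
        else list(w = w)
      },
      esa = list(w = rnorm(node$kernel, sd = 0.1),
                 b = if (node$bias) 0 else NULL),
      NULL)
    if (!is.null(p)) params[[node$name]] <- p
  }
  model$params <- params
  model$state <- state
  model
}

bn_channel_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2, 1, 3, 4)), nrow = d[2])
}

bn_unchannel <- function(m, d) {
  aperm(array(m, c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4))
}

esa_gate_runtime <- function(x, node, p) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])  # (n,c) rows over pixels
  if (identical(node$pool, "global_max")) {
    amax <- max.col(m, ties.method = "first")
    pooled <- m[cbind(seq_len(nrow(m)), amax)]
  } else {
    amax <- NULL
    pooled <- rowMeans(m)
  }
  pm <- matrix(pooled, d[1], d[2])
  z <- channel_conv1d(pm, p$w, p$b %||% 0)
  list(gate = stable_sigmoid(z), pooled = pm, argmax = amax)
}

node_forward <- function(node, ins, p, st, mode, bn_momentum = 0.1,
                         bn_eps = 1e-5) {
  x <- ins[[1]]
  switch(node$kind,
    conv = {
      y <- cpp_conv2d_forward(x, p$w, p$b %||% numeric(0), node$stride,
                              node$pad, node$groups)
      list(out = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      m <- bn_channel_matrix(x)
      if (mode == "train") {
        mu <- rowMeans(m)
        va <- rowMeans(m * m) - mu^2
        nm <- (1 - bn_momentum) * st$mean + bn_momentum * mu
        n <- ncol(m)
        nv <- (1 - bn_momentum) * st$var +
          bn_momentum * va * n / max(n - 1, 1)
        new_state <- list(mean = nm, var = nv)
      } else {
        mu <- st$mean
        va <- st$var
        new_state <- NULL
      }
      invstd <- 1 / sqrt(va + bn_eps)
      xhat <- (m - mu) * invstd
      y <- bn_unchannel(xhat * p$gamma + p$beta, d)
      list(out = y, cache = list(xhat = xhat, invstd = invstd, d = d),
           state = new_state)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    maxpool = {
      r <- cpp_maxpool_forward(x, node$kernel, node$stride, node$pad)
      list(out = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    gap = {
      d <- dim(x)
      y <- matrix(rowMeans(matrix(x, nrow = d[1] * d[2])), d[1], d[2])
      list(out = y, cache = list(d = d))
    },
    dropout = {
      if (mode == "train" && node$rate > 0) {
        mask <- (runif(length(x)) >= node$rate) / (1 - node$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    linear = {
      y <- x %*% t(p$w)
      if (!is.null(p$b)) y <- sweep(y, 2, p$b, `+`)
      list(out = y, cache = list(x = x))
    },
    add = list(out = ins[[1]] + ins[[2]], cache = NULL),
    concat = {
      ds <- lapply(ins, dim)
      d <- ds[[1]]
      d[2] <- sum(vapply(ds, `[`, integer(1), 2))
      out <- array(0, d)
      at <- 0L
      for (i in seq_along(ins)) {
        ci <- ds[[i]][2]
        out[, at + seq_len(ci), , ] <- ins[[i]]
        at <- at + ci
      }
      list(out = out, cache = list(channels = vapply(ds, `[`,
                                                     integer(1), 2)))
    },
    esa = {
      g <- esa_gate_runtime(x, node, p)
      d <- dim(x)
      list(out = x * array(g$gate, d),
           cache = list(x = x, gate = g$gate, pooled = g$pooled,
                        argmax = g$argmax))
    },
    stop("runtime does not implement forward for kind: ", node$kind,
         call. = FALSE)
  )
}

node_backward <- function(node, cache, gy, p) {
  switch(node$kind,
    conv = {
      r <- cpp_conv2d_backward(cache$x, p$w, gy, node$stride, node$pad,
                               node$groups, !is.null(p$b))
      g <- list(w = r$gw)
      if (!is.null(p$b)) g$b <- r$gb
      list(gin = list(r$gx), gpar = g)
    },
    bn = {
      d <- cache$d
      gm <- bn_channel_matrix(gy)
      dgamma <- rowSums(gm * cache$xhat)
      dbeta <- rowSums(gm)
      M <- ncol(gm)
      dxhat <- gm * p$gamma
      dx <- (cache$invstd / M) *
        (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
      list(gin = list(bn_unchannel(dx, d)),
           gpar = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(gin = list(gy * cache$mask), gpar = NULL),
    maxpool = list(gin = list(cpp_maxpool_backward(cache$xdim, cache$argmax,
                                                   gy)),
                   gpar = NULL),
    gap = {
      d <- cache$d
      npix <- d[3] * d[4]
      list(gin = list(array(gy / npix, d)), gpar = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(gin = list(gy), gpar = NULL)
      else list(gin = list(gy * cache$mask), gpar = NULL)
    },
    linear = {
      list(gin = list(gy %*% p$w),
           gpar = c(list(w = t(gy) %*% cache$x),
                    if (!is.null(p$b)) list(b = colSums(gy))))
    },
    add = list(gin = list(gy, gy), gpar = NULL),
    concat = {
      at <- 0L
      gin <- lapply(cache$channels, function(ci) {
        g <- gy[, at + seq_len(ci), , , drop = FALSE]
        at <<- at + ci
        g
      })
      list(gin = gin, gpar = NULL)
    },
    esa = {
      x <- cache$x
      d <- dim(x)
      G <- array(cache$gate, d)
      dx <- gy * G
      dg <- matrix(rowSums(matrix(gy * x, nrow = d[1] * d[2])), d[1], d[2])
      dz <- dg * cache$gate * (1 - cache$gate)
      # transpose of the zero-padded cross-channel correlation
      dp <- channel_conv1d(dz, rev(p$w), 0)
      k <- length(p$w)
      half <- (k - 1L) %/% 2L
      dw <- numeric(k)
      C <- d[2]
      for (j in seq_len(k)) {
        off <- j - 1L - half
        src <- seq_len(C) + off
        ok <- src >= 1L & src <= C
        dw[j] <- sum(dz[, ok, drop = FALSE] *
                     cache$pooled[, src[ok], drop = FALSE])
      }
      if (identical(node$pool, "global_max")) {
        m <- matrix(0, d[1] * d[2], d[3] * d[4])
        m[cbind(seq_len(nrow(m)), cache$argmax)] <- as.vector(dp)
        dx <- dx + array(m, d)
      } else {
        dx <- dx + array(as.vector(dp) / (d[3] * d[4]), d)
      }
      g <- list(w = dw)
      if (!is.null(p$b)) g$b <- sum(dz)
      list(gin = list(dx), gpar = g)
    },
    stop("runtime does not implement backward for kind: ", node$kind,
         call. = FALSE)
  )
}

#' Forward pass through a model
#'
#' @param model an initialized `nn_model`.
#' @param x input batch, array `(N, C, H, W)`.
#' @param mode `"train"` (batch statistics, dropout active) or `"eval"`.
#' @param keep_caches retain per-node caches for a subsequent
#'   [model_backward()] call.
#' @return list with `output`, `caches`, and `state` (updated batch-norm
#'   running statistics when `mode = "train"`).
#' @keywords internal
model_forward <- function(model, x, mode = c("eval", "train"),
                          keep_caches = FALSE) {
  mode <- match.arg(mode)
  if (is.null(model$params))
    stop("model has no parameters; call init_model_params() first",
         call. = FALSE)
  values <- list()
  caches <- if (keep_caches) list() else NULL
  state <- model$state
  out_name <- NULL
  for (node in model$graph$nodes) {
    if (node$kind == "input") {
      assert_tensor4(x)
      values[[node$name]] <- x
      out_name <- node$name
      next
    }
    ins <- lapply(node$inputs, function(nm) values[[nm]])
    r <- node_forward(node, ins, model$params[[node$name]],
                      state[[node$name]], mode)
    values[[node$name]] <- r$out
    if (keep_caches) caches[[node$name]] <- r$cache
    if (!is.null(r$state)) state[[node$name]] <- r$state
    out_name <- node$name
  }
  list(output = values[[out_name]], values = if (keep_caches) values,
       caches = caches, state = state, output_name = out_name)
}

#' Backward pass through a model
#'
#' @param model the model used in the forward pass.
#' @param fwd result of [model_forward()] with `keep_caches = TRUE`.
#' @param grad_output gradient of the scalar loss with respect to the
#'   model output.
#' @return named list of parameter gradients mirroring `model$params`.
#' @keywords internal
model_backward <- function(model, fwd, grad_output) {
  nodes <- model$graph$nodes
  gacc <- list()
  gacc[[fwd$output_name]] <- grad_output
  gpar <- list()
  for (node in rev(nodes)) {
    gy <- gacc[[node$name]]
    if (is.null(gy) || node$kind == "input") next
    r <- node_backward(node, fwd$caches[[node$name]], gy,
                       model$params[[node$name]])
    if (!is.null(r$gpar)) gpar[[node$name]] <- r$gpar
    for (i in seq_along(node$inputs)) {
      nm <- node$inputs[i]
      gacc[[nm]] <- if (is.null(gacc[[nm]])) r$gin[[i]]
                    else gacc[[nm]] + r$gin[[i]]
    }
    gacc[[node$name]] <- NULL  # free memory
  }
  gpar
}

#' Predict class scores
#'
#' Runs the model in evaluation mode (running batch-norm statistics,
#' dropout disabled) and returns the raw logits.
#'
#' @param object an initialized `nn_model`.
#' @param x input batch, array `(N, C, H, W)`.
#' @param batch_size process the input in chunks of this many samples.
#' @param ... unused.
#' @return `N x num_classes` matrix of logits.
#' @export
predict.nn_model <- function(object, x, batch_size = 64L, ...) {
  n <- dim(x)[1]
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  out <- lapply(chunks, function(ix) {
    model_forward(object, x[ix, , , , drop = FALSE], mode = "eval")$output
  })
  do.call(rbind, out)
}

# ---- optimizer -------------------------------------------------------------

flatten_params <- function(params) {
  out <- list()
  for (nm in names(params))
    for (pn in names(params[[nm]]))
      if (!is.null(params[[nm]][[pn]]))
        out[[paste(nm, pn, sep = "|")]] <- params[[nm]][[pn]]
  out
}

unflatten_params <- function(flat, template) {
  for (key in names(flat)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    template[[parts[1]]][[parts[2]]] <- flat[[key]]
  }
  template
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

# Adam with decoupled-from-nothing L2 (the classical formulation: weight
# decay is added to the gradient before the moment updates).
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (key in names(fp)) {
    g <- fg[[key]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * fp[[key]]
    opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * g
    opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * g * g
    fp[[key]] <- fp[[key]] -
      lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + eps)
  }
  list(params = unflatten_params(fp, params), opt = opt)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The learnable state is serialized with `saveRDS()`; alongside it a JSON
#' sidecar (`<path>.json`) records the architecture spec, so a checkpoint
#' is self-describing.
#'
#' @param model an initialized `nn_model`.
#' @param path file path for the checkpoint (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the restored `nn_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(name = model$name, params = model$params,
               state = model$state, spec = model$spec), path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(serialize_spec(model$spec, model$name), sidecar,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  blob <- readRDS(path)
  model <- if (!is.null(blob$spec)) {
    build_esa_resnet34(blob$spec, initialize = FALSE)
  } else {
    build_reference_model(blob$name, initialize = FALSE)
  }
  model$params <- blob$params
  model$state <- blob$state
  model
}

serialize_spec <- function(spec, name) {
  if (is.null(spec)) return(list(model = name))
  s <- unclass(spec)
  s$esa <- unclass(s$esa)
  c(list(model = name), s)
}
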