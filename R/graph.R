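#' Layer graphs
#'
#' A network is described declaratively as an ordered list of nodes
#' (`nn_graph`).  Each node has a `name`, a `kind`, the names of its input
#' nodes, and kind-specific attributes (channel counts, kernel sizes,
#' strides, ...).  The list is already in topological order: builders only
#' ever reference nodes that exist.  The same description drives both the
#' complexity profiler (shape propagation and closed-form counts) and the
#' runtime engine (parameter instantiation, forward and backward passes).
#'
#' @name nn_graph
#' @keywords internal
NULL

new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$add <- function(kind, name, inputs, ...) {
    if (name %in% names(env$nodes))
      stop("duplicate node name: ", name, call. = FALSE)
    if (kind != "input" && !all(inputs %in% names(env$nodes)))
      stop("unknown input node(s): ",
           paste(setdiff(inputs, names(env$nodes)), collapse = ", "),
           call. = FALSE)
    env$nodes[[name]] <- c(list(name = name, kind = kind, inputs = inputs),
                           list(...))
    invisible(name)
  }
  env$graph <- function() {
    structure(list(nodes = env$nodes), class = "nn_graph")
  }
  env
}

conv_out_dim <- function(size, kernel, stride, pad) {
  (size + 2L * pad - kernel) %/% stride + 1L
}

#' Propagate tensor shapes through a layer graph
#'
#' @param graph an `nn_graph`.
#' @param input_shape integer vector `(N, C, H, W)`.
#' @return named list of output shapes, one per node; 4-vectors for
#'   feature maps, 2-vectors `(N, features)` after global pooling/flatten.
#' @keywords internal
infer_shapes <- function(graph, input_shape = c(1L, 3L, 224L, 224L)) {
  shapes <- list()
  for (node in graph$nodes) {
    ins <- lapply(node$inputs, function(nm) shapes[[nm]])
    s <- switch(node$kind,
      input = as.integer(input_shape),
      conv = {
        d <- ins[[1]]
        if (d[2] != node$in_ch)
          stop(sprintf("node %s expects %d input channels, got %d",
                       node$name, node$in_ch, d[2]), call. = FALSE)
        c(d[1], node$out_ch,
          conv_out_dim(d[3], node$kernel, node$stride, node$pad),
          conv_out_dim(d[4], node$kernel, node$stride, node$pad))
      },
      bn = , relu = , esa = ins[[1]],
      dropout = ins[[1]],
      maxpool = , avgpool = {
        d <- ins[[1]]
        c(d[1], d[2],
          conv_out_dim(d[3], node$kernel, node$stride, node$pad),
          conv_out_dim(d[4], node$kernel, node$stride, node$pad))
      },
      adaptive_avgpool = {
        d <- ins[[1]]
        c(d[1], d[2], node$out_size, node$out_size)
      },
      gap = {
        d <- ins[[1]]
        c(d[1], d[2])
      },
      flatten = {
        d <- ins[[1]]
        c(d[1], prod(d[-1]))
      },
      linear = {
        d <- ins[[1]]
        if (d[2] != node$in_features)
          stop(sprintf("node %s expects %d input features, got %d",
                       node$name, node$in_features, d[2]), call. = FALSE)
        c(d[1], node$out_features)
      },
      add = {
        if (!identical(ins[[1]], ins[[2]]))
          stop(sprintf("node %s adds tensors of different shapes (%s vs %s)",
                       node$name, paste(ins[[1]], collapse = "x"),
                       paste(ins[[2]], collapse = "x")), call. = FALSE)
        ins[[1]]
      },
      concat = {
        d <- ins[[1]]
        d[2] <- sum(vapply(ins, function(s) s[2], integer(1)))
        d
      },
      stop("unknown node kind: ", node$kind, call. = FALSE)
    )
    shapes[[node$name]] <- as.integer(s)
  }
  shapes
}

#' Summarize a layer graph as a data frame of layer shapes
#'
#' One row per parameterized or shape-changing layer; used for the
#' layer-for-layer isomorphism checks between architecture variants.
#'
#' @param model an `nn_model` or `nn_graph`.
#' @return data.frame with columns `name`, `kind` and the main shape
#'   attributes.
#' @export
layer_table <- function(model) {
  graph <- as_nn_graph(model)
  rows <- lapply(graph$nodes, function(n) {
    data.frame(name = n$name, kind = n$kind,
               in_ch = n$in_ch %||% n$channels %||% n$in_features %||% NA,
               out_ch = n$out_ch %||% n$channels %||% n$out_features %||% NA,
               kernel = n$kernel %||% NA, stride = n$stride %||% NA,
               groups = n$groups %||% NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

as_nn_graph <- function(x) {
  if (inherits(x, "nn_graph")) return(x)
  if (inherits(x, "nn_model")) return(x$graph)
  stop("expected an nn_model or nn_graph", call. = FALSE)
}
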