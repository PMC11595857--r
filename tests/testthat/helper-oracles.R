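# Independent oracles used to freeze expected values.  These deliberately
# share no code with the package internals: plain quadruple-loop
# convolutions, scalar attention arithmetic, and sample-by-sample metric
# tallies.

# Direct-convolution oracle (cross-correlation, zero padding).  Returns the
# output and the number of scalar multiplications performed.
naive_conv2d <- function(x, w, bias = NULL, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  wd <- dim(w); Cout <- wd[1]; Cg <- wd[2]; k <- wd[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  cout_g <- Cout / groups
  y <- array(0, c(N, Cout, Ho, Wo))
  mults <- 0
  for (n in 1:N) for (co in 1:Cout) {
    g <- ceiling(co / cout_g)
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(bias)) 0 else bias[co]
      for (ci in 1:Cg) for (ki in 1:k) for (kj in 1:k) {
        hi <- (ho - 1) * stride - pad + ki
        wi <- (wo - 1) * stride - pad + kj
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[n, (g - 1) * Cg + ci, hi, wi] * w[co, ci, ki, kj]
          mults <- mults + 1
        }
      }
      y[n, co, ho, wo] <- acc
    }
  }
  list(y = y, mults = mults)
}

# Scalar oracle for the attention gate: global pooling, explicit 1-d
# cross-channel convolution, scalar logistic.
naive_esa_gate <- function(x, w, b = 0, pool = "avg") {
  d <- dim(x)
  k <- length(w)
  half <- (k - 1) / 2
  gates <- matrix(0, d[1], d[2])
  pooled <- matrix(0, d[1], d[2])
  for (n in 1:d[1]) for (c in 1:d[2])
    pooled[n, c] <- if (pool == "max") max(x[n, c, , ]) else mean(x[n, c, , ])
  for (n in 1:d[1]) for (c in 1:d[2]) {
    z <- b
    for (j in 1:k) {
      src <- c + (j - 1 - half)
      if (src >= 1 && src <= d[2]) z <- z + w[j] * pooled[n, src]
    }
    gates[n, c] <- 1 / (1 + exp(-z))
  }
  gates
}

# One-vs-rest enumeration oracle for multiclass metrics, computed sample by
# sample from the label vectors.
naive_metrics <- function(true, pred, M) {
  per <- lapply(0:(M - 1), function(k) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  })
  m <- do.call(rbind, per)
  list(accuracy = mean(true == pred),
       macro_precision = mean(m[, "p"]),
       macro_recall = mean(m[, "r"]),
       macro_f1 = mean(m[, "f"]))
}

# Tally oracle for confusion matrices, using an environment as dictionary.
naive_confusion <- function(true, pred, M) {
  tab <- new.env()
  for (i in seq_along(true)) {
    key <- paste(true[i], pred[i])
    tab[[key]] <- (tab[[key]] %||% 0L) + 1L
  }
  cm <- matrix(0L, M, M)
  for (key in ls(tab)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    cm[ij[1] + 1L, ij[2] + 1L] <- tab[[key]]
  }
  cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared small fixtures -----------------------------------------------------

tiny_arch <- function(num_classes = 5, dropout_rate = 0, ...) {
  architecture_spec(stage_block_counts = c(1, 1, 1, 1),
                    stage_widths = c(8, 16, 32, 64),
                    num_classes = num_classes,
                    dropout_rate = dropout_rate, ...)
}

tiny_synthetic <- function(samples_per_class = 40, num_classes = 5,
                           image_size = 32, seed = 2022) {
  generate_synthetic_dataset(
    synthetic_dataset_spec(num_classes = num_classes,
                           samples_per_class = samples_per_class,
                           image_size = image_size, seed = seed))
}

rand_tensor <- function(n, c, h, w) array(rnorm(n * c * h * w), c(n, c, h, w))
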