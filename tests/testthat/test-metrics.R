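test_that("confusion matrices match an independent tally", {
  # perfect predictions give a diagonal of class counts
  y <- rep(0:3, times = c(5, 2, 7, 1))
  cm <- confusion_matrix(y, y, 4)
  expect_equal(unname(diag(cm)), c(5L, 2L, 7L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  expect_equal(unname(confusion_matrix(integer(0), integer(0), 3)),
               matrix(0L, 3, 3))

  set.seed(71)
  true <- sample(0:4, 200, TRUE)
  pred <- sample(0:4, 200, TRUE)
  expect_equal(unname(confusion_matrix(true, pred, 5)),
               naive_confusion(true, pred, 5))

  expect_error(confusion_matrix(c(0L, 5L), c(0L, 0L), 5), "index 2")
})

test_that("worked metric cases: symmetric 2-class and enumerated 3-class", {
  r <- classification_metrics(matrix(c(30, 20, 20, 30), 2, byrow = TRUE))
  expect_equal(r$accuracy, 0.6)
  expect_equal(r$precision, 0.6)
  expect_equal(r$f1, 0.6)

  cm3 <- matrix(c(2, 1, 0,
                  0, 3, 0,
                  1, 0, 3), 3, byrow = TRUE)
  # reconstruct label vectors and use the sample-level enumeration oracle
  true <- rep(rep(0:2, each = 3), times = as.vector(t(cm3)))
  pred <- rep(rep(0:2, times = 3), times = as.vector(t(cm3)))
  expect_equal(unname(confusion_matrix(true, pred, 3)), cm3)
  o <- naive_metrics(true, pred, 3)
  r3 <- classification_metrics(cm3, "macro")
  expect_equal(r3$accuracy, o$accuracy)
  expect_equal(r3$precision, o$macro_precision)
  expect_equal(r3$recall, o$macro_recall)
  expect_equal(r3$f1, o$macro_f1)

  perfect <- classification_metrics(diag(c(4, 5, 6)))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$f1),
               c(1, 1, 1))
})

test_that("metric invariants hold on random confusion matrices", {
  set.seed(72)
  for (i in 1:40) {
    M <- sample(2:7, 1)
    true <- sample(0:(M - 1), 150, TRUE)
    pred <- ifelse(runif(150) < 0.6, true, sample(0:(M - 1), 150, TRUE))
    cm <- confusion_matrix(true, pred, M)
    macro <- suppressWarnings(classification_metrics(cm, "macro"))
    micro <- suppressWarnings(classification_metrics(cm, "micro"))
    # micro precision = micro recall = accuracy for single-label data
    expect_equal(micro$precision, macro$accuracy, tolerance = 1e-12)
    expect_equal(micro$recall, macro$accuracy, tolerance = 1e-12)
    # per-class and macro F1 never exceed the larger of precision/recall
    pc <- macro$per_class
    expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    expect_lte(macro$f1, max(macro$precision, macro$recall) + 1e-12)
    # simultaneous permutation of class indices leaves the metrics alone
    perm <- sample(M) - 1L
    cmp <- confusion_matrix(perm[true + 1L], perm[pred + 1L], M)
    mp <- suppressWarnings(classification_metrics(cmp, "macro"))
    expect_equal(mp$precision, macro$precision, tolerance = 1e-12)
    expect_equal(mp$f1, macro$f1, tolerance = 1e-12)
  }
})

test_that("a never-predicted class yields zero precision with a warning", {
  cm <- matrix(c(5, 0, 0,
                 2, 0, 0,
                 0, 0, 4), 3, byrow = TRUE)  # class 1 never predicted
  expect_warning(r <- classification_metrics(cm), "precision undefined")
  expect_equal(r$per_class$precision[2], 0)
  expect_equal(r$per_class$f1[2], 0)
})

test_that("metrics agree with an established implementation", {
  # cross-check (not a dependency): scikit-learn via the system python
  set.seed(73)
  true <- sample(0:3, 120, TRUE)
  pred <- ifelse(runif(120) < 0.5, true, sample(0:3, 120, TRUE))
  r <- classification_metrics(confusion_matrix(true, pred, 4), "macro")
  script <- paste(
    "import sys, json",
    "from sklearn.metrics import precision_score, recall_score, f1_score, accuracy_score",
    "d = json.load(sys.stdin)",
    "t, p = d['true'], d['pred']",
    "print(json.dumps({'acc': accuracy_score(t, p),",
    " 'prec': precision_score(t, p, average='macro', zero_division=0),",
    " 'rec': recall_score(t, p, average='macro', zero_division=0),",
    " 'f1': f1_score(t, p, average='macro', zero_division=0)}))",
    sep = "\n")
  out <- tryCatch(
    system2("python", c("-c", shQuote(script)),
            input = jsonlite::toJSON(list(true = true, pred = pred)),
            stdout = TRUE, stderr = FALSE),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out) || !length(out)) {
    # no usable python: the in-R enumeration oracle is the cross-check
    o <- naive_metrics(true, pred, 4)
    expect_equal(r$precision, o$macro_precision)
    expect_equal(r$f1, o$macro_f1)
  } else {
    sk <- jsonlite::fromJSON(paste(out, collapse = ""))
    expect_equal(r$accuracy, sk$acc, tolerance = 1e-10)
    expect_equal(r$precision, sk$prec, tolerance = 1e-10)
    expect_equal(r$recall, sk$rec, tolerance = 1e-10)
    expect_equal(r$f1, sk$f1, tolerance = 1e-10)
  }
})
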