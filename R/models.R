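#' @title Base classifiers on fingerprint variable subsets
#' @name models
#' @description
#' Three classifier families are supported, each trained on a small subset
#' (4-25) of the variance-filtered fingerprint columns: random forest (Gini
#' splits, 100 trees), a single decision tree (Gini splits, grown until every
#' leaf holds fewer than 2 samples), and k-nearest neighbors (k = 5,
#' Euclidean distance on the selected bits, which on binary data is the
#' square root of the Hamming distance). All models expose an active-class
#' probability: the fraction of trees voting active (RF), the leaf class
#' frequency (DTREE), or the neighbor vote fraction (KNN).
NULL

MODEL_ALGORITHMS <- c("RF", "DTREE", "KNN")

#' Specify a base model
#'
#' @param algorithm one of `"RF"`, `"DTREE"`, `"KNN"`.
#' @param variables unique indices into the dataset's `kept_columns`,
#'   between `min_vars` and `max_vars` of them.
#' @param hyperparams optional list; `ntree` (RF, default 100) or `k` (KNN,
#'   default 5).
#' @param seed integer seed fixing any training randomness.
#' @param min_vars,max_vars admissible variable-count window (default 4-25).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm, variables, hyperparams = list(), seed = 1L,
                       min_vars = 4L, max_vars = 25L) {
  algorithm <- match.arg(algorithm, MODEL_ALGORITHMS)
  variables <- as.integer(variables)
  if (anyDuplicated(variables)) {
    stop("variables must be unique", call. = FALSE)
  }
  if (length(variables) < min_vars || length(variables) > max_vars) {
    stop(sprintf("number of variables (%d) outside the admissible window [%d, %d]",
                 length(variables), min_vars, max_vars), call. = FALSE)
  }
  structure(list(algorithm = algorithm, variables = sort(variables),
                 hyperparams = hyperparams, seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a base model on a dataset
#'
#' Fits the specified classifier on the training partition, using only the
#' selected variables (indices into the dataset's variance-filtered
#' `kept_columns`). Performance metrics are computed on the test and
#' external partitions restricted to in-domain compounds; the external
#' partition plays no role in any fitness computation and is reported for
#' stability assessment only.
#'
#' @param spec a [model_spec()].
#' @param dataset a `qsar_dataset` from [build_dataset()].
#' @return object of class `qsar_model` with elements `spec`, `columns`
#'   (absolute fingerprint column indices), `fit`, `test_metrics`,
#'   `external_metrics`.
#' @export
train_model <- function(spec, dataset) {
  stopifnot(inherits(spec, "model_spec"), inherits(dataset, "qsar_dataset"))
  if (max(spec$variables) > length(dataset$kept_columns)) {
    stop("spec variables exceed the dataset's kept columns", call. = FALSE)
  }
  columns <- dataset$kept_columns[spec$variables]
  tr <- dataset$partition == "train"
  if (!any(tr)) stop("training partition is empty", call. = FALSE)
  Xtr <- dataset$bits[tr, columns, drop = FALSE]
  storage.mode(Xtr) <- "double"
  ytr <- factor(dataset$labels[tr], levels = c(0L, 1L))

  set.seed(spec$seed)
  fit <- switch(
    spec$algorithm,
    RF = randomForest::randomForest(
      x = Xtr, y = ytr,
      ntree = if (!is.null(spec$hyperparams$ntree)) spec$hyperparams$ntree else 100L),
    DTREE = {
      df <- as.data.frame(Xtr)
      names(df) <- paste0("V", seq_along(columns))
      df$.y <- ytr
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(minsplit = 2L, minbucket = 1L,
                                                  cp = 0, xval = 0L,
                                                  maxdepth = 30L))
    },
    KNN = list(train = Xtr, cl = ytr,
               k = if (!is.null(spec$hyperparams$k)) spec$hyperparams$k else 5L)
  )

  model <- structure(
    list(spec = spec, algorithm = spec$algorithm, columns = columns, fit = fit,
         test_metrics = NULL, external_metrics = NULL),
    class = "qsar_model"
  )
  for (part in c("test", "external")) {
    rows <- dataset$partition == part & dataset$in_domain
    met <- if (any(rows)) {
      class_metrics(dataset$labels[rows],
                    predict(model, dataset$bits[rows, , drop = FALSE]))
    } else {
      list(se = NA_real_, sp = NA_real_, bcr = NA_real_, f1 = NA_real_,
           acc = NA_real_, n = 0L)
    }
    model[[paste0(part, "_metrics")]] <- met
  }
  model
}

#' Predict active-class probabilities from a base model
#'
#' @param object a `qsar_model`.
#' @param bits full-width fingerprint matrix (the model selects its own
#'   columns).
#' @param ... unused.
#' @return numeric probability vector in \[0, 1\].
#' @export
predict.qsar_model <- function(object, bits, ...) {
  stopifnot(is.matrix(bits))
  X <- bits[, object$columns, drop = FALSE]
  storage.mode(X) <- "double"
  switch(
    object$algorithm,
    RF = unname(predict(object$fit, X, type = "prob")[, "1"]),
    DTREE = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_along(object$columns))
      unname(predict(object$fit, df, type = "prob")[, "1"])
    },
    KNN = {
      pred <- class::knn(object$fit$train, X, object$fit$cl,
                         k = object$fit$k, prob = TRUE, use.all = TRUE)
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    }
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("%s model, %d variables; test BCR %.3f, external BCR %.3f\n",
              x$algorithm, length(x$spec$variables),
              x$test_metrics$bcr, x$external_metrics$bcr))
  invisible(x)
}
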