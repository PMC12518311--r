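#' @title Model pools and ensemble optimization
#' @name ensemble
#' @description
#' Ensembles aggregate 2 to 20 qualified base models by the arithmetic mean
#' of their active-class probabilities. The pool is filled with randomly
#' generated candidates - random algorithm among RF/DTREE/KNN, random 4-25
#' variable subset - admitted only when their test-partition BCR exceeds the
#' qualification floor (0.65). Member subsets are then evolved by the same
#' genetic-algorithm engine used for variable selection, with the ensemble's
#' test-partition BCR as fitness.
NULL

#' Build a pool of qualified base models
#'
#' Repeatedly draws a random algorithm and a random variable subset, trains
#' the candidate, and admits it iff its test BCR exceeds `bcr_floor`, until
#' `target_size` models are admitted. Optionally the pool can be seeded from
#' an existing collection of trained models (e.g. a GA-selected population);
#' seeded models must still pass qualification.
#'
#' @param dataset a `qsar_dataset`.
#' @param target_size pool size to reach (default 200).
#' @param bcr_floor qualification threshold on test BCR (default 0.65,
#'   strict).
#' @param max_attempts cap on candidate draws (default `50 * target_size`);
#'   exhausting it raises an error naming the shortfall, the signal of an
#'   unlearnable dataset or a floor set too high.
#' @param seed integer seed.
#' @param min_vars,max_vars variable-count window (default 4-25).
#' @param algorithms families to draw from.
#' @param seed_models optional list of `qsar_model`s considered (in order)
#'   before random generation starts.
#' @return object of class `model_pool`: `models`, `qualification` (test BCR
#'   per member), `algorithms` (per member), `attempts`, `admission_rate`,
#'   `target_size`, `bcr_floor`.
#' @export
build_model_pool <- function(dataset, target_size = 200L, bcr_floor = 0.65,
                             max_attempts = 50L * target_size, seed = 1L,
                             min_vars = 4L, max_vars = 25L,
                             algorithms = MODEL_ALGORITHMS,
                             seed_models = NULL) {
  stopifnot(inherits(dataset, "qsar_dataset"), target_size >= 1L)
  if (max_attempts < target_size) {
    stop("max_attempts must be at least target_size", call. = FALSE)
  }
  u <- length(dataset$kept_columns)
  models <- list()
  quals <- numeric(0)
  for (m in seed_models) {
    if (length(models) >= target_size) break
    b <- m$test_metrics$bcr
    if (!is.na(b) && b > bcr_floor) {
      models[[length(models) + 1L]] <- m
      quals <- c(quals, b)
    }
  }
  set.seed(seed)
  attempts <- 0L
  while (length(models) < target_size && attempts < max_attempts) {
    attempts <- attempts + 1L
    alg <- sample(algorithms, 1L)
    vars <- random_subset(u, min_vars, min(max_vars, u))
    spec <- model_spec(alg, vars, seed = chrom_seed(seed + attempts, vars),
                       min_vars = min_vars, max_vars = max_vars)
    rs <- get(".Random.seed", envir = globalenv())
    cand <- train_model(spec, dataset)
    assign(".Random.seed", rs, envir = globalenv())
    b <- cand$test_metrics$bcr
    if (!is.na(b) && b > bcr_floor) {
      models[[length(models) + 1L]] <- cand
      quals <- c(quals, b)
    }
  }
  if (length(models) < target_size) {
    stop(sprintf(
      "model pool shortfall: %d of %d qualified models after %d attempts (BCR floor %.2f); the dataset may be unlearnable or the floor too high",
      length(models), target_size, attempts, bcr_floor), call. = FALSE)
  }
  structure(
    list(models = models, qualification = quals,
         algorithms = vapply(models, function(m) m$algorithm, character(1)),
         attempts = attempts,
         admission_rate = if (attempts > 0) length(models) / attempts else NA_real_,
         target_size = target_size, bcr_floor = bcr_floor, seed = seed),
    class = "model_pool"
  )
}

#' @export
print.model_pool <- function(x, ...) {
  tab <- table(x$algorithms)
  cat(sprintf(
    "Model pool: %d qualified models (BCR floor %.2f), %s\n  admission rate %.1f%% over %d attempts; test BCR %.3f-%.3f\n",
    length(x$models), x$bcr_floor,
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    100 * x$admission_rate, x$attempts,
    min(x$qualification), max(x$qualification)))
  invisible(x)
}

#' Mean-probability ensemble prediction
#'
#' The ensemble probability is the element-wise arithmetic mean of the
#' member models' active-class probabilities: permutation-invariant in
#' member order and idempotent when all members agree.
#'
#' @param member_ids indices into the pool's model list (unique, non-empty).
#' @param pool a `model_pool`.
#' @param bits full-width fingerprint matrix.
#' @return numeric probability vector in \[0, 1\].
#' @export
predict_ensemble <- function(member_ids, pool, bits) {
  stopifnot(inherits(pool, "model_pool"))
  member_ids <- unique(as.integer(member_ids))
  if (!length(member_ids)) stop("empty ensemble member list", call. = FALSE)
  if (any(member_ids < 1L | member_ids > length(pool$models))) {
    stop("member ids outside the pool", call. = FALSE)
  }
  P <- vapply(pool$models[member_ids], predict, numeric(nrow(bits)), bits)
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(bits))
  rowMeans(P)
}

#' Wrap an ensemble as a predictor object
#'
#' Gives a member set the same `predict()` surface as a single `qsar_model`,
#' so ensembles can enter cross-cell-line combination searches.
#'
#' @param member_ids indices into the pool.
#' @param pool a `model_pool`.
#' @return object of class `ensemble_model`.
#' @export
ensemble_model <- function(member_ids, pool) {
  member_ids <- unique(as.integer(member_ids))
  if (!length(member_ids)) stop("empty ensemble member list", call. = FALSE)
  structure(list(member_ids = sort(member_ids), pool = pool),
            class = "ensemble_model")
}

#' @export
predict.ensemble_model <- function(object, bits, ...) {
  predict_ensemble(object$member_ids, object$pool, bits)
}

#' Optimize ensemble member sets by genetic algorithm
#'
#' Chromosome = subset of pool member indices (2 to 20 members); fitness =
#' BCR of the mean-probability aggregate on the in-domain test partition.
#' Member test probabilities are precomputed once, so each fitness
#' evaluation is a column average. The external partition is evaluated only
#' after evolution finishes, for reporting: scrambling its labels changes
#' neither the fitness trace nor the final population. The final population
#' is deduplicated by member set in the returned ranking.
#'
#' @param pool a `model_pool`.
#' @param dataset the `qsar_dataset` the pool was trained on.
#' @param init_population GA population size (default 1000).
#' @param generations number of generations (default 5000).
#' @param min_size,max_size ensemble size window (default 2-20).
#' @param seed integer seed.
#' @param ... engine knobs (`tournament`, `cx_rate`, `elitism`).
#' @return object of class `ensemble_result`: `ensembles` (list of
#'   `member_ids`, `fitness`, `test_metrics`, `external_metrics`, ranked by
#'   fitness, duplicates removed), `trace`, `config`.
#' @export
optimize_ensembles <- function(pool, dataset, init_population = 1000L,
                               generations = 5000L, min_size = 2L,
                               max_size = 20L, seed = 1L, ...) {
  stopifnot(inherits(pool, "model_pool"), inherits(dataset, "qsar_dataset"))
  n_pool <- length(pool$models)
  if (n_pool < min_size) {
    stop(sprintf("pool of %d models is smaller than the minimum ensemble size %d",
                 n_pool, min_size), call. = FALSE)
  }
  test_rows <- dataset$partition == "test" & dataset$in_domain
  y_test <- dataset$labels[test_rows]
  B_test <- dataset$bits[test_rows, , drop = FALSE]
  P_test <- vapply(pool$models, predict, numeric(nrow(B_test)), B_test)

  fitness_fn <- function(ids) {
    b <- class_metrics(y_test, rowMeans(P_test[, ids, drop = FALSE]))$bcr
    if (is.na(b)) 0 else b
  }
  res <- ga_engine(n_pool, fitness_fn, pop_size = init_population,
                   generations = generations, min_size = min_size,
                   max_size = max_size, seed = seed, ...)

  keys <- vapply(res$population, chrom_key, character(1))
  keep <- !duplicated(keys)
  members <- res$population[keep]
  fitness <- res$fitness[keep]

  ext_rows <- dataset$partition == "external" & dataset$in_domain
  y_ext <- dataset$labels[ext_rows]
  B_ext <- dataset$bits[ext_rows, , drop = FALSE]
  P_ext <- if (any(ext_rows)) {
    vapply(pool$models, predict, numeric(nrow(B_ext)), B_ext)
  } else NULL

  ensembles <- lapply(seq_along(members), function(i) {
    ids <- members[[i]]
    tm <- class_metrics(y_test, rowMeans(P_test[, ids, drop = FALSE]))
    em <- if (!is.null(P_ext)) {
      class_metrics(y_ext, rowMeans(P_ext[, ids, drop = FALSE]))
    } else {
      list(se = NA_real_, sp = NA_real_, bcr = NA_real_, f1 = NA_real_,
           acc = NA_real_, n = 0L)
    }
    list(member_ids = ids, fitness = fitness[i],
         test_metrics = tm, external_metrics = em)
  })
  structure(
    list(ensembles = ensembles, trace = res$trace,
         config = list(init_population = init_population,
                       generations = generations, min_size = min_size,
                       max_size = max_size, seed = seed)),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  best <- x$ensembles[[1L]]
  cat(sprintf(
    "Ensemble GA: %d unique ensembles; best has %d members, test BCR %.3f (external %.3f)\n",
    length(x$ensembles), length(best$member_ids), best$fitness,
    best$external_metrics$bcr))
  invisible(x)
}
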