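#' @title Dataset construction: balancing, splitting, filtering, domain
#' @name dataset
#' @description
#' Turns a fingerprint matrix with binary activity labels into a modeling
#' dataset: cluster-based undersampling of the majority class, a random
#' 60/20/20 train/test/external split, a variance filter on the training
#' columns, and a PCA-Euclidean applicability domain fitted on the training
#' partition.
NULL

#' Largest-remainder apportionment
#'
#' Distributes `total` selections across groups proportionally to their
#' sizes: each group first receives the floor of its exact quota, then the
#' remaining units go to the groups with the largest fractional remainders
#' (ties resolved toward larger groups, then lower index).
#'
#' @param sizes positive integer group sizes.
#' @param total number of units to apportion (`<= sum(sizes)`).
#' @return integer vector of per-group allocations summing to `total`, each
#'   no larger than the group's size.
#' @export
largest_remainder_allocation <- function(sizes, total) {
  stopifnot(all(sizes >= 0), total >= 0, total <= sum(sizes))
  quota <- sizes / sum(sizes) * total
  alloc <- floor(quota)
  rem <- quota - alloc
  # never allocate above a group's size
  alloc <- pmin(alloc, sizes)
  left <- total - sum(alloc)
  while (left > 0) {
    avail <- which(alloc < sizes)
    ord <- avail[order(-rem[avail], -sizes[avail], avail)]
    take <- ord[seq_len(min(left, length(ord)))]
    alloc[take] <- alloc[take] + 1L
    rem[take] <- rem[take] - 1
    left <- total - sum(alloc)
  }
  as.integer(alloc)
}

#' Balance the majority class by k-means undersampling
#'
#' Clusters the majority-class fingerprints with k-means for every cluster
#' count k from 2 up to the minority-class size, scores each clustering by
#' the mean silhouette width, and keeps the k maximizing it (ties toward
#' smaller k). From each of the k* clusters a proportional number of
#' compounds (largest-remainder apportionment) is then drawn uniformly at
#' random so that exactly `minority_size` compounds are selected.
#'
#' @param majority_bits binary matrix of majority-class fingerprints.
#' @param minority_size target selection size (the minority-class count),
#'   at least 2 and smaller than `nrow(majority_bits)`.
#' @param seed integer seed governing k-means restarts and within-cluster
#'   sampling.
#' @param nstart k-means restarts per k (default 10).
#' @param silhouette_cap maximum number of rows used for the silhouette
#'   scan; larger majority classes are subsampled for the scan only.
#' @return Integer vector of selected row indices into `majority_bits`, with
#'   attributes `k_star`, `silhouette` (named score vector over the k grid),
#'   `allocation` (per-cluster draw counts) and `fallback` (logical; TRUE
#'   when degenerate input forced plain random sampling).
#' @export
balance_by_clustering <- function(majority_bits, minority_size, seed = 1L,
                                  nstart = 10L, silhouette_cap = 1000L) {
  stopifnot(is.matrix(majority_bits))
  m <- nrow(majority_bits)
  if (minority_size < 2L) stop("minority_size must be at least 2", call. = FALSE)
  if (m <= minority_size) {
    stop("majority class must be larger than minority_size", call. = FALSE)
  }
  X <- majority_bits
  storage.mode(X) <- "double"
  n_distinct <- nrow(unique(X))
  if (n_distinct < 2L) {
    set.seed(seed)
    sel <- sort(sample.int(m, minority_size))
    return(structure(sel, k_star = NA_integer_, silhouette = NULL,
                     allocation = NULL, fallback = TRUE))
  }
  scan_rows <- seq_len(m)
  if (m > silhouette_cap) {
    set.seed(seed)
    scan_rows <- sort(sample.int(m, silhouette_cap))
  }
  d <- stats::dist(X[scan_rows, , drop = FALSE])
  k_max <- min(minority_size, n_distinct, length(scan_rows) - 1L)
  sil <- rep(NA_real_, k_max - 1L)
  names(sil) <- as.character(2:k_max)
  best_k <- NA_integer_
  best_sil <- -Inf
  for (k in 2:k_max) {
    set.seed(seed + k)
    km <- suppressWarnings(stats::kmeans(X[scan_rows, , drop = FALSE], centers = k,
                                         nstart = nstart, iter.max = 100L))
    s <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    sil[as.character(k)] <- s
    if (s > best_sil) {            # strict: ties resolve toward smaller k
      best_sil <- s
      best_k <- k
    }
  }
  # final clustering of the full majority class at k*
  set.seed(seed + best_k)
  km <- suppressWarnings(stats::kmeans(X, centers = best_k, nstart = nstart,
                                       iter.max = 100L))
  sizes <- as.integer(table(factor(km$cluster, levels = seq_len(best_k))))
  alloc <- largest_remainder_allocation(sizes, minority_size)
  set.seed(seed)
  sel <- unlist(lapply(seq_len(best_k), function(cl) {
    idx <- which(km$cluster == cl)
    if (alloc[cl] == 0L) return(integer(0))
    if (length(idx) == 1L) return(idx)
    sample(idx, alloc[cl])
  }), use.names = FALSE)
  structure(sort(sel), k_star = best_k, silhouette = sil,
            allocation = alloc, fallback = FALSE)
}

#' Randomly split compounds into train / test / external partitions
#'
#' Label-agnostic seeded random assignment honoring the requested fractions
#' to within one compound per partition.
#'
#' @param n number of compounds (at least 10).
#' @param ratios partition fractions summing to 1 (default 60/20/20).
#' @param seed integer seed.
#' @return factor of length `n` with levels `train`, `test`, `external`.
#' @export
split_dataset <- function(n, ratios = c(train = 0.6, test = 0.2, external = 0.2),
                          seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  if (n < 10L) stop("at least 10 compounds are required to split", call. = FALSE)
  sizes <- {
    quota <- n * ratios
    alloc <- floor(quota)
    rem <- quota - alloc
    left <- n - sum(alloc)
    if (left > 0) {
      ord <- order(-rem)[seq_len(left)]
      alloc[ord] <- alloc[ord] + 1
    }
    as.integer(alloc)
  }
  set.seed(seed)
  labs <- rep(c("train", "test", "external"), times = sizes)
  factor(sample(labs), levels = c("train", "test", "external"))
}

#' Filter out low-variance fingerprint columns
#'
#' Computed on the training partition only and applied unchanged everywhere
#' else. Population variance is used (divide by n); for a binary column with
#' set-bit frequency p this equals p(1-p). Columns with variance strictly
#' below the threshold are removed.
#'
#' @param train_bits binary matrix of training-partition fingerprints.
#' @param threshold minimum retained variance (default 0.05).
#' @return integer vector of retained column indices.
#' @export
variance_filter <- function(train_bits, threshold = 0.05) {
  stopifnot(is.matrix(train_bits), nrow(train_bits) >= 1L)
  p <- colMeans(train_bits)
  v <- colMeans(train_bits^2) - p^2
  kept <- which(v >= threshold)
  if (!length(kept)) {
    stop(sprintf(
      "variance filter at %.3f removed every column (max variance %.4f)",
      threshold, max(v)), call. = FALSE)
  }
  kept
}

#' Fit a PCA-Euclidean applicability domain
#'
#' PCA (mean-centered, unscaled covariance) is fitted on the
#' variance-filtered training fingerprints; the smallest number of leading
#' components whose cumulative explained variance exceeds 90% is retained.
#' The domain is the ball, in that component space, around the centroid of
#' the training projections whose radius is the maximum training distance:
#' every training compound is in-domain by construction, and a query is
#' in-domain iff its Euclidean distance to the centroid does not exceed that
#' maximum.
#'
#' @param train_bits training fingerprint matrix (variance-filtered columns).
#' @param var_explained cumulative explained-variance target (default 0.9,
#'   exceeded strictly).
#' @return object of class `applicability_domain`.
#' @export
fit_applicability_domain <- function(train_bits, var_explained = 0.9) {
  stopifnot(is.matrix(train_bits), nrow(train_bits) >= 2L)
  X <- train_bits
  storage.mode(X) <- "double"
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  cum <- cumsum(ev) / sum(ev)
  nc <- which(cum > var_explained)[1L]
  if (is.na(nc)) nc <- length(ev)
  scores <- pr$x[, seq_len(nc), drop = FALSE]
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2L, centroid)^2))
  structure(
    list(center = pr$center,
         rotation = pr$rotation[, seq_len(nc), drop = FALSE],
         centroid = centroid,
         n_components = nc,
         cum_var = cum[nc],
         max_distance = max(d),
         n_train = nrow(X),
         n_columns = ncol(X)),
    class = "applicability_domain"
  )
}

#' Apply an applicability domain to query fingerprints
#'
#' @param ad an `applicability_domain` object.
#' @param bits query matrix over the same (variance-filtered) columns the
#'   domain was fitted on.
#' @return data.frame with `distance` (Euclidean, in component space) and
#'   `in_domain` (logical). A relative tolerance of 1e-8 on the radius
#'   absorbs floating-point noise so training compounds always re-enter
#'   their own domain.
#' @export
apply_applicability_domain <- function(ad, bits) {
  stopifnot(inherits(ad, "applicability_domain"), is.matrix(bits))
  if (ncol(bits) != ad$n_columns) {
    stop(sprintf("query has %d columns but the domain was fitted on %d",
                 ncol(bits), ad$n_columns), call. = FALSE)
  }
  X <- bits
  storage.mode(X) <- "double"
  proj <- sweep(X, 2L, ad$center) %*% ad$rotation
  d <- sqrt(rowSums(sweep(proj, 2L, ad$centroid)^2))
  tol <- ad$max_distance * 1e-8 + 1e-12
  data.frame(distance = as.numeric(d),
             in_domain = as.numeric(d) <= ad$max_distance + tol)
}

#' @export
print.applicability_domain <- function(x, ...) {
  cat(sprintf(
    "PCA-Euclidean applicability domain: %d components (%.1f%% variance), radius %.4f, fitted on %d compounds x %d columns\n",
    x$n_components, 100 * x$cum_var, x$max_distance, x$n_train, x$n_columns))
  invisible(x)
}

#' Build a modeling dataset from fingerprints and labels
#'
#' Chains the dataset-construction steps in their canonical order: balance
#' the classes by k-means undersampling of the majority class (skipped when
#' the classes already differ by at most one compound), randomly split
#' 60/20/20 into train/test/external, variance-filter the columns on the
#' training partition, and fit the PCA-Euclidean applicability domain on the
#' filtered training fingerprints. Test and external compounds are flagged
#' in- or out-of-domain for downstream metric computation.
#'
#' @param bits binary fingerprint matrix (rownames = compound keys).
#' @param labels binary activity vector (1 = active) aligned with `bits`.
#' @param cell_line identifier recorded with the dataset.
#' @param seed integer seed for balancing and splitting.
#' @param ratios split fractions (default 60/20/20).
#' @param var_threshold variance-filter cutoff (default 0.05).
#' @param balance undersample the majority class first (default TRUE).
#' @param ... passed to [balance_by_clustering()].
#' @return object of class `qsar_dataset`: list with `bits` (balanced rows,
#'   all 1,024 columns), `labels`, `partition`, `kept_columns`, `ad`,
#'   `in_domain`, `distance`, `keys`, `cell_line`, `seed`, `balance_info`.
#' @export
build_dataset <- function(bits, labels, cell_line = "CELL", seed = 1L,
                          ratios = c(train = 0.6, test = 0.2, external = 0.2),
                          var_threshold = 0.05, balance = TRUE, ...) {
  stopifnot(is.matrix(bits), nrow(bits) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  keys <- rownames(bits)
  if (is.null(keys)) keys <- sprintf("CPD%05d", seq_len(nrow(bits)))

  balance_info <- NULL
  idx <- seq_len(nrow(bits))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (balance && abs(n1 - n0) > 1L) {
    maj <- if (n1 > n0) 1L else 0L
    maj_idx <- which(labels == maj)
    min_idx <- which(labels != maj)
    sel <- balance_by_clustering(bits[maj_idx, , drop = FALSE],
                                 minority_size = length(min_idx),
                                 seed = seed, ...)
    balance_info <- list(k_star = attr(sel, "k_star"),
                         allocation = attr(sel, "allocation"),
                         silhouette = attr(sel, "silhouette"),
                         fallback = attr(sel, "fallback"),
                         majority_class = maj)
    idx <- sort(c(min_idx, maj_idx[sel]))
  }
  bits <- bits[idx, , drop = FALSE]
  labels <- labels[idx]
  keys <- keys[idx]

  partition <- split_dataset(nrow(bits), ratios = ratios, seed = seed)
  tr <- partition == "train"
  kept <- variance_filter(bits[tr, , drop = FALSE], threshold = var_threshold)
  ad <- fit_applicability_domain(bits[tr, kept, drop = FALSE])
  dom <- apply_applicability_domain(ad, bits[, kept, drop = FALSE])

  structure(
    list(bits = bits, labels = labels, partition = partition,
         kept_columns = kept, ad = ad,
         in_domain = dom$in_domain, distance = dom$distance,
         keys = keys, cell_line = cell_line, seed = seed,
         balance_info = balance_info),
    class = "qsar_dataset"
  )
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("QSAR dataset [%s]: %d compounds (%d active / %d inactive)\n",
              x$cell_line, nrow(x$bits), sum(x$labels == 1L), sum(x$labels == 0L)))
  cat(sprintf("  partition: %s\n",
              paste(sprintf("%s=%d", levels(x$partition), table(x$partition)),
                    collapse = ", ")))
  cat(sprintf("  kept columns: %d of %d; AD: %d components, radius %.3f\n",
              length(x$kept_columns), ncol(x$bits),
              x$ad$n_components, x$ad$max_distance))
  if (!is.null(x$balance_info) && !isTRUE(x$balance_info$fallback)) {
    cat(sprintf("  balanced by k-means undersampling (k* = %d)\n",
                x$balance_info$k_star))
  }
  invisible(x)
}
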