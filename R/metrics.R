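#' Balanced classification rate with imbalance penalty
#'
#' `bcr(se, sp) = ((se + sp) / 2) * (1 - |se - sp|)`: the mean of sensitivity
#' and specificity, multiplied by a penalty that punishes any gap between
#' them. It equals the plain balanced accuracy when `se == sp`, is bounded
#' above by `(se + sp) / 2`, and collapses to 0 at maximal imbalance. Used as
#' the fitness function for both variable selection and ensemble
#' optimization.
#'
#' @param se sensitivity (true-positive rate among actives), in \[0, 1\].
#' @param sp specificity (true-negative rate among inactives), in \[0, 1\].
#' @return numeric in \[0, 1\]; vectorized over `se`/`sp`.
#' @examples
#' bcr(1, 1)    # 1
#' bcr(0.8, 0.8) # 0.8
#' bcr(1, 0.5)  # 0.375
#' @export
bcr <- function(se, sp) {
  stopifnot(is.numeric(se), is.numeric(sp))
  if (any(!is.finite(se)) || any(!is.finite(sp)) ||
      any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    stop("se and sp must lie in [0, 1]", call. = FALSE)
  }
  ((se + sp) / 2) * (1 - abs(se - sp))
}

#' Classification metrics from predicted probabilities
#'
#' Predictions are thresholded at `prob > threshold` (default 0.5).
#'
#' @param labels binary vector (1 = active).
#' @param prob predicted active-class probabilities.
#' @param threshold decision threshold.
#' @return list with `se`, `sp`, `bcr`, `f1`, `acc`, `n`. When a class is
#'   absent from `labels` its rate is `NA` and `bcr` is `NA`.
#' @export
class_metrics <- function(labels, prob, threshold = 0.5) {
  stopifnot(length(labels) == length(prob))
  labels <- as.integer(labels)
  pred <- prob > threshold
  pos <- labels == 1L
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  b <- if (is.na(se) || is.na(sp)) NA_real_ else bcr(se, sp)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(se = se, sp = sp, bcr = b, f1 = f1,
       acc = (tp + tn) / length(labels), n = length(labels))
}
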