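#' @title Early-recognition metrics and cross-cell-line consensus screening
#' @name screening
#' @description
#' A ranked screen is a score vector over compounds with known
#' active/inactive labels (actives `n` of `N` total, `Ra = n/N`). Early
#' recognition is quantified by the robust initial enhancement
#' `RIE = sum_i exp(-alpha * r_i / N) / E_uniform`, where the sum runs over
#' the active ranks and the denominator is the expectation of that sum under
#' uniform random ranking, `(n/N) * (1 - e^(-alpha)) / (e^(alpha/N) - 1)`;
#' by BEDROC, its rescaling to \[0, 1\] via the attainable extremes
#' `RIEmax = (1 - e^(-alpha * Ra)) / (Ra * (1 - e^(-alpha)))` and
#' `RIEmin = (1 - e^(alpha * Ra)) / (Ra * (1 - e^(alpha)))`; and by the
#' enrichment factor at a top fraction chi,
#' `EF = #\{actives with rank <= chi * N\} / (chi * n)`. The exponent alpha
#' sets the early-recognition emphasis; alpha = 160.9 concentrates about 80%
#' of the weight mass in the top 1% of the list.
NULL

#' Construct a ranked screen
#'
#' @param scores numeric scores, higher = more likely active.
#' @param labels binary labels (1 = active); both classes must be present.
#' @param keys optional compound identifiers.
#' @return object of class `ranked_screen` with fields `scores`, `labels`,
#'   `keys`, `n` (actives), `N` (total), `Ra` (= n/N).
#' @export
ranked_screen <- function(scores, labels, keys = NULL) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n <- sum(labels == 1L)
  N <- length(labels)
  if (n == 0L || n == N) {
    stop("a ranked screen needs both actives and inactives", call. = FALSE)
  }
  if (is.null(keys)) keys <- sprintf("SCR%06d", seq_len(N))
  structure(list(scores = scores, labels = labels, keys = keys,
                 n = n, N = N, Ra = n / N),
            class = "ranked_screen")
}

# 1-based ranks (1 = best score); score ties broken by a seeded random
# permutation so tied blocks carry no ordering bias.
screen_ranks <- function(screen, tie_seed = 1L) {
  set.seed(tie_seed)
  jitter_ord <- sample.int(screen$N)
  o <- order(-screen$scores, jitter_ord)
  ranks <- integer(screen$N)
  ranks[o] <- seq_len(screen$N)
  ranks
}

rie_extremes <- function(alpha, Ra) {
  c(min = (1 - exp(alpha * Ra)) / (Ra * (1 - exp(alpha))),
    max = (1 - exp(-alpha * Ra)) / (Ra * (1 - exp(-alpha))))
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially rank-weighted recovery of actives, normalized by its
#' expectation under uniform random ranking; RIE = 1 for a typical random
#' ordering, larger when actives concentrate early.
#'
#' @param screen a [ranked_screen()].
#' @param alpha positive early-recognition exponent.
#' @param tie_seed seed for the tie-breaking permutation.
#' @param tie_draws number of tie-break draws to average over (default 1).
#' @return numeric RIE value.
#' @export
rie <- function(screen, alpha, tie_seed = 1L, tie_draws = 1L) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  N <- screen$N
  n <- screen$n
  denom <- (n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  vals <- vapply(seq_len(tie_draws), function(d) {
    r <- screen_ranks(screen, tie_seed + d - 1L)
    sum(exp(-alpha * r[screen$labels == 1L] / N)) / denom
  }, numeric(1))
  mean(vals)
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' RIE rescaled by its attainable minimum and maximum so that the value lies
#' in \[0, 1\], reaching 1 when all actives occupy the top ranks and 0 when
#' they occupy the bottom ranks.
#'
#' @inheritParams rie
#' @return numeric BEDROC value in \[0, 1\].
#' @export
bedroc <- function(screen, alpha, tie_seed = 1L, tie_draws = 1L) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  ex <- rie_extremes(alpha, screen$Ra)
  (rie(screen, alpha, tie_seed, tie_draws) - ex[["min"]]) /
    (ex[["max"]] - ex[["min"]])
}

#' Calibrate alpha from a top fraction and its weight mass
#'
#' The exponential rank weight `exp(-alpha * r / N)` places a fraction
#' `1 - exp(-alpha * chi)` of its total mass inside the top `chi` of the
#' list (continuum limit). Solving for alpha gives
#' `alpha = -log(1 - mass) / chi`: e.g. requiring 80% of the mass in the top
#' 1% yields alpha = 160.9.
#'
#' @param chi top fraction of the ranked list, in (0, 1).
#' @param mass weight mass to concentrate there, in (0, 1).
#' @return numeric alpha.
#' @seealso [mass_fraction_for_alpha()] for the inverse.
#' @export
alpha_for_mass_fraction <- function(chi, mass) {
  stopifnot(length(chi) == 1L, length(mass) == 1L)
  if (!is.finite(chi) || chi <= 0 || chi >= 1) {
    stop("chi must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(mass) || mass <= 0 || mass >= 1) {
    stop("mass must lie strictly in (0, 1)", call. = FALSE)
  }
  -log(1 - mass) / chi
}

#' Weight mass of the top fraction under an exponential rank weight
#'
#' Inverse of [alpha_for_mass_fraction()]: the fraction of the exponential
#' weight mass contained in the top `chi` of the list at a given alpha.
#'
#' @param alpha positive exponent.
#' @param chi top fraction, in (0, 1).
#' @return numeric mass in (0, 1).
#' @export
mass_fraction_for_alpha <- function(alpha, chi) {
  stopifnot(alpha > 0, chi > 0, chi < 1)
  1 - exp(-alpha * chi)
}

#' Enrichment factor at a top fraction
#'
#' `EF = #\{actives with rank <= chi * N\} / (chi * n)`, with the top window
#' holding `floor(chi * N)` compounds (at least 1). EF is about 1 for a
#' random ranking and reaches its maximum `1/chi` when the window contains
#' the whole active set.
#'
#' @param screen a [ranked_screen()].
#' @param chi top fraction, in (0, 1\]; `chi * N` must be at least 1.
#' @param tie_seed seed for the tie-breaking permutation.
#' @return numeric EF value.
#' @export
enrichment_factor <- function(screen, chi, tie_seed = 1L) {
  stopifnot(inherits(screen, "ranked_screen"))
  if (!is.finite(chi) || chi <= 0 || chi > 1) {
    stop("chi must lie in (0, 1]", call. = FALSE)
  }
  if (chi * screen$N < 1) {
    stop("chi * N is below 1: the top window would be empty", call. = FALSE)
  }
  w <- max(1L, floor(chi * screen$N))
  r <- screen_ranks(screen, tie_seed)
  sum(r[screen$labels == 1L] <= w) / (chi * screen$n)
}

#' Merge an evaluation table with a decoy table into a screening ledger
#'
#' Row-binds the labeled evaluation compounds with the (presumed-inactive)
#' decoys and deduplicates by compound key, keeping the evaluation entry
#' when a key occurs in both.
#'
#' @param evaluation data.frame with columns `key` (e.g. InChIKey) and
#'   `label` (1 = active); further columns are carried through.
#' @param decoys data.frame with a `key` column; labels forced to 0.
#' @return data.frame of unique ledger entries with `key`, `label`, `origin`
#'   (`"evaluation"` / `"decoy"`).
#' @export
build_screening_ledger <- function(evaluation, decoys) {
  stopifnot(is.data.frame(evaluation), is.data.frame(decoys),
            "key" %in% names(evaluation), "key" %in% names(decoys),
            "label" %in% names(evaluation))
  ev <- data.frame(key = as.character(evaluation$key),
                   label = as.integer(evaluation$label),
                   origin = "evaluation", stringsAsFactors = FALSE)
  dc <- data.frame(key = as.character(decoys$key), label = 0L,
                   origin = "decoy", stringsAsFactors = FALSE)
  all <- rbind(ev, dc)
  out <- all[!duplicated(all$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-cell-line combination search
#'
#' For each cell line one model family is chosen among the supplied
#' predictors (typically RF, DTREE, KNN and the optimized ensemble "E");
#' every family assignment across cell lines is enumerated (f^c
#' combinations, 256 for four cell lines and four families). A compound
#' enters a combination's ranking only if it is in-domain for every cell
#' line's applicability domain; its consensus score is the arithmetic mean
#' of the per-cell-line predicted probabilities. Combinations are ranked by
#' BEDROC at the anchor alpha, with BEDROC and EF profiles over the supplied
#' grids.
#'
#' @param cell_models named list (one element per cell line), each a list
#'   with `models` (named list of predictors - `qsar_model` or
#'   `ensemble_model` - keyed by family label) and `dataset` (the cell
#'   line's `qsar_dataset`, supplying kept columns and applicability
#'   domain).
#' @param bits full-width fingerprint matrix of the screening compounds.
#' @param labels optional binary labels enabling BEDROC/EF scoring.
#' @param alpha_grid alphas for the BEDROC profile.
#' @param chi_grid top fractions for the EF profile.
#' @param alpha_anchor alpha used to rank combinations (default 160.9).
#' @param tie_seed tie-breaking seed for rankings.
#' @return object of class `combination_search`: `results` (list, ranked by
#'   anchor BEDROC when labels are given, each holding `choice`,
#'   `consensus_scores`, `bedroc` profile, `ef` profile, `anchor_bedroc`),
#'   `in_domain` (per-compound logical), `n_excluded`, `families`,
#'   `cell_lines`.
#' @export
combination_search <- function(cell_models, bits, labels = NULL,
                               alpha_grid = c(10, 20, 53.6, 80.5, 160.9, 321.9),
                               chi_grid = c(0.005, 0.01, 0.02, 0.05, 0.1),
                               alpha_anchor = 160.9, tie_seed = 1L) {
  stopifnot(is.list(cell_models), length(cell_models) >= 1L, is.matrix(bits))
  cell_lines <- names(cell_models)
  stopifnot(!is.null(cell_lines), all(nzchar(cell_lines)))

  in_dom <- rep(TRUE, nrow(bits))
  probs <- list()
  for (cl in cell_lines) {
    cm <- cell_models[[cl]]
    ds <- cm$dataset
    dom <- apply_applicability_domain(ds$ad, bits[, ds$kept_columns, drop = FALSE])
    in_dom <- in_dom & dom$in_domain
    probs[[cl]] <- lapply(cm$models, function(m) predict(m, bits))
  }
  if (!any(in_dom)) {
    stop("no compound is in-domain for every cell line", call. = FALSE)
  }
  families <- lapply(cell_models, function(cm) names(cm$models))
  combos <- expand.grid(families, stringsAsFactors = FALSE)
  names(combos) <- cell_lines

  keep <- which(in_dom)
  scored <- !is.null(labels)
  results <- lapply(seq_len(nrow(combos)), function(i) {
    choice <- unlist(combos[i, , drop = TRUE])
    P <- vapply(cell_lines, function(cl) probs[[cl]][[choice[[cl]]]][keep],
                numeric(length(keep)))
    if (is.null(dim(P))) P <- matrix(P, nrow = length(keep))
    consensus <- rowMeans(P)
    names(consensus) <- rownames(bits)[keep]
    out <- list(choice = choice, consensus_scores = consensus)
    if (scored) {
      scr <- ranked_screen(consensus, labels[keep])
      out$bedroc <- vapply(alpha_grid, function(a) bedroc(scr, a, tie_seed),
                           numeric(1))
      names(out$bedroc) <- as.character(alpha_grid)
      out$ef <- vapply(chi_grid, function(x) enrichment_factor(scr, x, tie_seed),
                       numeric(1))
      names(out$ef) <- as.character(chi_grid)
      out$anchor_bedroc <- bedroc(scr, alpha_anchor, tie_seed)
    }
    out
  })
  if (scored) {
    results <- results[order(-vapply(results, `[[`, numeric(1), "anchor_bedroc"))]
  }
  structure(
    list(results = results, in_domain = in_dom,
         n_excluded = sum(!in_dom), families = families,
         cell_lines = cell_lines, alpha_anchor = alpha_anchor),
    class = "combination_search"
  )
}

#' @export
print.combination_search <- function(x, ...) {
  cat(sprintf(
    "Combination search: %d combinations over %d cell lines (%d compounds excluded by domain)\n",
    length(x$results), length(x$cell_lines), x$n_excluded))
  top <- x$results[[1L]]
  if (!is.null(top$anchor_bedroc)) {
    cat(sprintf("  best [%s]: BEDROC(alpha=%.1f) = %.3f\n",
                paste(top$choice, collapse = ", "), x$alpha_anchor,
                top$anchor_bedroc))
  }
  invisible(x)
}

#' Intersect consensus hits of two models across probability thresholds
#'
#' For each threshold t, returns the compounds whose consensus score exceeds
#' t in BOTH score maps, plus per-model exceedance counts and score maxima.
#'
#' @param consensus_a,consensus_b named numeric score vectors covering the
#'   same compound universe (names = compound keys).
#' @param thresholds probability cutoffs (default 0.5, 0.55, 0.6; strict
#'   `>`).
#' @return list with `hits` (named list of key vectors per threshold),
#'   `counts` (data.frame threshold / n_a / n_b / n_both) and `maxima`
#'   (per-model maximum scores).
#' @export
select_consensus_hits <- function(consensus_a, consensus_b,
                                  thresholds = c(0.5, 0.55, 0.6)) {
  stopifnot(!is.null(names(consensus_a)), !is.null(names(consensus_b)))
  if (!setequal(names(consensus_a), names(consensus_b))) {
    stop("the two consensus score maps must cover the same compound universe",
         call. = FALSE)
  }
  b <- consensus_b[names(consensus_a)]
  hits <- lapply(thresholds, function(t) {
    names(consensus_a)[consensus_a > t & b > t]
  })
  names(hits) <- as.character(thresholds)
  counts <- data.frame(
    threshold = thresholds,
    n_a = vapply(thresholds, function(t) sum(consensus_a > t), integer(1)),
    n_b = vapply(thresholds, function(t) sum(b > t), integer(1)),
    n_both = vapply(hits, length, integer(1))
  )
  rownames(counts) <- NULL
  list(hits = hits, counts = counts,
       maxima = c(a = max(consensus_a), b = max(b)))
}
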