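#' Compute 1,024-bit circular fingerprints (radius 2)
#'
#' Describes each standardized molecule by an ECFP4-style circular
#' fingerprint: atom environments up to radius 2 (diameter 4), hashed to
#' binary bits. OpenBabel emits 4,096-bit ECFP4 vectors; these are folded
#' 4-to-1 by bitwise OR onto 1,024 columns, the standard length-reduction for
#' hashed fingerprints. Bits are deterministic for a given canonical SMILES.
#'
#' @param smiles character vector of (standardized) SMILES strings.
#' @param keys row identifiers, typically InChIKeys; defaults to the names of
#'   `smiles` or the SMILES themselves.
#' @param n_bits folded fingerprint length (default 1024).
#' @return Integer 0/1 matrix, one row per successfully fingerprinted
#'   molecule, `n_bits` columns, rownames = `keys`. Molecules whose
#'   fingerprint computation fails are dropped; their keys are reported in
#'   the `"dropped"` attribute.
#' @export
compute_fingerprints <- function(smiles, keys = NULL, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, n_bits >= 1L)
  if (is.null(keys)) keys <- if (!is.null(names(smiles))) names(smiles) else smiles
  stopifnot(length(keys) == length(smiles))
  raw <- matrix(NA_integer_, nrow = length(smiles), ncol = 4096L)
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    v <- tryCatch(
      suppressWarnings(ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", smiles[i], identity), "ECFP4")),
      error = function(e) NULL)
    v <- as.integer(v)
    if (length(v) == 4096L && !anyNA(v)) {
      raw[i, ] <- v
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("no molecule could be fingerprinted", call. = FALSE)
  folded <- fold_bits(raw[ok, , drop = FALSE], n_bits)
  rownames(folded) <- keys[ok]
  structure(folded, dropped = keys[!ok])
}

# Fold a wider binary matrix onto n_bits columns by bitwise OR of the
# congruent column blocks.
fold_bits <- function(bits, n_bits) {
  p <- ncol(bits)
  stopifnot(p %% n_bits == 0L)
  blocks <- p / n_bits
  out <- matrix(0L, nrow = nrow(bits), ncol = n_bits)
  for (b in seq_len(blocks)) {
    out <- pmax(out, bits[, ((b - 1L) * n_bits + 1L):(b * n_bits), drop = FALSE])
  }
  storage.mode(out) <- "integer"
  out
}
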