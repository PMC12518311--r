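#' @title Molecule standardization via OpenBabel
#' @name standardize
#' @description
#' Compounds coming from heterogeneous bioactivity and natural-product
#' databases are reduced to a single achiral canonical representation before
#' any modeling: stereo descriptors are inconsistently reported across sources
#' (unknown absolute configuration, racemic mixtures) and binary circular
#' fingerprints do not encode chirality, so enantiomers must collapse to one
#' entry. Standardization is delegated to OpenBabel (the `obabel` executable):
#' canonical SMILES written without isotope/chirality markers, plus the
#' InChIKey of the standardized structure as the deduplication key.
NULL

OBABEL_REQUIRED_MSG <- "the 'obabel' executable (OpenBabel) is required but was not found on the PATH"

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop(OBABEL_REQUIRED_MSG, call. = FALSE)
  p
}

# Lightweight syntactic validity gate. OpenBabel silently repairs some
# malformed inputs (e.g. "C(" parses as methane), so structurally broken
# strings must be rejected before they reach the toolkit. This checks balance
# and character vocabulary only; all chemistry stays in OpenBabel.
smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[[:space:]]", s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth_p <- cumsum((chars == "(") - (chars == ")"))
  depth_b <- cumsum((chars == "[") - (chars == "]"))
  if (any(depth_p < 0) || any(depth_b < 0)) return(FALSE)
  if (depth_p[length(chars)] != 0 || depth_b[length(chars)] != 0) return(FALSE)
  # ring-closure labels must come in pairs (outside of bracket atoms, where
  # digits are charges/isotopes/H-counts instead)
  outside <- depth_b == 0 | (chars %in% c("[", "]"))
  ring <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (outside[i] && chars[i] == "%" && i + 2L <= n) {
      ring <- c(ring, paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else {
      if (outside[i] && grepl("[0-9]", chars[i])) ring <- c(ring, chars[i])
      i <- i + 1L
    }
  }
  if (length(ring) && any(table(ring) %% 2L != 0L)) return(FALSE)
  TRUE
}

# Keep the largest covalent fragment of a multi-fragment (salt/mixture)
# SMILES. Fragment size is approximated by its count of atom-symbol letters
# (H excluded); the dot separator never occurs inside bracket atoms.
largest_fragment <- function(s) {
  if (!grepl(".", s, fixed = TRUE)) return(s)
  frags <- strsplit(s, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) return(s)
  size <- vapply(frags, function(f) {
    sum(strsplit(gsub("H", "", f), "")[[1]] %in% c(letters, LETTERS))
  }, integer(1))
  frags[which.max(size)]
}

# Run obabel over a batch of SMILES, one call for the whole vector. Records
# are tagged with their index as the molecule title so failed conversions can
# be identified by their absence from the output.
obabel_batch <- function(smiles, out_format, extra_args = character(0)) {
  exe <- obabel_path()
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inf)
  out <- suppressWarnings(
    system2(exe, c(inf, paste0("-o", out_format), extra_args, "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  out[nzchar(trimws(out))]
}

#' Standardize SMILES strings to achiral canonical form with InChIKeys
#'
#' Applies the curation chain: largest-fragment selection for salts/mixtures,
#' syntactic validity gating, sanitization/canonicalization with stereo and
#' isotope markers removed, and InChIKey generation. Two enantiomeric inputs
#' yield identical canonical SMILES and InChIKey. Standardization is
#' idempotent: feeding the returned `canonical_smiles` back reproduces it.
#'
#' @param smiles character vector of SMILES strings.
#' @return A data.frame with one row per input: `input_smiles`,
#'   `canonical_smiles`, `inchikey` (14-10-1 hyphenated layout), `valid`
#'   (logical) and `reason` (`NA` when valid; otherwise `"parse_failure"` or
#'   `"inchikey_failure"`). Invalid records keep `NA` structure fields and are
#'   meant to be logged and dropped by callers, never silently kept.
#' @examples
#' \dontrun{
#' standardize_molecules(c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O", "C("))
#' }
#' @export
standardize_molecules <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  n <- length(smiles)
  res <- data.frame(
    input_smiles = smiles,
    canonical_smiles = NA_character_,
    inchikey = NA_character_,
    valid = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  frag <- vapply(smiles, function(s) {
    if (is.na(s)) "" else largest_fragment(trimws(s))
  }, character(1), USE.NAMES = FALSE)
  ok <- vapply(frag, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  res$reason[!ok] <- "parse_failure"
  if (any(ok)) {
    idx <- which(ok)
    out <- obabel_batch(frag[idx], "can", "-xi")
    # output lines are "<canonical-smiles>\t<index-title>"
    parts <- strsplit(out, "[\t ]+")
    got_idx <- suppressWarnings(
      vapply(parts, function(p) as.integer(p[length(p)]), integer(1))
    )
    can <- vapply(parts, function(p) p[1L], character(1))
    keep <- !is.na(got_idx) & got_idx >= 1L & got_idx <= length(idx) & nzchar(can)
    rows <- idx[got_idx[keep]]
    res$canonical_smiles[rows] <- can[keep]
    failed <- setdiff(idx, rows)
    res$reason[failed] <- "parse_failure"
    # InChIKeys for successfully canonicalized structures
    if (length(rows)) {
      ik <- inchikeys_for(res$canonical_smiles[rows])
      res$inchikey[rows] <- ik
      bad_ik <- rows[is.na(ik)]
      res$reason[bad_ik] <- "inchikey_failure"
      good <- setdiff(rows, bad_ik)
      res$valid[good] <- TRUE
    }
  }
  res
}

# InChIKey generation for already-canonical SMILES. The inchikey output
# format carries no molecule title, so alignment relies on every input
# converting; if counts mismatch, fall back to per-molecule calls.
inchikeys_for <- function(smiles) {
  pat <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"
  one <- function(s) {
    out <- trimws(obabel_batch(s, "inchikey"))
    out <- out[grepl(pat, out)]
    if (length(out) == 1L) out else NA_character_
  }
  out <- trimws(obabel_batch(smiles, "inchikey"))
  out <- out[grepl(pat, out)]
  if (length(out) == length(smiles)) return(out)
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}
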