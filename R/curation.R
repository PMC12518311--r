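#' @title Curation of compound-cell-line activity records
#' @name curation
#' @description
#' Raw activity tables hold one row per reported IC50 measurement of a
#' compound against a cell line. Curation standardizes the structures,
#' applies the 10 uM activity threshold, enforces replicate class consistency
#' within each compound-cell-line pair, and diverts compounds measured in
#' three or more cell lines to a reserved virtual-screening set so they never
#' leak into training.
NULL

#' Classify an IC50 value as active or inactive
#'
#' A compound is active against a cell line when its IC50 lies strictly below
#' the threshold (default 10 uM); values at or above the threshold, including
#' exact equality, are inactive.
#'
#' @param ic50 numeric vector of IC50 values in uM; must be positive.
#' @param threshold activity cutoff in uM (default 10).
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
classify_activity <- function(ic50, threshold = 10) {
  stopifnot(is.numeric(ic50), length(ic50) >= 1L, is.numeric(threshold),
            length(threshold) == 1L, threshold > 0)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 values must be positive and finite", call. = FALSE)
  }
  ifelse(ic50 < threshold, "active", "inactive")
}

#' Resolve replicate measurements of one compound-cell-line pair
#'
#' Replicates are compared on their activity class, never on the raw values:
#' a pair is kept only when every report lands in the same class, and is
#' excluded otherwise. Values are not averaged.
#'
#' @param ic50 numeric vector of replicate IC50 values (uM) for a single
#'   compound-cell-line pair.
#' @param threshold activity cutoff in uM.
#' @return A list with `kept` (logical), `label` (`"active"`/`"inactive"` or
#'   `NA` when excluded) and `n_reports`.
#' @export
resolve_replicates <- function(ic50, threshold = 10) {
  if (length(ic50) == 0L) stop("no replicate records supplied", call. = FALSE)
  cls <- unique(classify_activity(ic50, threshold))
  if (length(cls) == 1L) {
    list(kept = TRUE, label = cls, n_reports = length(ic50))
  } else {
    list(kept = FALSE, label = NA_character_, n_reports = length(ic50))
  }
}

#' Read a delimited activity table
#'
#' Accepts comma- or tab-separated text (dialect auto-detected, header
#' required) with columns `smiles`, `cell_line`, `ic50_um` and `source`.
#'
#' @param path path to the delimited file.
#' @return data.frame of raw activity records.
#' @export
read_activity_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("smiles", "cell_line", "ic50_um", "source")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("activity table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Curate raw activity records into per-cell-line labeled compound tables
#'
#' Runs the full curation chain on a raw record table: cell-line and IC50
#' validation, structure standardization (achiral canonical SMILES +
#' InChIKey), activity labeling at the IC50 threshold, replicate class
#' consistency per compound-cell-line pair, and the training-versus-screening
#' partition (compounds with retained labels in three or more distinct cell
#' lines are reserved for virtual screening only). Every input record is
#' accounted for: kept, reserved, or excluded with a reason.
#'
#' @param records data.frame with columns `smiles`, `cell_line`, `ic50_um`,
#'   `source` (as from [read_activity_table()]), or a file path.
#' @param cell_lines character vector of admissible cell-line identifiers.
#' @param threshold IC50 activity cutoff in uM.
#' @return An object of class `curated_activity`: a list with
#'   `training` (named list of per-cell-line data.frames with columns
#'   `inchikey`, `canonical_smiles`, `cell_line`, `label`, `n_reports`),
#'   `reserved` (same columns, compounds held out for screening),
#'   `exclusions` (data.frame `smiles`, `cell_line`, `reason`, one row per
#'   excluded raw record) and `counts` (accounting summary).
#' @export
curate_activity_records <- function(records,
                                    cell_lines = c("AGS", "NCI-N87", "BGC-823", "SNU-16"),
                                    threshold = 10) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_activity_table(records)
  }
  stopifnot(is.data.frame(records))
  need <- c("smiles", "cell_line", "ic50_um")
  stopifnot(all(need %in% names(records)))
  n_in <- nrow(records)
  records$.row <- seq_len(n_in)
  records$.reason <- NA_character_

  bad_cl <- !(records$cell_line %in% cell_lines)
  records$.reason[bad_cl] <- "unknown_cell_line"
  ic50 <- suppressWarnings(as.numeric(records$ic50_um))
  bad_ic <- is.na(records$.reason) & (!is.finite(ic50) | ic50 <= 0)
  records$.reason[bad_ic] <- "nonpositive_ic50"

  cand <- is.na(records$.reason)
  std_map <- NULL
  if (any(cand)) {
    uniq <- unique(records$smiles[cand])
    std <- standardize_molecules(uniq)
    std_map <- std[match(records$smiles, std$input_smiles), ]
    bad_std <- cand & !std_map$valid
    records$.reason[bad_std] <- ifelse(
      is.na(std_map$reason[bad_std]), "parse_failure", std_map$reason[bad_std])
  }

  keep <- is.na(records$.reason)
  labeled <- NULL
  if (any(keep)) {
    work <- data.frame(
      inchikey = std_map$inchikey[keep],
      canonical_smiles = std_map$canonical_smiles[keep],
      cell_line = records$cell_line[keep],
      label = classify_activity(ic50[keep], threshold),
      row = records$.row[keep],
      stringsAsFactors = FALSE
    )
    grp <- split(work, paste(work$inchikey, work$cell_line, sep = "\r"))
    rows <- lapply(grp, function(g) {
      if (length(unique(g$label)) == 1L) {
        data.frame(inchikey = g$inchikey[1L],
                   canonical_smiles = g$canonical_smiles[1L],
                   cell_line = g$cell_line[1L],
                   label = g$label[1L],
                   n_reports = nrow(g),
                   stringsAsFactors = FALSE)
      } else {
        records$.reason[g$row] <<- "inconsistent_replicates"
        NULL
      }
    })
    labeled <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(labeled) <- NULL
  }

  part <- partition_training_vs_screening(labeled, cell_lines = cell_lines)

  excl <- records[!is.na(records$.reason),
                  c("smiles", "cell_line", ".reason"), drop = FALSE]
  names(excl) <- c("smiles", "cell_line", "reason")
  rownames(excl) <- NULL

  n_reserved_records <- if (is.null(labeled)) 0L else
    sum(labeled$n_reports[labeled$inchikey %in% part$reserved$inchikey])
  n_kept_records <- if (is.null(labeled)) 0L else
    sum(labeled$n_reports) - n_reserved_records
  counts <- c(input = n_in,
              kept = n_kept_records,
              reserved = n_reserved_records,
              excluded_inconsistent = sum(excl$reason == "inconsistent_replicates"),
              excluded_invalid = sum(excl$reason != "inconsistent_replicates"))
  structure(
    list(training = part$training, reserved = part$reserved,
         exclusions = excl, counts = counts),
    class = "curated_activity"
  )
}

#' Partition labeled compounds into training pools and a reserved screening set
#'
#' Compounds carrying retained labels in three or more distinct cell lines go
#' exclusively to the reserved virtual-screening set; all other compounds go
#' to the training pool of each cell line where they are labeled. The two
#' sets are disjoint by InChIKey.
#'
#' @param labeled data.frame with columns `inchikey`, `canonical_smiles`,
#'   `cell_line`, `label`, `n_reports` (one row per compound-cell-line pair),
#'   or `NULL`.
#' @param cell_lines cell-line identifiers defining the training pools.
#' @return list with `training` (named list of per-cell-line data.frames) and
#'   `reserved` (data.frame).
#' @export
partition_training_vs_screening <- function(labeled,
                                            cell_lines = unique(labeled$cell_line)) {
  empty <- data.frame(inchikey = character(0), canonical_smiles = character(0),
                      cell_line = character(0), label = character(0),
                      n_reports = integer(0), stringsAsFactors = FALSE)
  if (is.null(labeled) || nrow(labeled) == 0L) {
    training <- stats::setNames(
      rep(list(empty), length(cell_lines)), cell_lines)
    return(list(training = training, reserved = empty))
  }
  n_lines <- tapply(labeled$cell_line, labeled$inchikey,
                    function(x) length(unique(x)))
  reserved_keys <- names(n_lines)[n_lines >= 3L]
  reserved <- labeled[labeled$inchikey %in% reserved_keys, , drop = FALSE]
  pool <- labeled[!(labeled$inchikey %in% reserved_keys), , drop = FALSE]
  training <- lapply(cell_lines, function(cl) {
    out <- pool[pool$cell_line == cl, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(training) <- cell_lines
  rownames(reserved) <- NULL
  list(training = training, reserved = reserved)
}

#' @export
print.curated_activity <- function(x, ...) {
  cat("Curated activity records\n")
  cat(sprintf("  input records:   %d\n", x$counts[["input"]]))
  cat(sprintf("  kept (training): %d records, %d cell-line pools\n",
              x$counts[["kept"]], length(x$training)))
  cat(sprintf("  reserved (screening): %d records, %d compounds\n",
              x$counts[["reserved"]],
              length(unique(x$reserved$inchikey))))
  cat(sprintf("  excluded: %d inconsistent, %d invalid\n",
              x$counts[["excluded_inconsistent"]],
              x$counts[["excluded_invalid"]]))
  invisible(x)
}
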