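#' @title Plant-source prioritization
#' @name plants
#' @description
#' Compound-plant association tables from natural-product databases are
#' merged, their species names resolved against an NCBI-style lineage dump
#' (`fullnamelineage.dmp` dialect) restricted to the green-plant clade
#' (Viridiplantae), and their structures standardized so enantiomers
#' collapse to one entry per species. Species are then ranked by how many of
#' their compounds fall in the consensus hit set, both in absolute count and
#' as a fraction of their reported compounds.
NULL

#' Build a taxonomy index from a lineage dump
#'
#' Parses pipe-and-tab delimited records (`taxid | name | lineage |`) in the
#' `fullnamelineage.dmp` dialect and retains only entries whose lineage
#' contains the green-plant clade marker. Name lookups are case- and
#' whitespace-normalized. Malformed lines are skipped and counted.
#'
#' @param lineage either a file path or a character vector of dump lines.
#' @param clade lineage marker to retain (default `"Viridiplantae"`).
#' @return object of class `taxonomy_index` with fields `table` (data.frame
#'   `name`, `name_norm`, `taxid`, `lineage`), `n_skipped`, `clade`.
#' @export
build_taxonomy_index <- function(lineage, clade = "Viridiplantae") {
  lines <- if (length(lineage) == 1L && file.exists(lineage)) {
    readLines(lineage, warn = FALSE)
  } else {
    lineage
  }
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(gsub("\t", "", lines, fixed = TRUE), "|", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) >= 3L
  n_skipped <- sum(!ok)
  parts <- parts[ok]
  tab <- data.frame(
    taxid = trimws(vapply(parts, `[[`, character(1), 1L)),
    name = trimws(vapply(parts, `[[`, character(1), 2L)),
    lineage = trimws(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(tab$name) | !grepl("^[0-9]+$", tab$taxid)
  n_skipped <- n_skipped + sum(bad)
  tab <- tab[!bad, , drop = FALSE]
  tab <- tab[grepl(clade, tab$lineage, fixed = TRUE), , drop = FALSE]
  tab$name_norm <- normalize_species(tab$name)
  tab <- tab[!duplicated(tab$name_norm), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, n_skipped = n_skipped, clade = clade),
            class = "taxonomy_index")
}

normalize_species <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Resolve species names against a taxonomy index
#'
#' @param names character vector of species names.
#' @param index a `taxonomy_index`.
#' @return data.frame with `name`, `resolved` (canonical indexed name or
#'   `NA`), `taxid` (`NA` on miss).
#' @export
resolve_species <- function(names, index) {
  stopifnot(inherits(index, "taxonomy_index"))
  i <- match(normalize_species(names), index$table$name_norm)
  data.frame(name = names,
             resolved = index$table$name[i],
             taxid = index$table$taxid[i],
             stringsAsFactors = FALSE)
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat(sprintf("Taxonomy index: %d %s names (%d malformed lines skipped)\n",
              nrow(x$table), x$clade, x$n_skipped))
  invisible(x)
}

#' Merge compound-plant association tables
#'
#' Concatenates (species, SMILES) tables from several source databases,
#' keeps only records whose species resolves in the taxonomy index (non-
#' plant entries such as processed foods drop out here), standardizes every
#' structure to its achiral canonical form, and collapses duplicates - in
#' particular enantiomers reported under the same species - to unique
#' (species, compound) pairs.
#'
#' @param tables list of data.frames with columns `species`, `smiles`
#'   (an optional `source` column is carried into the exclusion log).
#' @param index a `taxonomy_index`.
#' @return object of class `plant_associations`: `associations` (data.frame
#'   `species`, `taxid`, `inchikey`, `canonical_smiles`), `summary` (counts
#'   of species, unique compounds, associations), `exclusions` (data.frame
#'   `species`, `smiles`, `reason`).
#' @export
merge_compound_plant_tables <- function(tables, index) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            inherits(index, "taxonomy_index"))
  recs <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(all(c("species", "smiles") %in% names(t)))
    data.frame(species = as.character(t$species),
               smiles = as.character(t$smiles),
               stringsAsFactors = FALSE)
  }))
  res <- resolve_species(recs$species, index)
  unresolved <- is.na(res$resolved)

  excl <- data.frame(species = recs$species[unresolved],
                     smiles = recs$smiles[unresolved],
                     reason = rep("unresolved_taxonomy", sum(unresolved)),
                     stringsAsFactors = FALSE)
  recs <- recs[!unresolved, , drop = FALSE]
  res <- res[!unresolved, , drop = FALSE]
  if (nrow(recs)) {
    std <- standardize_molecules(unique(recs$smiles))
    m <- std[match(recs$smiles, std$input_smiles), ]
    bad <- !m$valid
    excl <- rbind(excl, data.frame(species = recs$species[bad],
                                   smiles = recs$smiles[bad],
                                   reason = rep("invalid_smiles", sum(bad)),
                                   stringsAsFactors = FALSE))
    assoc <- data.frame(species = res$resolved[!bad],
                        taxid = res$taxid[!bad],
                        inchikey = m$inchikey[!bad],
                        canonical_smiles = m$canonical_smiles[!bad],
                        stringsAsFactors = FALSE)
    assoc <- assoc[!duplicated(paste(assoc$species, assoc$inchikey, sep = "\r")),
                   , drop = FALSE]
    rownames(assoc) <- NULL
  } else {
    assoc <- data.frame(species = character(0), taxid = character(0),
                        inchikey = character(0),
                        canonical_smiles = character(0),
                        stringsAsFactors = FALSE)
  }
  if (!nrow(assoc)) {
    stop(sprintf(
      "no associations survived curation (%d records excluded: %s)",
      nrow(excl), paste(names(table(excl$reason)), table(excl$reason),
                        sep = "=", collapse = ", ")), call. = FALSE)
  }
  rownames(excl) <- NULL
  structure(
    list(associations = assoc,
         summary = c(n_species = length(unique(assoc$species)),
                     n_compounds = length(unique(assoc$inchikey)),
                     n_associations = nrow(assoc)),
         exclusions = excl),
    class = "plant_associations"
  )
}

#' @export
print.plant_associations <- function(x, ...) {
  cat(sprintf(
    "Plant associations: %d species, %d unique compounds, %d associations (%d records excluded)\n",
    x$summary[["n_species"]], x$summary[["n_compounds"]],
    x$summary[["n_associations"]], nrow(x$exclusions)))
  invisible(x)
}

hit_set_frame <- function(hit_set) {
  if (is.character(hit_set)) {
    return(data.frame(inchikey = hit_set, stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(hit_set), "inchikey" %in% names(hit_set))
  hit_set
}

#' Rank plant species by predicted-active compound content
#'
#' For each species: the number of unique linked compounds, how many of them
#' belong to the consensus hit set, the active fraction, and (when the hit
#' set carries probability columns) the mean predicted probabilities of the
#' species' hits per consensus model. Two sorted views mirror the absolute
#' and relative perspectives: by active count, and by active fraction.
#'
#' @param associations a `plant_associations` object (or its `associations`
#'   data.frame).
#' @param hit_set consensus hits: a character vector of InChIKeys or a
#'   data.frame with column `inchikey` plus optional numeric probability
#'   columns (e.g. `prob_c1`, `prob_c2`).
#' @param min_active_filters thresholds for the species tally (default
#'   1, 2, 5).
#' @return list with `species` (per-species table sorted by active count),
#'   `by_fraction` (same rows sorted by active fraction) and `tallies`
#'   (named count of species with at least each `min_active_filters` hits).
#' @export
rank_species <- function(associations, hit_set,
                         min_active_filters = c(1L, 2L, 5L)) {
  assoc <- if (inherits(associations, "plant_associations")) {
    associations$associations
  } else {
    associations
  }
  stopifnot(all(c("species", "inchikey") %in% names(assoc)))
  hs <- hit_set_frame(hit_set)
  prob_cols <- setdiff(names(hs), "inchikey")
  prob_cols <- prob_cols[vapply(hs[prob_cols], is.numeric, logical(1))]

  per <- lapply(split(assoc, assoc$species), function(g) {
    cmp <- unique(g$inchikey)
    hits <- intersect(cmp, hs$inchikey)
    row <- data.frame(species = g$species[1L],
                      n_total = length(cmp),
                      n_active = length(hits),
                      fraction = length(hits) / length(cmp),
                      stringsAsFactors = FALSE)
    for (pc in prob_cols) {
      row[[paste0("mean_", pc)]] <- if (length(hits)) {
        mean(hs[[pc]][match(hits, hs$inchikey)])
      } else {
        NA_real_
      }
    }
    row
  })
  tab <- do.call(rbind, per)
  rownames(tab) <- NULL
  by_count <- tab[order(-tab$n_active, -tab$fraction, tab$species), ]
  by_fraction <- tab[order(-tab$fraction, -tab$n_active, tab$species), ]
  rownames(by_count) <- rownames(by_fraction) <- NULL
  tallies <- vapply(min_active_filters,
                    function(m) sum(tab$n_active >= m), integer(1))
  names(tallies) <- paste0(">=", min_active_filters)
  list(species = by_count, by_fraction = by_fraction, tallies = tallies)
}

#' Summarize consensus hits by species group (genus by default)
#'
#' Aggregates the hit compounds of all species in a group, counting unique
#' compounds (a hit shared by two congeneric species counts once). The
#' default grouping takes the genus as the first token of the binomial; an
#' explicit species-to-group mapping overrides it. If the hit set carries a
#' `class` annotation column, the per-group class composition is reported.
#'
#' @param associations a `plant_associations` object or data.frame.
#' @param hit_set as in [rank_species()]; may include a character `class`
#'   column with external chemical-class annotations.
#' @param grouping optional named character vector mapping species to
#'   groups.
#' @return data.frame with `group`, `n_species`, `n_active` (unique hit
#'   compounds) sorted by `n_active`; when class annotations are present, a
#'   `composition` attribute holds the per-group class proportion tables.
#' @export
summarize_by_group <- function(associations, hit_set, grouping = NULL) {
  assoc <- if (inherits(associations, "plant_associations")) {
    associations$associations
  } else {
    associations
  }
  hs <- hit_set_frame(hit_set)
  grp <- if (is.null(grouping)) {
    vapply(strsplit(assoc$species, "[[:space:]]+"), `[[`, character(1), 1L)
  } else {
    unname(grouping[assoc$species])
  }
  assoc$.group <- grp
  per <- lapply(split(assoc, assoc$.group), function(g) {
    hits <- intersect(unique(g$inchikey), hs$inchikey)
    data.frame(group = g$.group[1L],
               n_species = length(unique(g$species)),
               n_active = length(hits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- out[order(-out$n_active, out$group), ]
  rownames(out) <- NULL
  if ("class" %in% names(hs)) {
    comp <- lapply(split(assoc, assoc$.group), function(g) {
      hits <- intersect(unique(g$inchikey), hs$inchikey)
      cls <- hs$class[match(hits, hs$inchikey)]
      if (!length(cls)) return(NULL)
      prop.table(table(cls))
    })
    attr(out, "composition") <- comp[out$group]
  }
  out
}
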