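#' @title Synthetic input generators
#' @name synthetic
#' @description
#' Every input the pipeline consumes can be generated with controllable
#' statistical structure: fingerprint datasets with planted informative bits
#' and majority-class cluster structure, score-separated active/decoy
#' screening sets, compound-plant association tables with planted
#' high-activity species, and raw activity-record tables. All generators are
#' pure functions of their configuration (seed included) and emit the ground
#' truth needed to verify downstream recovery without re-inspecting
#' generator internals. SMILES-bearing outputs use simple valid structures
#' (alcohol/amine homologs, halogenated enantiomer pairs); fingerprint-level
#' simulations bypass SMILES entirely.
NULL

#' Deterministic roster of simple valid SMILES
#'
#' Alternating primary alcohols and amines of growing chain length: n
#' distinct, achiral, trivially parseable structures with distinct
#' InChIKeys.
#'
#' @param n number of structures.
#' @return character vector of SMILES.
#' @export
synthetic_smiles <- function(n) {
  stopifnot(n >= 1L)
  vapply(seq_len(n), function(i) {
    k <- ceiling(i / 2)
    paste0(strrep("C", k), if (i %% 2L == 1L) "O" else "N")
  }, character(1))
}

#' An enantiomer pair of SMILES
#'
#' Both strings denote the two enantiomers of a halogenated alkane with one
#' stereocenter; they collapse to the same achiral canonical form and
#' InChIKey under [standardize_molecules()].
#'
#' @param j chain-length index (distinct `j` give distinct compounds).
#' @return character vector of length 2 (R and S SMILES).
#' @export
enantiomer_pair <- function(j) {
  stopifnot(j >= 1L)
  base <- strrep("C", j)
  c(sprintf("%s[C@H](Cl)Br", base), sprintf("%s[C@@H](Cl)Br", base))
}

#' Bundled fixture SMILES list
#'
#' A small list of real, named natural-product and drug structures shipped
#' with the package, for chemistry-dependent tests and examples.
#'
#' @return data.frame with columns `smiles`, `name`.
#' @export
fixture_smiles <- function() {
  path <- system.file("extdata", "fixture_smiles.smi", package = "phytoscreen")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr("[^[:space:]]+", lines))
  data.frame(smiles = parts,
             name = trimws(substring(lines, nchar(parts) + 1L)),
             stringsAsFactors = FALSE)
}

#' Simulate a fingerprint dataset with planted class signal
#'
#' Bits are independent Bernoulli draws at a background set-bit probability
#' `p_base` (default 0.1, which keeps uninformative columns above the 0.05
#' variance cut so variable selection stays non-trivial). Informative bits
#' are shifted between the classes by `effect`: actives carry them at
#' `p_base + effect * (1 - p_base)`, inactives at `p_base * (1 - effect)` -
#' so `effect = 0` plants no signal and `effect = 1` makes them
#' deterministic. When `n_majority_clusters >= 2`, the majority class is
#' drawn from that many distinct bit-pattern templates (Bernoulli(0.5)
#' centers on a dedicated block of `n_cluster_bits` columns) for balancing
#' tests. Finally every entry is flipped with probability `noise_flip_rate`.
#'
#' @param n_active,n_inactive class sizes.
#' @param n_bits fingerprint length (default 1024).
#' @param informative_bits column indices carrying class signal (default
#'   1:5).
#' @param effect per-bit probability shift in \[0, 1\] (default 0.8).
#' @param n_majority_clusters number of majority-class templates (default 1
#'   = no cluster structure).
#' @param noise_flip_rate global bit-flip probability in \[0, 0.5\]
#'   (default 0.02).
#' @param p_base background set-bit probability.
#' @param n_cluster_bits size of the cluster-template block (default 200).
#' @param seed integer seed; identical configurations yield identical
#'   datasets.
#' @return object of class `fp_simulation`: `bits` (0/1 integer matrix with
#'   key rownames), `labels`, `truth` (informative bits, cluster bits and
#'   per-row cluster assignment, majority class) and `config`.
#' @export
simulate_fingerprint_dataset <- function(n_active, n_inactive, n_bits = 1024L,
                                         informative_bits = 1:5, effect = 0.8,
                                         n_majority_clusters = 1L,
                                         noise_flip_rate = 0.02, p_base = 0.1,
                                         n_cluster_bits = 200L, seed = 1L) {
  stopifnot(n_active >= 1L, n_inactive >= 1L, n_bits >= 1L)
  informative_bits <- as.integer(informative_bits)
  if (length(informative_bits) &&
      (min(informative_bits) < 1L || max(informative_bits) > n_bits)) {
    stop("informative_bits outside [1, n_bits]", call. = FALSE)
  }
  if (effect < 0 || effect > 1) stop("effect must lie in [0, 1]", call. = FALSE)
  if (noise_flip_rate < 0 || noise_flip_rate > 0.5) {
    stop("noise_flip_rate must lie in [0, 0.5]", call. = FALSE)
  }
  n <- n_active + n_inactive
  if (n_majority_clusters > max(n_active, n_inactive)) {
    stop("more majority clusters than majority compounds", call. = FALSE)
  }
  set.seed(seed)
  labels <- c(rep(1L, n_active), rep(0L, n_inactive))
  X <- matrix(stats::rbinom(n * n_bits, 1L, p_base), nrow = n)

  p_act <- p_base + effect * (1 - p_base)
  p_ina <- p_base * (1 - effect)
  for (b in informative_bits) {
    X[labels == 1L, b] <- stats::rbinom(n_active, 1L, p_act)
    X[labels == 0L, b] <- stats::rbinom(n_inactive, 1L, p_ina)
  }

  cluster_bits <- integer(0)
  assignment <- rep(NA_integer_, n)
  majority <- if (n_active >= n_inactive) 1L else 0L
  if (n_majority_clusters >= 2L) {
    free <- setdiff(seq_len(n_bits), informative_bits)
    n_cb <- min(n_cluster_bits, length(free))
    if (n_cb < 1L) stop("no columns left for cluster templates", call. = FALSE)
    cluster_bits <- sort(sample(free, n_cb))
    centers <- matrix(stats::rbinom(n_majority_clusters * n_cb, 1L, 0.5),
                      nrow = n_majority_clusters)
    maj_rows <- which(labels == majority)
    assignment[maj_rows] <- sample(rep_len(seq_len(n_majority_clusters),
                                           length(maj_rows)))
    X[maj_rows, cluster_bits] <- centers[assignment[maj_rows], , drop = FALSE]
    min_rows <- which(labels != majority)
    X[min_rows, cluster_bits] <-
      stats::rbinom(length(min_rows) * n_cb, 1L, 0.5)
  }

  if (noise_flip_rate > 0) {
    flip <- matrix(stats::rbinom(n * n_bits, 1L, noise_flip_rate), nrow = n)
    X <- abs(X - flip)
  }
  perm <- sample.int(n)
  X <- X[perm, , drop = FALSE]
  labels <- labels[perm]
  assignment <- assignment[perm]
  storage.mode(X) <- "integer"
  rownames(X) <- sprintf("SYN%05d", seq_len(n))
  structure(
    list(bits = X, labels = labels,
         truth = list(informative_bits = informative_bits,
                      cluster_bits = cluster_bits,
                      cluster_assignment = assignment,
                      majority_class = majority),
         config = list(n_active = n_active, n_inactive = n_inactive,
                       n_bits = n_bits, informative_bits = informative_bits,
                       effect = effect,
                       n_majority_clusters = n_majority_clusters,
                       noise_flip_rate = noise_flip_rate, p_base = p_base,
                       seed = seed)),
    class = "fp_simulation"
  )
}

#' Simulate a score-separated active/decoy screening set
#'
#' Active scores are drawn from a unit-spread normal located `separation`
#' above the decoy distribution (a location-shift model; the early-
#' recognition metrics are rank-based and thus distribution-free).
#'
#' @param n_active number of actives (default 86).
#' @param n_decoys number of decoys (default 4357); must be at least
#'   `n_active`.
#' @param separation mean score gap in units of the common spread.
#' @param seed integer seed.
#' @return list with `screen` (a [ranked_screen()]) and `config`.
#' @export
simulate_screen <- function(n_active = 86L, n_decoys = 4357L, separation = 2,
                            seed = 1L) {
  stopifnot(n_active >= 1L)
  if (n_decoys < n_active) {
    stop("decoy-style imbalance requires n_decoys >= n_active", call. = FALSE)
  }
  set.seed(seed)
  scores <- c(stats::rnorm(n_active, mean = separation),
              stats::rnorm(n_decoys, mean = 0))
  labels <- c(rep(1L, n_active), rep(0L, n_decoys))
  keys <- c(sprintf("ACT%05d", seq_len(n_active)),
            sprintf("DEC%05d", seq_len(n_decoys)))
  perm <- sample.int(length(scores))
  list(screen = ranked_screen(scores[perm], labels[perm], keys[perm]),
       config = list(n_active = n_active, n_decoys = n_decoys,
                     separation = separation, seed = seed))
}

#' Simulate compound-plant association tables with planted hot species
#'
#' Emits (species, SMILES) tables across several pseudo-source files with
#' cross-source overlaps, a matching NCBI-style lineage dump in which a
#' configurable fraction of associated names are non-plant (and therefore
#' must be excluded on merge), planted enantiomer duplicates under single
#' species, and a hit set with known per-species counts: each hot species
#' carries exactly its planted number of distinct hit compounds and no other
#' species carries any.
#'
#' @param n_species number of plant species.
#' @param n_compounds number of distinct achiral compounds.
#' @param association_density expected fraction of the compound roster
#'   linked to each species.
#' @param hot_species integer vector of planted hit counts; count j is
#'   assigned to the j-th generated species.
#' @param n_tables number of pseudo-source tables (default 3).
#' @param non_plant_fraction fraction of additional non-plant source names
#'   (processed foods and the like) mixed into the tables.
#' @param n_enantiomer_pairs planted enantiomer pairs (each pair under one
#'   species).
#' @param n_hits size of the consensus hit set (at least
#'   `sum(hot_species)`).
#' @param seed integer seed.
#' @return list with `tables` (list of data.frames `species`, `smiles`,
#'   `source`), `lineage` (character dump lines), `hit_set` (data.frame
#'   `inchikey`, `smiles`, `prob_c1`, `prob_c2`) and `truth` (planted hot
#'   counts by species name, non-plant record log, enantiomer plantings,
#'   species and genus rosters).
#' @export
simulate_plant_tables <- function(n_species = 40L, n_compounds = 150L,
                                  association_density = 0.06,
                                  hot_species = c(5L, 3L, 2L),
                                  n_tables = 3L, non_plant_fraction = 0.1,
                                  n_enantiomer_pairs = 4L, n_hits = NULL,
                                  seed = 1L) {
  stopifnot(n_species >= length(hot_species), n_compounds >= 10L,
            association_density > 0, association_density <= 1, n_tables >= 1L)
  hot_species <- as.integer(hot_species)
  if (is.null(n_hits)) n_hits <- max(sum(hot_species) + 4L, 10L)
  if (n_hits < sum(hot_species)) {
    stop("n_hits must cover the planted hot-species counts", call. = FALSE)
  }
  if (n_hits > n_compounds) stop("more hits than compounds", call. = FALSE)
  per_species <- max(1L, round(association_density * n_compounds))
  if (length(hot_species) && any(hot_species < 0L)) {
    stop("planted hit counts must be non-negative", call. = FALSE)
  }
  set.seed(seed)

  n_genera <- max(2L, ceiling(n_species / 3))
  genus <- rep_len(seq_len(n_genera), n_species)
  species <- sprintf("Genus%02d sp%02d", genus, seq_len(n_species))

  smiles <- synthetic_smiles(n_compounds)
  std <- standardize_molecules(smiles)
  if (!all(std$valid)) stop("internal: synthetic SMILES failed to standardize")
  hit_idx <- sort(sample.int(n_compounds, n_hits))
  nonhit_idx <- setdiff(seq_len(n_compounds), hit_idx)

  # hot species get exactly their planted hit compounds (disjoint across
  # species); every other species draws from non-hit compounds only
  hit_pool <- sample(hit_idx)
  assoc <- list()
  taken <- 0L
  for (i in seq_len(n_species)) {
    planted <- if (i <= length(hot_species)) hot_species[i] else 0L
    mine_hits <- integer(0)
    if (planted > 0L) {
      mine_hits <- hit_pool[(taken + 1L):(taken + planted)]
      taken <- taken + planted
    }
    n_fill <- max(per_species - planted, 1L)
    fill <- sample(nonhit_idx, min(n_fill, length(nonhit_idx)))
    assoc[[i]] <- data.frame(species = species[i],
                             smiles = smiles[c(mine_hits, fill)],
                             stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, assoc)

  # planted enantiomer duplicates: both enantiomers of a new compound under
  # one species
  enant <- NULL
  if (n_enantiomer_pairs > 0L) {
    host <- sample(species, n_enantiomer_pairs, replace = TRUE)
    enant <- do.call(rbind, lapply(seq_len(n_enantiomer_pairs), function(j) {
      pr <- enantiomer_pair(j)
      data.frame(species = host[j], smiles = pr, pair = j,
                 stringsAsFactors = FALSE)
    }))
    records <- rbind(records, enant[, c("species", "smiles")])
  }

  # non-plant source names (processed foods etc.): present in the tables,
  # excluded on merge because they are absent from the plant index
  foods <- c("popcorn", "cheese", "milk", "yogurt", "bread", "beer", "honey",
             "butter", "vinegar", "tofu")
  n_nonplant <- max(1L, round(non_plant_fraction * n_species))
  nonplant_names <- sprintf("%s %02d", rep_len(foods, n_nonplant),
                            seq_len(n_nonplant))
  np_records <- do.call(rbind, lapply(nonplant_names, function(nm) {
    data.frame(species = nm,
               smiles = sample(smiles[nonhit_idx], sample(1:3, 1L)),
               stringsAsFactors = FALSE)
  }))
  records <- rbind(records, np_records)

  # spread records across pseudo-source tables, duplicating ~10% into a
  # second table to exercise cross-source deduplication
  tbl_of <- sample.int(n_tables, nrow(records), replace = TRUE)
  dup <- sample.int(nrow(records), max(1L, round(0.1 * nrow(records))))
  tables <- lapply(seq_len(n_tables), function(t) {
    base <- records[tbl_of == t, , drop = FALSE]
    extra <- records[dup[(tbl_of[dup] %% n_tables) + 1L == t], , drop = FALSE]
    out <- rbind(base, extra)
    out$source <- sprintf("sourcedb%d", t)
    rownames(out) <- NULL
    out
  })

  # lineage dump: plant species with a Viridiplantae lineage; half of the
  # non-plant names present with fungal/animal lineages, half absent
  plant_lines <- sprintf(
    "%d\t|\t%s\t|\tcellular organisms; Eukaryota; Viridiplantae; Streptophyta; Magnoliopsida; %s\t|",
    seq_len(n_species) + 1000L, species, sprintf("Genus%02d", genus))
  np_in_dump <- nonplant_names[seq_len(floor(n_nonplant / 2))]
  np_lines <- if (length(np_in_dump)) {
    sprintf("%d\t|\t%s\t|\tcellular organisms; Eukaryota; Opisthokonta; Fungi; Agaricomycetes\t|",
            seq_along(np_in_dump) + 9000L, np_in_dump)
  } else character(0)
  lineage <- c(plant_lines, np_lines)

  hit_keys <- std$inchikey[hit_idx]
  hit_set <- data.frame(
    inchikey = hit_keys,
    smiles = smiles[hit_idx],
    prob_c1 = stats::runif(n_hits, 0.56, 0.9),
    prob_c2 = stats::runif(n_hits, 0.56, 0.9),
    stringsAsFactors = FALSE
  )
  planted <- stats::setNames(integer(n_species), species)
  planted[seq_along(hot_species)] <- hot_species
  list(
    tables = tables, lineage = lineage, hit_set = hit_set,
    truth = list(
      hot_species = planted,
      species = species, genus = stats::setNames(
        sprintf("Genus%02d", genus), species),
      non_plant = data.frame(
        name = nonplant_names,
        in_dump = nonplant_names %in% np_in_dump,
        n_records = as.integer(table(np_records$species)[nonplant_names]),
        stringsAsFactors = FALSE),
      n_non_plant_records = sum(vapply(tables, function(t)
        sum(t$species %in% nonplant_names), integer(1))),
      enantiomer = enant,
      compounds = std,
      config = list(n_species = n_species, n_compounds = n_compounds,
                    association_density = association_density,
                    hot_species = hot_species, n_tables = n_tables,
                    non_plant_fraction = non_plant_fraction,
                    n_enantiomer_pairs = n_enantiomer_pairs,
                    n_hits = n_hits, seed = seed))
  )
}

#' Simulate a raw activity-record table
#'
#' Builds a delimited-text-shaped table of compound-cell-line IC50 records
#' with planted curation cases: consistent replicate pairs, inconsistent
#' replicate pairs (straddling the threshold), and compounds measured in
#' three cell lines (which curation must reserve for screening).
#'
#' @param n_compounds total distinct compounds (default 30).
#' @param cell_lines cell-line identifiers.
#' @param n_replicated compounds with a consistent replicate pair.
#' @param n_inconsistent compounds with a class-inconsistent replicate pair.
#' @param n_multiline compounds measured in three distinct cell lines.
#' @param threshold IC50 activity cutoff in uM.
#' @param seed integer seed.
#' @return list with `records` (data.frame `smiles`, `cell_line`, `ic50_um`,
#'   `source`) and `truth` (planted case rosters).
#' @export
simulate_activity_records <- function(n_compounds = 30L,
                                      cell_lines = c("AGS", "NCI-N87",
                                                     "BGC-823", "SNU-16"),
                                      n_replicated = 5L, n_inconsistent = 3L,
                                      n_multiline = 4L, threshold = 10,
                                      seed = 1L) {
  stopifnot(n_compounds >= n_replicated + n_inconsistent + n_multiline,
            length(cell_lines) >= 3L)
  set.seed(seed)
  smiles <- synthetic_smiles(n_compounds)
  roles <- rep("plain", n_compounds)
  roles[seq_len(n_multiline)] <- "multiline"
  roles[n_multiline + seq_len(n_inconsistent)] <- "inconsistent"
  roles[n_multiline + n_inconsistent + seq_len(n_replicated)] <- "replicated"

  draw_ic50 <- function(n, active) {
    if (active) stats::runif(n, 0.2, threshold * 0.9)
    else stats::runif(n, threshold * 1.1, threshold * 10)
  }
  rows <- list()
  for (i in seq_len(n_compounds)) {
    cl <- sample(cell_lines, 1L)
    active <- stats::runif(1) < 0.5
    rows[[i]] <- switch(
      roles[i],
      plain = data.frame(smiles = smiles[i], cell_line = cl,
                         ic50_um = draw_ic50(1L, active),
                         stringsAsFactors = FALSE),
      replicated = data.frame(smiles = smiles[i], cell_line = cl,
                              ic50_um = draw_ic50(2L, active),
                              stringsAsFactors = FALSE),
      inconsistent = data.frame(smiles = smiles[i], cell_line = cl,
                                ic50_um = c(draw_ic50(1L, TRUE),
                                            draw_ic50(1L, FALSE)),
                                stringsAsFactors = FALSE),
      multiline = {
        cls <- sample(cell_lines, 3L)
        data.frame(smiles = smiles[i], cell_line = cls,
                   ic50_um = draw_ic50(3L, active),
                   stringsAsFactors = FALSE)
      }
    )
  }
  records <- do.call(rbind, rows)
  records$source <- "synthetic"
  records <- records[sample.int(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       truth = list(multiline = smiles[roles == "multiline"],
                    inconsistent = smiles[roles == "inconsistent"],
                    replicated = smiles[roles == "replicated"],
                    plain = smiles[roles == "plain"],
                    seed = seed))
}
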