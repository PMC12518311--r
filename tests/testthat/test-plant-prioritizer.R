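test_that("taxonomy index keeps only green-plant lineages", {
  lines <- c(
    "1234\t|\tTaxus baccata\t|\tcellular organisms; Eukaryota; Viridiplantae; Streptophyta; Pinopsida; Taxus\t|",
    "5678\t|\tAgaricus bisporus\t|\tcellular organisms; Eukaryota; Opisthokonta; Fungi; Agaricomycetes\t|",
    "9999\t|\tGlycyrrhiza glabra\t|\tcellular organisms; Eukaryota; Viridiplantae; Streptophyta; Fabaceae\t|",
    "not a valid line",
    "12\t|\t\t|\tcellular organisms; Eukaryota; Viridiplantae\t|"
  )
  idx <- build_taxonomy_index(lines)
  expect_identical(nrow(idx$table), 2L)
  expect_identical(idx$n_skipped, 2L)
  res <- resolve_species(c("  taxus   BACCATA ", "Agaricus bisporus",
                           "Nonexistens plantae"), idx)
  expect_identical(res$resolved[1], "Taxus baccata")
  expect_true(all(is.na(res$resolved[2:3])))
})

test_that("a synthetic dump resolves exactly its planted plant fraction", {
  set.seed(2)
  plant <- sprintf("100%d\t|\tPlantgenus sp%02d\t|\tEukaryota; Viridiplantae; Streptophyta\t|", 1:60, 1:60)
  fungi <- sprintf("200%d\t|\tFungigenus sp%02d\t|\tEukaryota; Opisthokonta; Fungi\t|", 1:40, 1:40)
  idx <- build_taxonomy_index(sample(c(plant, fungi)))
  expect_identical(nrow(idx$table), 60L)
})

test_that("association merge excludes unresolved names and collapses enantiomers", {
  idx <- build_taxonomy_index(c(
    "1\t|\tGenus01 sp01\t|\tEukaryota; Viridiplantae; Streptophyta\t|",
    "2\t|\tGenus01 sp02\t|\tEukaryota; Viridiplantae; Streptophyta\t|"))
  pair <- enantiomer_pair(2)
  tables <- list(
    data.frame(species = c("Genus01 sp01", "Genus01 sp01", "popcorn"),
               smiles = c(pair, "CCO")),
    data.frame(species = c("Genus01 sp02", "Genus01 sp01"),
               smiles = c("CCO", "CCO")))
  pa <- merge_compound_plant_tables(tables, idx)
  # the enantiomer pair is one association; popcorn is excluded
  expect_identical(unname(pa$summary["n_associations"]), 3L)
  expect_identical(unname(pa$summary["n_compounds"]), 2L)
  expect_identical(pa$exclusions$species, "popcorn")
  expect_identical(pa$exclusions$reason, "unresolved_taxonomy")
  expect_identical(sum(pa$associations$species == "Genus01 sp01"), 2L)
})

test_that("merged association counts equal brute-force set arithmetic", {
  pt <- simulate_plant_tables(seed = 17)
  idx <- build_taxonomy_index(pt$lineage)
  pa <- merge_compound_plant_tables(pt$tables, idx)
  # brute force: standardize every surviving record and count unique pairs
  recs <- do.call(rbind, lapply(pt$tables, function(t)
    t[, c("species", "smiles")]))
  keep <- recs$species %in% pt$truth$species
  std <- standardize_molecules(unique(recs$smiles[keep]))
  keys <- std$inchikey[match(recs$smiles[keep], std$input_smiles)]
  brute <- unique(paste(recs$species[keep], keys))
  expect_identical(unname(pa$summary[["n_associations"]]),
                   length(brute))
  # every non-plant record is excluded, matching the planted tally
  expect_identical(nrow(pa$exclusions), pt$truth$n_non_plant_records)
})

test_that("species ranking recovers planted hot species and tallies exactly", {
  pt <- simulate_plant_tables(hot_species = c(6L, 3L, 2L, 2L), seed = 23)
  idx <- build_taxonomy_index(pt$lineage)
  pa <- merge_compound_plant_tables(pt$tables, idx)
  rs <- rank_species(pa, pt$hit_set)
  planted <- pt$truth$hot_species
  got <- stats::setNames(rs$species$n_active, rs$species$species)
  expect_identical(got[names(planted)], planted[names(planted)])
  expect_identical(rs$species$species[1], names(planted)[1])
  expect_identical(unname(rs$tallies),
                   vapply(c(1L, 2L, 5L), function(m) sum(planted >= m),
                          integer(1)))
  # fractions are exact ratios
  expect_equal(rs$species$fraction,
               rs$species$n_active / rs$species$n_total)
  # ranking is invariant to input record order
  shuf <- pa$associations[rev(seq_len(nrow(pa$associations))), ]
  rs2 <- rank_species(shuf, pt$hit_set)
  expect_identical(rs$species, rs2$species)
})

test_that("single-compound species show fraction 1 when their compound is a hit", {
  assoc <- data.frame(species = c("Genus01 spA", "Genus02 spB"),
                      inchikey = c("HIT_KEY", "MISS_KEY"))
  rs <- rank_species(assoc, "HIT_KEY")
  a <- rs$species[rs$species$species == "Genus01 spA", ]
  expect_identical(a$n_active, 1L)
  expect_identical(a$fraction, 1)
  expect_identical(unname(rs$tallies[">=1"]), 1L)
})

test_that("genus summaries count unique hit compounds across congeners", {
  assoc <- data.frame(
    species = c("Taxus baccata", "Taxus cuspidata", "Seseli montanum"),
    inchikey = c("SHARED_HIT", "SHARED_HIT", "OTHER_HIT"))
  gs <- summarize_by_group(assoc, c("SHARED_HIT", "OTHER_HIT"))
  expect_identical(gs$n_active[gs$group == "Taxus"], 1L)  # shared counts once
  expect_identical(gs$n_species[gs$group == "Taxus"], 2L)
  expect_false("Glycyrrhiza" %in% gs$group)
  # planted per-genus recovery on the simulated tables
  pt <- simulate_plant_tables(hot_species = c(4L, 3L), seed = 29)
  idx <- build_taxonomy_index(pt$lineage)
  pa <- merge_compound_plant_tables(pt$tables, idx)
  gs2 <- summarize_by_group(pa, pt$hit_set)
  planted <- pt$truth$hot_species
  genus_of <- pt$truth$genus
  expected <- tapply(planted, genus_of[names(planted)], sum)
  got <- stats::setNames(gs2$n_active, gs2$group)
  expect_identical(unname(got[names(expected)]),
                   unname(as.integer(expected)))
})

test_that("hit totals across species bound the distinct-hit count", {
  pt <- simulate_plant_tables(seed = 31)
  idx <- build_taxonomy_index(pt$lineage)
  pa <- merge_compound_plant_tables(pt$tables, idx)
  rs <- rank_species(pa, pt$hit_set)
  n_distinct_hits <- length(intersect(pa$associations$inchikey,
                                      pt$hit_set$inchikey))
  expect_gte(sum(rs$species$n_active), n_distinct_hits)
})
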