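test_that("enantiomers collapse to one standardized structure", {
  std <- standardize_molecules(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"))
  expect_true(all(std$valid))
  expect_identical(std$canonical_smiles[1], std$canonical_smiles[2])
  expect_identical(std$inchikey[1], std$inchikey[2])
  expect_false(grepl("@", std$canonical_smiles[1], fixed = TRUE))
  expect_match(std$inchikey[1], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("malformed SMILES are rejected with a reason, never kept", {
  std <- standardize_molecules(c("C(", "", "C)(", "[NoSuchElement]"))
  expect_false(any(std$valid))
  expect_true(all(std$reason == "parse_failure"))
  expect_true(all(is.na(std$canonical_smiles)))
})

test_that("standardization is idempotent and strips salt counterions", {
  first <- standardize_molecules(c("OC(=O)c1ccccc1O.[Na+]", "CCO"))
  again <- standardize_molecules(first$canonical_smiles)
  expect_identical(again$canonical_smiles, first$canonical_smiles)
  expect_identical(again$inchikey, first$inchikey)
  expect_false(grepl("Na", first$canonical_smiles[1]))
})

test_that("fixture list yields distinct InChIKeys agreeing with an independent toolkit", {
  fx <- fixture_smiles()
  expect_gte(nrow(fx), 10L)
  std <- standardize_molecules(fx$smiles)
  expect_true(all(std$valid))
  expect_equal(anyDuplicated(std$inchikey), 0L)
  # independent oracle: RDKit, called through the system python
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.rdBase import DisableLog",
    "DisableLog('rdApp.*')",
    "for s in sys.stdin:",
    "    m = Chem.MolFromSmiles(s.strip())",
    "    Chem.RemoveStereochemistry(m)",
    "    print(Chem.MolToInchiKey(m))",
    sep = "\n")
  rdkit <- system2("python", c("-c", shQuote(script)),
                   input = fx$smiles, stdout = TRUE, stderr = FALSE)
  expect_identical(std$inchikey, rdkit)
})

test_that("activity classification uses a strict 10 uM cutoff", {
  expect_identical(classify_activity(5.0), "active")
  expect_identical(classify_activity(50.0), "inactive")
  expect_identical(classify_activity(10.0), "inactive")  # boundary -> inactive
  expect_identical(classify_activity(c(9.999, 10.001)),
                   c("active", "inactive"))
  expect_error(classify_activity(0), "positive")
  expect_error(classify_activity(-3), "positive")
})

test_that("replicates are resolved on class consistency, not values", {
  kept <- resolve_replicates(c(3, 7))
  expect_true(kept$kept)
  expect_identical(kept$label, "active")
  expect_identical(kept$n_reports, 2L)
  expect_false(resolve_replicates(c(3, 30))$kept)
  single <- resolve_replicates(8)
  expect_true(single$kept)
  expect_identical(single$n_reports, 1L)
  expect_error(resolve_replicates(numeric(0)), "no replicate")
})

test_that("compounds in three or more cell lines are reserved for screening", {
  labeled <- data.frame(
    inchikey = c(rep("KEY_A", 3), "KEY_B"),
    canonical_smiles = c(rep("CCO", 3), "CCN"),
    cell_line = c("AGS", "NCI-N87", "SNU-16", "AGS"),
    label = "active", n_reports = 1L, stringsAsFactors = FALSE)
  part <- partition_training_vs_screening(
    labeled, cell_lines = c("AGS", "NCI-N87", "BGC-823", "SNU-16"))
  expect_identical(unique(part$reserved$inchikey), "KEY_A")
  expect_identical(part$training[["AGS"]]$inchikey, "KEY_B")
  expect_length(intersect(part$reserved$inchikey,
                          unlist(lapply(part$training, `[[`, "inchikey"))), 0L)
})

test_that("curation accounts for every input record and matches a brute-force tally", {
  ar <- simulate_activity_records(seed = 42)
  cur <- curate_activity_records(ar$records)
  # conservation: kept + reserved + exclusions == input
  expect_identical(
    unname(cur$counts[["kept"]] + cur$counts[["reserved"]] +
             cur$counts[["excluded_inconsistent"]] +
             cur$counts[["excluded_invalid"]]),
    nrow(ar$records))
  # reserved set = brute-force tally of distinct cell lines per key
  std <- standardize_molecules(unique(ar$records$smiles))
  key_of <- std$inchikey[match(ar$records$smiles, std$input_smiles)]
  consistent <- !(ar$records$smiles %in% ar$truth$inconsistent)
  tally <- tapply(ar$records$cell_line[consistent], key_of[consistent],
                  function(x) length(unique(x)))
  expect_setequal(unique(cur$reserved$inchikey),
                  names(tally)[tally >= 3])
  # inconsistent pairs excluded with the right reason
  expect_setequal(
    unique(cur$exclusions$smiles[cur$exclusions$reason == "inconsistent_replicates"]),
    ar$truth$inconsistent)
  # determinism: identical inputs give identical curated output
  cur2 <- curate_activity_records(ar$records)
  expect_identical(cur, cur2)
})

test_that("curation reads delimited tables in either dialect", {
  ar <- simulate_activity_records(n_compounds = 15, seed = 3)
  for (sep in c(",", "\t")) {
    path <- tempfile(fileext = ".txt")
    on.exit(unlink(path), add = TRUE)
    data.table::fwrite(ar$records, path, sep = sep)
    cur <- curate_activity_records(path)
    expect_identical(unname(cur$counts[["input"]]), nrow(ar$records))
  }
})
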