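#' Save a modeling dataset as a portable text bundle
#'
#' Writes the dataset to a directory: the bit matrix, labels, partition and
#' domain flags as tab-separated text, the applicability-domain projection
#' as numeric tables, and a JSON manifest recording the seed, variance
#' threshold survivors and component count.
#'
#' @param dataset a `qsar_dataset`.
#' @param dir target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(dataset$bits),
                     file.path(dir, "bits.tsv"), sep = "\t")
  meta <- data.frame(key = dataset$keys, label = dataset$labels,
                     partition = as.character(dataset$partition),
                     in_domain = dataset$in_domain,
                     distance = dataset$distance)
  data.table::fwrite(meta, file.path(dir, "compounds.tsv"), sep = "\t")
  ad <- dataset$ad
  data.table::fwrite(data.table::as.data.table(ad$rotation),
                     file.path(dir, "ad_rotation.tsv"), sep = "\t")
  manifest <- list(
    cell_line = dataset$cell_line, seed = dataset$seed,
    n_compounds = nrow(dataset$bits), n_bits = ncol(dataset$bits),
    kept_columns = dataset$kept_columns,
    ad = list(center = unname(ad$center), centroid = unname(ad$centroid),
              n_components = ad$n_components, cum_var = ad$cum_var,
              max_distance = ad$max_distance, n_train = ad$n_train,
              n_columns = ad$n_columns),
    balance_info = dataset$balance_info
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset bundle written by [save_dataset()]
#'
#' @param dir bundle directory.
#' @return a `qsar_dataset`.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  bits <- as.matrix(data.table::fread(file.path(dir, "bits.tsv")))
  storage.mode(bits) <- "integer"
  dimnames(bits) <- NULL
  meta <- as.data.frame(data.table::fread(file.path(dir, "compounds.tsv")))
  rownames(bits) <- meta$key
  rotation <- as.matrix(data.table::fread(file.path(dir, "ad_rotation.tsv")))
  colnames(rotation) <- NULL
  ad <- structure(
    list(center = manifest$ad$center, rotation = rotation,
         centroid = manifest$ad$centroid,
         n_components = manifest$ad$n_components,
         cum_var = manifest$ad$cum_var,
         max_distance = manifest$ad$max_distance,
         n_train = manifest$ad$n_train, n_columns = manifest$ad$n_columns),
    class = "applicability_domain")
  structure(
    list(bits = bits, labels = as.integer(meta$label),
         partition = factor(meta$partition,
                            levels = c("train", "test", "external")),
         kept_columns = as.integer(manifest$kept_columns), ad = ad,
         in_domain = as.logical(meta$in_domain), distance = meta$distance,
         keys = meta$key, cell_line = manifest$cell_line,
         seed = manifest$seed, balance_info = manifest$balance_info),
    class = "qsar_dataset"
  )
}
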