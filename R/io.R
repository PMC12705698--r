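# Plain-text round-tripping of the formats the package consumes and emits:
# protein metadata TSV, embedding store, label tables, virus-host pair
# tables, cluster outputs and run manifests.  Embeddings are stored as TSV
# (protein_id plus one column per dimension) so every artifact stays
# human-inspectable; at the scales this package targets the format is not a
# bottleneck.

#' Write / read a protein-set dataset
#'
#' Two files: `<prefix>_meta.tsv` with columns `protein_id`, `genome_id`,
#' `scaffold_id`, `position`, `strand`; and `<prefix>_embeddings.tsv` with
#' `protein_id` followed by the embedding dimensions, rows matching the
#' metadata order.
#'
#' @param pset A [protein_set()].
#' @param prefix Output path prefix.
#' @return `read_protein_set()` returns the restored [protein_set()].
#' @export
write_protein_set <- function(pset, prefix) {
  utils::write.table(pset$meta, paste0(prefix, "_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emb <- data.frame(protein_id = pset$meta$protein_id, pset$embeddings)
  names(emb) <- c("protein_id", sprintf("d%03d", seq_len(ncol(pset$embeddings))))
  utils::write.table(emb, paste0(prefix, "_embeddings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_protein_set
#' @export
read_protein_set <- function(prefix) {
  meta <- utils::read.delim(paste0(prefix, "_meta.tsv"),
                            stringsAsFactors = FALSE)
  emb <- utils::read.delim(paste0(prefix, "_embeddings.tsv"),
                           stringsAsFactors = FALSE)
  if (!identical(meta$protein_id, emb$protein_id)) {
    stop("metadata and embedding store disagree on protein order")
  }
  protein_set(meta, as.matrix(emb[, -1L, drop = FALSE]))
}

#' Cross-check a protein set against a FASTA file
#'
#' Protein FASTA input is used for id bookkeeping only: this verifies that
#' the record names (first whitespace-delimited token) match the metadata's
#' protein ids exactly.
#'
#' @param pset A [protein_set()].
#' @param fasta Path to a protein FASTA file or an
#'   [Biostrings::AAStringSet].
#' @return TRUE invisibly; mismatches raise an error.
#' @export
check_fasta_ids <- function(pset, fasta) {
  seqs <- if (inherits(fasta, "XStringSet")) {
    fasta
  } else {
    Biostrings::readAAStringSet(fasta)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(pset$meta$protein_id, ids)
  extra <- setdiff(ids, pset$meta$protein_id)
  if (length(missing) || length(extra)) {
    stop(sprintf("FASTA/metadata id mismatch: %d missing, %d extra",
                 length(missing), length(extra)))
  }
  invisible(TRUE)
}

#' Read a two-column label TSV (`protein_id`, `category`)
#' @param path TSV path.
#' @return Named character vector of categories.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' Read a virus-host pair TSV (`virus_id`, `host_id`)
#' @param path TSV path.
#' @return Data frame with the two id columns.
#' @export
read_virus_host_pairs <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)[, 1:2]
}

#' Write a cluster assignment TSV (`item_id`, `cluster`, `is_singleton`)
#' @param assignment A [leiden_clusters()] result.
#' @param path Output path.
#' @export
write_cluster_assignment <- function(assignment, path) {
  utils::write.table(
    data.frame(item_id = assignment$item, cluster = assignment$cluster,
               is_singleton = assignment$is_singleton),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records inputs, configuration, seed and package version as JSON so a run
#' can be repeated bit-for-bit (dropout off).
#'
#' @param path Output path.
#' @param ... Named fields to record.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package <- "genomeset"
  fields$version <- as.character(utils::packageVersion("genomeset"))
  fields$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
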