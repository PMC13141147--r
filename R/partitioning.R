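#' Split genes into k genomic partitions
#'
#' Protein-coding genes are randomly split into `k` partitions, stratified
#' by chromosome and by whether the gene carries a high-quality non-coding
#' pathogenic variant (determined from the post-curation positive set).
#' Within each `(chromosome, has_pathogenic)` stratum the gene ids are
#' shuffled with the seeded generator and dealt round-robin into the
#' partitions starting at a per-stratum random offset, so within every
#' stratum the largest and smallest partition counts differ by at most 1.
#' The partition map is the anti-leakage backbone: model `j` of the bundle
#' is trained with partition `j`'s genes excluded, so any variant can be
#' scored by a model blind to its gene.
#'
#' @param genes gene-model table (or data.frame with `gene_id`, `chrom`).
#' @param pathogenic_gene_ids character vector of genes carrying curated
#'   pathogenic variants.
#' @param k number of partitions (default 10).
#' @param seed integer seed; the map is deterministic given
#'   `(genes, pathogenic_gene_ids, k, seed)`.
#' @return An object of class `ncv_partition_map`: list with `map`
#'   (data.table `gene_id`, `partition` in `0..k-1`), `k`, `seed`, and
#'   `tallies` (per `(chrom, has_pathogenic, partition)` gene counts).
#' @export
make_partitions <- function(genes, pathogenic_gene_ids = character(0),
                            k = 10, seed = 1) {
  g <- as.data.table(genes)[, .(gene_id, chrom)]
  if (!nrow(g)) stop("genes must be non-empty")
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in gene table")
  if (k < 2) stop("k must be >= 2")
  g[, has_pathogenic := gene_id %in% pathogenic_gene_ids]
  out <- with_seed(seed, {
    g[, {
      ids <- sample(gene_id)
      off <- sample.int(k, 1L) - 1L
      list(gene_id = ids,
           partition = (off + seq_along(ids) - 1L) %% k)
    }, by = .(chrom, has_pathogenic)]
  })
  map <- out[, .(gene_id, partition = as.integer(partition))]
  setorder(map, gene_id)
  tallies <- out[, .N, by = .(chrom, has_pathogenic, partition)]
  spread <- tallies[, {
    cnt <- integer(k); cnt[partition + 1L] <- N
    list(spread = max(cnt) - min(cnt))
  }, by = .(chrom, has_pathogenic)]
  stopifnot(all(spread$spread <= 1L))
  structure(list(map = map, k = as.integer(k), seed = as.integer(seed),
                 tallies = tallies),
            class = "ncv_partition_map")
}

#' @export
print.ncv_partition_map <- function(x, ...) {
  cat("Partition map:", nrow(x$map), "genes into", x$k,
      "partitions (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Look up partition indices for genes
#'
#' @param pmap an `ncv_partition_map`.
#' @param gene_ids character vector.
#' @param strict error on unmapped genes (default) instead of returning NA.
#' @return Integer vector of partitions (NA for unmapped when
#'   `strict = FALSE`).
#' @export
partition_of <- function(pmap, gene_ids, strict = TRUE) {
  idx <- match(gene_ids, pmap$map$gene_id)
  if (strict && anyNA(idx))
    stop("gene(s) absent from partition map: ",
         paste(unique(gene_ids[is.na(idx)]), collapse = ", "))
  pmap$map$partition[idx]
}

#' Leakage gate: verify a training table avoids a held-out partition
#'
#' Returns `TRUE` iff no training variant's gene maps to
#' `held_out_partition`. Training variants whose gene is absent from the
#' map are an error — every training variant must be mapped. Run as a hard
#' gate before every model fit.
#'
#' @param pmap an `ncv_partition_map`.
#' @param training_table data.frame with a `gene_id` column.
#' @param held_out_partition partition index in `0..k-1`.
#' @return logical scalar.
#' @export
assert_no_leakage <- function(pmap, training_table, held_out_partition) {
  p <- partition_of(pmap, as.data.table(training_table)$gene_id,
                    strict = TRUE)
  !any(p == held_out_partition)
}

#' Write / read a partition map (2-column TSV + JSON metadata)
#'
#' @param pmap an `ncv_partition_map`.
#' @param path TSV path; metadata written next to it as `<path>.json`.
#' @return Invisibly `path` (writer); the map (reader).
#' @export
write_partition_map <- function(pmap, path) {
  fwrite(pmap$map, path, sep = "\t")
  meta <- list(k = pmap$k, seed = pmap$seed,
               tallies = as.data.frame(pmap$tallies))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_partition_map
#' @export
read_partition_map <- function(path) {
  map <- fread(path, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(map = map[, .(gene_id, partition = as.integer(partition))],
                 k = as.integer(meta$k), seed = as.integer(meta$seed),
                 tallies = as.data.table(meta$tallies)),
            class = "ncv_partition_map")
}
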