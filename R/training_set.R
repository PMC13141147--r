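#' Cap positives at one variant per gene
#'
#' At most one positive per gene is kept, chosen uniformly with the seeded
#' generator; deterministic given the seed.
#'
#' @param positives curated positive table with `gene_id`.
#' @param seed integer seed.
#' @return Capped positive table.
#' @export
cap_positives_per_gene <- function(positives, seed = 1) {
  dt <- as.data.table(positives)
  if (!nrow(dt)) return(dt)
  with_seed(seed, {
    pick <- dt[, .(row = .I[sample.int(.N, 1L)]), by = gene_id]$row
    out <- dt[sort(pick)]
  })
  out
}

#' Sample region- and partition-matched negatives at a fixed ratio
#'
#' Builds the 1:`ratio` training table: each positive is paired with
#' `ratio` negatives drawn uniformly without replacement from pool variants
#' in the same gene partition and the same non-coding region type. Across
#' the whole table each gene contributes at most one negative; when that
#' global distinct-gene constraint cannot be satisfied for some positive,
#' it is relaxed for that positive only (genes already used elsewhere
#' become eligible again, still at most one negative per gene within the
#' pairing group, and every pool variant is used at most once overall) and
#' the relaxation is recorded in the sampling metadata. If a
#' `(partition, region)` cell is exhausted even under relaxation, sampling
#' stops with an error naming the cell. On success the global negative
#' count is exactly `ratio` times the positive count.
#'
#' @param positives capped positive table (`gene_id`, `region`, variant key
#'   columns); at most one per gene.
#' @param pool negative candidate pool from [build_negative_pool()].
#' @param pmap an `ncv_partition_map` covering all genes involved.
#' @param ratio negatives per positive (default 10).
#' @param seed integer seed.
#' @param exclude_positive_gene if `TRUE`, a positive's own gene is not
#'   eligible to contribute its negatives (default `FALSE`).
#' @return data.table of class `ncv_training_table`: positives
#'   (`label = 1`) and negatives (`label = 0`) with `pairing_id` linking
#'   each positive to its negatives, plus columns `partition` and `region`.
#'   Attribute `sampling` records seed, ratio and relaxed pairing ids.
#' @export
sample_matched_negatives <- function(positives, pool, pmap, ratio = 10,
                                     seed = 1,
                                     exclude_positive_gene = FALSE) {
  stopifnot(ratio >= 1)
  P <- as.data.table(positives)
  if (!nrow(P)) stop("no positives to pair")
  if (anyDuplicated(P$gene_id))
    stop("positives must be capped to one per gene (cap_positives_per_gene)")
  Q <- as.data.table(pool)
  if (!nrow(Q)) stop("negative pool is empty")
  P[, partition := partition_of(pmap, gene_id)]
  Q <- copy(Q)[, partition := partition_of(pmap, gene_id)]
  if (!"key" %in% names(P)) P[, key := variant_key(chrom, pos, ref, alt)]
  if (!"key" %in% names(Q)) Q[, key := variant_key(chrom, pos, ref, alt)]
  setorder(P, chrom, pos, alt)
  P[, pairing_id := .I]

  used_genes <- character(0)   # global <=1 negative per gene
  used_keys <- character(0)    # each pool variant used at most once
  relaxed <- integer(0)
  picked <- vector("list", nrow(P))

  with_seed(seed, {
    for (i in seq_len(nrow(P))) {
      cell <- Q[partition == P$partition[i] & region == P$region[i] &
                !key %in% used_keys]
      if (exclude_positive_gene) cell <- cell[gene_id != P$gene_id[i]]
      draw_from <- function(cand, n_needed) {
        # uniform draw of <=1 variant per gene: shuffle, keep first per gene
        if (!nrow(cand)) return(cand[0])
        cand <- cand[sample.int(nrow(cand))]
        cand <- cand[!duplicated(gene_id)]
        head(cand, n_needed)
      }
      sel <- draw_from(cell[!gene_id %in% used_genes], ratio)
      if (nrow(sel) < ratio) {
        # relaxation: re-admit globally used genes for this positive
        extra <- draw_from(cell[gene_id %in% used_genes &
                                !gene_id %in% sel$gene_id],
                           ratio - nrow(sel))
        sel <- rbind(sel, extra)
        relaxed <- c(relaxed, P$pairing_id[i])
      }
      if (nrow(sel) < ratio)
        stop(sprintf(
          paste0("negative pool exhausted for (partition=%d, region=%s): ",
                 "needed %d, found %d eligible candidates; enlarge the pool ",
                 "or lower the ratio"),
          P$partition[i], P$region[i], ratio, nrow(sel)))
      sel[, pairing_id := P$pairing_id[i]]
      used_genes <- union(used_genes, sel$gene_id)
      used_keys <- c(used_keys, sel$key)
      picked[[i]] <- sel
    }
  })

  N <- rbindlist(picked, fill = TRUE)
  N[, label := 0L]
  common <- intersect(names(P), names(N))
  tab <- rbind(P[, ..common], N[, ..common])
  setorder(tab, pairing_id, -label, chrom, pos, alt)
  setattr(tab, "sampling",
          list(seed = as.integer(seed), ratio = as.integer(ratio),
               relaxed_pairings = sort(unique(relaxed)),
               exclude_positive_gene = exclude_positive_gene))
  setattr(tab, "class", c("ncv_training_table", class(tab)))
  tab[]
}

#' Write / read a training table as TSV
#'
#' Serializes variant key columns, gene, region, partition, label and
#' pairing id plus any feature columns present.
#'
#' @param table an `ncv_training_table`.
#' @param path output TSV.
#' @return Invisibly `path` (writer); a data.table (reader).
#' @export
write_training_table <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t")
  invisible(path)
}

#' @rdname write_training_table
#' @export
read_training_table <- function(path) {
  fread(path, sep = "\t", colClasses = list(character = "chrom"))
}
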