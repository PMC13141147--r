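#' Curate a high-confidence positive (pathogenic) variant set
#'
#' Applies a fixed sequence of high-confidence filters to clinical-assertion
#' records. Records must already carry region assignments (columns
#' `gene_id`, `region` joined from [classify_region()]). The filters, in
#' order:
#'
#' 1. single-nucleotide variants only;
#' 2. a scorable non-coding region assigned (one of [region_types()]);
#' 3. assertion consistency: pooled over all sources per variant key, at
#'    least one pathogenic-side assertion (pathogenic/likely_pathogenic) and
#'    no benign-side (benign/likely_benign) or uncertain assertion — any mix
#'    of the two sides is a conflict and the variant is dropped;
#' 4. inheritance `monogenic_mendelian` only (drops complex/somatic/unknown);
#' 5. no evidence of homozygosity (`n_homozygotes > max_homozygotes`) and
#'    population allele frequency at most `max_af`;
#' 6. deduplication by variant key, first-seen source retained.
#'
#' Each filter is a pure predicate on a record (given the pooled assertion
#' sets), so the surviving set does not depend on filter order; the
#' telescoping per-filter report does.
#'
#' @param records data.table of clinical records with region assignments.
#' @param max_homozygotes maximal homozygote count tolerated (default 0).
#' @param max_af maximal population allele frequency (default 0.001).
#' @return list with `positives` (surviving rows, `label = 1`) and `report`
#'   (a [curation report][curation_report] whose counts telescope).
#' @export
curate_positive_set <- function(records, max_homozygotes = 0,
                                max_af = 0.001) {
  dt <- as.data.table(records)
  if (!nrow(dt)) {
    rep0 <- data.table(filter = .curation_filters, n_in = 0L, n_out = 0L)
    ncv_log("curation received an empty record set")
    return(list(positives = dt, report = curation_report(rep0, 0L, 0L)))
  }
  if (!all(c("gene_id", "region") %in% names(dt)))
    stop("records must carry region assignments (gene_id, region)")
  dt[, key := variant_key(chrom, pos, ref, alt)]
  counts <- integer(0)

  step <- function(d, keep) { counts <<- c(counts, nrow(d)); d[keep] }
  dt <- step(dt, is_snv(dt$ref, dt$alt))
  dt <- step(dt, dt$region %in% region_types() & !is.na(dt$gene_id))

  # pooled assertion sets across sources per key
  if (nrow(dt)) {
    asr <- dt[, .(a = unlist(strsplit(assertions, ",", fixed = TRUE))),
              by = key]
    patho_keys <- asr[a %in% c("pathogenic", "likely_pathogenic"), unique(key)]
    soft_keys <- asr[a %in% c("benign", "likely_benign", "uncertain"),
                     unique(key)]
    ok_keys <- setdiff(patho_keys, soft_keys)
  } else ok_keys <- character(0)
  dt <- step(dt, dt$key %in% ok_keys)
  dt <- step(dt, dt$inheritance == "monogenic_mendelian")
  dt <- step(dt, dt$n_homozygotes <= max_homozygotes & dt$pop_af <= max_af)
  counts <- c(counts, nrow(dt))
  dt <- dt[!duplicated(key)]
  counts <- c(counts, nrow(dt))

  rep <- data.table(filter = .curation_filters,
                    n_in = counts[seq_along(.curation_filters)],
                    n_out = counts[seq_along(.curation_filters) + 1L])
  if (!nrow(dt)) ncv_log("curation produced an empty positive set")
  dt[, label := 1L]
  list(positives = dt[],
       report = curation_report(rep, nrow(dt),
                                length(unique(dt$gene_id))))
}

.curation_filters <- c("snv_only", "scorable_region", "assertion_consistency",
                       "monogenic_mendelian", "population_evidence",
                       "deduplicate")

#' Curation report
#'
#' Per-filter in/out counts (telescoping: filter i's output is filter
#' (i+1)'s input), final set size, and unique gene count.
#'
#' @param per_filter data.table with `filter`, `n_in`, `n_out`.
#' @param final_size,n_genes integers.
#' @return list of class `ncv_curation_report`.
#' @export
curation_report <- function(per_filter, final_size, n_genes) {
  stopifnot(all(per_filter$n_out <= per_filter$n_in))
  if (nrow(per_filter) > 1L)
    stopifnot(all(per_filter$n_in[-1L] ==
                  per_filter$n_out[-nrow(per_filter)]))
  structure(list(per_filter = per_filter, final_size = final_size,
                 n_genes = n_genes),
            class = "ncv_curation_report")
}

#' @export
print.ncv_curation_report <- function(x, ...) {
  cat("Curation report:", x$final_size, "variants in", x$n_genes, "genes\n")
  print(x$per_filter)
  invisible(x)
}

#' Build a common or rare negative candidate pool
#'
#' Negatives are presumed-benign variants without pathogenic clinical
#' assertions, region-assigned, filtered on population allele frequency:
#' `common` keeps `pop_af >= common_af_min` (default 1%), `rare` keeps
#' `0 < pop_af <= rare_af_max` (default 0.1%). Variants whose key also
#' appears in the positive set are removed with a logged count — the
#' positive and negative sets are disjoint by construction.
#'
#' @param variants region-assigned variant table with a `pop_af` column.
#' @param mode `"common"` or `"rare"`.
#' @param common_af_min,rare_af_max frequency thresholds.
#' @param positives optional positive set (or vector of variant keys) to
#'   exclude.
#' @return data.table pool with `label = 0`, indexed by `(region, gene_id)`
#'   for the matched sampler (the partition index is attached at sampling
#'   time from the partition map).
#' @export
build_negative_pool <- function(variants, mode = c("common", "rare"),
                                common_af_min = 0.01, rare_af_max = 0.001,
                                positives = NULL) {
  mode <- match.arg(mode)
  dt <- as.data.table(variants)
  if (!"pop_af" %in% names(dt)) stop("variants must carry pop_af")
  if (!all(c("gene_id", "region") %in% names(dt)))
    stop("variants must carry region assignments (gene_id, region)")
  dt <- dt[region %in% region_types() & !is.na(gene_id)]
  dt <- if (mode == "common") dt[pop_af >= common_af_min]
        else dt[pop_af > 0 & pop_af <= rare_af_max]
  dt[, key := variant_key(chrom, pos, ref, alt)]
  if (!is.null(positives)) {
    pk <- if (is.character(positives)) positives
          else {
            p <- as.data.table(positives)
            variant_key(p$chrom, p$pos, p$ref, p$alt)
          }
    n_overlap <- dt[key %in% pk, .N]
    if (n_overlap > 0L)
      ncv_log("removed %d pool variant(s) overlapping the positive set",
              n_overlap)
    dt <- dt[!key %in% pk]
  }
  dt[, label := 0L]
  data.table::setkeyv(dt, c("region", "gene_id"))
  dt[]
}
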