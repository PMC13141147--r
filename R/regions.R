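#' Assign variants a gene and a non-coding region type
#'
#' Each single-nucleotide variant is assigned to exactly one gene and one of
#' the six scorable non-coding region types (`upstream`, `UTR5`, `intronic`,
#' `UTR3`, `downstream`, `intergenic`), or marked `coding` (excluded from
#' scoring) or `unscorable`. Typing is strand-aware:
#'
#' * inside the transcript span: exonic positions within the CDS span are
#'   `coding`; exonic positions 5' of the CDS are `UTR5` and 3' of it `UTR3`
#'   (5'/3' taken on the gene's strand); non-exonic positions are `intronic`;
#' * within `upstream_window` bp 5' of the span: `upstream`; within
#'   `downstream_window` bp 3': `downstream`;
#' * otherwise, within `intergenic_cap` bp of the nearest transcript span:
#'   `intergenic`; beyond the cap (or on a chromosome with no gene model):
#'   `unscorable`, with a logged count rather than an error.
#'
#' When several genes could claim a position, precedence is `coding` >
#' `UTR5` > `UTR3` > `intronic` > `upstream` > `downstream` > `intergenic`;
#' remaining ties are broken by smaller distance to the transcript span,
#' then lexicographic `gene_id`, so assignment is deterministic.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (1-based positions, VCF convention).
#' @param gene_models a gene-model table from [load_gene_models()].
#' @param upstream_window,downstream_window window sizes in bp (default
#'   1000 each).
#' @param intergenic_cap maximal distance for intergenic assignment in bp
#'   (default 10000).
#' @return A data.table, one row per input variant in input order, with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gene_id`, `region`,
#'   `distance_to_gene` (0 inside the span). Unscorable variants carry
#'   `gene_id = NA`, `region = "unscorable"`.
#' @export
classify_region <- function(variants, gene_models,
                            upstream_window = 1000,
                            downstream_window = 1000,
                            intergenic_cap = 10000) {
  stopifnot(upstream_window > 0, downstream_window > 0, intergenic_cap > 0)
  V <- as.data.table(variants)[, .(chrom = as.character(chrom),
                                   pos = as.numeric(pos),
                                   ref = as.character(ref),
                                   alt = as.character(alt))]
  if (!all(is_snv(V$ref, V$alt)))
    stop("classify_region handles SNVs only (single-base ref and alt)")
  V[, idx := .I]
  G <- as.data.table(gene_models)
  maxw <- max(upstream_window, downstream_window, intergenic_cap)
  GW <- G[, .(gene_id, chrom, strand, tx_start, tx_end, cds_start, cds_end,
              lo = tx_start - maxw, hi = tx_end + maxw, grow = .I)]

  pairs <- GW[V, on = .(chrom, lo <= pos, hi >= pos),
              allow.cartesian = TRUE, nomatch = NULL,
              .(idx, pos = i.pos, gene_id, strand, tx_start, tx_end,
                cds_start, cds_end, grow)]
  res <- V[, .(idx, chrom, pos, ref, alt)]

  if (nrow(pairs)) {
    # exon membership for positions inside the transcript span
    E <- G[, {
      m <- exons[[1]]
      list(es = m[, 1], ee = m[, 2])
    }, by = .(grow = seq_len(nrow(G)))]
    pairs[, inside := pos >= tx_start & pos <= tx_end]
    pairs[, in_exon := FALSE]
    inside_rows <- pairs[, which(inside)]
    if (length(inside_rows)) {
      ins <- pairs[inside_rows, .(prow = seq_along(inside_rows), grow, pos)]
      hit <- E[ins, on = .(grow, es <= pos, ee >= pos), nomatch = NULL,
               .(prow)]
      if (nrow(hit))
        pairs[inside_rows[unique(hit$prow)], in_exon := TRUE]
    }
    pairs[, dist := pmax(tx_start - pos, pos - tx_end, 0)]
    pairs[, five_prime_side :=
              (strand == "+" & pos < tx_start) |
              (strand == "-" & pos > tx_end)]
    pairs[, utr5_side :=
              (strand == "+" & pos < cds_start) |
              (strand == "-" & pos > cds_end)]
    pairs[, rtype := NA_character_]
    pairs[inside & in_exon & pos >= cds_start & pos <= cds_end,
          rtype := "coding"]
    pairs[inside & in_exon & is.na(rtype) & utr5_side, rtype := "UTR5"]
    pairs[inside & in_exon & is.na(rtype), rtype := "UTR3"]
    pairs[inside & !in_exon, rtype := "intronic"]
    pairs[!inside & five_prime_side & dist <= upstream_window,
          rtype := "upstream"]
    pairs[!inside & !five_prime_side & dist <= downstream_window,
          rtype := "downstream"]
    pairs[!inside & is.na(rtype) & dist <= intergenic_cap,
          rtype := "intergenic"]
    pairs <- pairs[!is.na(rtype)]
    prec <- c(coding = 0L, UTR5 = 1L, UTR3 = 2L, intronic = 3L,
              upstream = 4L, downstream = 5L, intergenic = 6L)
    pairs[, prec := prec[rtype]]
    setorder(pairs, idx, prec, dist, gene_id)
    best <- pairs[, .SD[1L], by = idx,
                  .SDcols = c("gene_id", "rtype", "dist")]
    res <- best[res, on = "idx"]
  } else {
    res[, `:=`(gene_id = NA_character_, rtype = NA_character_,
               dist = NA_real_)]
  }
  res[is.na(rtype), `:=`(rtype = "unscorable", gene_id = NA_character_,
                         dist = NA_real_)]
  n_unsc <- res[rtype == "unscorable", .N]
  if (n_unsc > 0L)
    ncv_log("%d variant(s) unscorable (no gene within reach on their chromosome)",
            n_unsc)
  setorder(res, idx)
  res[, .(chrom, pos, ref, alt, gene_id, region = rtype,
          distance_to_gene = dist)]
}
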