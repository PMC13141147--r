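# Shared fixtures built in code.

# the toy gene used across region tests: + strand, tx 1000-2000,
# exons [1000-1200] and [1800-2000], CDS 1100-1900
toy_gene <- function(strand = "+", gene_id = "GENE1", chrom = "chr1") {
  data.table::data.table(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tx_start = 1000, tx_end = 2000, cds_start = 1100, cds_end = 1900,
    exons = list(cbind(start = c(1000, 1800), end = c(1200, 2000))),
    is_disease_gene = FALSE)
}

snv_at <- function(pos, chrom = "chr1", ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

# a hand-built partition map (no randomness)
manual_pmap <- function(gene_ids, partitions, k = max(partitions) + 1L) {
  structure(list(
    map = data.table::data.table(gene_id = gene_ids,
                                 partition = as.integer(partitions)),
    k = as.integer(k), seed = 0L,
    tallies = data.table::data.table(chrom = "chr1", has_pathogenic = FALSE,
                                     partition = partitions, N = 1L)),
    class = "ncv_partition_map")
}

# tiny but complete synthetic run shared by model/eval tests
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_genes = 100, n_positives = 60,
                          fraction_disease_genes = 0.7, d = 3,
                          n_pool_per_gene = 40, seed = 42)
      cache <<- suppressMessages(run_synthetic_pipeline(cfg, k = 3))
    }
    cache
  }
})
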