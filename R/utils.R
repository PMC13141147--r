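#' @importFrom data.table data.table as.data.table setDT setorder setorderv
#'   rbindlist fread fwrite copy setnames := .N .SD setattr
#' @importFrom stats rnorm runif rbinom rbeta median pnorm wilcox.test
#'   setNames predict
#' @importFrom utils head modifyList
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "..keep", "chrom", "pos", "ref", "alt", "gene_id", "region",
  "partition", "label", "pairing_id", "pop_af", "tx_start", "tx_end",
  "cds_start", "cds_end", "strand", "key", "dist", "score", "model_index",
  "n_homozygotes", "inheritance", "source", "assertions", "is_disease_gene",
  "has_pathogenic", "prec", "V1", "i.partition", "i.gene_id", "i.region",
  "rtype"
))

#' Canonical non-coding region types
#'
#' The six scorable non-coding region categories, in the canonical order
#' used by every report in the package, plus the `coding` sentinel for
#' excluded positions.
#'
#' @return Character vector of the six region names.
#' @export
region_types <- function() {
  c("upstream", "UTR5", "intronic", "UTR3", "downstream", "intergenic")
}

# sentinel values that are never scorable
.region_sentinels <- c("coding", "unscorable")

#' Build the canonical variant key
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return Character vector `chrom:pos:ref>alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

# run `expr` under a temporary seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# stage seeds derived from one global seed; kept below 2^31
derive_seed <- function(seed, stage) {
  stages <- c(
    synth = 1L, curate = 2L, partition = 3L, cap = 4L, sample = 5L,
    train = 6L, eval = 7L
  )
  idx <- stages[[stage]]
  as.integer((as.numeric(seed) * 131L + idx * 7919) %% 2147483647)
}

# shared check that a table is SNV-shaped
is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

ncv_log <- function(...) {
  message("[ncvscore] ", sprintf(...))
}
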