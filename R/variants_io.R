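#' Read a variant table from VCF or 4-column TSV
#'
#' Only `CHROM`, `POS`, `REF`, `ALT` are consumed from VCF; multi-allelic
#' records are expanded to one row per alternate allele. The TSV form has
#' columns `chrom`, `pos` (1-based), `ref`, `alt`; extra columns (e.g.
#' `pop_af`) are carried through.
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension), `"vcf"` or `"tsv"`.
#' @return data.table with at least `chrom`, `pos`, `ref`, `alt`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.vcf$", base, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("vcfR is required to read VCF")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    dt <- data.table(chrom = fx$CHROM, pos = as.numeric(fx$POS),
                     ref = fx$REF, alt = fx$ALT)
    # expand multi-allelic sites
    dt <- dt[, .(alt = strsplit(alt, ",", fixed = TRUE)[[1]]),
             by = .(chrom, pos, ref)]
    return(dt[, .(chrom, pos, ref, alt)])
  }
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("variant TSV missing columns: ", paste(miss, collapse = ", "))
  dt[, pos := as.numeric(pos)]
  dt[]
}

#' Read a clinical-assertion table
#'
#' Tab-separated with columns `chrom`, `pos`, `ref`, `alt`, `source`
#' (`clinvar-like`/`hgmd-like`), `assertions` (comma-separated subset of
#' pathogenic, likely_pathogenic, benign, likely_benign, uncertain),
#' `inheritance` (`monogenic_mendelian`, `complex`, `somatic`, `unknown`),
#' `n_homozygotes`, `pop_af`.
#'
#' @param path file path.
#' @return data.table of clinical records.
#' @export
read_clinical_records <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "ref", "alt", "source", "assertions",
            "inheritance", "n_homozygotes", "pop_af")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("clinical record TSV missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$n_homozygotes < 0)) stop("n_homozygotes must be >= 0")
  if (any(dt$pop_af < 0 | dt$pop_af > 1)) stop("pop_af must lie in [0, 1]")
  dt[]
}
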