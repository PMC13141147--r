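#' Gene models
#'
#' A gene model is one protein-coding gene's canonical transcript geometry:
#' transcript span, CDS span and exon blocks, all 1-based inclusive. Region
#' typing of non-coding variants and all per-gene bookkeeping are anchored
#' on these models. Multi-transcript collapse to one canonical transcript
#' per gene is the data producer's job; the package treats the input model
#' as the gene's single geometry.
#'
#' @name gene-models
NULL

new_gene_model_table <- function(dt) {
  setDT(dt)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exons")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("gene model table missing columns: ", paste(miss, collapse = ", "))
  if (!"is_disease_gene" %in% names(dt)) dt[, is_disease_gene := FALSE]
  validate_gene_models(dt)
  setorder(dt, chrom, tx_start)
  setattr(dt, "class", c("ncv_gene_models", class(dt)))
  dt[]
}

#' Validate gene model invariants
#'
#' Checks, per gene: `tx_start <= cds_start <= cds_end <= tx_end`; exons
#' sorted, non-overlapping and within the transcript span; exons cover both
#' CDS endpoints; strand is `+` or `-`.
#'
#' @param models a gene-model table.
#' @return Invisibly `TRUE`; stops with the offending `gene_id` otherwise.
#' @export
validate_gene_models <- function(models) {
  dt <- as.data.table(models)
  for (i in seq_len(nrow(dt))) {
    g <- dt[i]
    id <- g$gene_id
    if (!g$strand %in% c("+", "-"))
      stop("gene ", id, ": strand must be '+' or '-'")
    if (!(g$tx_start <= g$cds_start && g$cds_start <= g$cds_end &&
          g$cds_end <= g$tx_end))
      stop("gene ", id, ": require tx_start <= cds_start <= cds_end <= tx_end")
    ex <- g$exons[[1]]
    if (!is.matrix(ex) || ncol(ex) != 2L)
      stop("gene ", id, ": exons must be a 2-column matrix")
    if (any(ex[, 1] > ex[, 2]))
      stop("gene ", id, ": exon start > end")
    if (is.unsorted(ex[, 1], strictly = FALSE))
      stop("gene ", id, ": exons must be sorted by start")
    if (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
      stop("gene ", id, ": exons overlap")
    if (min(ex[, 1]) < g$tx_start || max(ex[, 2]) > g$tx_end)
      stop("gene ", id, ": exon outside transcript span")
    in_exon <- function(p) any(p >= ex[, 1] & p <= ex[, 2])
    if (!in_exon(g$cds_start) || !in_exon(g$cds_end))
      stop("gene ", id, ": exons must cover cds_start and cds_end")
  }
  invisible(TRUE)
}

parse_exon_blocks <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(parts) {
    m <- do.call(rbind, lapply(parts, function(p) {
      se <- as.numeric(strsplit(p, "-", fixed = TRUE)[[1]])
      if (length(se) != 2L || anyNA(se)) stop("bad exon block: ", p)
      se
    }))
    storage.mode(m) <- "double"
    colnames(m) <- c("start", "end")
    m
  })
}

format_exon_blocks <- function(exons) {
  vapply(exons, function(m) paste(paste0(m[, 1], "-", m[, 2]), collapse = ","),
         character(1))
}

#' Load gene models from GTF/GFF3 or a simplified gene-model TSV
#'
#' The simplified TSV has 8 tab-separated columns: `gene_id`, `chrom`,
#' `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, `exons` (blocks
#' encoded `"start1-end1,start2-end2"`), with an optional ninth column
#' `is_disease_gene`. GTF/GFF3 readers consume `transcript`/`mRNA`, `exon`
#' and `CDS` features grouped by `gene_id`, taking the first transcript per
#' gene as canonical. Records without a CDS (non-coding transcripts) are
#' skipped with a logged count: non-coding genes are out of scope.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"gtf"`, `"gff3"`; default guessed from the
#'   file extension.
#' @return A validated gene-model table sorted by `(chrom, tx_start)`.
#' @export
load_gene_models <- function(path, format = c("auto", "tsv", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                     gtf = "gtf", gff = "gff3", gff3 = "gff3", "tsv")
  }
  if (format == "tsv") {
    dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
    if (any(dt$tx_start > dt$tx_end))
      stop("malformed coordinates (tx_start > tx_end) at line(s): ",
           paste(which(dt$tx_start > dt$tx_end), collapse = ","))
    dt[, exons := parse_exon_blocks(as.character(exons))]
    return(new_gene_model_table(dt))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GTF/GFF3")
  gr <- rtracklayer::import(path, format = ifelse(format == "gtf", "gtf", "gff3"))
  df <- as.data.frame(gr)
  type_col <- as.character(df$type)
  gid <- as.character(df$gene_id)
  out <- list(); skipped <- 0L
  for (g in unique(gid[!is.na(gid)])) {
    sub <- df[gid == g & !is.na(gid), , drop = FALSE]
    tsub <- sub[type_col[gid == g & !is.na(gid)] %in% c("transcript", "mRNA"), ,
                drop = FALSE]
    # first transcript per gene is canonical
    tx_id <- if (nrow(tsub)) as.character(tsub$transcript_id)[1] else NA
    if (!is.na(tx_id) && "transcript_id" %in% names(sub))
      sub <- sub[is.na(sub$transcript_id) | sub$transcript_id == tx_id, ,
                 drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (!nrow(cds)) { skipped <- skipped + 1L; next }
    if (!nrow(ex)) ex <- cds
    exm <- as.matrix(ex[order(ex$start), c("start", "end")])
    storage.mode(exm) <- "double"
    out[[g]] <- data.table(
      gene_id = g, chrom = as.character(sub$seqnames[1]),
      strand = as.character(sub$strand[1]),
      tx_start = if (nrow(tsub)) as.numeric(tsub$start[1]) else min(exm[, 1]),
      tx_end = if (nrow(tsub)) as.numeric(tsub$end[1]) else max(exm[, 2]),
      cds_start = min(cds$start), cds_end = max(cds$end),
      exons = list(exm)
    )
  }
  if (skipped > 0L)
    ncv_log("skipped %d record(s) without CDS (non-coding transcripts)", skipped)
  if (!length(out)) stop("no coding gene models found in ", path)
  new_gene_model_table(rbindlist(out))
}

#' Write gene models to the simplified TSV format
#'
#' @param models gene-model table.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_gene_models <- function(models, path) {
  dt <- as.data.table(models)
  out <- dt[, .(gene_id, chrom, strand, tx_start, tx_end, cds_start, cds_end,
                exons = format_exon_blocks(exons), is_disease_gene)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
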