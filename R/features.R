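#' The 58-feature, four-category annotation schema
#'
#' The default schema has exactly 58 features, 26 of them new relative to
#' the first-generation score, across four categories:
#'
#' * `interspecies_conservation` (16; 8 new): long-term cross-species
#'   conservation at the position — per-clade phastCons/phyloP-style scores
#'   plus large-alignment (241-mammal / 43-primate) conservation and
#'   constraint/acceleration percentiles;
#' * `human_constraint` (16; 12 new): recent and ongoing sequence
#'   constraint in humans — context-tolerance and allele-frequency-spectrum
#'   summaries plus per-subpopulation constraint z-scores for nine major
#'   subpopulations and a global one;
#' * `gene_level` (16; 4 new): conservation/intolerance of the associated
#'   protein-coding gene, including the `loeuf` loss-of-function
#'   observed/expected upper bound and related depletion metrics;
#' * `sequence_context` (10; 2 new): GC and CpG content around the
#'   position, the six-way one-hot encoding of the overlapping non-coding
#'   region type, and the maximum splice-delta score at the variant and at
#'   the position level.
#'
#' Individual feature names other than `loeuf`, the subpopulation slots and
#' the four context features are provisional placeholders that preserve the
#' category structure and counts; real deployments bind them to concrete
#' annotation tracks through [annotation_source()] lookups.
#'
#' Missing values are passed to the tree learner as native missing (trees
#' route missing observations), never imputed.
#'
#' @return data.table of class `ncv_feature_schema` with columns `name`,
#'   `category`, `new_in_v2`, `domain_min`, `domain_max`, `missing_policy`,
#'   and attribute `version`. Row order is the canonical feature-vector
#'   column order.
#' @export
default_schema <- function() {
  f <- function(name, category, new, lo = -Inf, hi = Inf,
                missing = "native") {
    data.table(name = name, category = category, new_in_v2 = new,
               domain_min = lo, domain_max = hi, missing_policy = missing)
  }
  subpops <- c("afr", "amr", "asj", "eas", "fin", "mid", "nfe", "sas", "oth")
  sch <- rbindlist(list(
    # (i) interspecies conservation: 8 carried over + 8 new
    f(c("phastcons_primates", "phastcons_mammals", "phastcons_vertebrates"),
      "interspecies_conservation", FALSE, 0, 1),
    f(c("phylop_primates", "phylop_mammals", "phylop_vertebrates",
        "gerp_n", "gerp_s"),
      "interspecies_conservation", FALSE),
    f(c("phylop_mam241", "phylop_pri43"),
      "interspecies_conservation", TRUE),
    f(c("phastcons_mam241", "phastcons_pri43",
        "constraint_pct_mam241", "constraint_pct_pri43",
        "accel_pct_mam241", "accel_pct_pri43"),
      "interspecies_conservation", TRUE, 0, 1),
    # (ii) human constraint: 4 carried over + 12 new
    f(c("cdts", "mean_daf", "tajimas_d", "fu_li_f"),
      "human_constraint", FALSE),
    f(c("constraint_z_global", paste0("constraint_z_", subpops)),
      "human_constraint", TRUE),
    f(c("rare_variant_density", "singleton_fraction"),
      "human_constraint", TRUE, 0, 1),
    # (iii) gene level: 12 carried over + 4 new
    f(c("fam_member_count", "gene_age"), "gene_level", FALSE, 0, Inf),
    f(c("nc_rvis", "nc_gerp", "dnds_macaque", "dnds_mouse"),
      "gene_level", FALSE),
    f(c("rvis_percentile", "gdi_percentile", "pli",
        "utr5_gene_cons", "utr3_gene_cons", "promoter_gene_cons"),
      "gene_level", FALSE, 0, 1),
    f(c("loeuf", "mis_oe", "syn_oe", "s_het"), "gene_level", TRUE, 0, Inf),
    # (iv) sequence context: 8 carried over + 2 new
    f(c("gc_content", "cpg_content"), "sequence_context", FALSE, 0, 1),
    f(paste0("region_", c("upstream", "utr5", "intronic", "utr3",
                          "downstream", "intergenic")),
      "sequence_context", FALSE, 0, 1, missing = "never"),
    f(c("spliceai_variant_max", "spliceai_position_max"),
      "sequence_context", TRUE, 0, 1)
  ))
  stopifnot(nrow(sch) == 58L, sum(sch$new_in_v2) == 26L,
            !anyDuplicated(sch$name))
  setattr(sch, "version", "1.0")
  setattr(sch, "class", c("ncv_feature_schema", class(sch)))
  sch[]
}

#' Feature names of a schema in canonical order
#' @param schema an `ncv_feature_schema` (default [default_schema()]).
#' @return character vector of length 58 for the default schema.
#' @export
schema_features <- function(schema = default_schema()) schema$name

#' Serialize / deserialize a feature schema (YAML)
#'
#' The round trip is bit-identical: reading back a written schema yields a
#' table equal to the original, including the version attribute.
#'
#' @param schema an `ncv_feature_schema`.
#' @param path YAML file path.
#' @return Invisibly `path` (writer); the schema (reader).
#' @export
write_schema <- function(schema, path) {
  obj <- list(version = attr(schema, "version"),
              features = lapply(seq_len(nrow(schema)), function(i) {
                r <- schema[i]
                list(name = r$name, category = r$category,
                     new_in_v2 = r$new_in_v2,
                     domain_min = if (is.finite(r$domain_min)) r$domain_min else "-Inf",
                     domain_max = if (is.finite(r$domain_max)) r$domain_max else "Inf",
                     missing_policy = r$missing_policy)
              }))
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  sch <- rbindlist(lapply(obj$features, function(r) {
    data.table(name = r$name, category = r$category,
               new_in_v2 = r$new_in_v2,
               domain_min = as.numeric(r$domain_min),
               domain_max = as.numeric(r$domain_max),
               missing_policy = r$missing_policy)
  }))
  setattr(sch, "version", obj$version)
  setattr(sch, "class", c("ncv_feature_schema", class(sch)))
  sch[]
}

#' Declare an annotation source
#'
#' An annotation source declares the subset of schema features it can fill
#' and provides a lookup over variants. `lookup(chrom, pos, ref, alt)`
#' receives equal-length vectors and must return a data.frame with one row
#' per queried variant and columns a subset of `features`; position-keyed
#' sources simply ignore `ref`/`alt`. Values outside the declared feature
#' set are rejected; a lookup that throws leaves that source's features
#' missing for the batch, with a counted warning.
#'
#' @param features character vector of declared schema feature names.
#' @param lookup function as described.
#' @param name label used in messages.
#' @return object of class `ncv_annotation_source`.
#' @export
annotation_source <- function(features, lookup, name = "source") {
  stopifnot(is.character(features), length(features) > 0, is.function(lookup))
  structure(list(features = features, lookup = lookup, name = name),
            class = "ncv_annotation_source")
}

#' Annotation source backed by an in-memory / TSV feature table
#'
#' The table must have `chrom`, `pos` and optionally `ref`, `alt` keys plus
#' one column per declared feature. When `ref`/`alt` columns are present
#' the source is variant-keyed, otherwise position-keyed. A tabix-indexed
#' bgzipped TSV with the same layout can be read with `data.table::fread`
#' into this source; the lookup contract is the same.
#'
#' @param table data.frame or TSV path.
#' @param features declared features; default every non-key column.
#' @param name label.
#' @return `ncv_annotation_source`.
#' @export
table_annotation_source <- function(table, features = NULL,
                                    name = "table-source") {
  dt <- if (is.character(table)) fread(table, sep = "\t",
                                       colClasses = list(character = "chrom"))
        else as.data.table(table)
  keys <- intersect(c("chrom", "pos", "ref", "alt"), names(dt))
  if (!all(c("chrom", "pos") %in% keys))
    stop("feature table needs chrom and pos columns")
  if (is.null(features)) features <- setdiff(names(dt), keys)
  variant_keyed <- all(c("ref", "alt") %in% keys)
  data.table::setkeyv(dt, keys)
  lookup <- function(chrom, pos, ref, alt) {
    q <- if (variant_keyed) data.table(chrom = chrom, pos = pos,
                                       ref = ref, alt = alt)
         else data.table(chrom = chrom, pos = pos)
    hit <- dt[q, on = keys, mult = "first"]
    as.data.frame(hit[, features, with = FALSE])
  }
  annotation_source(features, lookup, name)
}

#' Annotate variants into schema-ordered feature vectors
#'
#' Each variant receives one feature vector of length `nrow(schema)` in
#' canonical schema order. Sources must declare disjoint feature subsets —
#' two sources declaring the same feature is a configuration error raised
#' at setup, before any lookup runs. Features not declared by any source
#' stay missing (`NA`). Annotation is idempotent and order-independent over
#' variants.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (extra
#'   columns carried through).
#' @param sources list of `ncv_annotation_source` objects.
#' @param schema feature schema (default [default_schema()]).
#' @return data.table: input columns plus one column per schema feature.
#' @export
annotate <- function(variants, sources, schema = default_schema()) {
  if (inherits(sources, "ncv_annotation_source")) sources <- list(sources)
  decl <- unlist(lapply(sources, `[[`, "features"))
  dup <- unique(decl[duplicated(decl)])
  if (length(dup))
    stop("feature(s) declared by more than one source: ",
         paste(dup, collapse = ", "))
  unknown <- setdiff(decl, schema$name)
  if (length(unknown))
    stop("source declares feature(s) absent from schema: ",
         paste(unknown, collapse = ", "))
  V <- as.data.table(variants)
  out <- copy(V)
  for (nm in schema$name) out[, (nm) := NA_real_]
  n_failed <- 0L
  for (src in sources) {
    vals <- tryCatch(
      src$lookup(V$chrom, V$pos, V$ref, V$alt),
      error = function(e) { n_failed <<- n_failed + 1L; NULL })
    if (is.null(vals)) next
    vals <- as.data.frame(vals)
    extra <- setdiff(names(vals), src$features)
    if (length(extra))
      stop("source '", src$name, "' returned undeclared feature(s): ",
           paste(extra, collapse = ", "))
    if (nrow(vals) != nrow(V))
      stop("source '", src$name, "' returned ", nrow(vals),
           " rows for ", nrow(V), " variants")
    for (nm in names(vals)) out[, (nm) := as.numeric(vals[[nm]])]
  }
  if (n_failed > 0L)
    warning(n_failed, " annotation source(s) failed; their features left missing")
  out[]
}

#' Collapse splice delta scores to variant- and position-level maxima
#'
#' Each alternate allele at a position carries four splice delta scores
#' (acceptor gain/loss, donor gain/loss) in `[0, 1]`. The variant-level
#' maximum is the max of the four deltas of the queried alt; the
#' position-level maximum is the max of the variant-level maxima over all
#' alts observed at the position. A missing alt yields both features
#' missing.
#'
#' @param delta_scores_by_alt named list: alt allele -> numeric(4) deltas.
#' @param alt the queried alternate allele.
#' @return named numeric `c(variant_max=, position_max=)` (NA, NA if the
#'   alt is absent).
#' @export
spliceai_max_features <- function(delta_scores_by_alt, alt) {
  if (!length(delta_scores_by_alt) || !alt %in% names(delta_scores_by_alt))
    return(c(variant_max = NA_real_, position_max = NA_real_))
  per_alt <- vapply(delta_scores_by_alt, function(d) {
    stopifnot(length(d) == 4L, all(d >= 0 & d <= 1))
    max(d)
  }, numeric(1))
  c(variant_max = unname(per_alt[[alt]]),
    position_max = max(per_alt))
}

#' GC and CpG content of a reference window
#'
#' For a window of width `W` (odd, default 101) centred on the position:
#' `gc_fraction` is (#G + #C) divided by the number of non-N bases;
#' `cpg_fraction` is the number of CG dinucleotides divided by the number
#' of dinucleotide positions (`W - 1` for a full window), with
#' N-containing dinucleotides excluded from the numerator. Windows
#' truncated at a chromosome end are handled by passing the shorter
#' sequence — denominators adjust to the actual length. CpG content is
#' invariant under reverse complement of the window.
#'
#' @param seq character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @return named numeric `c(gc_fraction=, cpg_fraction=)`.
#' @export
gc_cpg_content <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!length(s)) stop("empty sequence window")
  if (!all(s %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over {A,C,G,T,N}")
  non_n <- sum(s != "N")
  gc <- if (non_n > 0) sum(s %in% c("G", "C")) / non_n else NA_real_
  if (length(s) >= 2L) {
    a <- s[-length(s)]; b <- s[-1L]
    cpg <- sum(a == "C" & b == "G") / (length(s) - 1L)
  } else cpg <- 0
  c(gc_fraction = gc, cpg_fraction = cpg)
}
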