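#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the data shapes the pipeline consumes — gene
#' models, clinical-assertion records, a common/rare variant pool, and a
#' fully annotated 58-column feature matrix — with controllable statistical
#' structure. Defaults reflect the study conditions of the curated
#' Mendelian-disease setting the package targets: 765 curated pathogenic
#' non-coding SNVs, one per disease gene, a 1:10 negative ratio, 10 gene
#' partitions, and a region mix of 61/133/475/77/9/10 across
#' upstream/5'UTR/intronic/3'UTR/downstream/intergenic.
#'
#' @param n_genes number of protein-coding genes (default 900).
#' @param chromosomes chromosome names genes are dealt onto round-robin
#'   (default `chr1..chr22`).
#' @param fraction_disease_genes fraction flagged as Mendelian-disease
#'   genes (default 0.85, i.e. 765 of 900).
#' @param n_positives number of pathogenic variants, one per disease gene
#'   (default 765). Set `allow_multiple_per_gene = TRUE` to deliberately
#'   place several per gene for cap tests.
#' @param n_pool_per_gene target pool variants per gene, allocated across
#'   regions by `region_weights` with at least one per region (default 30).
#' @param common_fraction fraction of each gene-region pool block given a
#'   common allele frequency (default 0.7; the rest are rare).
#' @param ratio design negatives-per-positive used for the feasibility
#'   check (default 10).
#' @param d named mean shift (in SD units) of pathogenic vs benign feature
#'   distributions, one entry per feature category (default 1 each —
#'   moderate, realistically imperfect separation).
#' @param region_bias named per-region baseline shift added to all
#'   variants' continuous features in that region (default +0.5 on `UTR5`,
#'   emulating the 5'UTR score-inflation bias; 0 elsewhere).
#' @param missing_rate named per-category missingness rate applied to
#'   continuous features (default 0.05 for the three conservation-style
#'   categories, 0 for sequence context).
#' @param fraction_splice_driven fraction of positives whose separation is
#'   carried mainly by the two splice-delta slots (default 0.2): their
#'   splice maxima are near 1 while their other features get only 30% of
#'   the category shift.
#' @param region_weights region composition of positives and of the pool.
#' @param allow_multiple_per_gene place positives ignoring the
#'   one-per-gene rule (for cap tests).
#' @param seed integer; fixes the entire dataset.
#' @return list of class `ncv_synth_config`.
#' @export
synth_config <- function(n_genes = 900,
                         chromosomes = paste0("chr", 1:22),
                         fraction_disease_genes = 0.85,
                         n_positives = 765,
                         n_pool_per_gene = 30,
                         common_fraction = 0.7,
                         ratio = 10,
                         d = c(interspecies_conservation = 1,
                               human_constraint = 1,
                               gene_level = 1,
                               sequence_context = 1),
                         region_bias = c(upstream = 0, UTR5 = 0.5,
                                         intronic = 0, UTR3 = 0,
                                         downstream = 0, intergenic = 0),
                         missing_rate = c(interspecies_conservation = 0.05,
                                          human_constraint = 0.05,
                                          gene_level = 0.05,
                                          sequence_context = 0),
                         fraction_splice_driven = 0.2,
                         region_weights = c(upstream = 61, UTR5 = 133,
                                            intronic = 475, UTR3 = 77,
                                            downstream = 9,
                                            intergenic = 10) / 765,
                         allow_multiple_per_gene = FALSE,
                         seed = 1) {
  cats <- c("interspecies_conservation", "human_constraint", "gene_level",
            "sequence_context")
  if (length(d) == 1L && is.null(names(d))) d <- setNames(rep(d, 4), cats)
  stopifnot(all(cats %in% names(d)), all(d >= 0),
            all(cats %in% names(missing_rate)),
            all(missing_rate >= 0 & missing_rate <= 1),
            all(region_types() %in% names(region_bias)),
            fraction_disease_genes >= 0, fraction_disease_genes <= 1,
            fraction_splice_driven >= 0, fraction_splice_driven <= 1,
            common_fraction > 0, common_fraction <= 1,
            abs(sum(region_weights) - 1) < 1e-8)
  n_disease <- round(n_genes * fraction_disease_genes)
  if (!allow_multiple_per_gene && n_positives > n_disease)
    stop("n_positives exceeds the number of disease genes (one per gene)")
  structure(list(
    n_genes = n_genes, chromosomes = chromosomes,
    fraction_disease_genes = fraction_disease_genes,
    n_disease = n_disease,
    n_positives = n_positives, n_pool_per_gene = n_pool_per_gene,
    common_fraction = common_fraction, ratio = ratio,
    d = d[cats], region_bias = region_bias[region_types()],
    missing_rate = missing_rate[cats],
    fraction_splice_driven = fraction_splice_driven,
    region_weights = region_weights[region_types()],
    allow_multiple_per_gene = allow_multiple_per_gene,
    seed = as.integer(seed)), class = "ncv_synth_config")
}

# largest-remainder integer allocation of n across weights
allocate_counts <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# coordinate range of a region within/around one gene (strand-aware);
# returns c(lo, hi) or a two-row matrix for intronic/intergenic choices
region_ranges <- function(g, region) {
  ex <- g$exons[[1]]
  plus <- g$strand == "+"
  switch(region,
    upstream = if (plus) c(g$tx_start - 1000, g$tx_start - 1)
               else c(g$tx_end + 1, g$tx_end + 1000),
    downstream = if (plus) c(g$tx_end + 1, g$tx_end + 1000)
                 else c(g$tx_start - 1000, g$tx_start - 1),
    UTR5 = if (plus) c(g$tx_start, g$cds_start - 1)
           else c(g$cds_end + 1, g$tx_end),
    UTR3 = if (plus) c(g$cds_end + 1, g$tx_end)
           else c(g$tx_start, g$cds_start - 1),
    intronic = rbind(c(ex[1, 2] + 1, ex[2, 1] - 1),
                     c(ex[2, 2] + 1, ex[3, 1] - 1)),
    intergenic = rbind(c(g$tx_start - 5000, g$tx_start - 1101),
                       c(g$tx_end + 1101, g$tx_end + 5000))
  )
}

sample_region_positions <- function(g, region, n, exclude = NULL) {
  r <- region_ranges(g, region)
  cand <- if (is.matrix(r)) c(seq(r[1, 1], r[1, 2]), seq(r[2, 1], r[2, 2]))
          else seq(r[1], r[2])
  if (!is.null(exclude)) cand <- setdiff(cand, exclude)
  if (n > length(cand))
    stop("region ", region, " of gene ", g$gene_id,
         " too small for ", n, " distinct positions")
  sample(cand, n)
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
random_alt <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
         character(1), USE.NAMES = FALSE)
}

make_synthetic_genes <- function(cfg) {
  n <- cfg$n_genes
  chroms <- rep(cfg$chromosomes, length.out = n)
  rows <- vector("list", n)
  cursor <- setNames(rep(10000, length(cfg$chromosomes)), cfg$chromosomes)
  disease <- c(rep(TRUE, cfg$n_disease), rep(FALSE, n - cfg$n_disease))
  for (i in seq_len(n)) {
    ch <- chroms[i]
    e1 <- sample(250:400, 1); i1 <- sample(900:1500, 1)
    e2 <- sample(150:300, 1); i2 <- sample(900:1500, 1)
    e3 <- sample(250:400, 1)
    tx_start <- cursor[[ch]]
    tx_end <- tx_start + e1 + i1 + e2 + i2 + e3 - 1
    u5 <- sample(80:200, 1); u3 <- sample(80:200, 1)
    exons <- rbind(c(tx_start, tx_start + e1 - 1),
                   c(tx_start + e1 + i1, tx_start + e1 + i1 + e2 - 1),
                   c(tx_end - e3 + 1, tx_end))
    colnames(exons) <- c("start", "end")
    rows[[i]] <- data.table(
      gene_id = sprintf("G%04d", i), chrom = ch,
      strand = sample(c("+", "-"), 1),
      tx_start = tx_start, tx_end = tx_end,
      cds_start = tx_start + u5, cds_end = tx_end - u3,
      exons = list(exons), is_disease_gene = disease[i])
  }
  g <- rbindlist(rows)
  # shuffle which genes are disease genes, then advance chromosome cursors
  g[, is_disease_gene := sample(is_disease_gene)]
  # genes were laid down per chromosome in order; re-space them
  g[, row_i := .I]
  for (ch in unique(g$chrom)) {
    idx <- g[chrom == ch, row_i]
    pos <- 10000
    for (j in idx) {
      len <- g$tx_end[j] - g$tx_start[j]
      shift <- pos - g$tx_start[j]
      g[j, `:=`(tx_start = tx_start + shift, tx_end = tx_end + shift,
                cds_start = cds_start + shift, cds_end = cds_end + shift,
                exons = list(exons[[1]] + shift))]
      pos <- pos + len + sample(25000:40000, 1)
    }
  }
  g[, row_i := NULL]
  new_gene_model_table(g)
}

#' Generate a complete synthetic dataset
#'
#' Builds, under one seed: gene models laid out along the configured
#' chromosomes; pathogenic positives placed inside their intended region of
#' distinct disease genes (region counts follow `region_weights` exactly,
#' largest-remainder allocation); matching clinical-assertion records; a
#' benign pool with deterministic common/rare allele-frequency block
#' structure; and a full 58-column feature matrix. Continuous features are
#' unit-variance draws with mean `region_bias[region]` for benign variants
#' and additionally `+d[category]` for pathogenic ones (scaled to 30% for
#' splice-driven positives, whose splice-delta slots are instead near 1);
#' features with a `[0,1]` domain are passed through the normal CDF, a
#' monotone map that preserves separation while respecting the domain.
#' Missingness is applied per category at the configured rate (region
#' one-hot and splice slots stay observed). The same seed yields a
#' byte-identical dataset.
#'
#' @param cfg an [synth_config()] object.
#' @return list of class `ncv_synth_dataset`: `config`, `gene_models`,
#'   `clinical_records`, `positives`, `pool`, and `variants`
#'   (positives + pool, annotated, with `label`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ncv_synth_config"))
  regions <- region_types()
  m_r <- setNames(pmax(1L, allocate_counts(cfg$n_pool_per_gene,
                                           cfg$region_weights)), regions)
  pos_r <- setNames(allocate_counts(cfg$n_positives, cfg$region_weights),
                    regions)
  # feasibility: enough common pool variants per region for the 1:ratio draw
  n_common_r <- cfg$n_genes * ceiling(m_r * cfg$common_fraction)
  need_r <- cfg$ratio * pos_r
  if (any(n_common_r < need_r)) {
    bad <- regions[n_common_r < need_r][1]
    stop("infeasible config: region ", bad, " offers ~", n_common_r[bad],
         " common pool variants but the 1:", cfg$ratio, " design needs ",
         need_r[bad], "; increase n_pool_per_gene or n_genes")
  }

  with_seed(cfg$seed, {
    genes <- make_synthetic_genes(cfg)
    gdt <- as.data.table(genes)

    # --- positives: one per disease gene (unless deliberately violated)
    disease_ids <- gdt[is_disease_gene == TRUE, gene_id]
    host <- if (cfg$allow_multiple_per_gene)
      sample(disease_ids, cfg$n_positives, replace = TRUE)
    else sample(disease_ids, cfg$n_positives)
    pos_regions <- sample(rep(regions, times = pos_r))
    P <- data.table(gene_id = host, region = pos_regions)

    data.table::setkey(gdt, gene_id)
    place <- function(tab, exclude = NULL) {
      out <- vector("list", nrow(tab))
      for (i in seq_len(nrow(tab))) {
        g <- gdt[.(tab$gene_id[i])]
        excl <- if (is.null(exclude)) NULL
                else exclude[gene_id == g$gene_id & region == tab$region[i],
                             pos]
        p <- sample_region_positions(g, tab$region[i], tab$n[i], excl)
        ref <- random_bases(tab$n[i])
        out[[i]] <- data.table(chrom = g$chrom, pos = p, ref = ref,
                               alt = random_alt(ref),
                               gene_id = g$gene_id, region = tab$region[i])
      }
      rbindlist(out)
    }
    P <- place(P[, .(gene_id, region, n = 1L)])[
      , .(chrom, pos, ref, alt, gene_id, region)]
    P[, `:=`(label = 1L, pop_af = runif(.N, 0, 5e-4))]

    # --- clinical records mirroring the positives
    rec <- P[, .(chrom, pos, ref, alt,
                 source = sample(c("clinvar-like", "hgmd-like"), .N,
                                 replace = TRUE),
                 assertions = "pathogenic",
                 inheritance = "monogenic_mendelian",
                 n_homozygotes = 0L, pop_af = pop_af)]

    # --- benign pool: m_r variants per gene per region, block AF structure
    spec <- gdt[, .(gene_id)][, .(region = regions, n = m_r), by = gene_id]
    Q <- place(spec, exclude = P[, .(gene_id, region, pos)])
    n_common_blk <- ceiling(m_r * cfg$common_fraction)
    Q[, pop_af := {
      nc <- n_common_blk[[region[1]]]
      af <- numeric(.N)
      af[seq_len(min(nc, .N))] <- runif(min(nc, .N), 0.01, 0.5)
      if (.N > nc) af[(nc + 1):.N] <- runif(.N - nc, 1e-5, 1e-3)
      af
    }, by = .(gene_id, region)]
    # drop the rare chance of key collision with a positive
    Q[, key := variant_key(chrom, pos, ref, alt)]
    Q <- Q[!key %in% variant_key(P$chrom, P$pos, P$ref, P$alt)][, key := NULL]
    Q[, label := 0L]

    V <- rbind(P, Q)
    V <- add_synthetic_features(V, cfg)
    structure(list(config = cfg, gene_models = genes,
                   clinical_records = rec,
                   positives = V[label == 1L],
                   pool = V[label == 0L],
                   variants = V),
              class = "ncv_synth_dataset")
  })
}

# draw the 58 schema features for a labelled variant table (in place-ish)
add_synthetic_features <- function(V, cfg) {
  V <- copy(V)
  sch <- default_schema()
  n <- nrow(V)
  bias <- cfg$region_bias[V$region]
  splice_driven <- V$label == 1L &
    runif(n) < cfg$fraction_splice_driven
  shift_scale <- ifelse(splice_driven, 0.3, 1)
  onehot <- paste0("region_", tolower(region_types()))
  splice_cols <- c("spliceai_variant_max", "spliceai_position_max")
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]; cat_i <- sch$category[i]
    if (nm %in% onehot) {
      V[, (nm) := as.numeric(paste0("region_", tolower(region)) == nm)]
      next
    }
    if (nm %in% splice_cols) {
      v <- rbeta(n, 1, 80)                       # benign baseline near 0
      v[splice_driven] <- rbeta(sum(splice_driven), 60, 3)
      if (nm == "spliceai_position_max") {
        vm <- V[["spliceai_variant_max"]]
        v <- pmax(v, vm)                         # position max >= variant max
      }
      V[, (nm) := v]
      next
    }
    z <- rnorm(n) + bias + cfg$d[[cat_i]] * shift_scale * (V$label == 1L)
    val <- if (is.finite(sch$domain_min[i]) && is.finite(sch$domain_max[i]))
      sch$domain_min[i] + (sch$domain_max[i] - sch$domain_min[i]) * pnorm(z)
    else if (is.finite(sch$domain_min[i])) sch$domain_min[i] + exp(z / 2)
    else z
    mr <- cfg$missing_rate[[cat_i]]
    if (mr > 0) val[runif(n) < mr] <- NA_real_
    V[, (nm) := val]
  }
  V[]
}

#' Write a synthetic dataset in the pipeline's standard formats
#'
#' Emits `gene_models.tsv`, `clinical_records.tsv`, `pool.tsv`,
#' `annotated.tsv` and the resolved `config.yaml` into `dir`, the same
#' formats the real pipeline reads — synthetic and real runs are
#' path-identical.
#'
#' @param ds an `ncv_synth_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_models(ds$gene_models, file.path(dir, "gene_models.tsv"))
  fwrite(ds$clinical_records, file.path(dir, "clinical_records.tsv"),
         sep = "\t")
  fwrite(ds$pool, file.path(dir, "pool.tsv"), sep = "\t")
  fwrite(ds$variants, file.path(dir, "annotated.tsv"), sep = "\t")
  cfg <- ds$config
  cfg_list <- lapply(unclass(cfg), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  writeLines(yaml::as.yaml(cfg_list), file.path(dir, "config.yaml"))
  invisible(dir)
}
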