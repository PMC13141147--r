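#' Training hyperparameters for the gradient-boosted bundle
#'
#' Defaults: up to 500 boosting rounds with early stopping after 25
#' stagnant rounds on a 10% held-in validation split grouped by gene (so
#' the split itself cannot leak genes), learning rate 0.05, maximum depth
#' 6, minimum child weight 1, row subsample 0.8, column subsample 0.8, and
#' positive-class weight 1 — the 1:10 class ratio of the training design is
#' intentional and left unreweighted. All values are serialized with every
#' bundle.
#'
#' @param n_rounds,learning_rate,max_depth,min_child_weight,subsample,colsample,early_stopping_rounds,validation_fraction,scale_pos_weight,nthread
#'   see description; `nthread = 1` gives fully deterministic fits.
#' @return list of class `ncv_hyperparams`.
#' @export
hyperparams <- function(n_rounds = 500, learning_rate = 0.05, max_depth = 6,
                        min_child_weight = 1, subsample = 0.8,
                        colsample = 0.8, early_stopping_rounds = 25,
                        validation_fraction = 0.1, scale_pos_weight = 1,
                        nthread = 1) {
  stopifnot(n_rounds >= 1, learning_rate > 0, learning_rate <= 1,
            max_depth >= 1, subsample > 0, subsample <= 1,
            colsample > 0, colsample <= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(n_rounds = n_rounds, learning_rate = learning_rate,
                 max_depth = max_depth, min_child_weight = min_child_weight,
                 subsample = subsample, colsample = colsample,
                 early_stopping_rounds = early_stopping_rounds,
                 validation_fraction = validation_fraction,
                 scale_pos_weight = scale_pos_weight, nthread = nthread),
            class = "ncv_hyperparams")
}

feature_matrix <- function(table, schema) {
  miss <- setdiff(schema$name, names(table))
  if (length(miss))
    stop("table lacks ", length(miss), " schema feature column(s), e.g. ",
         paste(head(miss, 3), collapse = ", "))
  m <- as.matrix(as.data.table(table)[, schema$name, with = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train the k-model partition-hold-out bundle
#'
#' For every partition `j` in `0..k-1`, one gradient-boosted tree ensemble
#' is fit on all training rows whose gene does not belong to partition `j`
#' (binary log-loss objective; the score is the predicted positive-class
#' probability). The leakage gate [assert_no_leakage()] runs before every
#' fit and any failure aborts the whole training. The bundle therefore
#' contains, for every gene, a model that never saw that gene. Missing
#' feature values are passed natively to the trees. Deterministic given the
#' seed at `nthread = 1`.
#'
#' @param table training table carrying `gene_id`, `label` and all schema
#'   feature columns.
#' @param pmap `ncv_partition_map` covering all training genes.
#' @param params an [hyperparams()] object.
#' @param schema feature schema (default [default_schema()]).
#' @param seed integer seed.
#' @return list of class `ncv_model_bundle`: `models` (length k), `pmap`,
#'   `schema`, `params`, `metadata` (seed, per-model row counts, best
#'   iteration and feature importances).
#' @export
train_bundle <- function(table, pmap, params = hyperparams(),
                         schema = default_schema(), seed = 1) {
  tab <- as.data.table(table)
  stopifnot(all(c("gene_id", "label") %in% names(tab)))
  if (!all(tab$label %in% c(0L, 1L))) stop("labels must be 0/1")
  k <- pmap$k
  tab[, partition := partition_of(pmap, gene_id)]
  X <- feature_matrix(tab, schema)
  models <- vector("list", k)
  meta_models <- vector("list", k)
  for (j in seq_len(k) - 1L) {
    train_rows <- which(tab$partition != j)
    sub <- tab[train_rows]
    if (!assert_no_leakage(pmap, sub, j))
      stop("leakage gate failed for held-out partition ", j)
    if (sum(sub$label == 1L) == 0L)
      stop("no positive training variants outside partition ", j)
    # gene-grouped internal validation split for early stopping
    fit_seed <- derive_seed(seed, "train") + j
    genes_j <- unique(sub$gene_id)
    val_genes <- with_seed(fit_seed, {
      ng <- max(1L, round(length(genes_j) * params$validation_fraction))
      sample(genes_j, ng)
    })
    is_val <- sub$gene_id %in% val_genes
    if (all(is_val) || !any(is_val)) is_val <- rep(FALSE, nrow(sub))
    dtrain <- xgboost::xgb.DMatrix(X[train_rows[!is_val], , drop = FALSE],
                                   label = sub$label[!is_val])
    evals <- list()
    if (any(is_val) && sum(sub$label[is_val] == 1L) > 0L &&
        sum(sub$label[is_val] == 0L) > 0L) {
      evals <- list(val = xgboost::xgb.DMatrix(
        X[train_rows[is_val], , drop = FALSE], label = sub$label[is_val]))
    }
    xp <- xgboost::xgb.params(
      objective = "binary:logistic", eval_metric = "logloss",
      eta = params$learning_rate, max_depth = params$max_depth,
      min_child_weight = params$min_child_weight,
      subsample = params$subsample, colsample_bytree = params$colsample,
      scale_pos_weight = params$scale_pos_weight,
      nthread = params$nthread, seed = fit_seed)
    fit <- if (length(evals))
      xgboost::xgb.train(xp, dtrain, nrounds = params$n_rounds,
                         evals = evals,
                         early_stopping_rounds = params$early_stopping_rounds,
                         verbose = 0)
    else
      xgboost::xgb.train(xp, dtrain, nrounds = params$n_rounds, verbose = 0)
    imp <- tryCatch(
      as.data.frame(xgboost::xgb.importance(model = fit)),
      error = function(e) NULL)
    models[[j + 1L]] <- fit
    meta_models[[j + 1L]] <- list(
      held_out_partition = j, n_train = sum(!is_val), n_val = sum(is_val),
      n_pos = sum(sub$label == 1L),
      best_iteration = tryCatch(
        as.integer(xgboost::xgb.attr(fit, "best_iteration")),
        error = function(e) NA_integer_),
      importance = imp)
  }
  structure(list(models = models, pmap = pmap, schema = schema,
                 params = params,
                 metadata = list(seed = as.integer(seed), k = k,
                                 n_rows = nrow(tab),
                                 feature_names = schema$name,
                                 models = meta_models)),
            class = "ncv_model_bundle")
}

#' @export
print.ncv_model_bundle <- function(x, ...) {
  cat("Model bundle:", length(x$models), "partition-hold-out models,",
      nrow(x$schema), "features\n")
  invisible(x)
}

#' Score variants with the partition-appropriate model
#'
#' A variant in a gene of partition `j` is scored by model `j` — the model
#' blind to that partition. Variants whose gene is absent from the
#' partition map are scored by the arithmetic mean of all k models and
#' flagged `model_index = "mean"`. Output is sorted by
#' `(chrom, pos, alt)`.
#'
#' @param bundle an `ncv_model_bundle`.
#' @param variants annotated variant table (schema feature columns plus
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `region`).
#' @return data.table of score records: variant key columns, `gene_id`,
#'   `region`, `score` in `[0,1]`, `model_index` (`"0".."k-1"` or
#'   `"mean"`).
#' @export
score_variants <- function(bundle, variants) {
  V <- as.data.table(variants)
  X <- feature_matrix(V, bundle$schema)
  k <- length(bundle$models)
  part <- partition_of(bundle$pmap, V$gene_id, strict = FALSE)
  preds <- matrix(NA_real_, nrow(V), k)
  dm <- xgboost::xgb.DMatrix(X)
  for (j in seq_len(k))
    preds[, j] <- predict(bundle$models[[j]], dm)
  score <- ifelse(is.na(part), rowMeans(preds),
                  preds[cbind(seq_len(nrow(V)), part + 1L)])
  out <- V[, .(chrom, pos, ref, alt, gene_id, region)]
  out[, `:=`(score = score,
             model_index = ifelse(is.na(part), "mean", as.character(part)))]
  setorder(out, chrom, pos, alt)
  out[]
}

#' Write / read precomputed score records
#'
#' Tab-separated `chrom, pos, ref, alt, gene_id, region, score,
#' model_index` with a `#`-commented header line; scores at 6 decimal
#' places (the round trip is exact at that precision). Input must already
#' be sorted by `(chrom, pos, alt)` — unsorted input is an error. The
#' layout is bgzip/tabix-compatible.
#'
#' @param records score records from [score_variants()].
#' @param path output TSV.
#' @return Invisibly `path` (writer); a data.table (reader).
#' @export
write_precomputed_scores <- function(records, path) {
  dt <- as.data.table(records)
  cols <- c("chrom", "pos", "ref", "alt", "gene_id", "region", "score",
            "model_index")
  stopifnot(all(cols %in% names(dt)))
  if (nrow(dt)) {
    ord <- order(dt$chrom, dt$pos, dt$alt)
    if (!identical(ord, seq_len(nrow(dt))))
      stop("score records must be sorted by (chrom, pos, alt)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(dt)) {
    body <- dt[, cols, with = FALSE]
    body[, score := sprintf("%.6f", score)]
    writeLines(do.call(paste, c(as.list(body), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_precomputed_scores
#' @export
read_precomputed_scores <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  classes <- ifelse(cols %in% c("pos", "score"), "numeric", "character")
  if (length(lines) < 2L) {
    dt <- as.data.table(setNames(
      lapply(classes, function(cl) vector(cl, 0L)), cols))
    return(dt[])
  }
  dt <- fread(path, sep = "\t", skip = 1L, header = FALSE,
              col.names = cols, colClasses = classes)
  dt[]
}

#' Save / load a model bundle directory
#'
#' The bundle directory holds the k models in the booster library's native
#' serialization (`model_<j>.ubj`), the feature schema as YAML, the
#' partition map TSV (+ JSON tallies), and training metadata JSON. The
#' no-leakage invariant is re-checkable from the serialized metadata.
#'
#' @param bundle an `ncv_model_bundle`.
#' @param dir directory (created if needed).
#' @return Invisibly `dir` (saver); the bundle (loader).
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(bundle$models))
    xgboost::xgb.save(bundle$models[[j]],
                      file.path(dir, sprintf("model_%d.ubj", j - 1L)))
  write_schema(bundle$schema, file.path(dir, "schema.yaml"))
  write_partition_map(bundle$pmap, file.path(dir, "partitions.tsv"))
  meta <- bundle$metadata
  meta$params <- unclass(bundle$params)
  meta$models <- lapply(meta$models, function(m) {
    m$importance <- NULL  # kept in-memory only; large and derivable
    m
  })
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  k <- as.integer(meta$k)
  models <- lapply(seq_len(k) - 1L, function(j)
    xgboost::xgb.load(file.path(dir, sprintf("model_%d.ubj", j))))
  p <- meta$params
  structure(list(models = models,
                 pmap = read_partition_map(file.path(dir, "partitions.tsv")),
                 schema = read_schema(file.path(dir, "schema.yaml")),
                 params = do.call(hyperparams, list(
                   n_rounds = p$n_rounds, learning_rate = p$learning_rate,
                   max_depth = p$max_depth,
                   min_child_weight = p$min_child_weight,
                   subsample = p$subsample, colsample = p$colsample,
                   early_stopping_rounds = p$early_stopping_rounds,
                   validation_fraction = p$validation_fraction,
                   scale_pos_weight = p$scale_pos_weight,
                   nthread = p$nthread)),
                 metadata = meta),
            class = "ncv_model_bundle")
}
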