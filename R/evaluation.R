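#' Area under the ROC curve (rank-statistic form)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties credited one half — numerically equal to the
#' trapezoidal area under the ROC curve, and invariant under any strictly
#' monotone transform of the scores.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores numeric vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC requires both classes to be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-sum form: scores are swept from high to low over distinct
#' thresholds (equal scores form a single step), and the precision at each
#' step is weighted by the positives newly recalled there. Tie-robust and
#' invariant under strictly monotone transforms.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || sum(labels == 0L) == 0L)
    stop("AUPR requires both classes to be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)      # last index of each tie group
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  dtp <- diff(c(0, tp))
  sum(dtp * tp / n_at) / n_pos
}

#' Region-stratified AUROC/AUPR report
#'
#' One global row plus one row per non-coding region type in canonical
#' order, for each supplied score column. Regions where only one class is
#' present are reported with `NA` metrics and a warning rather than being
#' dropped, so region counts always sum to the global counts.
#'
#' @param scored data.frame with `label`, `region` and one or more score
#'   columns.
#' @param score_cols names of the score columns (default `"score"`).
#' @param setting label for the evaluation setting column (e.g.
#'   `"cross-validation"`, `"test"`, `"validation"`).
#' @return data.table with `setting`, `region`, `n_pathogenic`,
#'   `n_benign`, and `<col>_auroc` / `<col>_aupr` per score column.
#' @export
region_stratified_report <- function(scored, score_cols = "score",
                                     setting = "cross-validation") {
  dt <- as.data.table(scored)
  stopifnot(all(c("label", "region") %in% names(dt)),
            all(score_cols %in% names(dt)))
  one <- function(sub, region_name) {
    row <- data.table(setting = setting, region = region_name,
                      n_pathogenic = sum(sub$label == 1L),
                      n_benign = sum(sub$label == 0L))
    for (sc in score_cols) {
      ok <- row$n_pathogenic > 0L && row$n_benign > 0L
      if (!ok)
        warning("region ", region_name,
                ": single class present, metrics set to NA")
      row[, paste0(sc, "_auroc") := if (ok) auroc(sub$label, sub[[sc]])
                                     else NA_real_]
      row[, paste0(sc, "_aupr") := if (ok) aupr(sub$label, sub[[sc]])
                                    else NA_real_]
    }
    row
  }
  rows <- list(one(dt, "global"))
  for (r in region_types()) rows <- c(rows, list(one(dt[region == r], r)))
  rbindlist(rows)
}

#' Rank-sum (Mann-Whitney-Wilcoxon) test
#'
#' Exact p-value when both samples are small (combined n at most 12) and
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction. The two modes agree closely at the crossover size.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return list with `statistic` (Mann-Whitney U for x), `p.value`,
#'   `exact` (logical).
#' @export
ranksum_test <- function(x, y, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= 12L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = use_exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are discarded (standard convention) with a warning; if
#' all differences are zero the result is statistic 0, p-value 1. Exact
#' p-value when at most 12 non-zero differences with untied magnitudes;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param diffs numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` (differences tend
#'   positive) or `"less"`.
#' @return list with `statistic` (V, sum of positive ranks), `p.value`,
#'   `exact`, `n_used`.
#' @export
signed_rank_test <- function(diffs, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  nz <- diffs[diffs != 0]
  if (length(nz) < length(diffs))
    warning(length(diffs) - length(nz), " zero difference(s) discarded")
  if (!length(nz)) {
    warning("all differences zero; p = 1")
    return(list(statistic = 0, p.value = 1, exact = TRUE, n_used = 0L))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  use_exact <- !ties && length(nz) <= 12L
  wt <- suppressWarnings(
    wilcox.test(nz, alternative = alternative, mu = 0, exact = use_exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = use_exact, n_used = length(nz))
}

#' Per-gene region-bias analysis of common-variant scores
#'
#' The regulatory region a variant maps to systematically biases scores;
#' the reference comparison asks whether pathogenic variants still outrank
#' the most inflated benign background. For each `(gene, region)` with
#' common (unlabelled benign) variants, the median score is computed
#' (singleton gene-regions are kept but flagged). The per-gene medians of
#' the 5'UTR — the region with the strongest benign score inflation — are
#' then compared against the pathogenic scores of each region `r` with a
#' one-sided rank-sum test (alternative: pathogenic greater).
#'
#' @param common_scored data.table of scored common variants (`gene_id`,
#'   `region`, `score`).
#' @param pathogenic_scored data.table of scored pathogenic variants
#'   (`region`, `score`).
#' @param reference_region region whose per-gene common medians form the
#'   benign reference (default `"UTR5"`).
#' @return list with `gene_medians` (per gene-region median, `n`,
#'   `singleton` flag), `region_summary`, and `tests` (per region: n,
#'   median difference, one-sided p-value, direction).
#' @export
gene_region_bias <- function(common_scored, pathogenic_scored,
                             reference_region = "UTR5") {
  cs <- as.data.table(common_scored)
  ps <- as.data.table(pathogenic_scored)
  gm <- cs[, .(median_score = median(score), n = .N, singleton = .N < 2L),
           by = .(gene_id, region)]
  region_summary <- gm[, .(n_genes = .N,
                           median_of_medians = median(median_score)),
                       by = region]
  ref <- gm[region == reference_region, median_score]
  tests <- rbindlist(lapply(region_types(), function(r) {
    pr <- ps[region == r, score]
    if (!length(pr) || !length(ref))
      return(data.table(region = r, n_pathogenic = length(pr),
                        n_reference_genes = length(ref),
                        median_diff = NA_real_, p.value = NA_real_,
                        direction = NA_character_))
    tst <- ranksum_test(pr, ref, alternative = "greater")
    data.table(region = r, n_pathogenic = length(pr),
               n_reference_genes = length(ref),
               median_diff = median(pr) - median(ref),
               p.value = tst$p.value,
               direction = ifelse(median(pr) > median(ref),
                                  "pathogenic_greater", "reference_greater"))
  }))
  list(gene_medians = gm, region_summary = region_summary, tests = tests)
}

#' Within-individual rank percentile of an inserted score
#'
#' Midrank convention: `100 * (#below + ties/2) / (n + 1)` where `n` is the
#' background size (the inserted variant itself is excluded from the
#' background, hence the `+1` denominator). Monotone in the inserted score
#' and saturating strictly inside (0, 100). Set `naive = TRUE` for the
#' plain `100 * #below / n` form.
#'
#' @param background numeric vector of one individual's scores.
#' @param x inserted score(s).
#' @param naive use the naive convention.
#' @return percentile(s) in `[0, 100]`.
#' @export
spike_in_percentile <- function(background, x, naive = FALSE) {
  if (!length(background)) stop("empty background")
  vapply(x, function(xi) {
    below <- sum(background < xi); ties <- sum(background == xi)
    if (naive) 100 * below / length(background)
    else 100 * (below + ties / 2) / (length(background) + 1)
  }, numeric(1))
}

#' Simulated disease-genome spike-in ranking
#'
#' Emulates inserting each pathogenic variant — together with a random
#' common variant from the same region of the same gene — into each of N
#' healthy individuals' genomes, then asking where the inserted variants
#' rank within that individual's full distribution of non-coding variant
#' scores. For every (individual, insertion) pair the within-individual
#' percentile of the pathogenic and of the matched common score is
#' computed; the paired one-sided signed-rank test asks whether pathogenic
#' percentiles exceed their matched common percentiles.
#'
#' @param backgrounds list of numeric vectors, one per individual.
#' @param pathogenic_scores,common_scores equal-length vectors of inserted
#'   score pairs.
#' @return list of class `ncv_spikein`: `per_pair` table (individual,
#'   insertion, both percentiles), `median_pathogenic`, `median_common`,
#'   `p_pathogenic_vs_common`.
#' @export
spike_in_ranking <- function(backgrounds, pathogenic_scores,
                             common_scores) {
  stopifnot(length(pathogenic_scores) == length(common_scores),
            length(backgrounds) >= 1)
  rows <- vector("list", length(backgrounds))
  for (i in seq_along(backgrounds)) {
    bg <- backgrounds[[i]]
    rows[[i]] <- data.table(
      individual = i, insertion = seq_along(pathogenic_scores),
      pathogenic_pct = spike_in_percentile(bg, pathogenic_scores),
      common_pct = spike_in_percentile(bg, common_scores))
  }
  per_pair <- rbindlist(rows)
  tst <- signed_rank_test(per_pair$pathogenic_pct - per_pair$common_pct,
                          alternative = "greater")
  structure(list(per_pair = per_pair,
                 median_pathogenic = median(per_pair$pathogenic_pct),
                 median_common = median(per_pair$common_pct),
                 p_pathogenic_vs_common = tst$p.value),
            class = "ncv_spikein")
}

#' Compare the pathogenic spike-in percentiles of two methods
#'
#' One-sided paired signed-rank test that method A ranks the inserted
#' pathogenic variants higher (within individuals) than method B.
#'
#' @param result_a,result_b `ncv_spikein` results over the same
#'   (individual, insertion) grid.
#' @return list with `median_a`, `median_b`, `p.value`.
#' @export
compare_spike_in <- function(result_a, result_b) {
  a <- result_a$per_pair; b <- result_b$per_pair
  stopifnot(nrow(a) == nrow(b))
  tst <- signed_rank_test(a$pathogenic_pct - b$pathogenic_pct,
                          alternative = "greater")
  list(median_a = result_a$median_pathogenic,
       median_b = result_b$median_pathogenic, p.value = tst$p.value)
}

#' Splice-score added-value comparison
#'
#' For each protein-coding gene, the top-scoring splice position's raw
#' splice score and the model score at that position are converted to gene
#' rank percentiles across all genes (midrank ties; percentile of rank `r`
#' among `G` genes is `100 * r / (G + 1)`). Each column is compared between
#' disease and non-disease genes with a two-sided rank-sum test, and the
#' two columns are compared against each other with a two-sided paired
#' signed-rank test restricted to disease genes; direction is reported.
#'
#' @param splice_score,model_score numeric, one value per gene.
#' @param is_disease logical flag per gene.
#' @return list with `percentiles` (per-gene table), `disease_vs_other`
#'   (per column: p, medians), `model_vs_splice_in_disease` (paired p,
#'   direction).
#' @export
splice_added_value <- function(splice_score, model_score, is_disease) {
  G <- length(splice_score)
  stopifnot(length(model_score) == G, length(is_disease) == G)
  if (sum(is_disease) < 2L || sum(!is_disease) < 2L)
    stop("need at least 2 genes in each of the disease/non-disease groups")
  pct <- function(x) 100 * rank(x) / (G + 1)
  tab <- data.table(is_disease = is_disease,
                    splice_pct = pct(splice_score),
                    model_pct = pct(model_score))
  dvo <- rbindlist(lapply(c("splice_pct", "model_pct"), function(cl) {
    tst <- ranksum_test(tab[is_disease == TRUE][[cl]],
                        tab[is_disease == FALSE][[cl]],
                        alternative = "two.sided")
    data.table(column = cl, p.value = tst$p.value,
               median_disease = median(tab[is_disease == TRUE][[cl]]),
               median_other = median(tab[is_disease == FALSE][[cl]]))
  }))
  dd <- tab[is_disease == TRUE, model_pct - splice_pct]
  tst <- signed_rank_test(dd, alternative = "two.sided")
  list(percentiles = tab, disease_vs_other = dvo,
       model_vs_splice_in_disease = list(
         p.value = tst$p.value, statistic = tst$statistic,
         direction = if (median(dd) > 0) "model_higher"
                     else if (median(dd) < 0) "splice_higher" else "tied"))
}
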