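# --- metric tests -----------------------------------------------------------

test_that("AUROC matches its hand-checkable examples", {
  expect_equal(auroc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUPR matches its hand-checkable examples", {
  expect_equal(aupr(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  # worst ranking: one positive below three negatives
  expect_equal(aupr(c(0, 0, 0, 1), c(0.9, 0.8, 0.7, 0.1)), 0.25)
  expect_error(aupr(c(0, 0), c(0.2, 0.3)), "both classes")
})

test_that("AUROC and AUPR equal brute-force oracles on random instances with ties", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:200, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- if (rep %% 2) runif(n) else sample(seq(0, 1, 0.1), n, TRUE)
    expect_equal(auroc(labels, scores), auroc_oracle(labels, scores))
    expect_equal(aupr(labels, scores), aupr_oracle(labels, scores))
  }
})

test_that("AUROC and AUPR are invariant under strictly monotone score transforms", {
  set.seed(32)
  labels <- rbinom(100, 1, 0.3); labels[1:2] <- c(0, 1)
  scores <- rnorm(100)
  for (f in list(function(x) 3 * x + 2, function(x) exp(x),
                 function(x) atan(x))) {
    expect_equal(auroc(labels, f(scores)), auroc(labels, scores))
    expect_equal(aupr(labels, f(scores)), aupr(labels, scores))
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  labels <- rbinom(150, 1, 0.3); labels[1:2] <- c(0, 1)
  scores <- rnorm(150)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(labels, scores), ref)
})

# --- rank tests -------------------------------------------------------------

test_that("exact rank-sum p-values match full enumeration", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6), "less")$p.value, 1 / 20)
  set.seed(41)
  for (rep in 1:10) {
    x <- rnorm(sample(3:5, 1)); y <- rnorm(sample(3:6, 1))
    for (alt in c("two.sided", "greater", "less")) {
      got <- ranksum_test(x, y, alt)
      expect_true(got$exact)
      expect_equal(got$p.value, ranksum_oracle(x, y, alt), tolerance = 1e-10)
    }
  }
})

test_that("exact signed-rank p-values match sign-pattern enumeration", {
  expect_equal(signed_rank_test(c(1, 2, 3), "greater")$p.value, 1 / 8)
  set.seed(42)
  for (rep in 1:10) {
    d <- rnorm(sample(4:8, 1))
    for (alt in c("two.sided", "greater", "less")) {
      got <- signed_rank_test(d, alt)
      expect_true(got$exact)
      expect_equal(got$p.value, signed_rank_oracle(d, alt),
                   tolerance = 1e-10)
    }
  }
})

test_that("approximate and exact modes agree near the crossover size", {
  set.seed(43)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)   # combined n = 12: exact mode boundary
    exact_p <- ranksum_oracle(x, y, "two.sided")
    approx_p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact_p - approx_p), 0.01 + 0.02)  # stated tolerance band
    d <- rnorm(12)
    exact_s <- signed_rank_oracle(d, "two.sided")
    approx_s <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact_s - approx_s), 0.03)
  }
})

test_that("all-zero differences give statistic 0 and p = 1 with a warning", {
  expect_warning(
    expect_warning(res <- signed_rank_test(rep(0, 5), "greater"),
                   "discarded"),
    "all differences zero")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # symmetric two-sided input gives p = 1
  sym <- signed_rank_test(c(-2, -1, 1, 2), "two.sided")
  expect_equal(sym$p.value, 1.0, tolerance = 1e-9)
})

# --- report, spike-in, bias, splice value ----------------------------------

test_that("the region-stratified report decomposes consistently", {
  set.seed(51)
  n <- 600
  dt <- data.table::data.table(
    label = rbinom(n, 1, 0.2),
    region = sample(region_types(), n, replace = TRUE),
    score = runif(n))
  dt$label[1:2] <- c(0, 1)
  rep1 <- suppressWarnings(region_stratified_report(dt))
  expect_equal(rep1$region, c("global", region_types()))
  expect_equal(rep1$n_pathogenic[1], sum(rep1$n_pathogenic[-1]))
  expect_equal(rep1$n_benign[1], sum(rep1$n_benign[-1]))
  # report matches direct per-subset metric calls
  for (r in region_types()) {
    sub <- dt[dt$region == r]
    if (length(unique(sub$label)) == 2) {
      expect_equal(rep1[rep1$region == r]$score_auroc,
                   auroc(sub$label, sub$score))
      expect_equal(rep1[rep1$region == r]$score_aupr,
                   aupr(sub$label, sub$score))
    }
  }
  # restricted to one region, global equals that region's row
  intr <- dt[dt$region == "intronic"]
  rep2 <- suppressWarnings(region_stratified_report(intr))
  expect_equal(rep2[rep2$region == "global"]$score_auroc,
               rep2[rep2$region == "intronic"]$score_auroc)
  # extra score columns get their own metric columns
  dt$other <- runif(n)
  rep3 <- suppressWarnings(region_stratified_report(dt, c("score", "other")))
  expect_true(all(c("other_auroc", "other_aupr") %in% names(rep3)))
})

test_that("spike-in percentiles follow the midrank (n+1) convention and are monotone", {
  expect_equal(spike_in_percentile(c(0.1, 0.2, 0.3), 0.9), 75)
  expect_equal(spike_in_percentile(c(0.1, 0.2, 0.3), 0.05), 0)
  expect_equal(spike_in_percentile(c(0.1, 0.2, 0.3), 0.2), 100 * 1.5 / 4)
  expect_equal(spike_in_percentile(c(0.1, 0.2, 0.3), 0.9, naive = TRUE), 100)
  set.seed(52)
  bg <- runif(500)
  xs <- sort(runif(50))
  expect_false(is.unsorted(spike_in_percentile(bg, xs)))
  expect_error(spike_in_percentile(numeric(0), 1), "empty background")
})

test_that("spike-in ranking favors pathogenic over matched common insertions", {
  set.seed(53)
  backgrounds <- lapply(1:10, function(i) runif(2000))
  res <- spike_in_ranking(backgrounds,
                          pathogenic_scores = runif(30, 0.8, 1),
                          common_scores = runif(30, 0, 0.5))
  expect_gt(res$median_pathogenic, res$median_common)
  expect_lt(res$p_pathogenic_vs_common, 1e-10)
  expect_true(all(res$per_pair$pathogenic_pct >= 0 &
                  res$per_pair$pathogenic_pct <= 100))
  # identical methods: all paired differences zero -> p = 1
  cmp <- suppressWarnings(compare_spike_in(res, res))
  expect_equal(cmp$p.value, 1)
})

test_that("gene medians and bias direction are recovered", {
  # one gene, three common 5'UTR variants -> median 0.4
  cs <- data.table::data.table(gene_id = "G1", region = "UTR5",
                               score = c(0.2, 0.4, 0.9))
  ps <- data.table::data.table(region = "UTR5", score = 0.99)
  out <- gene_region_bias(cs, ps)
  expect_equal(out$gene_medians$median_score, 0.4)
  expect_true(out$gene_medians$singleton == FALSE)

  # pathogenic scores exceed the inflated 5'UTR benign background
  set.seed(54)
  genes <- paste0("G", 1:40)
  cs2 <- data.table::rbindlist(lapply(genes, function(g)
    data.table::data.table(
      gene_id = g, region = sample(region_types(), 4, replace = TRUE),
      score = runif(4, 0.1, 0.4))))
  cs2[region == "UTR5", score := score + 0.2]  # injected benign inflation
  ps2 <- data.table::data.table(
    region = sample(region_types(), 60, replace = TRUE),
    score = runif(60, 0.75, 1))
  out2 <- gene_region_bias(cs2, ps2)
  expect_true(all(out2$tests$direction == "pathogenic_greater"))
  expect_true(all(out2$tests$p.value < 0.01))
  umed <- out2$region_summary[region == "UTR5", median_of_medians]
  expect_true(all(out2$region_summary[region != "UTR5",
                                      median_of_medians] < umed))
})

test_that("splice added-value percentiles and paired comparison behave", {
  # percentile of the top-ranked gene among G = 4 genes is 100 * 4 / 5
  sv <- splice_added_value(c(0.1, 0.2, 0.3, 0.9), c(0.4, 0.3, 0.2, 0.1),
                           c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(max(sv$percentiles$splice_pct), 80)
  # identical columns: paired statistic degenerates, p = 1
  x <- c(0.1, 0.5, 0.9, 0.3, 0.7, 0.2)
  same <- suppressWarnings(
    splice_added_value(x, x, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_equal(same$model_vs_splice_in_disease$p.value, 1)
  expect_equal(same$model_vs_splice_in_disease$direction, "tied")
  # a disease-only boost on the model column is detected with direction
  set.seed(55)
  G <- 120
  dis <- rep(c(TRUE, FALSE), c(40, 80))
  splice <- runif(G)
  model <- splice + ifelse(dis, 0.8, 0)
  out <- suppressWarnings(splice_added_value(splice, model, dis))
  expect_lt(out$model_vs_splice_in_disease$p.value, 1e-5)
  expect_equal(out$model_vs_splice_in_disease$direction, "model_higher")
  expect_lt(out$disease_vs_other[column == "model_pct"]$p.value, 1e-5)
  expect_error(splice_added_value(1:3, 1:3, c(TRUE, FALSE, FALSE)),
               "at least 2 genes")
})
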