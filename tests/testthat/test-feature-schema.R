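test_that("the default schema has 58 features, 26 new, across four categories", {
  sch <- default_schema()
  expect_equal(nrow(sch), 58L)
  expect_equal(sum(sch$new_in_v2), 26L)
  expect_false(anyDuplicated(sch$name) > 0)
  cats <- table(sch$category)
  expect_setequal(names(cats),
                  c("interspecies_conservation", "human_constraint",
                    "gene_level", "sequence_context"))
  # the named slots the category structure requires
  expect_true("loeuf" %in% sch$name)
  expect_equal(sum(grepl("^constraint_z_", sch$name)), 10L)  # 9 subpops + global
  expect_true(all(c("gc_content", "cpg_content", "spliceai_variant_max",
                    "spliceai_position_max") %in% sch$name))
  expect_equal(sum(grepl("^region_", sch$name)), 6L)
  # order-stable across instantiations
  expect_identical(sch$name, default_schema()$name)
})

test_that("schemas round-trip through YAML bit-identically", {
  sch <- default_schema()
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, tf)
  back <- read_schema(tf)
  expect_equal(as.data.frame(back), as.data.frame(sch))
  expect_identical(attr(back, "version"), attr(sch, "version"))
})

test_that("splice delta maxima collapse correctly at variant and position level", {
  one <- spliceai_max_features(list(G = c(0.1, 0.7, 0.0, 0.2)), "G")
  expect_equal(unname(one), c(0.7, 0.7))
  multi <- spliceai_max_features(
    list(A = c(0.7, 0, 0, 0), C = c(0.3, 0.1, 0, 0), G = c(0.9, 0, 0, 0)),
    "C")
  expect_equal(unname(multi), c(0.3, 0.9))
  zero <- spliceai_max_features(list(T = rep(0, 4)), "T")
  expect_equal(unname(zero), c(0, 0))
  missing <- spliceai_max_features(list(A = rep(0.5, 4)), "G")
  expect_true(all(is.na(missing)))
})

test_that("GC and CpG content count bases and dinucleotides correctly", {
  expect_equal(unname(gc_cpg_content("CGCGC")), c(1.0, 0.5))
  expect_equal(unname(gc_cpg_content("ATATA")), c(0.0, 0.0))
  expect_equal(unname(gc_cpg_content("ACGTN"))[1], 2 / 4)  # N excluded
  # truncated window: denominators adjust to the actual length
  expect_equal(unname(gc_cpg_content("CG")), c(1.0, 1.0))
  expect_error(gc_cpg_content("ACGU"), "\\{A,C,G,T,N\\}")
})

test_that("CpG content is invariant under reverse complement", {
  revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  set.seed(12)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 51, replace = TRUE),
               collapse = "")
    expect_equal(gc_cpg_content(s)[["cpg_fraction"]],
                 gc_cpg_content(revcomp(s))[["cpg_fraction"]])
    expect_equal(gc_cpg_content(s)[["gc_fraction"]],
                 gc_cpg_content(revcomp(s))[["gc_fraction"]])
  }
})

test_that("annotation fills declared features and leaves the rest missing", {
  sch <- default_schema()
  v <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "G")
  ten <- sch$name[1:10]
  src <- annotation_source(ten, function(chrom, pos, ref, alt) {
    as.data.frame(setNames(lapply(seq_along(ten), function(i) pos + i),
                           ten))
  }, name = "ten")
  out <- annotate(v, list(src), sch)
  expect_equal(sum(is.na(as.matrix(out[1, sch$name, with = FALSE]))), 48L)
  expect_equal(out[[sch$name[1]]], c(101, 201))
})

test_that("conflicting and undeclared sources are configuration errors", {
  sch <- default_schema()
  v <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G")
  s1 <- annotation_source("loeuf", function(...) data.frame(loeuf = 0.1))
  s2 <- annotation_source(c("loeuf", "pli"),
                          function(...) data.frame(loeuf = 0.2, pli = 1))
  expect_error(annotate(v, list(s1, s2), sch), "more than one source")
  s3 <- annotation_source("not_a_feature", function(...)
    data.frame(not_a_feature = 1))
  expect_error(annotate(v, list(s3), sch), "absent from schema")
  s4 <- annotation_source("loeuf", function(...)
    data.frame(loeuf = 0.1, pli = 1))
  expect_error(annotate(v, list(s4), sch), "undeclared")
})

test_that("a failing source leaves its features missing with a warning, and annotation is idempotent", {
  sch <- default_schema()
  v <- data.frame(chrom = "chr1", pos = c(5, 6), ref = "A", alt = "G")
  boom <- annotation_source("loeuf", function(...) stop("io error"), "boom")
  ok <- annotation_source("pli", function(chrom, pos, ...)
    data.frame(pli = rep(0.9, length(pos))), "ok")
  expect_warning(out <- annotate(v, list(boom, ok), sch), "failed")
  expect_true(all(is.na(out$loeuf)))
  expect_equal(out$pli, c(0.9, 0.9))
  # order-independence over variants
  out_rev <- suppressWarnings(annotate(v[2:1, ], list(boom, ok), sch))
  expect_equal(out_rev$pli, c(0.9, 0.9))
  expect_equal(out_rev$pos, c(6, 5))
})

test_that("a table-backed source achieves full coverage with zero missing", {
  sch <- default_schema()
  v <- data.frame(chrom = "chr1", pos = c(10, 20), ref = c("A", "C"),
                  alt = c("G", "T"))
  ft <- cbind(v, as.data.frame(setNames(
    lapply(sch$name, function(n) stats::runif(2)), sch$name)))
  src <- table_annotation_source(ft)
  out <- annotate(v, list(src), sch)
  expect_equal(sum(is.na(as.matrix(out[, sch$name, with = FALSE]))), 0L)
  expect_equal(out$loeuf, ft$loeuf)
})
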