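test_that("positions around a plus-strand gene get the expected region types", {
  g <- toy_gene("+")
  cases <- list(
    list(950, "upstream"), list(1050, "UTR5"), list(1500, "intronic"),
    list(1950, "UTR3"), list(2100, "downstream"), list(1150, "coding"),
    list(1250, "intronic"),   # between exon1 end and exon2 start
    list(3100, "intergenic")) # beyond downstream window, within cap
  for (cs in cases) {
    res <- suppressMessages(classify_region(snv_at(cs[[1]]), g))
    expect_equal(res$region, cs[[2]], info = paste("pos", cs[[1]]))
  }
  inside <- suppressMessages(classify_region(snv_at(1500), g))
  expect_equal(inside$distance_to_gene, 0)
  up <- suppressMessages(classify_region(snv_at(950), g))
  expect_equal(up$distance_to_gene, 50)
})

test_that("minus strand mirrors upstream/downstream and UTR5/UTR3", {
  g <- toy_gene("-")
  expect_equal(suppressMessages(classify_region(snv_at(2100), g))$region,
               "upstream")
  expect_equal(suppressMessages(classify_region(snv_at(1950), g))$region,
               "UTR5")
  expect_equal(suppressMessages(classify_region(snv_at(1050), g))$region,
               "UTR3")
  expect_equal(suppressMessages(classify_region(snv_at(950), g))$region,
               "downstream")
  expect_equal(suppressMessages(classify_region(snv_at(1500), g))$region,
               "intronic")
})

test_that("strand flip on symmetric geometry swaps 5' and 3' labels, fixing intronic and coding", {
  # the toy gene's geometry is symmetric about position 1500, so flipping
  # only the strand must exchange upstream<->downstream and UTR5<->UTR3
  gp <- toy_gene("+"); gm <- toy_gene("-")
  pts <- c(20, 500, 950, 1050, 1150, 1250, 1500, 1850, 1950, 2100, 2600, 2990)
  swap <- c(upstream = "downstream", downstream = "upstream",
            UTR5 = "UTR3", UTR3 = "UTR5", intronic = "intronic",
            coding = "coding", intergenic = "intergenic",
            unscorable = "unscorable")
  a <- suppressMessages(classify_region(snv_at(pts), gp))
  b <- suppressMessages(classify_region(snv_at(pts), gm))
  expect_equal(unname(swap[a$region]), b$region)
})

test_that("every position near a single gene gets exactly one region type, tiling the line", {
  g <- toy_gene("+")
  pos <- 1:3200
  res <- suppressMessages(classify_region(snv_at(pos), g))
  expect_equal(nrow(res), length(pos))
  expect_false(anyNA(res$region))
  # regions are adjacent and non-overlapping, changing exactly at the
  # geometric boundaries
  expected <- rep("intergenic", 3200)
  expected[1:999] <- "upstream"       # within 1 kb of the tx start
  expected[1000:1099] <- "UTR5"
  expected[1100:1200] <- "coding"     # exon 1 within the CDS span
  expected[1201:1799] <- "intronic"
  expected[1800:1900] <- "coding"     # exon 2 within the CDS span
  expected[1901:2000] <- "UTR3"
  expected[2001:3000] <- "downstream"
  expect_equal(res$region, expected)
  # determinism
  res2 <- suppressMessages(classify_region(snv_at(pos), g))
  expect_identical(res, res2)
})

test_that("overlap precedence and tie-breaking are deterministic", {
  g2 <- rbind(toy_gene("+", "A"), toy_gene("+", "B"))
  g2$tx_start[2] <- 6000; g2$tx_end[2] <- 7000
  g2$cds_start[2] <- 6100; g2$cds_end[2] <- 6900
  g2$exons[[2]] <- cbind(start = c(6000, 6800), end = c(6200, 7000))
  gm <- ncvscore:::new_gene_model_table(g2)
  # equidistant intergenic position: 2000 bp from both spans -> lexicographic
  tie <- suppressMessages(classify_region(snv_at(4000), gm))
  expect_equal(tie$gene_id, "A")
  expect_equal(tie$region, "intergenic")
  # genic beats upstream: 1950 is UTR3 of A; also within 10 kb of B
  both <- suppressMessages(classify_region(snv_at(5500), gm))
  expect_equal(both$region, "upstream")  # B's upstream beats A's intergenic
  expect_equal(both$gene_id, "B")
})

test_that("unknown chromosomes become unscorable, not errors", {
  res <- suppressMessages(classify_region(snv_at(100, chrom = "chrZ"),
                                          toy_gene()))
  expect_equal(res$region, "unscorable")
  expect_true(is.na(res$gene_id))
})

test_that("non-SNV input is rejected", {
  v <- data.frame(chrom = "chr1", pos = 1500, ref = "AT", alt = "A")
  expect_error(classify_region(v, toy_gene()), "SNV")
})

test_that("gene model TSV round-trips and invariants are enforced", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  g <- rbind(toy_gene("+", "A"), toy_gene("-", "B", chrom = "chr2"))
  g$is_disease_gene[1] <- TRUE
  write_gene_models(ncvscore:::new_gene_model_table(data.table::copy(g)), tf)
  back <- load_gene_models(tf)
  expect_equal(as.data.frame(back)[, c("gene_id", "chrom", "strand",
                                       "tx_start", "tx_end")],
               as.data.frame(g[order(g$chrom), ])[, c("gene_id", "chrom",
                                                      "strand", "tx_start",
                                                      "tx_end")])
  expect_true(back$is_disease_gene[back$gene_id == "A"])

  bad <- toy_gene()
  bad$exons[[1]] <- cbind(start = c(900, 1800), end = c(1200, 2000))
  expect_error(validate_gene_models(bad), "outside transcript span")
  bad2 <- toy_gene(); bad2$cds_start <- 50
  expect_error(validate_gene_models(bad2), "tx_start <= cds_start")
})

test_that("malformed TSV coordinates name the offending line", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttx_start\ttx_end\tcds_start\tcds_end\texons",
               "G1\tchr1\t+\t2000\t1000\t1100\t1900\t1000-1200,1800-2000"),
             tf)
  expect_error(load_gene_models(tf), "line")
})

test_that("GTF reader keeps coding transcripts and skips non-coding ones", {
  skip_if_not_installed("rtracklayer")
  tf <- withr::local_tempfile(fileext = ".gtf")
  gtf <- c(
    'chr1\tsrc\ttranscript\t1000\t2000\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chr1\tsrc\texon\t1800\t2000\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chr1\tsrc\tCDS\t1100\t1900\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chr1\tsrc\ttranscript\t5000\t6000\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1";',
    'chr1\tsrc\texon\t5000\t6000\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1";')
  writeLines(gtf, tf)
  expect_message(models <- load_gene_models(tf, "gtf"), "skipped 1")
  df <- as.data.frame(models)
  expect_equal(nrow(df), 1L)
  expect_equal(df$gene_id, "GA")
  expect_equal(df$cds_start, 1100)
  expect_equal(nrow(df$exons[[1]]), 2L)
})
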