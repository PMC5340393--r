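test_that("GTF transcripts are parsed with correct CDS projection", {
  gtf <- c(
    'chr1\tx\texon\t101\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\tCDS\t201\t500\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t1\t100\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tx\texon\t201\t300\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'
  )
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  models <- load_annotation(path)

  t1 <- get_model(models, "t1")
  expect_equal(t1$tx_len, 500)
  expect_equal(t1$cds_tx_start, 100)
  expect_equal(t1$cds_tx_end, 400)

  # minus strand: transcript position 0 is the rightmost genomic base
  t2 <- get_model(models, "t2")
  expect_equal(t2$tx_len, 200)
  expect_equal(genomic_to_tx(t2, 299L), 0L)
  expect_equal(tx_to_genomic(t2, 0L), 299L)
  expect_equal(genomic_to_tx(t2, 0L), 199L)
})

test_that("malformed GTF lines raise errors naming the line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tbroken line"), path)
  expect_error(load_annotation(path), "line 2")

  writeLines(c(
    'chr1\tx\texon\tabc\t600\t.\t+\t.\tgene_id "g"; transcript_id "t";'),
    path)
  expect_error(load_annotation(path), "line 1.*non-numeric")

  writeLines(c(
    'chr1\tx\texon\t101\t600\t.\t+\t.\tfoo "bar";'), path)
  expect_error(load_annotation(path), "gene_id")
})

test_that("transcripts without exon records are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\tCDS\t201\t500\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'),
    path)
  expect_warning(models <- load_annotation(path), "zero exons")
  expect_equal(models$transcripts$transcript_id, "t1")
})

test_that("coordinate projection round-trips on random multi-exon models", {
  set.seed(41)
  models <- random_models(50)
  for (i in seq_len(50)) {
    m <- get_model(models, i)
    bases <- oracle_tx_bases(m)
    tp <- seq_len(m$tx_len) - 1L
    expect_identical(tx_to_genomic(m, tp), bases)
    expect_identical(genomic_to_tx(m, bases), tp)
    # round trip both ways
    expect_identical(genomic_to_tx(m, tx_to_genomic(m, tp)), tp)
  }
})

test_that("locate classifies exonic, intronic and outside positions", {
  set.seed(42)
  models <- random_models(5)
  m <- get_model(models, 1)
  ex0 <- m$exons$start[1]
  loc <- locate(m, c(ex0, max(m$exons$end) + 50L))
  expect_equal(loc$status[2], "outside")
  expect_equal(loc$status[1], "exonic")
  if (nrow(m$exons) > 1) {
    intron_pos <- m$exons$end[1]  # first base after exon 1
    expect_equal(locate(m, intron_pos)$status, "intronic")
  }
  expect_equal(locate(m, ex0, chrom = "other")$status, "outside")
})

test_that("five-segment partition follows the clipping rules", {
  # 5'UTR 300, CDS 2400, 3'UTR 300
  models <- random_models(1)
  models$transcripts$tx_len <- 3000L
  models$exons[[1]] <- data.frame(start = 0L, end = 3000L)
  models$transcripts$cds_tx_start <- 300L
  models$transcripts$cds_tx_end <- 2700L
  p <- build_partition(get_model(models, 1))
  expect_equal(p$tx_start, c(0, 200, 300, 2500, 2900))
  expect_equal(p$tx_end, c(200, 300, 2500, 2900, 3000))

  # short 5'UTR: TSS clipped to it, UTR5 empty
  models$transcripts$cds_tx_start <- 150L
  p <- build_partition(get_model(models, 1))
  expect_equal(p$tx_end[p$label == "TSS"], 150)
  expect_equal(p$tx_start[p$label == "UTR5"],
               p$tx_end[p$label == "UTR5"])
})

test_that("partitions are disjoint, exhaustive and match the per-base oracle", {
  set.seed(43)
  models <- random_models(200)
  for (i in seq_len(200)) {
    m <- get_model(models, i)
    p <- build_partition(m)
    expect_equal(sum(p$tx_end - p$tx_start), m$tx_len)
    lab <- segment_of(p, 0:(m$tx_len - 1L))
    expect_false(anyNA(lab))  # exhaustive
    expect_identical(lab, oracle_segment_labels(m))
  }
})

test_that("non-coding transcripts are rejected from partitioning", {
  models <- random_models(2, cds = FALSE)
  expect_error(build_partition(get_model(models, 1)), "non-coding")
})

test_that("segment length table fractions sum to one and scale-invariant", {
  set.seed(44)
  m1 <- random_models(20)
  parts <- build_partitions(m1)
  tab <- segment_length_table(parts)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(sum(tab$length),
               sum(m1$transcripts$tx_len))
  # duplicating every partition leaves fractions unchanged
  tab2 <- segment_length_table(c(parts, parts))
  expect_equal(tab2$fraction, tab$fraction)
  expect_error(segment_length_table(list()), "empty")
})

test_that("strand flip preserves transcript-space partitions", {
  set.seed(45)
  models <- random_models(10)
  for (i in seq_len(10)) {
    p1 <- build_partition(get_model(models, i))
    flipped <- models
    flipped$transcripts$strand <- ifelse(
      flipped$transcripts$strand == "+", "-", "+")
    p2 <- build_partition(get_model(flipped, i))
    expect_equal(p1$tx_start, p2$tx_start)
    expect_equal(p1$tx_end, p2$tx_end)
  }
})
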