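test_that("the 50% fragment counting rule behaves at its boundaries", {
  # overlap = half the fragment
  expect_true(fragment_hits_peak(100, 200, 150, 400))
  # overlap = all peak bases
  expect_true(fragment_hits_peak(0, 1000, 400, 500))
  # 10% of fragment, 10/310 of peak
  expect_false(fragment_hits_peak(0, 100, 90, 400))
  expect_false(fragment_hits_peak(0, 100, 40, 140, "c1", "c2"))
})

test_that("fragment counting matches the brute-force double loop", {
  set.seed(61)
  libs <- c("L1", "L2")
  for (case in 1:5) {
    st <- sample.int(50000L, 2000, replace = TRUE)
    frags <- data.frame(chrom = sample(c("c1", "c2"), 2000, replace = TRUE),
                        start = st,
                        end = st + sample(80:400, 2000, replace = TRUE),
                        library = sample(libs, 2000, replace = TRUE),
                        stringsAsFactors = FALSE)
    ps <- sample.int(50000L, 50)
    peaks <- data.frame(peak_id = paste0("p", 1:50),
                        chrom = sample(c("c1", "c2"), 50, replace = TRUE),
                        start = ps,
                        end = ps + sample(100:500, 50, replace = TRUE),
                        stringsAsFactors = FALSE)
    got <- count_fragments(frags, peaks, libs)
    expect_identical(unclass(got)[, ],
                     brute_count_matrix(frags, peaks, libs)[, ])
  }
})

test_that("a fragment overlapping two peaks increments both", {
  frags <- data.frame(chrom = "c1", start = 100, end = 200, library = "L1")
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = "c1",
                      start = c(50, 140), end = c(160, 260))
  m <- count_fragments(frags, peaks)
  expect_equal(as.vector(m), c(1L, 1L))
  # empty library in the declared universe is an error
  expect_error(count_fragments(frags, peaks, c("L1", "L2")),
               "empty library: L2")
})

test_that("enrichment arithmetic, identity and scale invariance", {
  counts <- matrix(c(10L, 5L), 1, 2,
                   dimnames = list("p1", c("ip1", "in1")))
  design <- library_design(c("ip1", "in1"), "s", 1,
                           c("IP", "input"), c(1e6, 1e6))
  # with no pseudocount the ratio is exactly 2
  e0 <- peak_enrichment(counts, design, pseudocount_fpm = 0)
  expect_equal(unname(e0$stage_log2[1, 1]), 1)
  # the default 0.25-FPM pseudocount barely perturbs well-covered peaks
  e1 <- peak_enrichment(counts, design)
  expect_equal(2^e1$stage_log2[1, 1], 2, tolerance = 0.05)

  # equal IP and input FPM -> log2 enrichment exactly 0 (eps symmetric)
  eq <- matrix(c(7L, 7L), 1, 2, dimnames = list("p", c("ip1", "in1")))
  expect_equal(unname(peak_enrichment(eq, design)$stage_log2[1, 1]), 0)

  # doubling counts and library sizes jointly changes nothing
  design2 <- library_design(c("ip1", "in1"), "s", 1,
                            c("IP", "input"), c(2e6, 2e6))
  e2 <- peak_enrichment(counts * 2L, design2)
  expect_equal(e1$stage_log2, e2$stage_log2)

  # missing input partner
  bad <- library_design("ip1", "s", 1, "IP", 1e6)
  expect_error(peak_enrichment(counts[, 1, drop = FALSE], bad), "partner")
})

test_that("FPKM follows count / (kb * million mapped) with expressed flag", {
  counts <- matrix(c(100L, 0L), 2, 1,
                   dimnames = list(c("g1", "g2"), "in1"))
  design <- library_design("in1", "s", 1, "input", 1e6)
  res <- gene_fpkm(counts, c(g1 = 1000, g2 = 500), design)
  expect_equal(unname(res$stage_fpkm["g1", 1]), 100)
  expect_equal(unname(res$stage_fpkm["g2", 1]), 0)
  expect_false(res$expressed["g2", 1])
  expect_true(res$expressed["g1", 1])
  expect_error(gene_fpkm(counts, c(g1 = 1000, g2 = 0), design),
               "zero-length")
})

test_that("gene counting from fragments matches overlap enumeration", {
  set.seed(62)
  models <- random_models(8)
  tx <- models$transcripts
  frag_rows <- list()
  for (i in seq_len(8)) {
    m <- get_model(models, i)
    n <- sample(3:10, 1)
    t0 <- sample.int(max(1, m$tx_len - 50L), n, replace = TRUE) - 1L
    g <- vapply(t0, function(t) tx_to_genomic(m, t), integer(1))
    frag_rows[[i]] <- data.frame(chrom = "chr1", start = g, end = g + 40L,
                                 library = "L1", stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frag_rows)
  got <- gene_counts_from_fragments(frags, models, "L1")
  # brute force: fragment -> set of genes with >= 1 bp exon overlap
  expected <- stats::setNames(integer(nrow(tx)), sort(tx$gene_id))
  for (k in seq_len(nrow(frags))) {
    hit_genes <- character(0)
    for (i in seq_len(nrow(tx))) {
      e <- models$exons[[tx$transcript_id[i]]]
      if (any(pmin(frags$end[k], e$end) > pmax(frags$start[k], e$start))) {
        hit_genes <- c(hit_genes, tx$gene_id[i])
      }
    }
    if (length(unique(hit_genes)) == 1L) {
      expected[hit_genes[1]] <- expected[hit_genes[1]] + 1L
    }
  }
  expect_equal(got[, "L1"], expected)
})

test_that("a planted 4x IP excess is recovered as log2 ~ 2", {
  set.seed(63)
  n_rep <- 3
  libs <- c(paste0("ip", 1:n_rep), paste0("in", 1:n_rep))
  design <- library_design(libs, "s", rep(1:n_rep, 2),
                           rep(c("IP", "input"), each = n_rep), 1e6)
  counts <- cbind(
    matrix(rnbinom(50 * n_rep, mu = 400, size = 10), 50, n_rep),
    matrix(rnbinom(50 * n_rep, mu = 100, size = 10), 50, n_rep))
  dimnames(counts) <- list(paste0("p", 1:50), libs)
  e <- peak_enrichment(counts, design)
  expect_equal(mean(e$stage_log2[, 1]), 2, tolerance = 0.5)
})
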