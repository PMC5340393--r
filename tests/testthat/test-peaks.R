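test_that("narrowPeak I/O round-trips and applies the summit rules", {
  df <- data.frame(chrom = c("c1", "c1"), start = c(100L, 500L),
                   end = c(300L, 700L), name = c("a", "b"),
                   score = c(10, 20), strand = ".",
                   signal = c(1.5, 2.5), pvalue = -1, qvalue = -1,
                   summit_offset = c(50L, -1L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(df, path)
  suppressMessages(back <- read_narrowpeak(path, stage = "s", replicate = 1))
  expect_equal(back$summit[1], 150)        # start + offset
  expect_equal(back$summit[2], 600)        # midpoint fallback for -1
  expect_equal(back[names(df)], df)

  # malformed: < 10 columns
  writeLines("c1\t1\t10\tx\t0\t.", path)
  expect_error(read_narrowpeak(path), "10 columns")

  # end <= start records are rejected with a warning
  writeLines(c("c1\t100\t100\tx\t0\t.\t1\t-1\t-1\t5",
               "c1\t100\t200\ty\t0\t.\t1\t-1\t-1\t5"), path)
  expect_warning(ok <- read_narrowpeak(path), "rejected")
  expect_equal(nrow(ok), 1)
})

test_that("overlap fraction is relative to the shorter interval", {
  expect_equal(overlap_fraction(0, 100, 50, 150), 0.5)
  expect_equal(overlap_fraction(10, 60, 10, 60), 1.0)
  expect_equal(overlap_fraction(0, 100, 90, 400), 0.1)
  expect_equal(overlap_fraction(0, 100, 200, 300), 0)
  expect_equal(overlap_fraction(0, 100, 0, 100, "c1", "c2"), 0)
})

test_that("replicate merging keeps only multi-replicate components", {
  pk <- data.frame(chrom = "c1",
                   start = c(100, 100, 100, 900),
                   end = c(300, 300, 300, 1100),
                   name = c("a", "a", "a", "b"),
                   summit = c(200, 200, 200, 1000),
                   score = c(5, 9, 7, 3),
                   stage = "s1",
                   replicate = c(1, 2, 3, 1), stringsAsFactors = FALSE)
  cons <- merge_replicates(pk)
  expect_equal(nrow(cons), 1)            # singleton in rep 1 dropped
  expect_equal(cons$support, 3)
  expect_equal(cons$summit, 200)         # summit of top-scoring member
  expect_equal(cons$name, "a")
  expect_error(merge_replicates(pk[pk$replicate == 1, ]), ">=2 replicates")
})

test_that("merging matches the all-pairs union-find oracle", {
  set.seed(51)
  for (case in 1:8) {
    pk <- random_replicate_peaks(n_per_rep = 40)
    cons <- merge_replicates(pk)
    got <- sort(paste0(cons$chrom, ":", cons$start, "-", cons$end))
    expect_identical(got, brute_consensus(pk))
  }
})

test_that("merging is idempotent and invariant to replicate relabeling", {
  set.seed(52)
  pk <- random_replicate_peaks(n_per_rep = 60)
  cons <- merge_replicates(pk)

  # re-merging the consensus set (presented as two identical replicates)
  # reproduces the same intervals
  again <- rbind(
    transform(cons[, c("chrom", "start", "end", "summit", "score")],
              stage = "s", replicate = 1),
    transform(cons[, c("chrom", "start", "end", "summit", "score")],
              stage = "s", replicate = 2))
  cons2 <- merge_replicates(again)
  expect_equal(cons2[, c("chrom", "start", "end")],
               cons[, c("chrom", "start", "end")],
               ignore_attr = TRUE)

  # permuting replicate labels and row order changes nothing
  relabel <- pk
  relabel$replicate <- c(3, 1, 2)[relabel$replicate]
  relabel <- relabel[sample.int(nrow(relabel)), ]
  cons3 <- merge_replicates(relabel)
  expect_equal(cons3[, c("chrom", "start", "end", "summit")],
               cons[, c("chrom", "start", "end", "summit")],
               ignore_attr = TRUE)

  expect_true(all(cons$support >= 2))
})

test_that("cross-stage overlap produces conserved venn counts", {
  mk <- function(starts, stage) {
    data.frame(peak_id = paste0(stage, "_", seq_along(starts)),
               chrom = "c1", start = starts, end = starts + 200,
               stringsAsFactors = FALSE)
  }
  # same peak everywhere -> one triple-region entity
  same <- list(a = mk(100, "a"), b = mk(110, "b"), c = mk(90, "c"))
  v <- cross_stage_overlap(same)
  expect_equal(v$regions$count[v$regions$region == "a&b&c"], 1)
  expect_equal(sum(v$regions$count), nrow(v$entities))

  # disjoint peaks -> all singleton regions
  disj <- list(a = mk(100, "a"), b = mk(5000, "b"), c = mk(9000, "c"))
  v2 <- cross_stage_overlap(disj)
  expect_equal(sum(v2$regions$count[v2$regions$region %in%
                                      c("a", "b", "c")]), 3)
  expect_equal(sum(v2$regions$count), 3)
  expect_error(cross_stage_overlap(same["a"]), ">=2 stages")
})

test_that("venn regions match the brute-force closure oracle", {
  set.seed(53)
  for (case in 1:6) {
    sets <- lapply(c(a = "a", b = "b", c = "c"), function(s) {
      st <- sample.int(8000L, 30)
      data.frame(peak_id = paste0(s, "_", 1:30), chrom = "c1",
                 start = st, end = st + sample(80:250, 30, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    v <- cross_stage_overlap(sets)
    pooled <- do.call(rbind, lapply(names(sets), function(s) {
      cbind(sets[[s]], stage = s)
    }))
    expect_identical(sort(v$regions$count[v$regions$count > 0]),
                     as.integer(brute_venn(pooled)))
  }
})

test_that("peaks are assigned to genes by summit with deterministic ties", {
  set.seed(54)
  models <- random_models(5)
  m <- get_model(models, 2)
  inside <- tx_to_genomic(m, m$tx_len %/% 2L)
  far <- max(models$exons[[5]]$end) + 10000L
  cons <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                     chrom = "chr1",
                     summit = c(inside, far, inside + 1L, inside),
                     stringsAsFactors = FALSE)
  res <- assign_genes(cons, models)
  expect_equal(res$assignment$gene_id[1], m$gene_id)
  expect_equal(res$assignment$gene_id[2], "intergenic")
  # gene 2 carries three assigned peaks -> histogram bin "3"
  expect_equal(unname(res$histogram["3"]), 1L)
  expect_equal(res$frac_le2, 0)
})
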