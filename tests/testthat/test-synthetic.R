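# small config shared by the generator tests (kept fast; the acceptance
# suite exercises the full default scale)
small_cfg <- function(seed = 5, n_hmle = 2, ...) {
  synthetic_config(seed = seed, n_genes = 60, genes_per_chrom = 30,
                   n_hmle = n_hmle, ...)
}

test_that("identical seed and config give byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_synthetic(small_cfg(), d1)
  generate_synthetic(small_cfg(), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_synthetic(small_cfg(seed = 6), d3)
  expect_false(identical(tools::md5sum(file.path(d1, "truth_peaks.tsv")),
                         tools::md5sum(file.path(d3, "truth_peaks.tsv"))))
})

test_that("every emitted file round-trips through its reader", {
  d <- withr::local_tempdir()
  out <- generate_synthetic(small_cfg(), d)
  models <- load_annotation(out$paths$gtf)
  expect_equal(nrow(models$transcripts), 60)
  expect_true(all(!is.na(models$transcripts$cds_tx_start)))
  # generated annotation equals the in-memory models used for planting
  expect_equal(models$transcripts$tx_len, out$models$transcripts$tx_len)
  expect_equal(models$transcripts$cds_tx_start,
               out$models$transcripts$cds_tx_start)

  genome <- Biostrings::readDNAStringSet(out$paths$genome)
  expect_equal(length(genome), 2L)

  pk <- read_narrowpeak(out$paths$narrowpeak[1], "newborn", 1)
  expect_true(all(pk$start < pk$end))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))

  counts <- read_count_matrix(out$paths$peak_counts)
  expect_identical(rownames(counts), out$truth_peaks$peak_id)
  expect_equal(ncol(counts), 18)
  gcounts <- read_count_matrix(out$paths$gene_counts)
  expect_identical(rownames(gcounts), out$truth_genes$gene_id)
})

test_that("planted RRACH sites sit at true summits on a clean background", {
  d <- withr::local_tempdir()
  out <- generate_synthetic(small_cfg(), d)
  genome <- Biostrings::readDNAStringSet(out$paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  tp <- out$truth_peaks
  strand <- tp$strand
  st <- peak_motif_stats(data.frame(peak_id = tp$peak_id,
                                    chrom = tp$chrom, summit = tp$summit),
                         genome, strand = strand, window = 101)
  with_hit <- unique(st$hits$peak_id)
  expect_setequal(with_hit, tp$peak_id[tp$motif_planted])
  # planted variant is recovered verbatim at the central offset
  center <- st$hits[st$hits$offset == 48, ]
  expect_equal(
    sort(center$peak_id),
    sort(tp$peak_id[tp$motif_planted]))
  idx <- match(center$peak_id, tp$peak_id)
  expect_identical(center$fivemer, tp$variant[idx])
})

test_that("degenerate configs behave sensibly", {
  d <- withr::local_tempdir()
  out <- generate_synthetic(small_cfg(methylated_fraction = 0, n_hmle = 0),
                            d)
  expect_equal(nrow(out$truth_peaks), 0)
  expect_false(any(out$truth_genes$methylated))
  expect_error(synthetic_config(methylated_fraction = 1.5), "config error")
  expect_error(synthetic_config(nb_dispersion = 0), "config error")
  expect_error(synthetic_config(summit_weights = c(stop = 1, tss = 1,
                                                   cds = 0)), "config error")
  expect_error(synthetic_config(hmle_stage = "nope"), "config error")
})

test_that("emitted fragments reproduce the emitted count matrices", {
  d <- withr::local_tempdir()
  out <- generate_synthetic(small_cfg(emit_fragments = TRUE), d)
  frags <- do.call(rbind, lapply(out$paths$fragments, read_fragments_bed))
  # gene-level: counting the input fragments recovers gene_counts exactly
  gcounts <- read_count_matrix(out$paths$gene_counts)
  libs <- colnames(gcounts)
  got <- gene_counts_from_fragments(frags[frags$library %in% libs, ],
                                    out$models, libs)
  expect_equal(unclass(got)[, ], gcounts[, ])
  # peak-level IP: fragments were drawn to satisfy the 50% counting rule
  pcounts <- read_count_matrix(out$paths$peak_counts)
  ip_libs <- grep("\\.IP$", colnames(pcounts), value = TRUE)
  peaks <- data.frame(peak_id = out$truth_peaks$peak_id,
                      chrom = out$truth_peaks$chrom,
                      start = out$truth_peaks$start,
                      end = out$truth_peaks$end)
  gotp <- count_fragments(frags[frags$library %in% ip_libs, ], peaks,
                          ip_libs)
  expect_equal(unclass(gotp)[, ], pcounts[, ip_libs])
})

test_that("tiny fixture matches its hand-computed expectations", {
  fx <- tiny_fixture()
  # annotation: T1 has two exons, length 1000, CDS transcript [150, 750)
  t1 <- get_model(fx$models, "T1")
  expect_equal(t1$tx_len, 1000)
  expect_equal(c(t1$cds_tx_start, t1$cds_tx_end), c(150, 750))
  p <- build_partition(t1)
  expect_equal(p$tx_start, c(0, 150, 150, 550, 950))
  expect_equal(p$tx_end, c(150, 150, 550, 950, 1000))

  # consensus: A in 3 replicates, B in 2, C dropped
  cons <- merge_replicates(fx$replicate_peaks)
  expect_equal(cons$name, c("A", "B"))
  expect_equal(cons$support, c(3, 2))
  expect_equal(cons$start, c(245, 900))
  expect_equal(cons$end, c(455, 1105))
  expect_equal(cons$summit, c(300, 950))

  # hand-enumerated fragment counts: A gets 3 IP + 2 input, B none
  m <- count_fragments(fx$fragments, cons, fx$design$library)
  expect_equal(unname(m[, "s1.r1.IP"]), c(3L, 0L))
  expect_equal(unname(m[, "s1.r1.input"]), c(2L, 0L))

  # gene assignment: A and B both live in G1
  asg <- assign_genes(cons, fx$models)
  expect_equal(asg$assignment$gene_id, c("G1", "G1"))
  expect_equal(unname(asg$histogram["2"]), 1L)
})
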