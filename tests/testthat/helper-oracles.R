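# Independent brute-force oracles and random-instance builders shared by
# the unit and acceptance tests. Everything here is deliberately naive:
# per-base loops, all-pairs comparisons, closed-form formulas.

# ---- random transcript models ----------------------------------------

# Build a tx_models collection directly (not via GTF) with random exon
# structure; cds = TRUE adds a CDS spanning random interior tx positions.
random_models <- function(n, cds = TRUE, max_exons = 6, chrom = "chr1") {
  tx <- data.frame(
    transcript_id = sprintf("rtx%03d", seq_len(n)),
    gene_id = sprintf("rg%03d", seq_len(n)),
    chrom = chrom,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  exons <- list()
  cursor <- 100L
  tx$tx_len <- 0L
  tx$cds_tx_start <- NA_integer_
  tx$cds_tx_end <- NA_integer_
  for (i in seq_len(n)) {
    k <- sample.int(max_exons, 1)
    len <- sample(30:400, k, replace = TRUE)
    gaps <- if (k > 1) sample(20:200, k - 1, replace = TRUE) else integer(0)
    starts <- cursor + cumsum(c(0L, len[-k] + gaps))
    exons[[tx$transcript_id[i]]] <- data.frame(start = starts,
                                               end = starts + len)
    tx$tx_len[i] <- sum(len)
    cursor <- max(starts + len) + sample(200:500, 1)
    if (cds) {
      L <- tx$tx_len[i]
      a <- sample.int(max(1L, L - 10L), 1)
      b <- min(L, a + sample(6:max(7L, L %/% 2L), 1))
      tx$cds_tx_start[i] <- a
      tx$cds_tx_end[i] <- b
    }
  }
  m <- structure(list(transcripts = tx, exons = exons), class = "tx_models")
  # genomic CDS extent, as load_annotation records it
  for (i in seq_len(n)) {
    if (!is.na(tx$cds_tx_start[i])) {
      mod <- get_model(m, i)
      g <- tx_to_genomic(mod, c(tx$cds_tx_start[i], tx$cds_tx_end[i] - 1L))
      m$transcripts$cds_start_genomic[i] <- min(g)
      m$transcripts$cds_end_genomic[i] <- max(g) + 1L
    }
  }
  m
}

# Per-base projection oracle: ordered genomic positions of transcript
# bases 0..L-1 (5' to 3').
oracle_tx_bases <- function(model) {
  g <- unlist(lapply(seq_len(nrow(model$exons)), function(k) {
    seq(model$exons$start[k], model$exons$end[k] - 1L)
  }))
  if (model$strand == "-") g <- rev(g)
  g
}

# Per-base five-segment labeling oracle following the same rules as
# build_partition but base by base: stop window (anchored at the CDS end,
# 200 nt each side) wins; then TSS (first min(200, 5'UTR) nt), UTR5, CDS,
# UTR3 by position.
oracle_segment_labels <- function(model, tss_len = 200, stop_window = 400) {
  L <- model$tx_len
  cs <- model$cds_tx_start
  ce <- model$cds_tx_end
  half <- stop_window %/% 2
  lab <- character(L)
  for (p in 0:(L - 1)) {
    if (p >= ce - half && p < ce + half) lab[p + 1] <- "STOP"
    else if (p < min(tss_len, cs)) lab[p + 1] <- "TSS"
    else if (p < cs) lab[p + 1] <- "UTR5"
    else if (p < ce) lab[p + 1] <- "CDS"
    else lab[p + 1] <- "UTR3"
  }
  lab
}

# ---- interval oracles -------------------------------------------------

brute_overlap_fraction <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  ov / min(e1 - s1, e2 - s2)
}

# All-pairs + transitive-closure consensus oracle. Returns a canonical
# character representation of the consensus set: for every component with
# >= min_reps distinct replicates, "chrom:min_start-max_end".
brute_consensus <- function(peaks, min_overlap = 0.5, min_reps = 2) {
  n <- nrow(peaks)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (peaks$chrom[i] != peaks$chrom[j]) next
    if (peaks$replicate[i] == peaks$replicate[j]) next
    f <- brute_overlap_fraction(peaks$start[i], peaks$end[i],
                                peaks$start[j], peaks$end[j])
    if (f >= min_overlap) adj[i, j] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- apply(adj, 1, function(r) min(which(r)))
  out <- character(0)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (length(unique(peaks$replicate[idx])) < min_reps) next
    out <- c(out, paste0(peaks$chrom[idx[1]], ":", min(peaks$start[idx]),
                         "-", max(peaks$end[idx])))
  }
  sort(out)
}

# Cross-set entity oracle: same closure over peaks labeled by stage,
# returning sorted "stageset=chrom:span" strings.
brute_venn <- function(pooled, min_overlap = 0.5) {
  n <- nrow(pooled)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || pooled$chrom[i] != pooled$chrom[j]) next
    if (pooled$stage[i] == pooled$stage[j]) next
    f <- brute_overlap_fraction(pooled$start[i], pooled$end[i],
                                pooled$start[j], pooled$end[j])
    if (f >= min_overlap) adj[i, j] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- apply(adj, 1, function(r) min(which(r)))
  regions <- vapply(unique(comp), function(g) {
    paste(sort(unique(pooled$stage[comp == g])), collapse = "&")
  }, character(1))
  sort(as.vector(table(regions))) # counts only, order-free
}

brute_count_matrix <- function(fragments, peaks, libraries) {
  mat <- matrix(0L, nrow(peaks), length(libraries),
                dimnames = list(peaks$peak_id, libraries))
  for (i in seq_len(nrow(fragments))) for (j in seq_len(nrow(peaks))) {
    if (fragments$chrom[i] != peaks$chrom[j]) next
    ov <- max(0, min(fragments$end[i], peaks$end[j]) -
                max(fragments$start[i], peaks$start[j]))
    if (ov >= 0.5 * (fragments$end[i] - fragments$start[i]) ||
        ov >= 0.5 * (peaks$end[j] - peaks$start[j])) {
      lib <- fragments$library[i]
      mat[j, lib] <- mat[j, lib] + 1L
    }
  }
  mat
}

# ---- closed-form statistical oracles ---------------------------------

oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# RRACH offsets by regular expression (overlap-aware lookahead)
oracle_rrach <- function(s) {
  m <- gregexpr("(?=[AG][AG]AC[ACT])", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random replicate peak sets for consensus oracles
random_replicate_peaks <- function(n_per_rep, n_reps = 3,
                                   span = 20000L, chroms = c("c1", "c2")) {
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    st <- sample.int(span, n_per_rep)
    w <- sample(50:300, n_per_rep, replace = TRUE)
    data.frame(chrom = sample(chroms, n_per_rep, replace = TRUE),
               start = st, end = st + w,
               summit = st + w %/% 2,
               score = stats::runif(n_per_rep, 1, 100),
               stage = "s", replicate = r, stringsAsFactors = FALSE)
  }))
}
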