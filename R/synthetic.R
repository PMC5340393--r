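#' Configuration for the synthetic MeRIP-seq generator
#'
#' Defaults emulate the aggregate structure of a three-stage, three-replicate
#' liver m6A study: about one third of expressed genes methylated, ~1.37
#' peaks per modified gene, summit density concentrated at the stop codon,
#' 79% of peaks carrying a planted RRACH site, and a negative correlation
#' (rho = -0.45) between log2 peak enrichment and log gene expression, with
#' negative-binomial count noise per replicate.
#'
#' @param seed Integer RNG seed; identical seed and config give
#'   byte-identical output files.
#' @param n_genes Number of genes, default 2000.
#' @param genes_per_chrom Genes laid per chromosome, default 100.
#' @param stages Stage labels.
#' @param replicates Replicates per stage, default 3.
#' @param methylated_fraction Fraction of genes carrying peaks (exact-count
#'   subset), default 0.33.
#' @param peaks_per_gene_lambda Peaks per modified gene = 1 + Poisson(lambda),
#'   default 0.37 (mean 1.37), capped by available transcript space.
#' @param summit_weights Mixture weights for summit placement:
#'   stop-codon window / TSS+5'UTR / uniform CDS.
#' @param stop_sd SD (nt) of the normal summit offset around the stop codon
#'   within its 400-nt window, default 70.
#' @param motif_planting_prob Fraction of peaks with a planted RRACH 5-mer
#'   at the summit (exact-count subset), default 0.79. The background genome
#'   is RRACH-suppressed so this fraction is identifiable.
#' @param rho Target sample correlation between per-peak log2 enrichment and
#'   host-gene log2 expression, default -0.45 (constructed exactly on the
#'   latent scale).
#' @param mean_log2_enrich,sd_log2_enrich Latent log2 enrichment
#'   distribution.
#' @param expr_log10_mean,expr_log10_sd Latent log10 FPKM distribution.
#' @param nb_dispersion Negative-binomial dispersion (1/size), default 0.1.
#' @param library_size Declared mapped fragments per library, default 2e7.
#' @param input_peak_mean Expected input fragments per peak per library,
#'   default 200 (constant, so log-enrichment noise is homoscedastic).
#' @param detect_prob Per-replicate detection probability of a true peak,
#'   default 0.92 (exercises the >=2-replicate consensus rule).
#' @param stage_unique_frac Probability a peak is unique to each given
#'   stage, default 0.04 (so ~12% of peaks are stage-unique).
#' @param false_peak_frac False single-replicate peaks per replicate file,
#'   as a fraction of true peaks, default 0.05.
#' @param jitter_frac Replicate boundary jitter, uniform within +/- this
#'   fraction of peak length, default 0.1.
#' @param peak_width_range Total peak width range (nt).
#' @param n_hmle Planted higher-methylation/lower-expression genes, default
#'   5 (all in `hmle_stage`, log2 effects `hmle_log2fc`).
#' @param hmle_stage Stage carrying the planted effect.
#' @param hmle_log2fc Planted effect size (log2), default 4 (16-fold),
#'   placing the planted genes well above the detection boundary of a
#'   three-replicate pooled t test under the default count dispersion.
#' @param emit_fragments Also write per-library fragment BED files (small
#'   designs only), default FALSE.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 2000L,
                             genes_per_chrom = 100L,
                             stages = c("newborn", "suckling", "adult"),
                             replicates = 3L,
                             methylated_fraction = 0.33,
                             peaks_per_gene_lambda = 0.37,
                             summit_weights = c(stop = 0.45, tss = 0.20,
                                                cds = 0.35),
                             stop_sd = 70,
                             motif_planting_prob = 0.79,
                             rho = -0.45,
                             mean_log2_enrich = 1.5,
                             sd_log2_enrich = 1.5,
                             expr_log10_mean = 1.0,
                             expr_log10_sd = 0.6,
                             nb_dispersion = 0.1,
                             library_size = 2e7,
                             input_peak_mean = 200,
                             detect_prob = 0.92,
                             stage_unique_frac = 0.04,
                             false_peak_frac = 0.05,
                             jitter_frac = 0.1,
                             peak_width_range = c(150L, 250L),
                             n_hmle = 5L,
                             hmle_stage = "newborn",
                             hmle_log2fc = 4,
                             emit_fragments = FALSE) {
  cfg <- as.list(environment())
  probs <- c(cfg$methylated_fraction, cfg$motif_planting_prob,
             cfg$detect_prob, cfg$stage_unique_frac, cfg$false_peak_frac,
             cfg$jitter_frac, cfg$summit_weights)
  if (any(probs < 0 | probs > 1)) stop("config error: probability out of [0,1]")
  if (abs(sum(cfg$summit_weights) - 1) > 1e-8) {
    stop("config error: summit_weights must sum to 1")
  }
  if (cfg$nb_dispersion <= 0 || cfg$sd_log2_enrich <= 0 ||
      cfg$expr_log10_sd <= 0) {
    stop("config error: invalid distribution parameter")
  }
  if (abs(cfg$rho) > 1) stop("config error: |rho| must be <= 1")
  if (!cfg$hmle_stage %in% cfg$stages) stop("config error: unknown hmle_stage")
  class(cfg) <- "synthetic_config"
  cfg
}

# ---- sequence helpers on integer byte codes (A=65 C=67 G=71 T=84) ----

codes_random_seq <- function(n) {
  sample(c(65L, 67L, 71L, 84L), n, replace = TRUE)
}

rrach_starts_codes <- function(x) {
  n <- length(x)
  if (n < 5L) return(integer(0))
  i <- seq_len(n - 4L)
  hit <- (x[i] == 65L | x[i] == 71L) &
    (x[i + 1L] == 65L | x[i + 1L] == 71L) &
    x[i + 2L] == 65L & x[i + 3L] == 67L &
    (x[i + 4L] != 71L)
  i[hit]
}

# Minus-strand RRACH reads as DGTYY on the plus strand
# (D = A/G/T, Y = C/T).
dgtyy_starts_codes <- function(x) {
  n <- length(x)
  if (n < 5L) return(integer(0))
  i <- seq_len(n - 4L)
  hit <- (x[i] != 67L) & x[i + 1L] == 71L & x[i + 2L] == 84L &
    (x[i + 3L] == 67L | x[i + 3L] == 84L) &
    (x[i + 4L] == 67L | x[i + 4L] == 84L)
  i[hit]
}

# Remove every RRACH occurrence on both strands: the central A of a
# plus-strand site becomes C, the central T of a minus-strand site (DGTYY
# on the plus strand) becomes G — neither substitution can recreate a site
# at the same offset. Iterate because a substitution can expose a shifted
# occurrence.
suppress_rrach <- function(x, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    h1 <- rrach_starts_codes(x)
    h2 <- dgtyy_starts_codes(x)
    if (!length(h1) && !length(h2)) break
    if (length(h1)) x[h1 + 2L] <- 67L
    if (length(h2)) x[h2 + 2L] <- 71L
  }
  x
}

seq_from_codes <- function(x) rawToChar(as.raw(x))
codes_from_seq <- function(s) as.integer(charToRaw(s))

# ---- structure generation ----

# Draw one gene structure in transcript space, then lay exons genomically.
# Returns exon table plus CDS tx coords.
draw_gene_structure <- function() {
  utr5 <- sample(100:300, 1)
  cds <- 3L * sample(300:800, 1)          # 900-2400 nt
  utr3 <- sample(200:600, 1)
  tx_len <- utr5 + cds + utr3
  n_exons <- 1L + stats::rpois(1, 2)
  cuts <- sort(sample(seq_len(tx_len - 1L),
                      min(n_exons - 1L, tx_len - 1L)))
  bounds <- c(0L, cuts, tx_len)
  exon_len <- diff(bounds)
  introns <- if (length(exon_len) > 1L) {
    sample(100:500, length(exon_len) - 1L, replace = TRUE)
  } else integer(0)
  list(utr5 = utr5, cds = cds, utr3 = utr3, tx_len = tx_len,
       exon_len = exon_len, introns = introns)
}

#' Generate a fully ground-truthed synthetic MeRIP-seq dataset
#'
#' Emits, under `out_dir`: `genome.fa` (+ `.fai`), `annotation.gtf`,
#' `peaks/<stage>_rep<r>.narrowPeak`, `counts/peak_counts.tsv`,
#' `counts/gene_counts.tsv`, `libraries.tsv`, `truth_genes.tsv`,
#' `truth_peaks.tsv`, `config.tsv`, and (optionally) per-library fragment
#' BEDs. narrowPeak names carry the true peak id, so consensus peaks can be
#' matched to the count matrix. The returned ground truth records, per
#' gene, methylation status and latent expression, and per peak, summit
#' position, segment, motif planting and the per-stage latent log2
#' enrichment.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `paths`, `truth_genes`, `truth_peaks`,
#'   `design` (library_design), and `models` (the generated annotation,
#'   already loaded).
#' @export
generate_synthetic <- function(config = synthetic_config(),
                               out_dir = tempfile("merip_synth_")) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "counts"), showWarnings = FALSE)

  n <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  tx_ids <- sprintf("T%04d", seq_len(n))
  chrom_of <- paste0("chr", 1L + (seq_len(n) - 1L) %/% config$genes_per_chrom)
  strand_of <- sample(c("+", "-"), n, replace = TRUE)

  # --- gene structures and genomic layout ---
  structures <- replicate(n, draw_gene_structure(), simplify = FALSE)
  gtf_lines <- character(0)
  exon_tab <- vector("list", n)
  gene_start <- integer(n)
  cursor <- stats::setNames(rep(1000L, length(unique(chrom_of))),
                            unique(chrom_of))
  for (i in seq_len(n)) {
    st <- structures[[i]]
    gap <- sample(500:1500, 1)
    g0 <- cursor[chrom_of[i]] + gap
    gene_start[i] <- g0
    ex_start <- integer(length(st$exon_len))
    pos <- g0
    for (j in seq_along(st$exon_len)) {
      ex_start[j] <- pos
      pos <- pos + st$exon_len[j]
      if (j < length(st$exon_len)) pos <- pos + st$introns[j]
    }
    exon_tab[[i]] <- data.frame(start = ex_start,
                                end = ex_start + st$exon_len)
    cursor[chrom_of[i]] <- pos
  }
  chrom_len <- cursor + 1000L

  # Build tx_models directly (same structure load_annotation produces)
  tx_df <- data.frame(transcript_id = tx_ids, gene_id = gene_ids,
                      chrom = chrom_of, strand = strand_of,
                      tx_len = vapply(structures, `[[`, numeric(1), "tx_len"),
                      stringsAsFactors = FALSE)
  tx_df$cds_tx_start <- vapply(structures, `[[`, numeric(1), "utr5")
  tx_df$cds_tx_end <- tx_df$cds_tx_start +
    vapply(structures, `[[`, numeric(1), "cds")
  models <- structure(list(
    transcripts = tx_df,
    exons = stats::setNames(exon_tab, tx_ids)), class = "tx_models")
  # genomic CDS extent via projection
  cds_g <- t(vapply(seq_len(n), function(i) {
    m <- get_model(models, i)
    g <- tx_to_genomic(m, c(tx_df$cds_tx_start[i], tx_df$cds_tx_end[i] - 1L))
    range(g)
  }, numeric(2)))
  models$transcripts$cds_start_genomic <- as.integer(cds_g[, 1])
  models$transcripts$cds_end_genomic <- as.integer(cds_g[, 2] + 1L)

  # --- GTF ---
  for (i in seq_len(n)) {
    e <- exon_tab[[i]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     gene_ids[i], tx_ids[i])
    gtf_lines <- c(gtf_lines, sprintf(
      "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
      chrom_of[i], e$start + 1L, e$end, strand_of[i], attrs))
    # CDS = intersection of exons with genomic CDS extent
    cs <- models$transcripts$cds_start_genomic[i]
    ce <- models$transcripts$cds_end_genomic[i]
    lo <- pmax(e$start, cs); hi <- pmin(e$end, ce)
    keep <- lo < hi
    gtf_lines <- c(gtf_lines, sprintf(
      "%s\tsynth\tCDS\t%d\t%d\t.\t%s\t.\t%s",
      chrom_of[i], lo[keep] + 1L, hi[keep], strand_of[i], attrs))
  }
  gtf_path <- file.path(out_dir, "annotation.gtf")
  writeLines(gtf_lines, gtf_path)

  # --- expression and methylation latents ---
  log10_fpkm <- stats::rnorm(n, config$expr_log10_mean, config$expr_log10_sd)
  fpkm_base <- 10^log10_fpkm
  n_meth <- round(config$methylated_fraction * n)
  methylated <- sort(sample.int(n, n_meth))
  hmle_genes <- sort(sample(methylated, min(config$n_hmle, n_meth)))

  # --- peaks: placement in transcript space ---
  peak_rows <- list()
  for (i in methylated) {
    m <- get_model(models, i)
    cs <- m$cds_tx_start; ce <- m$cds_tx_end; L <- m$tx_len
    k <- 1L + stats::rpois(1, config$peaks_per_gene_lambda)
    summits <- integer(0)
    for (p in seq_len(k)) {
      for (try in 1:20) {
        u <- sample(c("stop", "tss", "cds"), 1,
                    prob = config$summit_weights[c("stop", "tss", "cds")])
        t <- switch(u,
          stop = ce + round(stats::rnorm(1, 0, config$stop_sd)),
          tss = sample.int(cs, 1) - 1L,
          cds = cs + sample.int(ce - cs, 1) - 1L)
        t <- max(0L, min(L - 1L, as.integer(t)))
        if (u == "stop") t <- max(ce - 200L, min(ce + 199L, t))
        t <- max(0L, min(L - 1L, t))
        if (!length(summits) || min(abs(summits - t)) >= 600L) break
        t <- NA_integer_
      }
      if (!is.na(t)) summits <- c(summits, t)
    }
    for (t in summits) {
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        gene_idx = i, tx_summit = t, stringsAsFactors = FALSE)
    }
  }
  pk <- do.call(rbind, peak_rows)
  if (is.null(pk)) pk <- data.frame(gene_idx = integer(0),
                                    tx_summit = integer(0))
  n_pk <- nrow(pk)
  pk$peak_id <- sprintf("pk%05d", seq_len(n_pk))
  pk$gene_id <- gene_ids[pk$gene_idx]
  pk$chrom <- chrom_of[pk$gene_idx]
  pk$strand <- strand_of[pk$gene_idx]
  pk$summit <- vapply(seq_len(n_pk), function(r) {
    tx_to_genomic(get_model(models, pk$gene_idx[r]), pk$tx_summit[r])
  }, integer(1))
  w <- if (n_pk) sample(config$peak_width_range[1]:config$peak_width_range[2],
                        n_pk, replace = TRUE) else integer(0)
  up <- round(w * stats::runif(n_pk, 0.35, 0.65))
  pk$start <- pk$summit - up
  pk$end <- pk$start + w
  pk$width <- w
  # segment label of the true summit
  pk$segment <- vapply(seq_len(n_pk), function(r) {
    m <- get_model(models, pk$gene_idx[r])
    segment_of(build_partition(m), pk$tx_summit[r])
  }, character(1))

  # --- correlated enrichment latent (exact sample correlation rho) ---
  if (n_pk >= 3L) {
    e_expr <- log10_fpkm[pk$gene_idx]
    z <- as.vector(scale(e_expr))
    wlat <- stats::rnorm(n_pk)
    worth <- stats::residuals(stats::lm(wlat ~ z))
    worth <- as.vector(scale(worth))
    mlat <- config$rho * z + sqrt(1 - config$rho^2) * worth
    pk$log2_enrich <- config$mean_log2_enrich +
      config$sd_log2_enrich * as.vector(scale(mlat))
  } else {
    pk$log2_enrich <- rep(config$mean_log2_enrich, n_pk)
  }

  # --- stage structure: presence, hmle effects ---
  stages <- config$stages
  ns <- length(stages)
  pres <- matrix(TRUE, n_pk, ns, dimnames = list(pk$peak_id, stages))
  u <- stats::runif(n_pk)
  uniq_stage <- ifelse(u < ns * config$stage_unique_frac,
                       ceiling(u / config$stage_unique_frac), NA)
  # Planted higher-meth/lower-expr genes: their peaks are called only in
  # the high-methylation stage (in the other stages the 2^-hmle_log2fc
  # enrichment falls below the caller's detection), entering the
  # stage-higher set through the stage-unique clause.
  hmle_peak <- pk$gene_idx %in% hmle_genes
  uniq_stage[hmle_peak] <- match(config$hmle_stage, stages)
  for (r in which(!is.na(uniq_stage))) {
    pres[r, ] <- FALSE
    pres[r, uniq_stage[r]] <- TRUE
  }
  stage_log2 <- matrix(pk$log2_enrich, n_pk, ns,
                       dimnames = list(pk$peak_id, stages))
  stage_log2[hmle_peak, setdiff(stages, config$hmle_stage)] <-
    stage_log2[hmle_peak, setdiff(stages, config$hmle_stage)] -
    config$hmle_log2fc
  fpkm_stage <- matrix(fpkm_base, n, ns,
                       dimnames = list(gene_ids, stages))
  fpkm_stage[hmle_genes, config$hmle_stage] <-
    fpkm_stage[hmle_genes, config$hmle_stage] / 2^config$hmle_log2fc

  # --- motif planting set (exact count) ---
  planted <- rep(FALSE, n_pk)
  if (n_pk) {
    planted[sample.int(n_pk, round(config$motif_planting_prob * n_pk))] <- TRUE
  }
  variant_pool <- rrach_variants()
  vprob <- stats::setNames(rep(0.412 / 9, 12), variant_pool)
  vprob[c("GGACC", "GGACT", "GGACA")] <- c(0.22, 0.218, 0.15)
  pk$variant <- rep(NA_character_, n_pk)
  pk$variant[planted] <- sample(variant_pool, sum(planted), replace = TRUE,
                                prob = vprob[variant_pool])
  pk$motif_planted <- planted

  # --- genome sequence (RRACH-suppressed background + planted 5-mers) ---
  fa_path <- file.path(out_dir, "genome.fa")
  fai <- NULL
  con <- file(fa_path, "w")
  for (chr in names(chrom_len)) {
    x <- suppress_rrach(codes_random_seq(chrom_len[chr]))
    rows <- which(pk$chrom == chr & planted)
    for (r in rows) {
      five <- pk$variant[r]
      if (pk$strand[r] == "-") {
        five <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(five)))
      }
      s0 <- pk$summit[r] - 2L  # 0-based start of the 5-mer, centered
      if (s0 >= 0L && s0 + 5L <= chrom_len[chr]) {
        x[(s0 + 1L):(s0 + 5L)] <- codes_from_seq(five)
      }
    }
    seqc <- seq_from_codes(x)
    writeLines(paste0(">", chr), con)
    lines <- substring(seqc, seq(1, nchar(seqc), 70),
                       pmin(seq(70, nchar(seqc) + 69, 70), nchar(seqc)))
    writeLines(lines, con)
    fai <- rbind(fai, data.frame(name = chr, length = chrom_len[chr]))
  }
  close(con)
  # simple fai (name, length, offset, linebases, linewidth)
  offs <- cumsum(c(0, utils::head(
    nchar(fai$name) + 2 + fai$length + ceiling(fai$length / 70), -1)))
  offs <- offs + nchar(fai$name) + 2
  utils::write.table(
    data.frame(fai$name, fai$length, offs, 70L, 71L),
    paste0(fa_path, ".fai"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  # --- replicate narrowPeak files ---
  reps <- seq_len(config$replicates)
  peak_paths <- character(0)
  for (s in seq_along(stages)) {
    present <- which(pres[, s])
    detected <- matrix(stats::runif(length(present) * length(reps)) <
                         config$detect_prob,
                       nrow = length(present), ncol = length(reps))
    detected[hmle_peak[present], ] <- TRUE
    for (rp in reps) {
      idx <- present[detected[, rp]]
      jit <- function(k) {
        round(stats::runif(length(k), -config$jitter_frac,
                           config$jitter_frac) * pk$width[k])
      }
      st <- pk$start[idx] + jit(idx)
      en <- pk$end[idx] + jit(idx)
      st <- pmin(st, pk$summit[idx] - 10L)
      en <- pmax(en, pk$summit[idx] + 10L)
      df <- data.frame(chrom = pk$chrom[idx], start = st, end = en,
                       name = pk$peak_id[idx],
                       score = round(stats::runif(length(idx), 50, 300)),
                       strand = rep(".", length(idx)),
                       signal = round(stats::runif(length(idx), 1, 10), 3),
                       pvalue = rep(-1, length(idx)),
                       qvalue = rep(-1, length(idx)),
                       summit_offset = pk$summit[idx] - st,
                       stringsAsFactors = FALSE)
      # false peaks, unique to this replicate
      n_false <- round(config$false_peak_frac * length(idx))
      if (n_false > 0) {
        fchr <- sample(names(chrom_len), n_false, replace = TRUE)
        fst <- vapply(fchr, function(ch) {
          sample.int(chrom_len[ch] - 400L, 1)
        }, integer(1))
        fw <- sample(150:250, n_false, replace = TRUE)
        df <- rbind(df, data.frame(
          chrom = fchr, start = fst, end = fst + fw,
          name = sprintf("fp_%s_r%d_%d", stages[s], rp, seq_len(n_false)),
          score = round(stats::runif(n_false, 50, 300)),
          strand = ".", signal = 1, pvalue = -1, qvalue = -1,
          summit_offset = fw %/% 2L, stringsAsFactors = FALSE))
      }
      df <- df[order(df$chrom, df$start), ]
      path <- file.path(out_dir, "peaks",
                        sprintf("%s_rep%d.narrowPeak", stages[s], rp))
      write_narrowpeak(df, path)
      peak_paths <- c(peak_paths, path)
    }
  }

  # --- library design and count matrices ---
  lib_rows <- expand.grid(replicate = reps, stage = stages,
                          type = c("IP", "input"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lib_rows$library <- sprintf("%s.r%d.%s", lib_rows$stage,
                              lib_rows$replicate, lib_rows$type)
  design <- library_design(lib_rows$library, lib_rows$stage,
                           lib_rows$replicate, lib_rows$type,
                           rep(config$library_size, nrow(lib_rows)))

  size_nb <- 1 / config$nb_dispersion
  peak_counts <- matrix(0L, n_pk, nrow(design),
                        dimnames = list(pk$peak_id, design$library))
  for (j in seq_len(nrow(design))) {
    s <- match(design$stage[j], stages)
    mu <- if (design$type[j] == "input") {
      rep(config$input_peak_mean, n_pk)
    } else {
      # IP coverage follows the true enrichment where the peak exists in
      # this stage; elsewhere the region is at input-level background
      ifelse(pres[, s], config$input_peak_mean * 2^stage_log2[, s],
             config$input_peak_mean)
    }
    peak_counts[, j] <- stats::rnbinom(n_pk, mu = mu, size = size_nb)
  }

  gene_len <- gene_exon_lengths(models)[gene_ids]
  input_design <- design[design$type == "input", ]
  gene_counts <- matrix(0L, n, nrow(input_design),
                        dimnames = list(gene_ids, input_design$library))
  for (j in seq_len(nrow(input_design))) {
    s <- match(input_design$stage[j], stages)
    mu <- fpkm_stage[, s] * (gene_len / 1000) *
      (input_design$size[j] / 1e6)
    gene_counts[, j] <- stats::rnbinom(n, mu = mu, size = size_nb)
  }

  write_count_matrix(peak_counts, file.path(out_dir, "counts",
                                            "peak_counts.tsv"), "peak_id")
  write_count_matrix(gene_counts, file.path(out_dir, "counts",
                                            "gene_counts.tsv"), "gene_id")
  utils::write.table(design, file.path(out_dir, "libraries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- optional fragment BEDs (small designs) ---
  frag_paths <- character(0)
  if (config$emit_fragments) {
    dir.create(file.path(out_dir, "fragments"), showWarnings = FALSE)
    for (j in seq_len(nrow(design))) {
      rows <- list()
      if (design$type[j] == "input") {
        jj <- match(design$library[j], colnames(gene_counts))
        for (i in seq_len(n)) {
          cnt <- gene_counts[i, jj]
          if (cnt == 0) next
          m <- get_model(models, i)
          t0 <- sample.int(max(1L, m$tx_len - 150L), cnt, replace = TRUE) - 1L
          g <- lapply(t0, function(t) {
            range(tx_to_genomic(m, c(t, min(m$tx_len - 1L, t + 149L))))
          })
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom_of[i],
            start = vapply(g, `[`, numeric(1), 1),
            end = vapply(g, `[`, numeric(1), 2) + 1,
            library = design$library[j])
        }
      } else {
        jj <- match(design$library[j], colnames(peak_counts))
        for (r in seq_len(n_pk)) {
          cnt <- peak_counts[r, jj]
          if (cnt == 0) next
          fst <- sample(pk$start[r]:(pk$end[r] - 100L), cnt, replace = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = pk$chrom[r], start = fst, end = fst + 150L,
            library = design$library[j])
        }
      }
      df <- do.call(rbind, rows)
      path <- file.path(out_dir, "fragments",
                        paste0(design$library[j], ".bed"))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      frag_paths <- c(frag_paths, path)
    }
  }

  # --- ground truth tables ---
  truth_genes <- data.frame(
    gene_id = gene_ids, chrom = chrom_of, strand = strand_of,
    tx_len = tx_df$tx_len, methylated = seq_len(n) %in% methylated,
    hmle = seq_len(n) %in% hmle_genes,
    fpkm_base = fpkm_base, stringsAsFactors = FALSE)
  for (s in seq_along(stages)) {
    truth_genes[[paste0("fpkm_", stages[s])]] <- fpkm_stage[, s]
  }
  truth_peaks <- pk[, c("peak_id", "gene_id", "chrom", "strand", "start",
                        "end", "summit", "tx_summit", "segment",
                        "motif_planted", "variant", "log2_enrich")]
  for (s in seq_along(stages)) {
    truth_peaks[[paste0("present_", stages[s])]] <- pres[, s]
    truth_peaks[[paste0("log2_enrich_", stages[s])]] <- stage_log2[, s]
  }
  utils::write.table(truth_genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_peaks, file.path(out_dir, "truth_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flat <- config[!vapply(config, is.function, logical(1))]
  flat <- vapply(flat, function(v) paste(v, collapse = ","), character(1))
  utils::write.table(data.frame(key = names(flat), value = unname(flat)),
                     file.path(out_dir, "config.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(
    paths = list(dir = out_dir, gtf = gtf_path, genome = fa_path,
                 narrowpeak = peak_paths,
                 peak_counts = file.path(out_dir, "counts", "peak_counts.tsv"),
                 gene_counts = file.path(out_dir, "counts", "gene_counts.tsv"),
                 libraries = file.path(out_dir, "libraries.tsv"),
                 fragments = frag_paths),
    truth_genes = truth_genes, truth_peaks = truth_peaks,
    design = design, models = models, config = config))
}
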