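#' Pipeline configuration
#'
#' Collects input paths and every tunable default of the analysis stages.
#'
#' @param gtf GTF annotation path.
#' @param genome Genome FASTA path.
#' @param peak_files data.frame with columns path, stage, replicate
#'   (one narrowPeak per stage x replicate).
#' @param peak_counts Path to the peak x library fragment-count TSV (rows
#'   keyed by the peak names carried in narrowPeak column 4).
#' @param gene_counts Path to the gene x input-library count TSV.
#' @param libraries Path to the library design TSV (library, stage,
#'   replicate, type, size).
#' @param min_overlap Consensus/venn overlap fraction, default 0.5.
#' @param min_replicates Minimum replicates per consensus peak, default 2.
#' @param pseudocount_fpm FPM pseudo-count for enrichment, default 0.25.
#' @param expressed_fpkm_threshold Default 0.1.
#' @param alpha Significance level for differential calls, default 0.05.
#' @param fpkm_log_eps Pseudo-FPKM inside log2, default 0.01.
#' @param motif_window RRACH scan window around summits, default 101.
#' @param density_window,density_bin Positional-density window/bin, 301/40.
#' @param n_expression_bins Equal-count bins for the methylation-vs-
#'   expression curve, default 20.
#' @param tss_len,stop_window Segment partition parameters, 200/400.
#' @param flank,bins_per_part,ma_window Metagene axis parameters,
#'   2000/100/4.
#' @return list of class `merip_config`.
#' @export
merip_config <- function(gtf, genome, peak_files, peak_counts, gene_counts,
                         libraries,
                         min_overlap = 0.5, min_replicates = 2L,
                         pseudocount_fpm = 0.25,
                         expressed_fpkm_threshold = 0.1,
                         alpha = 0.05, fpkm_log_eps = 0.01,
                         motif_window = 101L,
                         density_window = 301L, density_bin = 40L,
                         n_expression_bins = 20L,
                         tss_len = 200L, stop_window = 400L,
                         flank = 2000, bins_per_part = 100L,
                         ma_window = 4L) {
  cfg <- as.list(environment())
  class(cfg) <- "merip_config"
  cfg
}

#' Convenience: configuration for a generated synthetic dataset
#'
#' @param dir Output directory of [generate_synthetic()].
#' @param ... Overrides passed to [merip_config()].
#' @return A `merip_config`.
#' @export
merip_config_from_dir <- function(dir, ...) {
  np <- list.files(file.path(dir, "peaks"), "\\.narrowPeak$",
                   full.names = TRUE)
  meta <- regmatches(basename(np),
                     regexec("^(.*)_rep([0-9]+)\\.narrowPeak$",
                             basename(np)))
  peak_files <- data.frame(
    path = np,
    stage = vapply(meta, `[`, character(1), 2),
    replicate = as.integer(vapply(meta, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  merip_config(
    gtf = file.path(dir, "annotation.gtf"),
    genome = file.path(dir, "genome.fa"),
    peak_files = peak_files,
    peak_counts = file.path(dir, "counts", "peak_counts.tsv"),
    gene_counts = file.path(dir, "counts", "gene_counts.tsv"),
    libraries = file.path(dir, "libraries.tsv"),
    ...)
}

#' Validate pipeline inputs
#'
#' Checks file existence, light format sniffing, and design completeness
#' (every stage has >= min_replicates peak files; every IP library has an
#' input partner). Problems are returned, not raised.
#'
#' @param config A `merip_config`.
#' @return Character vector of problems (empty = ok).
#' @export
validate_inputs <- function(config) {
  problems <- character(0)
  need <- c(gtf = config$gtf, genome = config$genome,
            peak_counts = config$peak_counts,
            gene_counts = config$gene_counts,
            libraries = config$libraries)
  for (k in names(need)) {
    if (!file.exists(need[[k]])) {
      problems <- c(problems, paste0("missing ", k, " file: ", need[[k]]))
    }
  }
  for (i in seq_len(nrow(config$peak_files))) {
    p <- config$peak_files$path[i]
    if (!file.exists(p)) {
      problems <- c(problems, paste0("missing narrowPeak file: ", p))
      next
    }
    first <- strsplit(readLines(p, n = 1L), "\t")[[1]]
    if (length(first) < 10L) {
      problems <- c(problems, paste0(
        "truncated narrowPeak (line 1 has ", length(first),
        " columns): ", p))
    }
  }
  tab <- table(config$peak_files$stage)
  for (s in names(tab)) {
    if (tab[s] < config$min_replicates) {
      problems <- c(problems, paste0(
        "stage ", s, " has ", tab[s], " replicate file(s); ",
        config$min_replicates, " required"))
    }
  }
  if (file.exists(config$libraries)) {
    d <- utils::read.table(config$libraries, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    ip <- d[d$type == "IP", ]
    inp <- d[d$type == "input", ]
    key <- function(x) paste(x$stage, x$replicate)
    orphan <- !key(ip) %in% key(inp)
    if (any(orphan)) {
      problems <- c(problems, paste0(
        "IP library without input partner: ", ip$library[orphan]))
    }
  }
  problems
}

# Internal: segment label per consensus peak summit (NA for intergenic,
# non-coding hosts, or intronic summits)
peak_segments <- function(consensus, assignment, models, partitions) {
  reps <- representative_transcripts(models)
  gid <- assignment$gene_id[match(consensus$peak_id, assignment$peak_id)]
  out <- rep(NA_character_, nrow(consensus))
  for (i in seq_len(nrow(consensus))) {
    if (is.na(gid[i]) || gid[i] == "intergenic") next
    tx <- reps[gid[i]]
    if (is.na(tx) || !tx %in% names(partitions)) next
    m <- get_model(models, tx)
    loc <- locate(m, consensus$summit[i], chrom = consensus$chrom[i])
    if (loc$status != "exonic") next
    out[i] <- segment_of(partitions[[tx]], loc$tx_pos)
  }
  out
}

#' Run the full MeRIP-seq downstream analysis
#'
#' Orchestrates annotation loading, per-stage consensus peak merging,
#' cross-stage overlap, gene assignment, enrichment and expression
#' quantification, metagene and five-segment topology, RRACH motif
#' statistics, stage-pairwise differential methylation/expression, and the
#' methylation-expression association analyses. Any stage failure aborts
#' with the stage name.
#'
#' @param config A `merip_config`.
#' @return Object of class `merip_result`; see the elements in the return
#'   value and the print/summary methods.
#' @export
run_merip <- function(config) {
  problems <- validate_inputs(config)
  if (length(problems)) {
    stop("input validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  models <- step("annotation", load_annotation(config$gtf))
  partitions <- step("annotation", build_partitions(
    models, tss_len = config$tss_len, stop_window = config$stop_window))
  length_table <- step("annotation", segment_length_table(partitions))

  stages <- unique(config$peak_files$stage)
  consensus <- step("consensus", {
    stats::setNames(lapply(stages, function(s) {
      rows <- config$peak_files[config$peak_files$stage == s, ]
      pk <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        read_narrowpeak(rows$path[i], stage = s,
                        replicate = rows$replicate[i])
      }))
      merge_replicates(pk, min_overlap = config$min_overlap,
                       min_replicates = config$min_replicates)
    }), stages)
  })
  venn <- step("consensus", cross_stage_overlap(consensus,
                                                config$min_overlap))

  assignment <- step("gene_assignment", {
    stats::setNames(lapply(stages, function(s) {
      assign_genes(consensus[[s]], models)
    }), stages)
  })

  peak_counts <- step("quantify", read_count_matrix(config$peak_counts))
  gene_counts <- step("quantify", read_count_matrix(config$gene_counts))
  lib <- utils::read.table(config$libraries, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  design <- library_design(lib$library, lib$stage, lib$replicate, lib$type,
                           lib$size)
  enr <- step("quantify", peak_enrichment(peak_counts, design,
                                          config$pseudocount_fpm))
  gene_len <- step("quantify", gene_exon_lengths(models))
  expr <- step("quantify", gene_fpkm(gene_counts, gene_len, design,
                                     config$expressed_fpkm_threshold))

  # per-stage summit tables with host gene
  summits <- stats::setNames(lapply(stages, function(s) {
    cs <- consensus[[s]]
    a <- assignment[[s]]$assignment
    df <- data.frame(peak_id = cs$peak_id, name = cs$name,
                     chrom = cs$chrom, summit = cs$summit,
                     gene_id = a$gene_id[match(cs$peak_id, a$peak_id)],
                     stringsAsFactors = FALSE)
    df$segment <- peak_segments(cs, a, models, partitions)
    df
  }), stages)

  # pooled (cross-stage) view: one row per distinct peak entity
  pooled <- step("gene_assignment", {
    gene_of_peak <- unlist(lapply(stages, function(s) {
      a <- assignment[[s]]$assignment
      stats::setNames(a$gene_id, a$peak_id)
    }))
    ent <- venn$peak_regions
    ent$gene_id <- gene_of_peak[ent$peak_id]
    # one gene per entity (members agree except at assignment boundaries;
    # take the first member's gene)
    per_entity <- ent[!duplicated(ent$entity), c("entity", "gene_id")]
    genic <- per_entity$gene_id[per_entity$gene_id != "intergenic"]
    expressed_any <- rownames(expr$stage_fpkm)[
      rowSums(expr$expressed) > 0]
    list(entity_genes = per_entity,
         n_entities = nrow(per_entity),
         modified_genes = unique(genic),
         peaks_per_gene = if (length(genic)) mean(table(genic)) else NA_real_,
         frac_le2 = if (length(genic)) {
           mean(table(genic) <= 2)
         } else NA_real_,
         modified_fraction = length(unique(genic)) /
           length(expressed_any))
  })

  topology <- step("topology", {
    stats::setNames(lapply(stages, function(s) {
      sm <- summits[[s]]
      sm <- sm[sm$gene_id != "intergenic", , drop = FALSE]
      list(profile = metagene_profile(sm, models, flank = config$flank,
                                      bins_per_part = config$bins_per_part,
                                      ma_window = config$ma_window),
           segments = segment_frequencies(sm, models, partitions,
                                          length_table))
    }), stages)
  })
  topology_pooled <- step("topology", {
    sm <- do.call(rbind, summits)
    sm <- sm[sm$gene_id != "intergenic", , drop = FALSE]
    list(profile = metagene_profile(sm, models, flank = config$flank,
                                    bins_per_part = config$bins_per_part,
                                    ma_window = config$ma_window),
         segments = segment_frequencies(sm, models, partitions,
                                        length_table))
  })

  motif <- step("motif", {
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    all_cons <- do.call(rbind, lapply(stages, function(s) {
      cs <- consensus[[s]]
      cs$host_strand <- peak_strands(cs, assignment[[s]]$assignment, models)
      cs
    }))
    pooled_stats <- peak_motif_stats(all_cons, genome,
                                     strand = all_cons$host_strand,
                                     window = config$motif_window)
    per_stage <- stats::setNames(lapply(stages, function(s) {
      sub <- all_cons[all_cons$stage == s, ]
      peak_motif_stats(sub, genome, strand = sub$host_strand,
                       window = config$motif_window)$fraction
    }), stages)
    list(pooled = pooled_stats, per_stage_fraction = unlist(per_stage))
  })

  differential <- step("differential", {
    # entity universe: count-matrix peaks appearing in >= 1 consensus set
    presence <- sapply(stages, function(s) {
      rownames(peak_counts) %in% consensus[[s]]$name
    })
    rownames(presence) <- rownames(peak_counts)
    keep <- rowSums(presence) > 0L
    presence <- presence[keep, , drop = FALSE]
    rep_log2 <- enr$replicate_log2[keep, , drop = FALSE]
    groups <- sub("\\.[0-9]+$", "", colnames(rep_log2))
    masked <- rep_log2
    for (s in stages) masked[!presence[, s], groups == s] <- NA
    meth_sets <- call_stage_higher(masked, groups, presence, config$alpha)
    complete <- rowSums(presence) == length(stages)
    meth_calls <- if (any(complete)) {
      pairwise_differential(rep_log2[complete, , drop = FALSE], groups,
                            config$alpha)
    } else NULL
    expr_groups <- design$stage[match(colnames(expr$fpkm), design$library)]
    expr_sets <- call_expression(expr$fpkm, expr_groups, config$alpha,
                                 config$fpkm_log_eps)
    peak_gene_map <- do.call(rbind, summits)
    peak_genes <- stats::setNames(peak_gene_map$gene_id,
                                  peak_gene_map$name)
    peak_genes <- peak_genes[!duplicated(names(peak_genes))]
    hmle <- higher_meth_lower_expr(meth_sets, expr_sets$lower, peak_genes)
    n_modified <- length(unique(unlist(lapply(summits, function(x) {
      x$gene_id[x$gene_id != "intergenic"]
    }))))
    n_expressed <- length(unique(rownames(expr$stage_fpkm)[
      rowSums(expr$expressed) > 0]))
    summary_tab <- if (!is.null(meth_calls)) {
      summarize_differential(meth_calls, expr_sets$calls, peak_genes,
                             n_modified, n_expressed)
    } else NULL
    list(meth_sets = meth_sets, meth_calls = meth_calls,
         expr_sets = expr_sets, hmle = hmle, summary = summary_tab,
         presence = presence)
  })

  association <- step("association", {
    cors <- list()
    curves <- list()
    for (s in stages) {
      sm <- summits[[s]]
      ok <- sm$gene_id != "intergenic" & !is.na(sm$name) &
        sm$name %in% rownames(enr$stage_log2) &
        sm$gene_id %in% rownames(expr$stage_fpkm)
      sm <- sm[ok, , drop = FALSE]
      x <- enr$stage_log2[sm$name, s]
      y <- expr$stage_fpkm[sm$gene_id, s]
      expressed <- y > config$expressed_fpkm_threshold
      cors[[paste0(s, ".all")]] <- enrichment_expression_correlation(
        x[expressed], y[expressed], scope = paste0(s, ".all"),
        eps = config$fpkm_log_eps)
      for (lab in c("TSS", "UTR5", "CDS", "STOP", "UTR3")) {
        sel <- expressed & !is.na(sm$segment) & sm$segment == lab
        if (sum(sel) >= 3L &&
            stats::var(x[sel]) > 0 && stats::var(log2(y[sel])) > 0) {
          cors[[paste(s, lab, sep = ".")]] <-
            enrichment_expression_correlation(
              x[sel], y[sel], scope = paste(s, lab, sep = "."),
              eps = config$fpkm_log_eps)
        }
      }
      # methylation fraction vs expression curve
      st_fpkm <- expr$stage_fpkm[, s]
      st_fpkm <- st_fpkm[st_fpkm > config$expressed_fpkm_threshold]
      gene_segs <- split(sm$segment[!is.na(sm$segment)],
                         sm$gene_id[!is.na(sm$segment)])
      meth_genes <- unique(sm$gene_id)
      gene_segs2 <- lapply(stats::setNames(meth_genes, meth_genes),
                           function(g) {
        v <- gene_segs[[g]]
        if (is.null(v)) character(0) else v
      })
      if (length(st_fpkm) >= config$n_expression_bins) {
        curves[[s]] <- fraction_vs_expression(st_fpkm, gene_segs2,
                                              config$n_expression_bins)
      }
    }
    list(correlations = do.call(rbind, cors), curves = curves)
  })

  res <- list(
    config = config, stages = stages, models = models,
    partitions = partitions, length_table = length_table,
    consensus = consensus, venn = venn, assignment = assignment,
    pooled = pooled, summits = summits, enrichment = enr,
    expression = expr, topology = topology,
    topology_pooled = topology_pooled, motif = motif,
    differential = differential, association = association)
  class(res) <- "merip_result"
  res
}

#' @export
print.merip_result <- function(x, ...) {
  cat("merip_result —", length(x$stages), "stages\n")
  for (s in x$stages) {
    cat(sprintf("  %s: %d consensus peaks, %d modified genes\n", s,
                nrow(x$consensus[[s]]),
                length(unique(x$assignment[[s]]$assignment$gene_id[
                  x$assignment[[s]]$assignment$gene_id != "intergenic"]))))
  }
  cat(sprintf("  RRACH-bearing peak fraction (pooled): %.3f\n",
              x$motif$pooled$fraction))
  invisible(x)
}

#' @export
summary.merip_result <- function(object, ...) {
  x <- object
  expr_n <- colSums(x$expression$expressed)
  rows <- do.call(rbind, lapply(x$stages, function(s) {
    mg <- unique(x$assignment[[s]]$assignment$gene_id)
    mg <- mg[mg != "intergenic"]
    per_gene <- table(x$assignment[[s]]$assignment$gene_id[
      x$assignment[[s]]$assignment$gene_id != "intergenic"])
    data.frame(stage = s,
               consensus_peaks = nrow(x$consensus[[s]]),
               modified_genes = length(mg),
               expressed_genes = expr_n[s],
               modified_fraction = length(mg) / expr_n[s],
               peaks_per_gene = mean(per_gene),
               motif_fraction = x$motif$per_stage_fraction[s],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Write every report table of a pipeline run
#'
#' Emits the stage outputs as deterministic TSVs under `dir`: consensus
#' peaks, venn regions, gene assignments, metagene profiles, segment
#' tables, motif variant table, differential summary and stage-higher
#' sets, correlations and methylation-vs-expression curves.
#'
#' @param result A `merip_result`.
#' @param dir Output directory (created).
#' @return Invisibly, the vector of files written.
#' @export
write_merip_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (s in result$stages) {
    w(result$consensus[[s]], paste0("consensus_", s, ".tsv"))
    w(result$assignment[[s]]$assignment, paste0("assignment_", s, ".tsv"))
    w(result$topology[[s]]$profile, paste0("metagene_", s, ".tsv"))
    w(result$topology[[s]]$segments, paste0("segments_", s, ".tsv"))
  }
  w(result$venn$regions, "venn_regions.tsv")
  w(result$motif$pooled$variants, "motif_variants.tsv")
  if (!is.null(result$differential$summary)) {
    w(result$differential$summary, "differential_summary.tsv")
  }
  hm <- result$differential$hmle
  w(data.frame(stage = rep(names(hm), lengths(hm)),
               gene_id = unlist(hm, use.names = FALSE)),
    "higher_meth_lower_expr.tsv")
  w(result$association$correlations, "correlations.tsv")
  for (s in names(result$association$curves)) {
    w(result$association$curves[[s]], paste0("expression_curve_", s, ".tsv"))
  }
  w(summary(result), "summary.tsv")
  invisible(files)
}
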