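#' Read a MACS2-style narrowPeak file
#'
#' ENCODE narrowPeak is 10-column BED6+4; column 10 is the summit offset from
#' `start` (-1 when unknown). The summit is materialized as `start + offset`;
#' for offset -1 the interval midpoint is used and a message is logged.
#' Records with `end <= start` are rejected with a warning.
#'
#' @param path narrowPeak file path.
#' @param stage Stage (condition) label to attach to every record.
#' @param replicate Replicate id (integer) to attach.
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   signal, pvalue, qvalue, summit_offset, summit, stage, replicate.
#'   Coordinates 0-based half-open, as in the file.
#' @export
read_narrowpeak <- function(path, stage = NA_character_,
                            replicate = NA_integer_) {
  nf <- length(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]])
  if (nf < 10L) {
    stop("narrowPeak format error in ", path, ": expected 10 columns, found ",
         nf)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "numeric", "numeric", "numeric",
                                         "integer"))
  if (ncol(df) < 10L) {
    stop("narrowPeak format error in ", path, ": expected 10 columns, found ",
         ncol(df))
  }
  names(df)[1:10] <- c("chrom", "start", "end", "name", "score", "strand",
                       "signal", "pvalue", "qvalue", "summit_offset")
  bad <- df$end <= df$start
  if (any(bad)) {
    warning(sum(bad), " narrowPeak record(s) with end <= start rejected in ",
            path)
    df <- df[!bad, , drop = FALSE]
  }
  no_summit <- df$summit_offset < 0
  if (any(no_summit)) {
    message(sum(no_summit), " record(s) without summit offset in ", path,
            "; using interval midpoint")
  }
  df$summit <- ifelse(no_summit,
                      df$start + (df$end - df$start) %/% 2L,
                      df$start + df$summit_offset)
  df$stage <- stage
  df$replicate <- replicate
  rownames(df) <- NULL
  df
}

#' Write peaks in narrowPeak format
#'
#' @param peaks data.frame as returned by [read_narrowpeak()] (columns
#'   chrom, start, end, name, score, strand, signal, pvalue, qvalue,
#'   summit_offset, or a summit column from which the offset is derived).
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (!"summit_offset" %in% names(peaks)) {
    peaks$summit_offset <- peaks$summit - peaks$start
  }
  if (!"name" %in% names(peaks)) peaks$name <- "."
  if (!"strand" %in% names(peaks)) peaks$strand <- "."
  if (!"signal" %in% names(peaks)) peaks$signal <- 0
  if (!"pvalue" %in% names(peaks)) peaks$pvalue <- -1
  if (!"qvalue" %in% names(peaks)) peaks$qvalue <- -1
  out <- peaks[, c("chrom", "start", "end", "name", "score", "strand",
                   "signal", "pvalue", "qvalue", "summit_offset")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap fraction of two intervals
#'
#' Fraction of the *shorter* interval covered by the overlap — the symmetric,
#' most permissive reading of a ">= 50% length overlap" reproducibility rule.
#' Intervals on different chromosomes overlap by 0. Vectorized and recycled.
#'
#' @param start1,end1,start2,end2 0-based half-open interval coordinates.
#' @param chrom1,chrom2 Optional chromosome names.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(start1, end1, start2, end2,
                             chrom1 = NULL, chrom2 = NULL) {
  ov <- pmax(0L, pmin(end1, end2) - pmax(start1, start2))
  f <- ov / pmin(end1 - start1, end2 - start2)
  if (!is.null(chrom1) && !is.null(chrom2)) f[chrom1 != chrom2] <- 0
  f
}

# Internal: iterative union-find with path halving
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_components <- function(n, from, to) {
  parent <- uf_new(n)
  for (k in seq_along(from)) {
    a <- uf_find(parent, from[k]); b <- uf_find(parent, to[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Internal: edges (i,j) between intervals with overlap fraction >= min_overlap
overlap_edges <- function(df, min_overlap) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  f <- overlap_fraction(df$start[i], df$end[i], df$start[j], df$end[j])
  keep <- f >= min_overlap
  list(i = i[keep], j = j[keep])
}

#' Merge replicate peaks into high-confidence consensus peaks
#'
#' Builds the graph whose nodes are replicate peaks of one stage and whose
#' edges connect peaks from *different* replicates with overlap fraction
#' (relative to the shorter peak) `>= min_overlap`. Connected components
#' spanning at least `min_replicates` distinct replicates become consensus
#' peaks: interval = union (span) of members, representative summit = summit
#' of the highest-score member (ties: leftmost summit), score = max member
#' score. Components confined to a single replicate are discarded. The
#' result is independent of replicate ordering.
#'
#' @param peaks data.frame of replicate peaks (one stage), with columns
#'   chrom, start, end, summit, score, replicate (and optionally stage).
#' @param min_overlap Overlap-fraction threshold, default 0.5.
#' @param min_replicates Minimum distinct replicates per consensus peak,
#'   default 2.
#' @return data.frame of class `consensus_peaks`: peak_id, chrom, start,
#'   end, summit, score, support (number of distinct replicates),
#'   replicates (comma-joined ids), n_members, stage.
#' @export
merge_replicates <- function(peaks, min_overlap = 0.5, min_replicates = 2L) {
  if (length(unique(peaks$replicate)) < 2L) {
    stop("consensus requires >=2 replicates")
  }
  n <- nrow(peaks)
  ed <- overlap_edges(peaks, min_overlap)
  cross <- peaks$replicate[ed$i] != peaks$replicate[ed$j]
  comp <- uf_components(n, ed$i[cross], ed$j[cross])

  stage <- if ("stage" %in% names(peaks)) peaks$stage[1] else NA_character_
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    reps <- unique(peaks$replicate[idx])
    if (length(reps) < min_replicates) return(NULL)
    best <- idx[order(-peaks$score[idx], peaks$summit[idx])][1]
    data.frame(name = if ("name" %in% names(peaks)) peaks$name[best]
               else NA_character_,
               chrom = peaks$chrom[idx[1]],
               start = min(peaks$start[idx]),
               end = max(peaks$end[idx]),
               summit = peaks$summit[best],
               score = max(peaks$score[idx]),
               support = length(reps),
               replicates = paste(sort(reps), collapse = ","),
               n_members = length(idx),
               stage = stage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), score = numeric(0),
                      support = integer(0), replicates = character(0),
                      n_members = integer(0), stage = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(peak_id = paste0(if (is.na(stage)) "peak" else stage,
                                "_", seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  class(out) <- c("consensus_peaks", "data.frame")
  out
}

#' Cross-stage peak overlap (Venn regions)
#'
#' Pools consensus peaks of all stages and clusters them with the same
#' `>= min_overlap`-of-shorter rule across stages (connected components).
#' Each component is one distinct peak entity; its Venn region is the set of
#' stages contributing members.
#'
#' @param consensus_list Named list of `consensus_peaks` (one per stage).
#' @param min_overlap Overlap-fraction threshold, default 0.5.
#' @return list with `entities` (data.frame: entity, stages, n_peaks, and
#'   chrom/start/end of the merged span, plus member peak_ids), `regions`
#'   (data.frame: region, count), and `peak_regions` (data.frame mapping
#'   every input peak_id to its entity and region).
#' @export
cross_stage_overlap <- function(consensus_list, min_overlap = 0.5) {
  if (length(consensus_list) < 2L) stop("need >=2 stages")
  stages <- names(consensus_list)
  if (is.null(stages)) stop("consensus_list must be named by stage")
  pooled <- do.call(rbind, lapply(stages, function(s) {
    df <- consensus_list[[s]]
    data.frame(peak_id = df$peak_id, chrom = df$chrom, start = df$start,
               end = df$end, stage = s, stringsAsFactors = FALSE)
  }))
  n <- nrow(pooled)
  ed <- overlap_edges(pooled, min_overlap)
  cross <- pooled$stage[ed$i] != pooled$stage[ed$j]
  comp <- uf_components(n, ed$i[cross], ed$j[cross])
  groups <- split(seq_len(n), comp)
  ent <- do.call(rbind, lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    data.frame(entity = g,
               chrom = pooled$chrom[idx[1]],
               start = min(pooled$start[idx]),
               end = max(pooled$end[idx]),
               stages = paste(sort(unique(pooled$stage[idx])),
                              collapse = "&"),
               n_peaks = length(idx),
               peak_ids = paste(pooled$peak_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  region_levels <- unlist(lapply(seq_along(stages), function(k) {
    combn(stages, k, paste, collapse = "&", simplify = TRUE)
  }))
  counts <- table(factor(ent$stages, levels = region_levels))
  regions <- data.frame(region = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  entity_of <- integer(n)
  for (g in seq_along(groups)) entity_of[groups[[g]]] <- g
  peak_regions <- data.frame(peak_id = pooled$peak_id,
                             stage = pooled$stage,
                             entity = entity_of,
                             region = ent$stages[entity_of],
                             stringsAsFactors = FALSE)
  list(entities = ent, regions = regions, peak_regions = peak_regions)
}

# Internal: gene spans (transcript span incl. introns, over all isoforms)
gene_spans <- function(models) {
  tx <- models$transcripts
  lo <- vapply(models$exons[tx$transcript_id],
               function(e) min(e$start), integer(1))
  hi <- vapply(models$exons[tx$transcript_id],
               function(e) max(e$end), integer(1))
  agg_lo <- tapply(lo, tx$gene_id, min)
  agg_hi <- tapply(hi, tx$gene_id, max)
  chrom <- tapply(tx$chrom, tx$gene_id, `[`, 1)
  strand <- tapply(tx$strand, tx$gene_id, `[`, 1)
  max_len <- tapply(tx$tx_len, tx$gene_id, max)
  data.frame(gene_id = names(agg_lo), chrom = as.character(chrom),
             start = as.integer(agg_lo), end = as.integer(agg_hi),
             strand = as.character(strand),
             max_tx_len = as.integer(max_len),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign consensus peaks to genes by summit
#'
#' A peak is intragenic when its summit lies within a gene's transcript span
#' (exons plus introns, any isoform). A summit inside several overlapping
#' genes goes to the gene whose longest transcript is longest, ties broken
#' by gene_id order; all other peaks are `intergenic`.
#'
#' @param consensus A `consensus_peaks` data.frame (or any data.frame with
#'   peak_id, chrom, summit).
#' @param models A `tx_models` collection.
#' @return list with `assignment` (data.frame: peak_id, gene_id —
#'   "intergenic" where unassigned), `histogram` (table of peaks-per-gene
#'   counts over modified genes), `frac_le2` (fraction of modified genes
#'   with <= 2 peaks), and `frac_intragenic`.
#' @export
assign_genes <- function(consensus, models) {
  spans <- gene_spans(models)
  gr_gene <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1L,
                                                     spans$end))
  gr_sum <- GenomicRanges::GRanges(consensus$chrom,
                                   IRanges::IRanges(consensus$summit + 1L,
                                                    consensus$summit + 1L))
  hits <- GenomicRanges::findOverlaps(gr_sum, gr_gene)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  assignment <- data.frame(peak_id = consensus$peak_id,
                           gene_id = "intergenic",
                           stringsAsFactors = FALSE)
  if (length(qh)) {
    ord <- order(qh, -spans$max_tx_len[sh], spans$gene_id[sh])
    qh <- qh[ord]; sh <- sh[ord]
    first <- !duplicated(qh)
    assignment$gene_id[qh[first]] <- spans$gene_id[sh[first]]
  }
  modified <- assignment$gene_id[assignment$gene_id != "intergenic"]
  histogram <- table(table(modified))
  n_genes <- length(unique(modified))
  per_gene <- table(modified)
  frac_le2 <- if (n_genes) sum(per_gene <= 2) / n_genes else NA_real_
  list(assignment = assignment,
       histogram = histogram,
       frac_le2 = frac_le2,
       frac_intragenic = mean(assignment$gene_id != "intergenic"))
}
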