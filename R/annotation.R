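#' Load transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `gene_id "..."; transcript_id
#' "..."`) into a collection of transcript models carrying exon structure and,
#' where annotated, CDS boundaries. All internal coordinates are 0-based
#' half-open; the GTF's 1-based closed coordinates are converted at this
#' boundary. Minus-strand exons are stored in genomic order; coordinate
#' projection accounts for strand so that transcript position 0 is always the
#' 5' end of the transcript.
#'
#' Transcripts whose GTF records contain no `exon` feature are skipped with a
#' warning. A malformed line (fewer than 9 tab-separated fields, non-numeric
#' coordinates, or missing gene_id/transcript_id) raises an error naming the
#' line number.
#'
#' @param path Path to a GTF file (plain text).
#' @return An object of class `tx_models`: a list with elements
#'   `transcripts` (data.frame: transcript_id, gene_id, chrom, strand,
#'   tx_len, cds_tx_start, cds_tx_end — NA for non-coding), and `exons`
#'   (named list of data.frames with 0-based half-open `start`, `end`,
#'   sorted by start). Subset single models with `[[`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  raw <- readLines(path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  line_no <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0L) stop("GTF contains no feature lines: ", path)

  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GTF line ", line_no[which(nf < 9L)[1]],
         ": expected 9 tab-separated fields, found ", nf[which(nf < 9L)[1]])
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  feat <- m[, 3L]
  sel <- feat %in% c("exon", "CDS")
  if (!any(sel)) stop("GTF contains no exon or CDS features: ", path)
  m <- m[sel, , drop = FALSE]
  line_no <- line_no[sel]
  feat <- feat[sel]

  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    stop("malformed GTF line ", line_no[bad[1]], ": non-numeric coordinates")
  }
  gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9L])
  tx_id <- sub('.*transcript_id "([^"]+)".*', "\\1", m[, 9L])
  no_attr <- !grepl('gene_id "', m[, 9L], fixed = TRUE) |
    !grepl('transcript_id "', m[, 9L], fixed = TRUE)
  if (any(no_attr)) {
    stop("malformed GTF line ", line_no[which(no_attr)[1]],
         ": missing gene_id or transcript_id attribute")
  }

  df <- data.frame(
    tx_id = tx_id, gene_id = gene_id, chrom = m[, 1L],
    feature = feat, start = start1 - 1L, end = end1,  # to 0-based half-open
    strand = m[, 7L], stringsAsFactors = FALSE
  )
  is_exon <- df$feature == "exon"
  exon_tx <- unique(df$tx_id[is_exon])
  all_tx <- unique(df$tx_id)
  no_exon <- setdiff(all_tx, exon_tx)
  if (length(no_exon)) {
    warning("skipping ", length(no_exon),
            " transcript(s) with zero exons: ",
            paste(utils::head(no_exon, 5), collapse = ", "))
    df <- df[df$tx_id %in% exon_tx, , drop = FALSE]
    is_exon <- df$feature == "exon"
  }

  exon_list <- split(df[is_exon, c("start", "end"), drop = FALSE],
                     df$tx_id[is_exon])
  exon_list <- lapply(exon_list, function(e) {
    e <- e[order(e$start), , drop = FALSE]
    rownames(e) <- NULL
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("overlapping exons within one transcript")
    }
    e
  })

  first <- !duplicated(df$tx_id)
  tx <- data.frame(
    transcript_id = df$tx_id[first],
    gene_id = df$gene_id[first],
    chrom = df$chrom[first],
    strand = df$strand[first],
    stringsAsFactors = FALSE
  )
  tx <- tx[tx$transcript_id %in% exon_tx, , drop = FALSE]
  rownames(tx) <- NULL
  tx$tx_len <- vapply(exon_list[tx$transcript_id],
                      function(e) sum(e$end - e$start), integer(1))

  # CDS genomic extent per transcript, then projected to transcript coords
  cds <- df[df$feature == "CDS", , drop = FALSE]
  tx$cds_start_genomic <- NA_integer_
  tx$cds_end_genomic <- NA_integer_
  if (nrow(cds)) {
    cds_lo <- tapply(cds$start, cds$tx_id, min)
    cds_hi <- tapply(cds$end, cds$tx_id, max)
    idx <- match(tx$transcript_id, names(cds_lo))
    tx$cds_start_genomic <- as.integer(cds_lo[idx])
    tx$cds_end_genomic <- as.integer(cds_hi[idx])
  }

  models <- structure(list(transcripts = tx, exons = exon_list),
                      class = "tx_models")
  # project CDS to transcript coordinates once
  tx$cds_tx_start <- NA_integer_
  tx$cds_tx_end <- NA_integer_
  coding <- which(!is.na(tx$cds_start_genomic))
  for (i in coding) {
    mod <- model_at(models, i)
    lo <- genomic_to_tx(mod, tx$cds_start_genomic[i])
    hi <- genomic_to_tx(mod, tx$cds_end_genomic[i] - 1L)
    if (is.na(lo) || is.na(hi)) stop("CDS boundary outside exons for ",
                                     tx$transcript_id[i])
    tx$cds_tx_start[i] <- min(lo, hi)
    tx$cds_tx_end[i] <- max(lo, hi) + 1L
  }
  models$transcripts <- tx
  models
}

#' @export
print.tx_models <- function(x, ...) {
  tx <- x$transcripts
  cat("tx_models: ", nrow(tx), " transcripts, ",
      length(unique(tx$gene_id)), " genes (",
      sum(!is.na(tx$cds_tx_start)), " coding)\n", sep = "")
  invisible(x)
}

# Internal: materialize one transcript model (list) from row index
model_at <- function(models, i) {
  tx <- models$transcripts[i, ]
  structure(list(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = tx$chrom, strand = tx$strand,
    exons = models$exons[[tx$transcript_id]],
    tx_len = tx$tx_len,
    cds_start_genomic = tx$cds_start_genomic,
    cds_end_genomic = tx$cds_end_genomic,
    cds_tx_start = if ("cds_tx_start" %in% names(tx)) tx$cds_tx_start else NA_integer_,
    cds_tx_end = if ("cds_tx_end" %in% names(tx)) tx$cds_tx_end else NA_integer_
  ), class = "tx_model")
}

#' Extract one transcript model
#'
#' @param x A `tx_models` collection.
#' @param id A transcript_id (character) or row index.
#' @return A `tx_model` list with exon table and CDS coordinates.
#' @export
get_model <- function(x, id) {
  stopifnot(inherits(x, "tx_models"))
  i <- if (is.character(id)) match(id, x$transcripts$transcript_id) else id
  if (is.na(i)) stop("unknown transcript: ", id)
  model_at(x, i)
}

#' @export
`[[.tx_models` <- function(x, id) get_model(x, id)

#' Project genomic positions onto transcript coordinates
#'
#' Transcript coordinates are 0-based, 5' to 3' along the mature transcript
#' (strand-aware). Non-exonic positions return NA.
#'
#' @param model A `tx_model`.
#' @param gpos Integer vector of genomic positions (0-based).
#' @return Integer vector of transcript positions in `[0, tx_len)`, NA where
#'   the position is not exonic.
#' @export
genomic_to_tx <- function(model, gpos) {
  e <- model$exons
  cum <- cumsum(c(0L, e$end - e$start))
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_len(nrow(e))) {
    in_k <- gpos >= e$start[k] & gpos < e$end[k]
    out[in_k] <- cum[k] + (gpos[in_k] - e$start[k])
  }
  if (model$strand == "-") out <- ifelse(is.na(out), NA_integer_,
                                         model$tx_len - 1L - out)
  out
}

#' Project transcript positions back to genomic coordinates
#'
#' Inverse of [genomic_to_tx()] on exonic bases.
#'
#' @param model A `tx_model`.
#' @param tpos Integer vector of transcript positions in `[0, tx_len)`.
#' @return Integer vector of genomic positions; NA for out-of-range input.
#' @export
tx_to_genomic <- function(model, tpos) {
  e <- model$exons
  p <- tpos
  if (model$strand == "-") p <- model$tx_len - 1L - p
  cum <- cumsum(c(0L, e$end - e$start))
  out <- rep(NA_integer_, length(p))
  ok <- !is.na(p) & p >= 0L & p < model$tx_len
  k <- findInterval(p[ok], cum)  # exon index for each position
  out[ok] <- as.integer(e$start[k] + (p[ok] - cum[k]))
  out
}

#' Locate genomic positions relative to a transcript
#'
#' Classifies each position as `exonic` (with its transcript coordinate),
#' `intronic` (within the transcript's genomic span but not exonic), or
#' `outside` (beyond the span or on another chromosome).
#'
#' @param model A `tx_model`.
#' @param gpos Integer vector of genomic positions (0-based).
#' @param chrom Optional chromosome name(s) of the positions; positions on a
#'   different chromosome are `outside`.
#' @return data.frame with columns `genomic_pos`, `status`, `tx_pos`.
#' @export
locate <- function(model, gpos, chrom = NULL) {
  tpos <- genomic_to_tx(model, gpos)
  span_lo <- min(model$exons$start)
  span_hi <- max(model$exons$end)
  status <- ifelse(!is.na(tpos), "exonic",
                   ifelse(gpos >= span_lo & gpos < span_hi,
                          "intronic", "outside"))
  if (!is.null(chrom)) {
    wrong <- chrom != model$chrom
    status[wrong] <- "outside"
    tpos[wrong] <- NA_integer_
  }
  data.frame(genomic_pos = gpos, status = status, tx_pos = tpos,
             stringsAsFactors = FALSE)
}

#' Five-segment partition of a coding transcript
#'
#' Divides the transcript-coordinate interval `[0, L)` into five disjoint,
#' exhaustive segments: `TSS` (up to the first 200 nt of the transcript,
#' clipped to the 5'UTR), `UTR5` (remaining 5'UTR), `CDS`, `STOP` (a window
#' of up to `stop_window` nt centered on the first base of the stop codon —
#' i.e. the first base after the annotated CDS — clipped to the transcript),
#' and `UTR3` (remaining 3'UTR). CDS, UTR5, TSS and UTR3 are set-differenced
#' against the stop window, which takes precedence.
#'
#' @param model A coding `tx_model` (error for non-coding).
#' @param tss_len TSS segment length cap (nt), default 200.
#' @param stop_window Full width of the stop-codon window (nt), default 400.
#' @return data.frame of class `segment_partition` with columns
#'   `label`, `tx_start`, `tx_end` (empty segments have tx_start == tx_end),
#'   one row per label in order TSS, UTR5, CDS, STOP, UTR3.
#' @export
build_partition <- function(model, tss_len = 200L, stop_window = 400L) {
  L <- model$tx_len
  if (is.null(L) || L < 1L) stop("transcript shorter than 1 nt")
  if (is.na(model$cds_tx_start)) {
    stop("non-coding transcript excluded from segment analyses: ",
         model$transcript_id)
  }
  cs <- model$cds_tx_start
  ce <- model$cds_tx_end
  half <- stop_window %/% 2L
  stop_lo <- max(0L, ce - half)
  stop_hi <- min(L, ce + half)

  # base intervals before removing the stop window
  tss <- c(0L, min(tss_len, cs))
  utr5 <- c(min(tss_len, cs), cs)
  cdsb <- c(cs, ce)
  utr3 <- c(ce, L)

  clip <- function(iv) {
    # subtract [stop_lo, stop_hi); result is a single interval because the
    # window is anchored at the CDS end (see partition invariants)
    lo <- iv[1]; hi <- iv[2]
    if (hi <= stop_lo || lo >= stop_hi) return(c(lo, hi))
    if (lo >= stop_lo && hi <= stop_hi) return(c(lo, lo))
    if (lo < stop_lo) return(c(lo, stop_lo))
    c(stop_hi, hi)
  }
  tss <- clip(tss); utr5 <- clip(utr5); cdsb <- clip(cdsb); utr3 <- clip(utr3)

  out <- data.frame(
    label = c("TSS", "UTR5", "CDS", "STOP", "UTR3"),
    tx_start = c(tss[1], utr5[1], cdsb[1], stop_lo, utr3[1]),
    tx_end = c(tss[2], utr5[2], cdsb[2], stop_hi, utr3[2]),
    stringsAsFactors = FALSE
  )
  attr(out, "transcript_id") <- model$transcript_id
  attr(out, "tx_len") <- L
  class(out) <- c("segment_partition", "data.frame")
  out
}

#' Segment label for transcript positions
#'
#' @param partition A `segment_partition`.
#' @param tpos Integer vector of transcript positions.
#' @return Character vector of labels (NA outside `[0, L)`).
#' @export
segment_of <- function(partition, tpos) {
  out <- rep(NA_character_, length(tpos))
  for (i in seq_len(nrow(partition))) {
    hit <- tpos >= partition$tx_start[i] & tpos < partition$tx_end[i]
    out[hit & is.na(out)] <- partition$label[i]
  }
  out
}

#' Representative (longest coding) transcript per gene
#'
#' Metagene and segment analyses use one isoform per gene: the longest
#' coding transcript, ties broken by transcript_id.
#'
#' @param models A `tx_models` collection.
#' @return Named character vector: gene_id -> transcript_id (coding genes
#'   only).
#' @export
representative_transcripts <- function(models) {
  tx <- models$transcripts
  tx <- tx[!is.na(tx$cds_tx_start), , drop = FALSE]
  if (nrow(tx) == 0L) return(stats::setNames(character(0), character(0)))
  tx <- tx[order(tx$gene_id, -tx$tx_len, tx$transcript_id), , drop = FALSE]
  tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  stats::setNames(tx$transcript_id, tx$gene_id)
}

#' Build partitions for all representative coding transcripts
#'
#' @param models A `tx_models` collection.
#' @param ... Passed to [build_partition()].
#' @return Named list of `segment_partition` objects keyed by transcript_id.
#' @export
build_partitions <- function(models, ...) {
  reps <- representative_transcripts(models)
  out <- lapply(reps, function(id) build_partition(get_model(models, id), ...))
  stats::setNames(out, unname(reps))
}

#' Transcriptome-wide segment length table
#'
#' Sums the five segment lengths over a set of partitions (by default the
#' representative coding transcript of each gene) and reports the fraction
#' of the transcriptome each segment occupies — the normalizer for relative
#' segment enrichment.
#'
#' @param partitions Named list of `segment_partition` objects (e.g. from
#'   [build_partitions()]).
#' @return data.frame of class `segment_length_table` with columns `label`,
#'   `length`, `fraction`; fractions sum to 1.
#' @export
segment_length_table <- function(partitions) {
  if (length(partitions) == 0L) stop("empty model set")
  labs <- c("TSS", "UTR5", "CDS", "STOP", "UTR3")
  tot <- stats::setNames(numeric(5), labs)
  for (p in partitions) {
    len <- p$tx_end - p$tx_start
    tot[p$label] <- tot[p$label] + len
  }
  out <- data.frame(label = labs, length = as.numeric(tot),
                    fraction = as.numeric(tot) / sum(tot),
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_length_table", "data.frame")
  out
}

#' Write a set of partitions as TSV
#'
#' Columns: transcript_id, label, tx_start, tx_end.
#' @param partitions Named list of `segment_partition` objects.
#' @param path Output TSV path.
#' @export
write_segment_table <- function(partitions, path) {
  rows <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(transcript_id = attr(p, "transcript_id"),
               label = p$label, tx_start = p$tx_start, tx_end = p$tx_end,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
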