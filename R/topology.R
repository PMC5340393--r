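#' Extended transcript coordinate of a genomic position
#'
#' Coordinate system used by the metagene axis: exonic positions map to
#' their transcript coordinate in `[0, L)`; genomic positions upstream of
#' the transcript 5' end map to negative values (distance upstream), and
#' positions downstream of the 3' end to `L + distance`. Intronic positions
#' do not map (NA).
#'
#' @param model A `tx_model`.
#' @param gpos Genomic positions (0-based).
#' @param chrom Optional chromosome names.
#' @return Numeric vector of extended transcript coordinates, NA where the
#'   position is intronic or on the wrong chromosome.
#' @export
extended_tx_coord <- function(model, gpos, chrom = NULL) {
  tpos <- as.numeric(genomic_to_tx(model, gpos))
  span_lo <- min(model$exons$start)
  span_hi <- max(model$exons$end)
  upstream <- is.na(tpos) & gpos < span_lo
  downstream <- is.na(tpos) & gpos >= span_hi
  if (model$strand == "+") {
    tpos[upstream] <- gpos[upstream] - span_lo
    tpos[downstream] <- model$tx_len + (gpos[downstream] - span_hi)
  } else {
    tpos[downstream] <- span_hi - 1 - gpos[downstream]
    tpos[upstream] <- model$tx_len + (span_lo - 1 - gpos[upstream])
  }
  if (!is.null(chrom)) tpos[chrom != model$chrom] <- NA_real_
  tpos
}

#' Metagene bin of a summit
#'
#' The metagene axis has 300 bins: bins 0-99 cover the 2,000 nt 5' of the
#' CDS start (20 nt per bin, through the 5'UTR and into genomic flank where
#' the UTR is shorter), bins 100-199 the length-scaled CDS, and bins
#' 200-299 the 2,000 nt 3' of the CDS end. Summits farther than 2,000 nt
#' from the CDS, or intronic summits, are "outside" (NA).
#'
#' @param model A coding `tx_model`.
#' @param summit_gpos Genomic summit positions.
#' @param chrom Optional chromosome names.
#' @param flank Flank width in nt, default 2000.
#' @param bins_per_part Bins per axis part, default 100.
#' @return Integer bin indices in `[0, 3*bins_per_part)`, NA = outside.
#' @export
metagene_bin <- function(model, summit_gpos, chrom = NULL,
                         flank = 2000, bins_per_part = 100L) {
  if (is.na(model$cds_tx_start)) stop("non-coding model has no metagene axis")
  ext <- extended_tx_coord(model, summit_gpos, chrom)
  cs <- model$cds_tx_start
  ce <- model$cds_tx_end
  cds_len <- ce - cs
  x <- ext - cs
  y <- ext - ce
  bin <- rep(NA_integer_, length(ext))
  bw <- flank / bins_per_part
  in5 <- !is.na(x) & x < 0 & x >= -flank
  bin[in5] <- as.integer(bins_per_part + floor(x[in5] / bw))
  incds <- !is.na(x) & x >= 0 & ext < ce
  bin[incds] <- as.integer(bins_per_part +
                             floor(x[incds] / cds_len * bins_per_part))
  in3 <- !is.na(y) & y >= 0 & y < flank
  bin[in3] <- as.integer(2L * bins_per_part + floor(y[in3] / bw))
  bin
}

#' Trailing moving average
#'
#' Window-of-`k` trailing mean: output bin `i` is the mean of bins
#' `i-k+1 ... i`; the first `k-1` bins carry the raw values.
#'
#' @param x Numeric vector.
#' @param k Window size, default 4.
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, k = 4L) {
  n <- length(x)
  out <- x
  if (n >= k) {
    cs <- cumsum(x)
    out[k:n] <- (cs[k:n] - c(0, cs[seq_len(n - k)])) / k
  }
  out
}

#' Metagene summit profile
#'
#' Bins every summit on its host gene's representative transcript axis and
#' reports the percentage of mapped summits per bin, raw and smoothed with a
#' 4-bin trailing moving average.
#'
#' @param summits data.frame with chrom, summit, gene_id (host gene; peaks
#'   assigned to non-coding or intergenic space are skipped).
#' @param models A `tx_models` collection.
#' @param flank,bins_per_part See [metagene_bin()].
#' @param ma_window Moving-average window, default 4.
#' @return data.frame of class `metagene_profile` with columns bin
#'   (0-based), part ("flank5"/"CDS"/"flank3"), raw_pct, smoothed_pct;
#'   attribute `n_mapped` = summits inside the window.
#' @export
metagene_profile <- function(summits, models, flank = 2000,
                             bins_per_part = 100L, ma_window = 4L) {
  reps <- representative_transcripts(models)
  nb <- 3L * bins_per_part
  counts <- numeric(nb)
  n_mapped <- 0L
  for (g in unique(summits$gene_id)) {
    tx_id <- reps[g]
    if (is.na(tx_id)) next
    model <- get_model(models, tx_id)
    rows <- summits$gene_id == g
    b <- metagene_bin(model, summits$summit[rows],
                      chrom = summits$chrom[rows],
                      flank = flank, bins_per_part = bins_per_part)
    b <- b[!is.na(b)]
    n_mapped <- n_mapped + length(b)
    if (length(b)) counts <- counts + tabulate(b + 1L, nbins = nb)
  }
  if (n_mapped == 0L) stop("no summits map into the metagene window")
  raw <- counts / n_mapped * 100
  out <- data.frame(
    bin = 0:(nb - 1L),
    part = rep(c("flank5", "CDS", "flank3"), each = bins_per_part),
    raw_pct = raw,
    smoothed_pct = moving_average(raw, ma_window),
    stringsAsFactors = FALSE
  )
  attr(out, "n_mapped") <- n_mapped
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Five-segment summit frequencies and normalized enrichment
#'
#' Assigns each summit to exactly one segment of its host transcript's
#' partition, reports per-segment counts and percentages (over assigned
#' summits), and the relative enrichment = percentage / (100 x the fraction
#' of the transcriptome the segment occupies).
#'
#' @param summits data.frame with chrom, summit, gene_id.
#' @param models A `tx_models` collection.
#' @param partitions Named list of partitions (default built from `models`).
#' @param length_table A `segment_length_table` (default from `partitions`).
#' @return data.frame of class `segment_frequency_table`: label, count,
#'   pct, transcriptome_fraction, norm_enrichment.
#' @export
segment_frequencies <- function(summits, models, partitions = NULL,
                                length_table = NULL) {
  if (is.null(partitions)) partitions <- build_partitions(models)
  if (is.null(length_table)) length_table <- segment_length_table(partitions)
  reps <- representative_transcripts(models)
  labs <- c("TSS", "UTR5", "CDS", "STOP", "UTR3")
  counts <- stats::setNames(integer(5), labs)
  for (g in unique(summits$gene_id)) {
    tx_id <- reps[g]
    if (is.na(tx_id) || !tx_id %in% names(partitions)) next
    model <- get_model(models, tx_id)
    rows <- summits$gene_id == g
    loc <- locate(model, summits$summit[rows], chrom = summits$chrom[rows])
    tp <- loc$tx_pos[loc$status == "exonic"]
    if (!length(tp)) next
    seg <- segment_of(partitions[[tx_id]], tp)
    tb <- table(factor(seg, levels = labs))
    counts <- counts + as.integer(tb)
  }
  total <- sum(counts)
  pct <- if (total) counts / total * 100 else rep(0, 5)
  frac <- length_table$fraction[match(labs, length_table$label)]
  out <- data.frame(label = labs, count = as.integer(counts),
                    pct = as.numeric(pct),
                    transcriptome_fraction = frac,
                    norm_enrichment = ifelse(frac > 0,
                                             as.numeric(pct) / (100 * frac),
                                             0),
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_frequency_table", "data.frame")
  out
}
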