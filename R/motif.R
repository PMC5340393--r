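#' The 12 RRACH consensus 5-mers
#'
#' R = A/G (purine), central A (the methylated adenosine), C, H = A/C/T
#' (non-guanine).
#'
#' @return Character vector of the 12 RRACH instances.
#' @export
rrach_variants <- function() {
  v <- expand.grid(r1 = c("A", "G"), r2 = c("A", "G"),
                   h = c("A", "C", "T"), stringsAsFactors = FALSE)
  sort(paste0(v$r1, v$r2, "AC", v$h))
}

#' Scan a sequence for RRACH consensus sites
#'
#' Reports every (overlapping) offset whose 5-mer matches
#' `[AG][AG]AC[ACT]`; `N` never matches.
#'
#' @param sequence A single character string over A/C/G/T/N (case
#'   insensitive).
#' @return data.frame with `offset` (0-based start within the sequence) and
#'   `fivemer`; zero rows for sequences shorter than 5.
#' @export
scan_rrach <- function(sequence) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 5L) {
    return(data.frame(offset = integer(0), fivemer = character(0),
                      stringsAsFactors = FALSE))
  }
  i <- seq_len(n - 4L)
  hit <- (s[i] == "A" | s[i] == "G") &
    (s[i + 1L] == "A" | s[i + 1L] == "G") &
    s[i + 2L] == "A" & s[i + 3L] == "C" &
    (s[i + 4L] == "A" | s[i + 4L] == "C" | s[i + 4L] == "T")
  off <- i[hit] - 1L
  data.frame(offset = off,
             fivemer = vapply(off, function(o) {
               paste(s[(o + 1L):(o + 5L)], collapse = "")
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Scan for an exact 5-mer (control patterns)
#'
#' @param sequence A single character string.
#' @param pattern A 5-mer over A/C/G/T (exact match, no ambiguity codes)
#'   or "RRACH" for the consensus.
#' @return Integer vector of 0-based offsets.
#' @export
scan_pattern <- function(sequence, pattern) {
  if (toupper(pattern) == "RRACH") return(scan_rrach(sequence)$offset)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  k <- length(p)
  n <- length(s)
  if (n < k) return(integer(0))
  i <- seq_len(n - k + 1L)
  hit <- rep(TRUE, length(i))
  for (d in seq_len(k)) hit <- hit & s[i + d - 1L] == p[d]
  i[hit] - 1L
}

# Internal: fetch a clipped window around a summit from a DNAStringSet
# genome; returns list(seq = character, offset_shift = left clipping).
summit_window <- function(genome, chrom, summit, window) {
  half <- (window - 1L) %/% 2L
  if (!chrom %in% names(genome)) return(NULL)
  len <- Biostrings::width(genome[chrom])
  lo <- max(1L, summit + 1L - half)           # 1-based inclusive
  hi <- min(len, summit + 1L + half)
  if (lo > hi) return(NULL)
  list(seq = as.character(Biostrings::subseq(genome[[chrom]], lo, hi)),
       start0 = lo - 1L)
}

# Internal: strand of the host gene per peak ("+"/"-"/NA for intergenic)
peak_strands <- function(consensus, assignment, models) {
  spans <- gene_spans(models)
  gid <- assignment$gene_id[match(consensus$peak_id, assignment$peak_id)]
  spans$strand[match(gid, spans$gene_id)]
}

#' RRACH content of peaks
#'
#' Extracts the `window`-nt sequence centered on each consensus summit
#' (clipped at chromosome ends), scans for RRACH on the host gene's strand
#' (reverse complement for minus-strand genes; intergenic peaks are scanned
#' on both strands and count once), and reports the fraction of peaks with
#' at least one hit plus the frequency table over the 12 RRACH variants.
#'
#' @param consensus `consensus_peaks` data.frame (peak_id, chrom, summit).
#' @param genome A named `DNAStringSet` (or path to a FASTA file).
#' @param strand Optional character vector of per-peak strands ("+", "-",
#'   NA = intergenic/unknown); defaults to NA for all peaks.
#' @param window Window width (nt), default 101.
#' @return list with `fraction` (peaks with >=1 hit / peaks scanned),
#'   `n_peaks`, `n_with_hit`, `variants` (data.frame fivemer, count, pct —
#'   pct over all hits), and `hits` (data.frame peak_id, offset, fivemer).
#' @export
peak_motif_stats <- function(consensus, genome, strand = NULL,
                             window = 101L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.null(strand)) strand <- rep(NA_character_, nrow(consensus))
  hits_list <- vector("list", nrow(consensus))
  scanned <- logical(nrow(consensus))
  for (i in seq_len(nrow(consensus))) {
    w <- summit_window(genome, consensus$chrom[i], consensus$summit[i],
                       window)
    if (is.null(w)) {
      warning("summit on missing chromosome, peak skipped: ",
              consensus$peak_id[i])
      next
    }
    scanned[i] <- TRUE
    seqs <- if (is.na(strand[i])) {
      c(w$seq, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(w$seq))))
    } else if (strand[i] == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(w$seq)))
    } else {
      w$seq
    }
    h <- do.call(rbind, lapply(seqs, scan_rrach))
    if (nrow(h)) {
      h <- h[!duplicated(h), , drop = FALSE]
      h$peak_id <- consensus$peak_id[i]
      hits_list[[i]] <- h
    }
  }
  hits <- do.call(rbind, hits_list)
  if (is.null(hits)) {
    hits <- data.frame(offset = integer(0), fivemer = character(0),
                       peak_id = character(0), stringsAsFactors = FALSE)
  }
  n_peaks <- sum(scanned)
  n_with_hit <- length(unique(hits$peak_id))
  vt <- table(factor(hits$fivemer, levels = rrach_variants()))
  variants <- data.frame(fivemer = names(vt), count = as.integer(vt),
                         pct = if (sum(vt)) as.integer(vt) / sum(vt) * 100
                               else rep(0, length(vt)),
                         stringsAsFactors = FALSE)
  list(fraction = if (n_peaks) n_with_hit / n_peaks else NA_real_,
       n_peaks = n_peaks, n_with_hit = n_with_hit,
       variants = variants,
       hits = hits[, c("peak_id", "offset", "fivemer")])
}

#' Positional motif density around summits
#'
#' For each pattern, computes the per-position start-site indicator in a
#' `window`-nt window centered on every summit, averages over windows, and
#' then averages within `bin`-nt position bins — the central-enrichment
#' profile. Windows clipped at chromosome ends are padded out of the
#' average (positions outside contribute nothing).
#'
#' @param consensus `consensus_peaks` data.frame.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param patterns Character vector of 5-mers and/or "RRACH".
#' @param strand Optional per-peak strand vector as in
#'   [peak_motif_stats()].
#' @param window Window width, default 301.
#' @param bin Position bin width, default 40 (the last bin may be shorter).
#' @return data.frame of class `positional_density`: pattern, bin_start
#'   (0-based window position), bin_end, density (mean per-position
#'   occurrence), n_windows.
#' @export
positional_density <- function(consensus, genome, patterns = c(
                                 "GGACT", "GGACA", "GGACC", "GCAGC"),
                               strand = NULL, window = 301L, bin = 40L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.null(strand)) strand <- rep(NA_character_, nrow(consensus))
  half <- (window - 1L) %/% 2L
  occ <- matrix(0, nrow = length(patterns), ncol = window,
                dimnames = list(patterns, NULL))
  cov <- numeric(window)  # how many windows cover each position
  n_windows <- 0L
  for (i in seq_len(nrow(consensus))) {
    w <- summit_window(genome, consensus$chrom[i], consensus$summit[i],
                       window)
    if (is.null(w)) next
    n_windows <- n_windows + 1L
    # position of window start within the ideal [summit-half, summit+half]
    shift <- w$start0 - (consensus$summit[i] - half)
    span <- nchar(w$seq)
    cov[(shift + 1L):(shift + span)] <- cov[(shift + 1L):(shift + span)] + 1
    seqs <- if (is.na(strand[i]) || strand[i] == "+") w$seq else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(w$seq)))
    for (p in patterns) {
      off <- scan_pattern(seqs, p)
      if (strand[i] %in% "-") {
        # map minus-strand offsets back onto plus-strand window positions
        off <- span - (off + nchar(p))
      }
      pos <- shift + off + 1L
      if (length(pos)) occ[p, pos] <- occ[p, pos] + 1
    }
  }
  bin_starts <- seq(0L, window - 1L, by = bin)
  rows <- do.call(rbind, lapply(patterns, function(p) {
    dens <- vapply(bin_starts, function(b) {
      idx <- (b + 1L):min(b + bin, window)
      denom <- sum(cov[idx])
      if (denom > 0) sum(occ[p, idx]) / denom else 0
    }, numeric(1))
    data.frame(pattern = p, bin_start = bin_starts,
               bin_end = pmin(bin_starts + bin, window),
               density = dens, n_windows = n_windows,
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("positional_density", "data.frame")
  rows
}
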