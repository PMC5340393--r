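#' Fragment-peak counting rule
#'
#' A fragment is counted for a peak when the overlap covers at least half of
#' the fragment or at least half of the peak. Vectorized; different
#' chromosomes never hit.
#'
#' @param frag_start,frag_end Fragment coordinates (0-based half-open).
#' @param peak_start,peak_end Peak coordinates.
#' @param frag_chrom,peak_chrom Optional chromosome names.
#' @return Logical vector.
#' @export
fragment_hits_peak <- function(frag_start, frag_end, peak_start, peak_end,
                               frag_chrom = NULL, peak_chrom = NULL) {
  ov <- pmax(0L, pmin(frag_end, peak_end) - pmax(frag_start, peak_start))
  hit <- ov >= 0.5 * (frag_end - frag_start) | ov >= 0.5 * (peak_end - peak_start)
  if (!is.null(frag_chrom) && !is.null(peak_chrom)) {
    hit[frag_chrom != peak_chrom] <- FALSE
  }
  hit
}

#' Read fragments from a BED3+library file
#'
#' Expects 4 tab-separated columns: chrom, start, end, library id. No header.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, library.
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "library"))
  df$library <- as.character(df$library)
  df
}

#' Count fragments per peak per library
#'
#' Applies [fragment_hits_peak()] between every fragment and every peak on
#' the same chromosome; each fragment contributes at most one count to each
#' peak it hits (a fragment overlapping two peaks increments both).
#'
#' @param fragments data.frame with chrom, start, end, library.
#' @param peaks data.frame with peak_id, chrom, start, end.
#' @param libraries Optional character vector fixing column order/universe;
#'   defaults to the libraries present. An empty library is an error.
#' @return Integer matrix peaks x libraries (dimnames peak_id / library)
#'   with attribute `library_sizes` = total fragments per library.
#' @export
count_fragments <- function(fragments, peaks, libraries = NULL) {
  if (is.null(libraries)) libraries <- sort(unique(fragments$library))
  sizes <- table(factor(fragments$library, levels = libraries))
  if (any(sizes == 0L)) {
    stop("empty library: ", names(sizes)[which(sizes == 0L)[1]])
  }
  gr_f <- GenomicRanges::GRanges(fragments$chrom,
                                 IRanges::IRanges(fragments$start + 1L,
                                                  fragments$end))
  gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L,
                                                  peaks$end))
  hits <- GenomicRanges::findOverlaps(gr_f, gr_p)
  fi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  ok <- fragment_hits_peak(fragments$start[fi], fragments$end[fi],
                           peaks$start[pi], peaks$end[pi])
  fi <- fi[ok]; pi <- pi[ok]
  mat <- matrix(0L, nrow = nrow(peaks), ncol = length(libraries),
                dimnames = list(peaks$peak_id, libraries))
  if (length(fi)) {
    tab <- table(factor(pi, levels = seq_len(nrow(peaks))),
                 factor(fragments$library[fi], levels = libraries))
    mat[] <- as.integer(tab)
  }
  attr(mat, "library_sizes") <- stats::setNames(as.integer(sizes), libraries)
  mat
}

#' Fragments per million
#'
#' @param counts Numeric vector/matrix of fragment counts.
#' @param library_size Total mapped fragments of the library (recycled over
#'   matrix columns).
#' @return counts scaled to fragments per million.
#' @export
fpm <- function(counts, library_size) {
  if (is.matrix(counts)) {
    sweep(counts, 2L, library_size / 1e6, "/")
  } else {
    counts / (library_size / 1e6)
  }
}

#' Library design table
#'
#' Convenience constructor/validator for the library metadata every
#' quantification step needs.
#'
#' @param library Character library ids (must match count-matrix columns).
#' @param stage Stage label per library.
#' @param replicate Integer replicate id per library.
#' @param type "IP" or "input".
#' @param size Total mapped fragments per library.
#' @return data.frame of class `library_design`.
#' @export
library_design <- function(library, stage, replicate, type, size) {
  type <- match.arg(type, c("IP", "input"), several.ok = TRUE)
  df <- data.frame(library = library, stage = stage,
                   replicate = as.integer(replicate), type = type,
                   size = as.numeric(size), stringsAsFactors = FALSE)
  class(df) <- c("library_design", "data.frame")
  df
}

#' Per-peak IP/input enrichment
#'
#' For every peak and replicate, enrichment = (IP FPM + eps) / (input FPM +
#' eps); the stage-level statistic is the arithmetic mean of replicate log2
#' enrichments. Every IP library must have an input partner (same stage and
#' replicate).
#'
#' @param counts Count matrix (peaks x libraries) as from
#'   [count_fragments()] or [read_count_matrix()].
#' @param design A `library_design`; sizes taken from here (falling back to
#'   the matrix's `library_sizes` attribute when `size` is NA).
#' @param pseudocount_fpm Symmetric pseudo-count eps in FPM units, default
#'   0.25, keeping ratios finite for zero-input peaks.
#' @return list with `replicate_log2` (matrix peaks x stage.replicate of
#'   log2 enrichment), `stage_log2` (matrix peaks x stages), and `records`
#'   (long data.frame: peak_id, stage, replicate, ip_count, input_count,
#'   ip_fpm, input_fpm, enrichment, log2_enrichment).
#' @export
peak_enrichment <- function(counts, design, pseudocount_fpm = 0.25) {
  sizes <- design$size
  attr_sizes <- attr(counts, "library_sizes")
  if (any(is.na(sizes)) && !is.null(attr_sizes)) {
    sizes[is.na(sizes)] <- attr_sizes[design$library[is.na(sizes)]]
  }
  design$size <- sizes
  ip <- design[design$type == "IP", , drop = FALSE]
  input <- design[design$type == "input", , drop = FALSE]
  key <- function(d) paste(d$stage, d$replicate, sep = ".")
  idx <- match(key(ip), key(input))
  if (any(is.na(idx))) {
    stop("IP library without input partner: ",
         ip$library[which(is.na(idx))[1]])
  }
  input <- input[idx, , drop = FALSE]

  ip_fpm <- fpm(counts[, ip$library, drop = FALSE], ip$size)
  in_fpm <- fpm(counts[, input$library, drop = FALSE], input$size)
  ratio <- (ip_fpm + pseudocount_fpm) / (in_fpm + pseudocount_fpm)
  rep_log2 <- log2(ratio)
  colnames(rep_log2) <- key(ip)

  stages <- unique(ip$stage)
  stage_log2 <- sapply(stages, function(s) {
    rowMeans(rep_log2[, ip$stage == s, drop = FALSE])
  })
  stage_log2 <- matrix(stage_log2, nrow = nrow(counts),
                       dimnames = list(rownames(counts), stages))

  records <- data.frame(
    peak_id = rep(rownames(counts), times = nrow(ip)),
    stage = rep(ip$stage, each = nrow(counts)),
    replicate = rep(ip$replicate, each = nrow(counts)),
    ip_count = as.vector(counts[, ip$library]),
    input_count = as.vector(counts[, input$library]),
    ip_fpm = as.vector(ip_fpm),
    input_fpm = as.vector(in_fpm),
    enrichment = as.vector(ratio),
    log2_enrichment = as.vector(rep_log2),
    stringsAsFactors = FALSE
  )
  list(replicate_log2 = rep_log2, stage_log2 = stage_log2,
       records = records, design = design)
}

# Internal: exon-union length per gene (merged across isoforms)
gene_exon_lengths <- function(models) {
  tx <- models$transcripts
  per_gene <- split(tx$transcript_id, tx$gene_id)
  out <- vapply(per_gene, function(ids) {
    ex <- do.call(rbind, models$exons[ids])
    ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    sum(IRanges::width(ir))
  }, numeric(1))
  out
}

#' Count fragments per gene (exon-union, ambiguous discarded)
#'
#' A fragment is assigned to a gene when it overlaps the gene's exons by at
#' least one base; fragments overlapping the exons of more than one gene are
#' discarded as ambiguous.
#'
#' @param fragments data.frame with chrom, start, end, library.
#' @param models A `tx_models` collection.
#' @param libraries Optional library universe (columns).
#' @return Integer matrix genes x libraries with attribute `library_sizes`.
#' @export
gene_counts_from_fragments <- function(fragments, models, libraries = NULL) {
  if (is.null(libraries)) libraries <- sort(unique(fragments$library))
  sizes <- table(factor(fragments$library, levels = libraries))
  tx <- models$transcripts
  ex <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    e <- models$exons[[tx$transcript_id[i]]]
    data.frame(gene_id = tx$gene_id[i], chrom = tx$chrom[i],
               start = e$start, end = e$end, stringsAsFactors = FALSE)
  }))
  genes <- sort(unique(tx$gene_id))
  gr_e <- GenomicRanges::GRanges(ex$chrom,
                                 IRanges::IRanges(ex$start + 1L, ex$end))
  gr_f <- GenomicRanges::GRanges(fragments$chrom,
                                 IRanges::IRanges(fragments$start + 1L,
                                                  fragments$end))
  hits <- GenomicRanges::findOverlaps(gr_f, gr_e)
  fi <- S4Vectors::queryHits(hits)
  gi <- ex$gene_id[S4Vectors::subjectHits(hits)]
  # unique (fragment, gene) pairs; fragments hitting >1 gene are ambiguous
  pair <- !duplicated(paste(fi, gi))
  fi <- fi[pair]; gi <- gi[pair]
  n_genes_per_frag <- table(factor(fi, levels = unique(fi)))
  ambiguous <- as.integer(names(n_genes_per_frag)[n_genes_per_frag > 1L])
  keep <- !(fi %in% ambiguous)
  fi <- fi[keep]; gi <- gi[keep]
  mat <- matrix(0L, nrow = length(genes), ncol = length(libraries),
                dimnames = list(genes, libraries))
  if (length(fi)) {
    tab <- table(factor(gi, levels = genes),
                 factor(fragments$library[fi], levels = libraries))
    mat[] <- as.integer(tab)
  }
  attr(mat, "library_sizes") <- stats::setNames(as.integer(sizes), libraries)
  mat
}

#' Gene expression as FPKM with expressed-gene flag
#'
#' FPKM = count / (exon kb x library size in millions), computed per input
#' library; the stage value is the mean over that stage's input replicates,
#' and a gene is "expressed" in a stage when its mean FPKM exceeds the
#' threshold.
#'
#' @param gene_counts Matrix genes x input libraries.
#' @param gene_lengths Named numeric vector of exon-union lengths (nt); a
#'   zero-length gene is an error.
#' @param design `library_design` rows for the input libraries involved.
#' @param expressed_fpkm_threshold Default 0.1.
#' @return list with `fpkm` (matrix genes x libraries), `stage_fpkm`
#'   (matrix genes x stages), `expressed` (logical matrix genes x stages),
#'   and `table` (long data.frame).
#' @export
gene_fpkm <- function(gene_counts, gene_lengths, design,
                      expressed_fpkm_threshold = 0.1) {
  design <- design[design$type == "input", , drop = FALSE]
  sizes <- design$size
  attr_sizes <- attr(gene_counts, "library_sizes")
  if (any(is.na(sizes)) && !is.null(attr_sizes)) {
    sizes[is.na(sizes)] <- attr_sizes[design$library[is.na(sizes)]]
  }
  len <- gene_lengths[rownames(gene_counts)]
  if (any(is.na(len) | len <= 0)) {
    stop("zero-length gene: ",
         rownames(gene_counts)[which(is.na(len) | len <= 0)[1]])
  }
  counts <- gene_counts[, design$library, drop = FALSE]
  fpkm_mat <- sweep(fpm(counts, sizes), 1L, len / 1000, "/")
  stages <- unique(design$stage)
  stage_fpkm <- sapply(stages, function(s) {
    rowMeans(fpkm_mat[, design$stage == s, drop = FALSE])
  })
  stage_fpkm <- matrix(stage_fpkm, nrow = nrow(counts),
                       dimnames = list(rownames(counts), stages))
  expressed <- stage_fpkm > expressed_fpkm_threshold
  tab <- data.frame(
    gene_id = rep(rownames(stage_fpkm), times = length(stages)),
    stage = rep(stages, each = nrow(stage_fpkm)),
    mean_fpkm = as.vector(stage_fpkm),
    expressed = as.vector(expressed),
    stringsAsFactors = FALSE
  )
  list(fpkm = fpkm_mat, stage_fpkm = stage_fpkm, expressed = expressed,
       table = tab)
}

#' Read a precomputed count matrix (TSV)
#'
#' First column = row id (peak or gene), remaining columns = libraries.
#'
#' @param path TSV path (header line required).
#' @return Integer matrix with dimnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count matrix as TSV
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (id) column.
#' @export
write_count_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
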