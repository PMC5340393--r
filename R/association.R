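#' Fraction of methylated genes as a function of expression level
#'
#' Ranks expressed genes by log10 stage-mean FPKM, cuts them into
#' `n_bins` equal-count bins, and reports per bin the fraction of genes
#' carrying at least one peak — overall and per five-segment location of
#' the peak summit.
#'
#' @param stage_fpkm Named numeric vector: stage-mean FPKM per gene
#'   (expressed genes only, > 0).
#' @param gene_segments Named list: gene_id -> character vector of segment
#'   labels in which the gene has peak summits (may be empty); genes absent
#'   from the list are unmethylated.
#' @param n_bins Number of equal-count expression bins, default 20.
#' @return data.frame of class `expression_bin_curve`: bin (1-based,
#'   ascending expression), n_genes, median_log10_fpkm, then one fraction
#'   column per segment plus `any`.
#' @export
fraction_vs_expression <- function(stage_fpkm, gene_segments,
                                   n_bins = 20L) {
  n <- length(stage_fpkm)
  if (n < n_bins) stop("fewer genes than bins")
  ord <- order(stage_fpkm, names(stage_fpkm))
  genes <- names(stage_fpkm)[ord]
  lg <- log10(stage_fpkm[ord])
  # equal-count bins: sizes differ by at most one
  bin_of <- as.integer(ceiling(seq_len(n) / n * n_bins))
  labs <- c("TSS", "UTR5", "CDS", "STOP", "UTR3")
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    g <- genes[bin_of == b]
    segs <- gene_segments[g]
    has <- function(lab) {
      mean(vapply(segs, function(x) !is.null(x) && lab %in% x, logical(1)))
    }
    row <- data.frame(bin = b, n_genes = length(g),
                      median_log10_fpkm = stats::median(lg[bin_of == b]),
                      stringsAsFactors = FALSE)
    for (lab in labs) row[[lab]] <- has(lab)
    row$any <- mean(vapply(segs, function(x) !is.null(x) && length(x) > 0,
                           logical(1)))
    row
  }))
  class(out) <- c("expression_bin_curve", "data.frame")
  out
}

#' Pearson correlation of peak enrichment and host-gene expression
#'
#' Classical product-moment correlation (via `stats::cor.test`) between
#' stage-level log2 peak enrichment and log2(stage-mean FPKM + eps) of the
#' host gene, over a filtered scope of peaks.
#'
#' @param log2_enrichment Numeric vector (one value per peak).
#' @param gene_fpkm Numeric vector of host-gene stage-mean FPKM, parallel
#'   to `log2_enrichment`.
#' @param scope Optional label stored in the result.
#' @param eps Pseudo-FPKM inside the log, default 0.01.
#' @return data.frame of class `correlation_result`: scope, n, r, p.
#' @export
enrichment_expression_correlation <- function(log2_enrichment, gene_fpkm,
                                              scope = "all", eps = 0.01) {
  keep <- is.finite(log2_enrichment) & is.finite(gene_fpkm)
  x <- log2_enrichment[keep]
  y <- log2(gene_fpkm[keep] + eps)
  if (length(x) < 3L) stop("need n >= 3 for a correlation")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate correlation input: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- data.frame(scope = scope, n = length(x),
                    r = unname(ct$estimate), p = ct$p.value,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Per-base coverage tracks for one gene (profile export)
#'
#' Per-base fragment depth over the gene's genomic span, per library class
#' (IP and input), together with the consensus peaks overlapping the span —
#' the ingredients of a single-gene methylation/expression profile figure.
#'
#' @param gene_id Gene of interest.
#' @param fragments data.frame with chrom, start, end, library.
#' @param design `library_design` mapping libraries to IP/input.
#' @param consensus `consensus_peaks` data.frame (may span several stages
#'   when row-bound).
#' @param models A `tx_models` collection.
#' @return list with `span` (chrom/start/end), `coverage` (data.frame:
#'   pos, depth_ip, depth_input — bedGraph-style per-base rows), and
#'   `peaks` (consensus rows overlapping the span).
#' @export
gene_profile_export <- function(gene_id, fragments, design, consensus,
                                models) {
  spans <- gene_spans(models)
  sp <- spans[spans$gene_id == gene_id, , drop = FALSE]
  if (nrow(sp) == 0L) stop("unknown gene: ", gene_id)
  lo <- sp$start; hi <- sp$end
  frag <- fragments[fragments$chrom == sp$chrom &
                      fragments$end > lo & fragments$start < hi, ,
                    drop = FALSE]
  depth_for <- function(libs) {
    d <- numeric(hi - lo)
    f <- frag[frag$library %in% libs, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      a <- max(f$start[i], lo) - lo + 1L
      b <- min(f$end[i], hi) - lo
      d[a:b] <- d[a:b] + 1
    }
    d
  }
  ip_libs <- design$library[design$type == "IP"]
  in_libs <- design$library[design$type == "input"]
  coverage <- data.frame(pos = lo:(hi - 1L),
                         depth_ip = depth_for(ip_libs),
                         depth_input = depth_for(in_libs))
  pk <- consensus[consensus$chrom == sp$chrom & consensus$end > lo &
                    consensus$start < hi, , drop = FALSE]
  list(span = sp, coverage = coverage, peaks = pk)
}

#' Write a per-base coverage track as bedGraph
#'
#' Collapses runs of equal depth into bedGraph intervals.
#'
#' @param coverage data.frame with pos and a depth column.
#' @param chrom Chromosome name.
#' @param depth_col Which column to export.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, chrom, depth_col, path) {
  d <- coverage[[depth_col]]
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  df <- data.frame(chrom = chrom,
                   start = coverage$pos[1] + starts,
                   end = coverage$pos[1] + ends,
                   depth = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
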