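#' Tiny hand-checkable fixture dataset
#'
#' A deterministic in-memory dataset small enough to verify every analysis
#' stage by hand: three genes (one minus-strand, one non-coding) on one
#' 6,000-nt chromosome whose background sequence (ACGT repeats) contains no
#' RRACH site, GGACT planted at two peak summits, three replicate peak sets
#' for one stage (one peak in all three replicates, one in two, one in a
#' single replicate), and a handful of fragments across one IP and one
#' input library.
#'
#' @return list with `models` (tx_models), `genome` (DNAStringSet),
#'   `replicate_peaks` (data.frame of replicate peak calls, stage "s1"),
#'   `fragments`, `design` (library_design), and `notes` describing the
#'   planted expectations.
#' @export
tiny_fixture <- function() {
  gtf <- c(
    'chrT\tfix\texon\t101\t600\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\tfix\texon\t701\t1200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\tfix\tCDS\t251\t600\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\tfix\tCDS\t701\t950\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\tfix\texon\t2001\t2500\t.\t-\t.\tgene_id "G2"; transcript_id "T2";',
    'chrT\tfix\tCDS\t2101\t2400\t.\t-\t.\tgene_id "G2"; transcript_id "T2";',
    'chrT\tfix\texon\t3001\t3300\t.\t+\t.\tgene_id "G3"; transcript_id "T3";'
  )
  tmp <- tempfile(fileext = ".gtf")
  writeLines(gtf, tmp)
  models <- load_annotation(tmp)
  unlink(tmp)

  base <- strrep("ACGT", 1500)  # 6000 nt, RRACH-free
  s <- strsplit(base, "")[[1]]
  plant <- function(s, pos0, motif) {  # 0-based start
    s[(pos0 + 1):(pos0 + nchar(motif))] <- strsplit(motif, "")[[1]]
    s
  }
  s <- plant(s, 298, "GGACT")   # centered on summit 300 of peak A
  s <- plant(s, 2248, "AGTCC")  # reverse complement of GGACT, minus strand
  genome <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(genome) <- "chrT"

  replicate_peaks <- data.frame(
    chrom = "chrT",
    start = c(250, 255, 245,   900, 905,   2200),
    end = c(450, 455, 445,   1100, 1105,   2400),
    name = c("A", "A", "A", "B", "B", "C"),
    score = c(100, 120, 90, 80, 85, 60),
    summit = c(300, 300, 300, 950, 950, 2250),
    stage = "s1",
    replicate = c(1L, 2L, 3L, 1L, 2L, 3L),
    stringsAsFactors = FALSE)

  fragments <- data.frame(
    chrom = "chrT",
    start = c(280, 300, 350, 2150,   260, 320, 3050),
    end = c(430, 450, 500, 2300,   410, 470, 3200),
    library = c("s1.r1.IP", "s1.r1.IP", "s1.r1.IP", "s1.r1.IP",
                "s1.r1.input", "s1.r1.input", "s1.r1.input"),
    stringsAsFactors = FALSE)

  design <- library_design(
    library = c("s1.r1.IP", "s1.r1.input"),
    stage = "s1", replicate = 1L,
    type = c("IP", "input"), size = c(4, 3))

  list(models = models, genome = genome,
       replicate_peaks = replicate_peaks, fragments = fragments,
       design = design,
       notes = paste(
         "Peak A: 3 replicates, summit 300, GGACT planted;",
         "peak B: 2 replicates, summit 950 (no motif);",
         "peak C: single replicate, dropped by consensus."))
}
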