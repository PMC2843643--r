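#' Build promoter window ranges around TSS coordinates
#'
#' Constructs the 2,700-bp promoter windows (`[tss - 2200, tss + 500)` in
#' transcription orientation, 0-based half-open genomic coordinates) for a
#' table of TSS positions. On the minus strand the window is
#' `(tss - 500, tss + 2200]` in genome coordinates, so that after
#' reverse-complementation the sequence still reads upstream-to-downstream.
#'
#' @param tss_table data.frame with columns `promoter_id`, `chrom`, `tss`
#'   (0-based TSS coordinate) and `strand` (`"+"` or `"-"`).
#' @param grid Sub-bin grid defining the window extent.
#' @return A `GenomicRanges::GRanges` with names set to `promoter_id`.
#' @export
promoter_windows <- function(tss_table, grid = subbin_grid()) {
  require_bioc(c("GenomicRanges", "IRanges"))
  stopifnot(all(c("promoter_id", "chrom", "tss", "strand") %in%
                  names(tss_table)))
  if (!all(tss_table$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  up <- -grid$start[1L]                  # 2200
  down <- grid$end[nrow(grid)]           # 500
  plus <- tss_table$strand == "+"
  start0 <- ifelse(plus, tss_table$tss - up, tss_table$tss - down + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = tss_table$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, width = up + down),
    strand = tss_table$strand
  )
  names(gr) <- tss_table$promoter_id
  gr
}

#' Read promoter windows from a 6-column BED file
#'
#' @param bed_file Path to a BED file whose records are the promoter
#'   windows (not the TSS positions); the `name` field is the promoter id.
#' @return A `GRanges` named by promoter id.
#' @export
read_promoter_windows <- function(bed_file) {
  require_bioc("rtracklayer")
  gr <- rtracklayer::import(bed_file, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Extract promoter window sequences in transcription orientation
#'
#' Minus-strand windows are reverse-complemented, so position 1 of every
#' returned sequence is 2,200 bp upstream of the TSS.
#'
#' @param genome A named `Biostrings::DNAStringSet` (one entry per
#'   chromosome) or a path to a FASTA file.
#' @param windows `GRanges` of promoter windows, e.g. from
#'   [promoter_windows()] or [read_promoter_windows()].
#' @return A `DNAStringSet` named by promoter id.
#' @export
extract_promoter_sequences <- function(genome, windows) {
  require_bioc(c("Biostrings", "GenomicRanges"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chr <- as.character(GenomicRanges::seqnames(windows))
  missing_chr <- setdiff(unique(chr), names(genome))
  if (length(missing_chr)) {
    stop("chromosomes absent from genome: ", paste(missing_chr, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(windows), function(i) {
    s <- Biostrings::subseq(genome[[chr[i]]],
                            start = GenomicRanges::start(windows)[i],
                            end = GenomicRanges::end(windows)[i])
    if (as.character(GenomicRanges::strand(windows))[i] == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    s
  }))
  names(seqs) <- names(windows)
  seqs
}

#' Compute CpG features for a set of promoter sequences
#'
#' @param sequences A `DNAStringSet`, a named character vector of sequences
#'   in transcription orientation, or a path to a FASTA file.
#' @param grid Sub-bin grid.
#' @return data.frame with columns `promoter_id`, `cpg_count` and
#'   `cpg_bin1..cpg_bin6`.
#' @export
promoter_cpg_features <- function(sequences, grid = subbin_grid()) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    require_bioc("Biostrings")
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (!is.character(sequences)) {
    seq_chr <- as.character(sequences)
  } else {
    seq_chr <- sequences
  }
  ids <- names(seq_chr)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seq_chr))
  counts <- lapply(seq_chr, count_cpg, grid = grid)
  per <- do.call(rbind, lapply(counts, `[[`, "per_subbin"))
  colnames(per) <- paste0("cpg_", grid$bin)
  out <- data.frame(promoter_id = ids,
                    cpg_count = vapply(counts, `[[`, integer(1L), "total"),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(per))
}

require_bioc <- function(pkgs) {
  for (p in pkgs) {
    if (!requireNamespace(p, quietly = TRUE)) {
      stop("package '", p, "' is required for sequence/range I/O")
    }
  }
  invisible(TRUE)
}
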