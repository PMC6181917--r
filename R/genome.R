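#' Read a genome FASTA into a named sequence set
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to the first whitespace-delimited token so sequences are
#' addressable by chromosome name.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch genomic sequence, strand-aware
#'
#' Extracts `[start, end)` (0-based half-open) from `chrom` and returns the
#' reverse complement for `-` strand queries, i.e. the sequence as read by
#' the spliceosome.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param chrom,start,end,strand Vectors describing the intervals
#'   (recycled to common length).
#' @return Character vector of sequences.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  if (any(!chrom %in% names(genome))) {
    stop_spliceland("chromosome(s) absent from genome: %s",
                    paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(start < 0L) || any(end > lens[chrom]) || any(end < start)) {
    stop_spliceland("sequence query outside chromosome bounds")
  }
  out <- character(n)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    v <- Biostrings::Views(genome[[cn]], start = start[idx] + 1L, end = end[idx])
    s <- as.character(v)
    neg <- strand[idx] == "-"
    if (any(neg)) {
      s[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s[neg])))
    }
    out[idx] <- s
  }
  out
}
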