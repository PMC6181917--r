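# Builders for small hand-specified fixtures used across tests.

# exon table from a list of (start, end) pairs per transcript
make_models <- function(..., chrom = "chr1", strand = "+", gene_id = "g1",
                        novelty = "known") {
  txs <- list(...)
  if (is.null(names(txs)) || any(!nzchar(names(txs)))) {
    names(txs) <- paste0("t", seq_along(txs))
  }
  dplyr::bind_rows(lapply(names(txs), function(id) {
    ex <- txs[[id]]
    tibble::tibble(chrom = chrom, start = as.integer(ex[, 1]),
                   end = as.integer(ex[, 2]), strand = strand,
                   feature = "exon", gene_id = gene_id, transcript_id = id,
                   novelty = novelty)
  }))
}

ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# genome with one chromosome built from an explicit sequence
make_genome <- function(seq, chrom = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

# a junction tibble row
jrow <- function(start, end, dedup, perfect = dedup, chrom = "chr1",
                 strand = "+", sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 reads_total = as.integer(dedup),
                 reads_dedup = as.integer(dedup),
                 reads_perfect = as.integer(perfect),
                 reads_mismatch = as.integer(dedup - perfect),
                 novelty = "unassigned")
}
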