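#' Extract introns from transcript models
#'
#' An intron is the gap between two consecutive exons of the same
#' transcript. A transcript with `k` exons yields `k - 1` introns; its exons
#' and introns tile the transcript's genomic span. Introns longer than 50 kb
#' are flagged `enormous` (a length class of biological interest because
#' such introns are disproportionately hard to splice and to assemble).
#'
#' @param models Exon table (see [read_gtf()]).
#' @return A tibble with columns `chrom`, `strand`, `gene_id`,
#'   `transcript_id`, `intron_index`, `start`, `end`, `length`, `novelty`,
#'   `enormous`.
#' @examples
#' m <- tibble::tibble(chrom = "chr1", start = c(0L, 200L, 400L),
#'   end = c(100L, 300L, 500L), strand = "+", feature = "exon",
#'   gene_id = "g", transcript_id = "t", novelty = "known")
#' extract_introns(m)
#' @export
extract_introns <- function(models) {
  exons <- models %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::arrange(.data$transcript_id, .data$start)
  introns <- exons %>%
    dplyr::group_by(.data$chrom, .data$strand, .data$gene_id,
                    .data$transcript_id, .data$novelty) %>%
    dplyr::reframe({
      es <- .data$start
      ee <- .data$end
      tibble::tibble(
        intron_index = seq_len(max(length(es) - 1L, 0L)),
        start = utils::head(ee, -1L),
        end = utils::tail(es, -1L)
      )
    }) %>%
    dplyr::mutate(length = .data$end - .data$start,
                  enormous = .data$length > 50000L)
  if (any(introns$length < 1L)) {
    bad <- introns[introns$length < 1L, ][1, ]
    stop_spliceland("zero-length intron (abutting exons) in transcript %s at %s:%d",
                    bad$transcript_id, bad$chrom, bad$start)
  }
  introns
}

#' Classify introns as constitutive or alternative within each gene
#'
#' An intron is *constitutive* when it appears with an identical span in
#' every isoform of its gene whose genomic span contains the intron;
#' otherwise it is *alternative*. Restricting the universality requirement
#' to isoforms that cover the intron keeps isoforms truncated at either end
#' (e.g. alternative transcription start/polyadenylation) from turning
#' shared internal introns into alternative ones.
#'
#' @param models Exon table (see [read_gtf()]).
#' @return One row per distinct intron span: `chrom`, `strand`, `gene_id`,
#'   `start`, `end`, `length`, `novelty`, `status`
#'   (`"constitutive"`/`"alternative"`).
#' @export
classify_intron_status <- function(models) {
  introns <- extract_introns(models)
  spans <- models %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(tx_start = min(.data$start), tx_end = max(.data$end),
                     .groups = "drop")
  uniq <- introns %>%
    dplyr::group_by(.data$chrom, .data$strand, .data$gene_id,
                    .data$start, .data$end, .data$length) %>%
    dplyr::summarise(
      novelty = if (all(.data$novelty == "known")) "known" else "novel",
      carriers = list(unique(.data$transcript_id)),
      .groups = "drop"
    )
  status <- purrr::pmap_chr(
    list(uniq$gene_id, uniq$start, uniq$end, uniq$carriers),
    function(gid, s, e, carriers) {
      covering <- spans$transcript_id[spans$gene_id == gid &
                                        spans$tx_start <= s & spans$tx_end >= e]
      if (length(covering) > 0L && all(covering %in% carriers)) {
        "constitutive"
      } else {
        "alternative"
      }
    }
  )
  uniq %>%
    dplyr::mutate(status = status) %>%
    dplyr::select(-"carriers")
}

#' Pick the representative (longest) isoform of each gene
#'
#' The representative isoform is the transcript with the greatest summed
#' exon length (mature transcript length, not genomic span). Ties break to
#' the smaller genomic start coordinate, then lexicographically by
#' transcript id, so the choice is deterministic.
#'
#' @param models Exon table (see [read_gtf()]).
#' @return A tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `exonic_length`, `tx_start`, `tx_end`.
#' @export
longest_isoform <- function(models) {
  models %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(
      exonic_length = sum(.data$end - .data$start),
      tx_start = min(.data$start), tx_end = max(.data$end),
      .groups = "drop_last"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$exonic_length), .data$tx_start,
                   .data$transcript_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
}

# per-transcript CDS span (min start, max end over CDS records)
cds_spans <- function(models) {
  cds <- dplyr::filter(models, .data$feature == "CDS")
  if (nrow(cds) == 0L) {
    return(tibble::tibble(gene_id = character(), transcript_id = character(),
                          cds_start = integer(), cds_end = integer()))
  }
  cds %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(cds_start = min(.data$start), cds_end = max(.data$end),
                     .groups = "drop")
}

#' Partition genes into 5'UTR / CDS / 3'UTR regions
#'
#' For each gene the representative (longest) isoform's genomic span is
#' split at its CDS boundaries into three non-overlapping regions that tile
#' the span. Labels are strand-aware: on the `-` strand the 5'UTR is the
#' genomically downstream (right) segment. Genes whose representative
#' isoform carries no CDS are left out (their events are later labelled
#' `unpartitioned`).
#'
#' @param models Exon table (see [read_gtf()]).
#' @return A tibble `gene_id`, `chrom`, `strand`, `region`
#'   (`"5UTR"`, `"CDS"`, `"3UTR"`), `start`, `end`; zero-width regions are
#'   dropped.
#' @export
partition_regions <- function(models) {
  rep_iso <- longest_isoform(models)
  cds <- cds_spans(models)
  info <- models %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::distinct(.data$gene_id, .data$chrom, .data$strand)
  joined <- rep_iso %>%
    dplyr::inner_join(cds, by = c("gene_id", "transcript_id")) %>%
    dplyr::inner_join(info, by = "gene_id")
  if (nrow(joined) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), region = character(),
                          start = integer(), end = integer()))
  }
  bad <- joined$cds_start < joined$tx_start | joined$cds_end > joined$tx_end
  if (any(bad)) {
    stop_spliceland("CDS span outside transcript span for gene %s",
                    joined$gene_id[which(bad)[1]])
  }
  purrr::pmap_dfr(
    joined[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
               "cds_start", "cds_end")],
    function(gene_id, chrom, strand, tx_start, tx_end, cds_start, cds_end) {
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        region = if (strand == "+") c("5UTR", "CDS", "3UTR")
                 else c("3UTR", "CDS", "5UTR"),
        start = c(tx_start, cds_start, cds_end),
        end = c(cds_start, cds_end, tx_end)
      )
    }
  ) %>%
    dplyr::filter(.data$end > .data$start)
}
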