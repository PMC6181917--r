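#' Read transcript models from a GTF file
#'
#' Parses `exon` (and, when present, `CDS`) features into a tidy exon table,
#' the package's representation of gene/transcript models. GTF coordinates
#' (1-based, inclusive) are converted to the internal 0-based half-open
#' convention, so an exon printed as `1 100` in the file becomes
#' `start = 0, end = 100`.
#'
#' @param path Path to a GTF file.
#' @param genome Optional genome sequence set (a named
#'   [Biostrings::DNAStringSet]); when supplied, features are validated
#'   against chromosome bounds.
#' @return A tibble with one row per exon/CDS feature and columns
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `feature`
#'   (`"exon"` or `"CDS"`), `gene_id`, `transcript_id`, `novelty`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", 1, 100, ".", "+", ".",
#'   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' read_gtf(gtf)
#' @export
read_gtf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_spliceland("GTF file not found: %s", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  keep <- meta$type %in% c("exon", "CDS")
  meta <- meta[keep, , drop = FALSE]
  if (nrow(meta) == 0L) stop_spliceland("GTF contains no exon/CDS features: %s", path)
  novelty <- if ("novelty" %in% names(meta)) {
    dplyr::coalesce(as.character(meta$novelty), "known")
  } else {
    rep("known", nrow(meta))
  }
  models <- tibble::tibble(
    chrom = as.character(meta$seqnames),
    start = as.integer(meta$start) - 1L,
    end = as.integer(meta$end),
    strand = as.character(meta$strand),
    feature = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id),
    novelty = novelty
  ) %>%
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$feature, .data$start)
  validate_models(models, genome = genome)
  models
}

# cheap structural scan so parse errors carry a line number (rtracklayer's
# own errors do not)
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) {
      stop_spliceland("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                      i, length(fields))
    }
    s <- suppressWarnings(as.integer(fields[4]))
    e <- suppressWarnings(as.integer(fields[5]))
    if (is.na(s) || is.na(e)) {
      stop_spliceland("malformed GTF line %d: non-numeric coordinates", i)
    }
    if (e < s) {
      stop_spliceland("malformed GTF line %d: end (%d) < start (%d)", i, e, s)
    }
  }
  invisible(TRUE)
}

validate_models <- function(models, genome = NULL) {
  exons <- dplyr::filter(models, .data$feature == "exon")
  if (any(exons$end <= exons$start)) {
    stop_spliceland("exon with non-positive length found")
  }
  # exons of a transcript must be disjoint and sorted
  bad <- exons %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::summarise(
      ok = all(diff(.data$start) > 0) && all(utils::head(.data$end, -1) <= utils::tail(.data$start, -1)),
      n_strand = dplyr::n_distinct(.data$strand),
      n_chrom = dplyr::n_distinct(.data$chrom),
      .groups = "drop"
    ) %>%
    dplyr::filter(!.data$ok | .data$n_strand > 1L | .data$n_chrom > 1L)
  if (nrow(bad) > 0L) {
    stop_spliceland("overlapping/unsorted exons or mixed chrom/strand in transcript(s): %s",
                    paste(utils::head(bad$transcript_id, 5), collapse = ", "))
  }
  if (!is.null(genome)) {
    lens <- tibble::tibble(chrom = names(genome),
                           chrom_len = Biostrings::width(genome))
    oob <- models %>%
      dplyr::left_join(lens, by = "chrom") %>%
      dplyr::filter(is.na(.data$chrom_len) | .data$end > .data$chrom_len | .data$start < 0L)
    if (nrow(oob) > 0L) {
      stop_spliceland("%d feature(s) outside chromosome bounds (first: %s:%d-%d)",
                      nrow(oob), oob$chrom[1], oob$start[1], oob$end[1])
    }
  }
  invisible(models)
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive GTF fields. Round-tripping a model
#' table through `write_gtf()`/[read_gtf()] preserves coordinates,
#' identifiers and the novelty label.
#'
#' @param models Exon table as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "spliceland") {
  models <- dplyr::arrange(models, .data$chrom, .data$gene_id,
                           .data$transcript_id,
                           factor(.data$feature, levels = c("exon", "CDS")),
                           .data$start)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; novelty "%s";',
                   models$gene_id, models$transcript_id, models$novelty)
  lines <- paste(models$chrom, source, models$feature,
                 models$start + 1L, models$end, ".", models$strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
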