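#' Read a STAR-style splice-junction table (`SJ.out.tab` dialect)
#'
#' Columns: chrom, 1-based first and last intronic base, strand code
#' (0 undefined, 1 `+`, 2 `-`), motif code, annotated flag, unique-read
#' count, multi-mapping read count, max overhang. Coordinates are converted
#' to 0-based half-open intron spans. The dialect carries no PCR-duplicate
#' or mismatch metadata, so unique reads are taken as deduplicated,
#' perfectly matching support (`reads_mismatch = 0`); tables with such
#' metadata are produced by [dedup_support()] or the simulator.
#'
#' @param path Path to the tab-separated file (no header).
#' @param sample_id Optional sample label attached to every row.
#' @return A junction tibble: `sample_id`, `chrom`, `strand`, `start`,
#'   `end`, `reads_total`, `reads_dedup`, `reads_perfect`,
#'   `reads_mismatch`, `novelty`.
#' @export
read_star_sj <- function(path, sample_id = NA_character_) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "first_base", "last_base",
                                     "strand_code", "motif", "annotated",
                                     "reads_unique", "reads_multi", "overhang"),
                       col_types = "ciiiiiiii", progress = FALSE)
  tibble::tibble(
    sample_id = sample_id,
    chrom = x$chrom,
    strand = c("*", "+", "-")[x$strand_code + 1L],
    start = x$first_base - 1L,
    end = x$last_base,
    reads_total = x$reads_unique + x$reads_multi,
    reads_dedup = x$reads_unique,
    reads_perfect = x$reads_unique,
    reads_mismatch = 0L,
    novelty = "unassigned"
  )
}

#' Read a BED12 junction track (TopHat `junctions.bed` dialect)
#'
#' Each BED12 record is a two-block anchor pair; the intron span is
#' derived from the block layout: intron start = chromStart + blockSizes
#' of block 1, intron end = chromStart + blockStarts of block 2. The score
#' column is the supporting read count (taken as deduplicated perfect
#' support, as for [read_star_sj()]).
#'
#' @inheritParams read_star_sj
#' @return A junction tibble (see [read_star_sj()]).
#' @export
read_junctions_bed <- function(path, sample_id = NA_character_) {
  x <- readr::read_tsv(path, col_names = c(
    "chrom", "chromStart", "chromEnd", "name", "score", "strand",
    "thickStart", "thickEnd", "itemRgb", "blockCount", "blockSizes",
    "blockStarts"), col_types = "ciiciciicicc", comment = "track",
    progress = FALSE)
  sizes <- strsplit(x$blockSizes, ",")
  starts <- strsplit(x$blockStarts, ",")
  size1 <- vapply(sizes, function(v) as.integer(v[1]), integer(1))
  start2 <- vapply(starts, function(v) as.integer(v[2]), integer(1))
  tibble::tibble(
    sample_id = sample_id,
    chrom = x$chrom,
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"),
    start = x$chromStart + size1,
    end = x$chromStart + start2,
    reads_total = x$score,
    reads_dedup = x$score,
    reads_perfect = x$score,
    reads_mismatch = 0L,
    novelty = "unassigned"
  )
}

#' Collapse junction-supporting read records into deduplicated support
#'
#' PCR duplicates are defined as records with identical alignment
#' endpoints supporting the same junction; each duplicate set collapses to
#' one read. Perfect/mismatch tallies are computed on the collapsed set
#' (a duplicate set inherits the minimum mismatch count of its members,
#' i.e. the best copy).
#'
#' @param records Tibble of junction-spanning read records with columns
#'   `chrom`, `strand`, `start`, `end` (junction span), `aln_start`,
#'   `aln_end` (alignment endpoints) and `mismatches`.
#' @param sample_id Optional sample label.
#' @return A junction tibble (see [read_star_sj()]).
#' @export
dedup_support <- function(records, sample_id = NA_character_) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), reads_total = integer(),
                          reads_dedup = integer(), reads_perfect = integer(),
                          reads_mismatch = integer(), novelty = character()))
  }
  records %>%
    dplyr::group_by(.data$chrom, .data$strand, .data$start, .data$end) %>%
    dplyr::summarise(
      reads_total = dplyr::n(),
      collapsed = list(
        dplyr::summarise(
          dplyr::group_by(dplyr::pick(dplyr::everything()),
                          .data$aln_start, .data$aln_end),
          mismatches = min(.data$mismatches), .groups = "drop")),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      reads_dedup = purrr::map_int(.data$collapsed, nrow),
      reads_perfect = purrr::map_int(.data$collapsed,
                                     ~ sum(.x$mismatches == 0L)),
      reads_mismatch = .data$reads_dedup - .data$reads_perfect,
      sample_id = .env$sample_id,
      novelty = "unassigned"
    ) %>%
    dplyr::select("sample_id", "chrom", "strand", "start", "end",
                  "reads_total", "reads_dedup", "reads_perfect",
                  "reads_mismatch", "novelty")
}

#' Filter splice junctions on read support
#'
#' Applies, in order, the three evidence rules used to clean a junction
#' set before assembly:
#' \describe{
#'   \item{R1 `min_reads`}{junctions supported by fewer than `min_reads`
#'     deduplicated reads are removed (default 2);}
#'   \item{R2 `mismatch_only`}{junctions supported exclusively by reads
#'     carrying mismatches are removed;}
#'   \item{R3 `near_perfect`}{junctions with any mismatch-carrying support
#'     whose donor or acceptor lies within `proximity_nt` of the
#'     corresponding site of a different junction that has perfectly
#'     matching support are removed (alignment wobble moves one splice
#'     site, so the distance is measured per site, donor-to-donor and
#'     acceptor-to-acceptor, on the same chromosome and compatible
#'     strand).}
#' }
#' Filtering is idempotent: re-filtering the kept set removes nothing.
#'
#' @param sj Junction tibble (see [read_star_sj()]); multiple samples may
#'   be present, rules are applied within each `sample_id`.
#' @param min_reads Minimum deduplicated read support (R1), default 2.
#' @param proximity_nt Site distance for R3, default 10.
#' @param apply_r2,apply_r3 Logical toggles for the two mismatch rules.
#' @return `sj` with logical `kept` and character `reason`
#'   (`NA` when kept, else `"R1"`, `"R2"` or `"R3"`).
#' @export
filter_junctions <- function(sj, min_reads = 2L, proximity_nt = 10L,
                             apply_r2 = TRUE, apply_r3 = TRUE) {
  if (!"sample_id" %in% names(sj)) sj$sample_id <- NA_character_
  sj %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::group_modify(~ filter_junctions_one(.x, min_reads, proximity_nt,
                                               apply_r2, apply_r3)) %>%
    dplyr::ungroup()
}

filter_junctions_one <- function(sj, min_reads, proximity_nt,
                                 apply_r2, apply_r3) {
  reason <- rep(NA_character_, nrow(sj))
  reason[sj$reads_dedup < min_reads] <- "R1"
  if (apply_r2) {
    reason[is.na(reason) & sj$reads_perfect == 0L] <- "R2"
  }
  if (apply_r3) {
    refs <- sj[sj$reads_dedup >= min_reads & sj$reads_perfect >= 1L, ,
               drop = FALSE]
    cand <- which(is.na(reason) & sj$reads_mismatch >= 1L)
    for (i in cand) {
      same <- refs$chrom == sj$chrom[i] &
        (refs$strand == sj$strand[i] | refs$strand == "*" | sj$strand[i] == "*") &
        !(refs$start == sj$start[i] & refs$end == sj$end[i])
      if (any(same &
              (abs(refs$start - sj$start[i]) <= proximity_nt |
               abs(refs$end - sj$end[i]) <= proximity_nt))) {
        reason[i] <- "R3"
      }
    }
  }
  sj %>% dplyr::mutate(kept = is.na(reason), reason = reason)
}

#' Classify junctions as known or novel against an annotation
#'
#' A junction is *known* when its exact intron span (and strand, when both
#' strands are defined) matches an intron of the annotation; otherwise it
#' is *novel*.
#'
#' @param sj Junction tibble.
#' @param models Exon table of the annotation (see [read_gtf()]).
#' @return `sj` with `novelty` set to `"known"` or `"novel"`.
#' @export
classify_novelty <- function(sj, models) {
  ann <- extract_introns(models) %>%
    dplyr::distinct(.data$chrom, .data$strand, .data$start, .data$end)
  stranded <- dplyr::semi_join(sj, ann,
                               by = c("chrom", "strand", "start", "end"))
  unstranded <- dplyr::semi_join(
    dplyr::filter(sj, .data$strand == "*"),
    dplyr::distinct(ann, .data$chrom, .data$start, .data$end),
    by = c("chrom", "start", "end"))
  key <- function(d) paste(d$sample_id, d$chrom, d$strand, d$start, d$end)
  known <- key(sj) %in% c(key(stranded), key(unstranded))
  dplyr::mutate(sj, novelty = ifelse(known, "known", "novel"))
}
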