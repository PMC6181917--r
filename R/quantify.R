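#' Percent spliced in
#'
#' `PSI = counts_EII / (counts_EII + counts_EEI)`: the fraction of
#' junction evidence supporting the exon-inclusion isoform. Undefined
#' (`NA`) when the event has no junction evidence at all.
#'
#' @param counts_EII,counts_EEI Non-negative integer vectors of
#'   inclusion/exclusion junction read support.
#' @return Numeric vector in `[0, 1]` (NA where both counts are zero).
#' @examples
#' psi(6, 2) # 0.75
#' @export
psi <- function(counts_EII, counts_EEI) {
  if (any(counts_EII < 0) || any(counts_EEI < 0)) {
    stop_spliceland("psi: negative counts")
  }
  total <- counts_EII + counts_EEI
  ifelse(total > 0, counts_EII / total, NA_real_)
}

#' AS score
#'
#' `AS score = (PSI - 0.5) / 0.5`, a linear rescaling of PSI to
#' `[-1, 1]`: -1 means only the exon-exclusion isoform is expressed, +1
#' only the exon-inclusion isoform, and 0 equal expression of both.
#'
#' @param psi Numeric vector of PSI values in `[0, 1]` (NA propagates).
#' @return Numeric vector in `[-1, 1]`.
#' @examples
#' as_score(c(0, 0.5, 1)) # -1 0 1
#' @export
as_score <- function(psi) {
  if (any(psi < 0 | psi > 1, na.rm = TRUE)) {
    stop_spliceland("as_score: psi outside [0, 1]")
  }
  (psi - 0.5) / 0.5
}

#' FPKM
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `1e9 * fragments / (transcript_length_nt * library_fragments)`. Plain
#' per-library normalisation; no effective-length correction.
#'
#' @param fragments Fragment count(s) assigned to the transcript.
#' @param transcript_length_nt Mature transcript length in nt (> 0).
#' @param library_fragments Total mapped fragments in the library (> 0).
#' @return Numeric vector of FPKM values.
#' @examples
#' fpkm(100, 1000, 1e6) # 100
#' @export
fpkm <- function(fragments, transcript_length_nt, library_fragments) {
  if (any(transcript_length_nt <= 0) || any(library_fragments <= 0)) {
    stop_spliceland("fpkm: transcript length and library size must be positive")
  }
  1e9 * fragments / (transcript_length_nt * library_fragments)
}

#' Count junction support for events, per sample
#'
#' For each event and sample, `counts_EII` is the summed deduplicated read
#' support over the event's inclusion junctions and `counts_EEI` over its
#' exclusion junctions. Retained-intron events have no inclusion junction;
#' their inclusion evidence comes from `retention`, a per-intron count of
#' reads lying inside the retained interval (supplied by the simulator or
#' an external counter), keeping this module alignment-free.
#'
#' @param events Event catalog from [detect_events()].
#' @param junctions Filtered junction tibble with `sample_id`, `chrom`,
#'   `start`, `end`, `reads_dedup` (use the `kept` rows of
#'   [filter_junctions()]).
#' @param retention Optional tibble `sample_id`, `chrom`, `start`, `end`,
#'   `count` with retention read counts for RI intron intervals.
#' @param samples Optional sample sheet (`sample_id` column); samples
#'   listed there but absent from `junctions` get zero counts with a
#'   warning.
#' @return Long tibble: `event_id`, `event_type`, `sample_id`,
#'   `counts_EII`, `counts_EEI`, `psi`, `as_score`.
#' @export
count_event_support <- function(events, junctions, retention = NULL,
                                samples = NULL) {
  sample_ids <- unique(junctions$sample_id)
  if (!is.null(samples)) {
    missing <- setdiff(samples$sample_id, sample_ids)
    if (length(missing) > 0L) {
      warning(sprintf("no junction data for sample(s): %s; counts set to 0",
                      paste(missing, collapse = ", ")))
    }
    sample_ids <- samples$sample_id
  }
  ej <- event_junctions(events)
  hits <- ej %>%
    dplyr::inner_join(
      dplyr::select(junctions, "sample_id", "chrom", "start", "end",
                    "reads_dedup"),
      by = c("chrom", "start", "end"), relationship = "many-to-many") %>%
    dplyr::group_by(.data$event_id, .data$sample_id, .data$role) %>%
    dplyr::summarise(count = sum(.data$reads_dedup), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "count",
                       values_fill = 0L)
  if (!"inclusion" %in% names(hits)) hits$inclusion <- 0L
  if (!"exclusion" %in% names(hits)) hits$exclusion <- 0L
  grid <- tidyr::expand_grid(
    events[, c("event_id", "event_type", "chrom", "defining_start",
               "defining_end")],
    sample_id = sample_ids)
  out <- grid %>%
    dplyr::left_join(hits, by = c("event_id", "sample_id")) %>%
    dplyr::mutate(counts_EII = dplyr::coalesce(.data$inclusion, 0L),
                  counts_EEI = dplyr::coalesce(.data$exclusion, 0L))
  if (!is.null(retention)) {
    ret <- dplyr::select(retention, "sample_id", "chrom",
                         defining_start = "start", defining_end = "end",
                         ret_count = "count")
    out <- out %>%
      dplyr::left_join(ret, by = c("sample_id", "chrom", "defining_start",
                                   "defining_end")) %>%
      dplyr::mutate(counts_EII = ifelse(
        .data$event_type == "RI",
        dplyr::coalesce(.data$ret_count, 0L), .data$counts_EII)) %>%
      dplyr::select(-"ret_count")
  }
  out %>%
    dplyr::mutate(psi = psi(.data$counts_EII, .data$counts_EEI),
                  as_score = as_score(.data$psi)) %>%
    dplyr::select("event_id", "event_type", "sample_id", "counts_EII",
                  "counts_EEI", "psi", "as_score")
}

#' Filter assembled transcripts on intronic signal and relative expression
#'
#' A transcript is discarded when its intronic read fraction exceeds
#' `intronic_max` or its FPKM is below `rel_min` times the FPKM of its
#' gene's major (highest-FPKM) isoform; the major isoform is exempt from
#' the relative-expression rule. The two rules combine with OR by default
#' (`combine = "and"` requires both). If every isoform of an expressed
#' gene would be discarded, the major isoform is retained and flagged
#' `rescued`, so no expressed gene loses all of its isoforms.
#'
#' @param abundances Tibble with `transcript_id`, `gene_id`, `fpkm`,
#'   `intronic_read_fraction`.
#' @param intronic_max Maximum tolerated intronic read fraction (0.15).
#' @param rel_min Minimum FPKM relative to the major isoform (0.10).
#' @param combine `"or"` (default) or `"and"`.
#' @return `abundances` with `major`, `kept`, `reason`, `rescued` columns.
#' @export
filter_transcripts <- function(abundances, intronic_max = 0.15,
                               rel_min = 0.10, combine = c("or", "and")) {
  combine <- match.arg(combine)
  out <- abundances %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(
      major = dplyr::row_number() == which.max(.data$fpkm),
      fail_intronic = .data$intronic_read_fraction > intronic_max,
      fail_rel = !.data$major & .data$fpkm < rel_min * max(.data$fpkm)
    ) %>%
    dplyr::mutate(
      discard = if (combine == "or") .data$fail_intronic | .data$fail_rel
                else .data$fail_intronic & .data$fail_rel,
      reason = dplyr::case_when(
        !.data$discard ~ NA_character_,
        .data$fail_intronic & .data$fail_rel ~ "intronic+relative",
        .data$fail_intronic ~ "intronic",
        TRUE ~ "relative"
      ),
      rescued = .data$major & .data$discard & all(.data$discard) &
        max(.data$fpkm) > 0,
      kept = !.data$discard | .data$rescued
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"fail_intronic", -"fail_rel", -"discard")
  out
}
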