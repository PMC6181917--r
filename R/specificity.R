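#' Aggregate event isoform counts into groups
#'
#' Sums each event's inclusion (EII) and exclusion (EEI) counts over the
#' samples of a group — all samples of a tissue (pooling stages and
#' replicates), or of a tissue-stage combination — and normalises to
#' counts per million junction reads within the group so that groups with
#' different sequencing depth are comparable.
#'
#' @param quants Long quantification table from [count_event_support()].
#' @param samples Sample sheet tibble with `sample_id`, `tissue`, `stage`.
#' @param mode `"tissue"` (default) or `"stage_within_tissue"`; the latter
#'   groups by tissue x stage.
#' @param lib_sizes Optional tibble `sample_id`, `lib_size` giving the
#'   filtered junction library size per sample; defaults to each sample's
#'   total event junction counts.
#' @return Long tibble: `event_id`, `side` (`"EII"`/`"EEI"`), `group`,
#'   `count` (raw summed), `cpm`.
#' @export
aggregate_groups <- function(quants, samples,
                             mode = c("tissue", "stage_within_tissue"),
                             lib_sizes = NULL) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(quants$sample_id), samples$sample_id)
  if (length(unknown) > 0L) {
    stop_spliceland("sample(s) absent from sample sheet: %s",
                    paste(unknown, collapse = ", "))
  }
  grouped <- quants %>%
    dplyr::inner_join(samples, by = "sample_id") %>%
    dplyr::mutate(group = if (mode == "tissue") .data$tissue
                  else paste(.data$tissue, .data$stage, sep = ":"))
  if (is.null(lib_sizes)) {
    lib_sizes <- quants %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::summarise(lib_size = sum(.data$counts_EII + .data$counts_EEI),
                       .groups = "drop")
  }
  group_lib <- grouped %>%
    dplyr::distinct(.data$sample_id, .data$group) %>%
    dplyr::inner_join(lib_sizes, by = "sample_id") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(lib_size = sum(.data$lib_size), .groups = "drop")
  empty <- group_lib$group[group_lib$lib_size == 0]
  if (length(empty) > 0L) {
    warning(sprintf("dropping group(s) with no junction reads: %s",
                    paste(empty, collapse = ", ")))
  }
  grouped %>%
    dplyr::group_by(.data$event_id, .data$group) %>%
    dplyr::summarise(EII = sum(.data$counts_EII), EEI = sum(.data$counts_EEI),
                     .groups = "drop") %>%
    tidyr::pivot_longer(c("EII", "EEI"), names_to = "side",
                        values_to = "count") %>%
    dplyr::inner_join(group_lib, by = "group") %>%
    dplyr::filter(.data$lib_size > 0) %>%
    dplyr::mutate(cpm = 1e6 * .data$count / .data$lib_size) %>%
    dplyr::select("event_id", "side", "group", "count", "cpm")
}

#' Remove isoform sides with low coverage
#'
#' An isoform side of an event is eligible for specificity calling only if
#' its maximum per-group raw count is at least `min_count` (default 3);
#' lower-coverage sides are too noisy for presence/absence statements.
#'
#' @param profile Output of [aggregate_groups()].
#' @param min_count Minimum of the per-group raw count maxima.
#' @return Filtered profile (whole event x side blocks removed).
#' @export
coverage_filter <- function(profile, min_count = 3L) {
  profile %>%
    dplyr::group_by(.data$event_id, .data$side) %>%
    dplyr::filter(max(.data$count) >= min_count) %>%
    dplyr::ungroup()
}

#' Tau specificity index
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` over `n >= 2` group
#' abundances: 0 for uniform expression, 1 for expression confined to a
#' single group. Scale-invariant and permutation-equivariant.
#'
#' @param x Non-negative numeric vector of per-group abundances.
#' @return Tau in `[0, 1]`, or `NA` when all abundances are zero.
#' @examples
#' tau(c(10, 0, 0, 0, 0)) # 1
#' tau(c(4, 4, 4, 4))     # 0
#' tau(c(8, 4))           # 0.5
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop_spliceland("tau: need at least 2 groups")
  if (any(x < 0)) stop_spliceland("tau: negative abundances")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1L)
}

#' Call tissue-/stage-specific events
#'
#' With the default `tau_threshold = 1` an isoform side is specific iff it
#' has nonzero abundance in exactly one group (the literal single-group
#' rule, equivalent to tau = 1); with a lower threshold, iff
#' `tau >= tau_threshold`, with the specific group taken as the abundance
#' argmax. An event is specific when at least one eligible side is.
#'
#' @param profile Output of [coverage_filter()].
#' @param tau_threshold Numeric in `(0, 1]`, default 1.
#' @return Per event x side tibble: `event_id`, `side`, `tau`, `specific`,
#'   `specific_group` (`NA` when not specific).
#' @export
call_specific <- function(profile, tau_threshold = 1) {
  stopifnot(tau_threshold > 0, tau_threshold <= 1)
  profile %>%
    dplyr::group_by(.data$event_id, .data$side) %>%
    dplyr::summarise(
      tau = tau(.data$cpm),
      n_nonzero = sum(.data$count > 0),
      top_group = .data$group[which.max(.data$cpm)],
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      specific = if (tau_threshold >= 1) .data$n_nonzero == 1L
                 else !is.na(.data$tau) & .data$tau >= tau_threshold,
      specific_group = ifelse(.data$specific, .data$top_group, NA_character_)
    ) %>%
    dplyr::select("event_id", "side", "tau", "specific", "specific_group")
}
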