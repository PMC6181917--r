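# Differential splicing: binomial logistic likelihood-ratio test.
#
# For one event with per-replicate inclusion/exclusion counts (I_r, E_r)
# in two conditions, the alternative model gives each condition its own
# inclusion probability (MLE: pooled I / (I + E) within condition), the
# null a common one (pooled over both). Because the model is a binomial
# GLM with a single two-level factor, both MLEs are closed-form and
# LR = 2 (ll_alt - ll_null) ~ chi-square(1).

binom_ll <- function(I, E, p) {
  # 0 * log(0) := 0 convention handles boundary MLEs (complete separation)
  t1 <- ifelse(I > 0, I * log(p), 0)
  t2 <- ifelse(E > 0, E * log(1 - p), 0)
  sum(t1 + t2)
}

lrt_one <- function(I_a, E_a, I_b, E_b) {
  sa_i <- sum(I_a); sa_e <- sum(E_a)
  sb_i <- sum(I_b); sb_e <- sum(E_b)
  p_a <- sa_i / (sa_i + sa_e)
  p_b <- sb_i / (sb_i + sb_e)
  p_0 <- (sa_i + sb_i) / (sa_i + sa_e + sb_i + sb_e)
  lr <- 2 * (binom_ll(sa_i, sa_e, p_a) + binom_ll(sb_i, sb_e, p_b) -
               binom_ll(sa_i + sb_i, sa_e + sb_e, p_0))
  lr <- max(lr, 0)
  c(lr = lr, p_a = p_a, p_b = p_b,
    boundary = as.numeric(p_a %in% c(0, 1) || p_b %in% c(0, 1)))
}

#' Likelihood-ratio test for differential splicing between two conditions
#'
#' Per event, replicate-level inclusion/exclusion counts are modelled as
#' binomial with a condition-specific inclusion probability
#' (alternative) versus a shared one (null); the likelihood-ratio
#' statistic is referred to a chi-square distribution with 1 df.
#' Events with zero total count in either condition are skipped. Events
#' whose condition MLE sits on the boundary (all-inclusion or
#' all-exclusion; complete separation) are flagged `boundary`; their
#' statistic is still the profile log-likelihood ratio, which is finite
#' under the `0 log 0 = 0` convention.
#'
#' Benjamini-Hochberg q-values are attached and events with
#' `q < alpha` are called significant.
#'
#' @param quants Long quantification table from [count_event_support()].
#' @param samples Sample sheet with `sample_id` plus the `condition`
#'   column.
#' @param condition Name of the sample-sheet column defining conditions
#'   (e.g. `"tissue"`).
#' @param groups Character vector of exactly two condition levels to
#'   compare.
#' @param alpha FDR threshold for the `significant` call (default 0.05).
#' @param min_replicates Minimum replicates required per condition
#'   (default 2).
#' @return An object of class `splice_diff`; see [tidy.splice_diff()] and
#'   [glance.splice_diff()].
#' @export
differential_splicing <- function(quants, samples, condition = "tissue",
                                  groups, alpha = 0.05, min_replicates = 2L) {
  stopifnot(length(groups) == 2L, condition %in% names(samples))
  sheet <- samples %>%
    dplyr::mutate(cond = .data[[condition]]) %>%
    dplyr::filter(.data$cond %in% groups)
  n_rep <- table(sheet$cond)
  if (length(n_rep) < 2L || any(n_rep < min_replicates)) {
    stop_spliceland("need at least %d replicates in each condition", min_replicates)
  }
  dat <- quants %>%
    dplyr::inner_join(sheet[, c("sample_id", "cond")], by = "sample_id")
  res <- dat %>%
    dplyr::group_by(.data$event_id) %>%
    dplyr::summarise(
      total_a = sum(.data$counts_EII[.data$cond == groups[1]] +
                      .data$counts_EEI[.data$cond == groups[1]]),
      total_b = sum(.data$counts_EII[.data$cond == groups[2]] +
                      .data$counts_EEI[.data$cond == groups[2]]),
      stats = list(if (.data$total_a[1] > 0 && .data$total_b[1] > 0) {
        lrt_one(.data$counts_EII[.data$cond == groups[1]],
                .data$counts_EEI[.data$cond == groups[1]],
                .data$counts_EII[.data$cond == groups[2]],
                .data$counts_EEI[.data$cond == groups[2]])
      } else {
        c(lr = NA_real_, p_a = NA_real_, p_b = NA_real_, boundary = NA_real_)
      }),
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("stats")
  tested <- res %>%
    dplyr::filter(!is.na(.data$lr)) %>%
    dplyr::mutate(
      df = 1L,
      p_value = stats::pchisq(.data$lr, df = 1L, lower.tail = FALSE),
      q_value = bh_fdr(.data$p_value),
      significant = .data$q_value < alpha,
      delta_psi = .data$p_a - .data$p_b,
      boundary = .data$boundary > 0
    ) %>%
    dplyr::rename(lr_statistic = "lr", psi_a = "p_a", psi_b = "p_b")
  skipped <- res %>%
    dplyr::filter(is.na(.data$lr)) %>%
    dplyr::pull("event_id")
  structure(list(results = tested, comparison = groups,
                 condition = condition, alpha = alpha,
                 skipped = skipped),
            class = "splice_diff")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]); q-values are
#' monotone in the p-value ranks and never smaller than their p-value.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  stats::p.adjust(p_values, method = "BH")
}

#' @export
print.splice_diff <- function(x, ...) {
  cat(sprintf("Differential splicing (%s): %s vs %s\n", x$condition,
              x$comparison[1], x$comparison[2]))
  cat(sprintf("  %d events tested, %d significant at FDR < %g, %d skipped\n",
              nrow(x$results), sum(x$results$significant), x$alpha,
              length(x$skipped)))
  invisible(x)
}

#' Tidy per-event results of a differential-splicing fit
#'
#' @param x A `splice_diff` object.
#' @param ... Unused.
#' @return Tibble with one row per tested event: `event_id`,
#'   `lr_statistic`, `df`, `p_value`, `q_value`, `significant`, `psi_a`,
#'   `psi_b`, `delta_psi`, `boundary`.
#' @export
tidy.splice_diff <- function(x, ...) {
  x$results %>%
    dplyr::select("event_id", "lr_statistic", "df", "p_value", "q_value",
                  "significant", "psi_a", "psi_b", "delta_psi", "boundary")
}

#' One-row summary of a differential-splicing fit
#'
#' @param x A `splice_diff` object.
#' @param ... Unused.
#' @return One-row tibble: comparison labels, events tested/skipped,
#'   number significant, alpha.
#' @export
glance.splice_diff <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    group_a = x$comparison[1], group_b = x$comparison[2],
    n_tested = nrow(x$results), n_skipped = length(x$skipped),
    n_significant = sum(x$results$significant), alpha = x$alpha
  )
}
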