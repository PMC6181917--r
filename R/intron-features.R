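#' AU-richness of nucleotide sequences
#'
#' Fraction of A plus U (T) bases; `N` bases are excluded from both the
#' numerator and the denominator. AU-rich introns are recognised and
#' spliced more efficiently, which is why this quantity is profiled across
#' intron classes.
#'
#' @param seq Character vector of nucleotide sequences (case-insensitive;
#'   T and U are equivalent).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' au_richness(c("ATAT", "GCGC", "GTAG"))
#' @export
au_richness <- function(seq) {
  if (length(seq) == 0L) return(numeric())
  if (any(!nzchar(seq)) || any(is.na(seq))) {
    stop_spliceland("au_richness: empty or missing sequence")
  }
  s <- toupper(seq)
  au <- stringr::str_count(s, "[ATU]")
  valid <- nchar(s) - stringr::str_count(s, "N")
  if (any(valid == 0L)) {
    stop_spliceland("au_richness: sequence consists entirely of N")
  }
  au / valid
}

#' Border dinucleotides of introns
#'
#' Returns the first two and last two intronic nucleotides, strand
#' corrected so that a canonical intron always reads `GT`..`AG` regardless
#' of which genomic strand its gene lies on.
#'
#' @param introns Intron table with `chrom`, `strand`, `start`, `end`
#'   columns (see [extract_introns()]).
#' @param genome Named [Biostrings::DNAStringSet].
#' @return `introns` with `donor_dinuc`, `acceptor_dinuc` and `border`
#'   (e.g. `"GT-AG"`) columns added.
#' @export
border_dinucleotides <- function(introns, genome) {
  if (any(introns$end - introns$start < 4L)) {
    stop_spliceland("intron shorter than 4 nt has no distinct border dinucleotides")
  }
  seqs <- genome_seq(genome, introns$chrom, introns$start, introns$end,
                     introns$strand)
  introns %>%
    dplyr::mutate(
      donor_dinuc = toupper(substr(seqs, 1L, 2L)),
      acceptor_dinuc = toupper(substr(seqs, nchar(seqs) - 1L, nchar(seqs))),
      border = paste0(.data$donor_dinuc, "-", .data$acceptor_dinuc)
    )
}

# splice-site windows in spliced orientation:
#   donor: last 3 exonic + first 6 intronic nt (9 nt)
#   acceptor: last 20 intronic + first 3 exonic nt (23 nt)
DONOR_EXONIC <- 3L
DONOR_INTRONIC <- 6L
ACCEPTOR_INTRONIC <- 20L
ACCEPTOR_EXONIC <- 3L

splice_site_windows <- function(introns, genome) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  plus <- introns$strand != "-"
  d_start <- ifelse(plus, introns$start - DONOR_EXONIC,
                    introns$end - DONOR_INTRONIC)
  d_end <- ifelse(plus, introns$start + DONOR_INTRONIC,
                  introns$end + DONOR_EXONIC)
  a_start <- ifelse(plus, introns$end - ACCEPTOR_INTRONIC,
                    introns$start - ACCEPTOR_EXONIC)
  a_end <- ifelse(plus, introns$end + ACCEPTOR_EXONIC,
                  introns$start + ACCEPTOR_INTRONIC)
  ok <- introns$end - introns$start >= DONOR_INTRONIC + ACCEPTOR_INTRONIC &
    d_start >= 0L & a_start >= 0L &
    d_end <= lens[introns$chrom] & a_end <= lens[introns$chrom]
  donor <- acceptor <- rep(NA_character_, nrow(introns))
  if (any(ok)) {
    donor[ok] <- genome_seq(genome, introns$chrom[ok], d_start[ok],
                            d_end[ok], introns$strand[ok])
    acceptor[ok] <- genome_seq(genome, introns$chrom[ok], a_start[ok],
                               a_end[ok], introns$strand[ok])
  }
  tibble::tibble(donor = toupper(donor), acceptor = toupper(acceptor), ok = ok)
}

pwm_from_seqs <- function(seqs, width, pseudocount) {
  mat <- matrix(0, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (s in chars) {
    for (j in seq_len(width)) {
      b <- s[j]
      if (b %in% rownames(mat)) mat[b, j] <- mat[b, j] + 1
    }
  }
  sweep(mat + pseudocount, 2, colSums(mat) + 4 * pseudocount, "/")
}

#' Train a position-weight-matrix splice-site model
#'
#' Builds per-position nucleotide frequency matrices over a 9-nt donor
#' window (last 3 exonic + first 6 intronic nt) and a 23-nt acceptor
#' window (last 20 intronic + first 3 exonic nt), with a pseudocount, plus
#' a background distribution pooled over all window positions. Introns too
#' short for non-overlapping windows, or whose windows fall off the
#' chromosome, are excluded from training.
#'
#' @param introns Intron table (ideally constitutive, annotated introns).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param pseudocount Positive real added to every count (default 1).
#' @return An object of class `splice_pwm` with elements `donor`,
#'   `acceptor` (4 x width frequency matrices), `background`, `pseudocount`
#'   and `n_train`.
#' @export
train_pwm <- function(introns, genome, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (nrow(introns) == 0L) stop_spliceland("train_pwm: empty training set")
  w <- splice_site_windows(introns, genome)
  w <- w[w$ok, , drop = FALSE]
  if (nrow(w) == 0L) stop_spliceland("train_pwm: no trainable introns after window clipping")
  if (nrow(w) < 50L) {
    message(sprintf("train_pwm: only %d training introns; PWM is low-confidence", nrow(w)))
  }
  donor <- pwm_from_seqs(w$donor, DONOR_EXONIC + DONOR_INTRONIC, pseudocount)
  acceptor <- pwm_from_seqs(w$acceptor, ACCEPTOR_INTRONIC + ACCEPTOR_EXONIC,
                            pseudocount)
  pooled <- paste0(paste(w$donor, collapse = ""), paste(w$acceptor, collapse = ""))
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) stringr::str_count(pooled, b), numeric(1))
  background <- (counts + pseudocount) / (sum(counts) + 4 * pseudocount)
  structure(list(donor = donor, acceptor = acceptor, background = background,
                 pseudocount = pseudocount, n_train = nrow(w)),
            class = "splice_pwm")
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf("splice_pwm: donor 9 nt / acceptor 23 nt, %d training sites, pseudocount %g\n",
              x$n_train, x$pseudocount))
  cat("donor consensus:   ", paste(rownames(x$donor)[apply(x$donor, 2, which.max)],
                                   collapse = ""), "\n")
  cat("acceptor consensus:", paste(rownames(x$acceptor)[apply(x$acceptor, 2, which.max)],
                                   collapse = ""), "\n")
  invisible(x)
}

score_window <- function(seqs, mat, background) {
  width <- ncol(mat)
  score <- rep(NA_real_, length(seqs))
  skipped <- rep(NA_integer_, length(seqs))
  ok <- !is.na(seqs)
  chars <- strsplit(seqs[ok], "", fixed = TRUE)
  res <- vapply(chars, function(s) {
    sc <- 0; sk <- 0L
    for (j in seq_len(width)) {
      b <- s[j]
      if (b %in% rownames(mat)) {
        sc <- sc + log2(mat[b, j] / background[b])
      } else {
        sk <- sk + 1L
      }
    }
    c(sc, sk)
  }, numeric(2))
  score[ok] <- res[1, ]
  skipped[ok] <- as.integer(res[2, ])
  list(score = score, skipped = skipped)
}

#' Score splice sites against a trained PWM
#'
#' Log-odds score in bits: the sum over window positions of
#' `log2(p_pos(base) / background(base))`. Positions containing `N` are
#' skipped and counted. The per-intron site score is the mean of the donor
#' and acceptor scores; the per-position consensus sequence attains the
#' maximal score by construction.
#'
#' @param introns Intron table.
#' @param pwm A `splice_pwm` from [train_pwm()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return `introns` with `donor_score`, `acceptor_score`, `site_score` and
#'   `n_skipped_positions` columns; introns whose windows cannot be
#'   extracted get `NA` scores.
#' @export
splice_site_score <- function(introns, pwm, genome) {
  stopifnot(inherits(pwm, "splice_pwm"))
  w <- splice_site_windows(introns, genome)
  d <- score_window(w$donor, pwm$donor, pwm$background)
  a <- score_window(w$acceptor, pwm$acceptor, pwm$background)
  introns %>%
    dplyr::mutate(
      donor_score = d$score,
      acceptor_score = a$score,
      site_score = (d$score + a$score) / 2,
      n_skipped_positions = d$skipped + a$skipped
    )
}

#' Compare a feature between two intron groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test, the standard
#' distribution-free comparison for skewed intron features such as length
#' or splice-site score. Exact p-values are used for small tie-free
#' samples, the tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b Numeric vectors.
#' @return A one-row tibble: `statistic` (W), `p_value`, `n_a`, `n_b`,
#'   `median_a`, `median_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop_spliceland("compare_groups: both groups must be non-empty")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    warning("compare_groups: constant pooled input; p = 1")
    return(tibble::tibble(
      statistic = length(values_a) * length(values_b) / 2, p_value = 1,
      n_a = length(values_a), n_b = length(values_b),
      median_a = stats::median(values_a), median_b = stats::median(values_b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 median_a = stats::median(values_a),
                 median_b = stats::median(values_b))
}

#' Per-intron feature table
#'
#' Convenience wrapper combining length, AU-richness, border dinucleotides
#' and (optionally) PWM splice-site scores into one table, the unit of the
#' intron-characteristics analyses.
#'
#' @param introns Intron table with at least `chrom`, `strand`, `start`,
#'   `end`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param pwm Optional `splice_pwm`; when supplied, score columns are added.
#' @return `introns` with `length`, `au_fraction`, border and (optionally)
#'   score columns.
#' @export
intron_features <- function(introns, genome, pwm = NULL) {
  out <- introns %>%
    dplyr::mutate(length = .data$end - .data$start) %>%
    border_dinucleotides(genome) %>%
    dplyr::mutate(au_fraction = au_richness(
      genome_seq(.env$genome, .data$chrom, .data$start, .data$end, .data$strand)))
  if (!is.null(pwm)) out <- splice_site_score(out, pwm, genome)
  out
}

#' Summarise intron features by group
#'
#' @param features Feature table from [intron_features()].
#' @param ... Grouping columns (tidy-select), e.g. `status` or `novelty`;
#'   omit for a single overall summary.
#' @return One row per group: n, mean/median length, count of enormous
#'   (>50 kb) introns, mean AU fraction, GT-AG border fraction, mean/median
#'   site score (NA when scores absent).
#' @export
summarize_introns <- function(features, ...) {
  grouped <- dplyr::group_by(features, ...)
  out <- grouped %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_length = mean(.data$length),
      median_length = stats::median(.data$length),
      n_enormous = sum(.data$length > 50000L),
      mean_au = mean(.data$au_fraction),
      gt_ag_fraction = mean(.data$border == "GT-AG"),
      mean_site_score = if ("site_score" %in% names(features))
        mean(.data$site_score, na.rm = TRUE) else NA_real_,
      median_site_score = if ("site_score" %in% names(features))
        stats::median(.data$site_score, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  if (nrow(out) == 0L) warning("summarize_introns: no groups to summarise")
  out
}
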