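#' Ratio statistics used throughout the summary report
#'
#' `pct_of()` is the percentage `100 * numerator / denominator` rounded to
#' `digits` decimals (the precision the summary report prints);
#' `per_gene_rate()` is the mean number of events per gene at the same
#' rounding. These are the primitives behind every fraction in
#' [splice_report()] — per-type event shares, the AS-gene fraction,
#' per-region type shares.
#'
#' @param numerator,denominator Non-negative numerics (`denominator > 0`).
#' @param digits Decimal places, default 2.
#' @return Numeric vector.
#' @examples
#' pct_of(8508, 22970)      # RI share of a 22,970-event catalog
#' per_gene_rate(22970, 8460)
#' @export
pct_of <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop_spliceland("pct_of: denominator must be > 0")
  round(100 * numerator / denominator, digits)
}

#' @rdname pct_of
#' @param n_events,n_genes Event and gene counts.
#' @export
per_gene_rate <- function(n_events, n_genes, digits = 2) {
  if (any(n_genes <= 0)) stop_spliceland("per_gene_rate: n_genes must be > 0")
  round(n_events / n_genes, digits)
}

#' Summary report of a splicing analysis
#'
#' Collects the catalog-level statistics of a run into one list: total
#' events, per-type counts and percentage shares, AS-gene count and mean
#' events per AS gene, the AS fraction of multi-isoform genes, and — when
#' regions are assigned — the per-region type matrix with each type's
#' share of its region. Totals are internally consistent by construction
#' (type counts sum to the total; region counts sum to the number of
#' region-assignable events).
#'
#' @param events Event catalog (after [assign_region()] for region stats).
#' @param models Optional exon table, used to count multi-isoform genes.
#' @return A list of class `splice_report`.
#' @export
splice_report <- function(events, models = NULL) {
  cat <- event_catalog(events)
  n_multi <- NA_integer_
  as_gene_pct <- NA_real_
  if (!is.null(models)) {
    n_multi <- models %>%
      dplyr::filter(.data$feature == "exon") %>%
      dplyr::distinct(.data$gene_id, .data$transcript_id) %>%
      dplyr::count(.data$gene_id) %>%
      dplyr::filter(.data$n >= 2L) %>%
      nrow()
    if (n_multi > 0) as_gene_pct <- pct_of(cat$n_genes, n_multi)
  }
  region_shares <- NULL
  if (!is.null(cat$by_region)) {
    region_shares <- cat$by_region %>%
      dplyr::filter(.data$region != "unpartitioned")
  }
  structure(list(
    n_events = cat$n_events,
    n_as_genes = cat$n_genes,
    events_per_gene = cat$events_per_gene,
    n_multi_isoform_genes = n_multi,
    as_gene_pct = as_gene_pct,
    by_type = cat$by_type,
    by_region = region_shares
  ), class = "splice_report")
}

#' @export
print.splice_report <- function(x, ...) {
  cat(sprintf("AS landscape: %d events in %d AS genes (%.2f events/gene)\n",
              x$n_events, x$n_as_genes, x$events_per_gene))
  if (!is.na(x$n_multi_isoform_genes)) {
    cat(sprintf("  %s%% of %d multi-isoform genes undergo AS\n",
                format(x$as_gene_pct), x$n_multi_isoform_genes))
  }
  if (nrow(x$by_type) > 0) {
    cat("  by type:\n")
    for (i in seq_len(nrow(x$by_type))) {
      cat(sprintf("    %-4s %6d (%5.2f%%)\n", x$by_type$event_type[i],
                  x$by_type$n[i], x$by_type$pct[i]))
    }
  }
  invisible(x)
}

#' Run the full splicing pipeline on files or simulated inputs
#'
#' Orchestrates the stages in order: junction filtering, annotation
#' parsing and intron extraction, event detection and region assignment,
#' intron feature computation, event quantification (PSI/AS score) and
#' tissue specificity. All result tables are returned and, when `out_dir`
#' is given, written as TSV with a schema header plus a JSON summary. The
#' run is deterministic given its inputs.
#'
#' @param gtf,genome_fa,junctions_tsv,sample_sheet_csv Input file paths
#'   (GTF annotation, FASTA genome, long junction-support TSV as written
#'   by [write_simulation()], sample sheet CSV).
#' @param retention_tsv Optional retention-count TSV for RI events.
#' @param out_dir Optional output directory.
#' @param min_sj_reads,proximity_nt Junction-filter thresholds (2, 10).
#' @param min_isoform_count Coverage floor for specificity (3).
#' @param tau_threshold Specificity threshold (1.0).
#' @return A list with `models`, `introns`, `junctions` (filtered, with
#'   `kept`/`reason`), `events` (region-assigned catalog), `features`,
#'   `quants`, `specificity`, `report`.
#' @export
run_pipeline <- function(gtf, genome_fa, junctions_tsv, sample_sheet_csv,
                         retention_tsv = NULL, out_dir = NULL,
                         min_sj_reads = 2L, proximity_nt = 10L,
                         min_isoform_count = 3L, tau_threshold = 1) {
  for (f in c(gtf, genome_fa, junctions_tsv, sample_sheet_csv,
              retention_tsv)) {
    if (!is.null(f) && !file.exists(f)) {
      stop_spliceland("input file not found: %s", f)
    }
  }
  genome <- read_genome(genome_fa)
  models <- read_gtf(gtf, genome = genome)
  samples <- readr::read_csv(sample_sheet_csv, show_col_types = FALSE)
  junctions_raw <- readr::read_tsv(junctions_tsv, show_col_types = FALSE)
  retention <- if (!is.null(retention_tsv)) {
    readr::read_tsv(retention_tsv, show_col_types = FALSE)
  } else NULL

  junctions <- junctions_raw %>%
    filter_junctions(min_reads = min_sj_reads, proximity_nt = proximity_nt) %>%
    classify_novelty(models)
  kept <- dplyr::filter(junctions, .data$kept)

  introns <- classify_intron_status(models)
  pwm <- train_pwm(dplyr::filter(introns, .data$status == "constitutive"),
                   genome)
  features <- intron_features(introns, genome, pwm = pwm)

  events <- detect_events(models) %>%
    assign_region(partition_regions(models))

  quants <- count_event_support(events, kept, retention = retention,
                                samples = samples)
  profile <- aggregate_groups(quants, samples, mode = "tissue") %>%
    coverage_filter(min_count = min_isoform_count)
  specificity <- call_specific(profile, tau_threshold = tau_threshold)

  report <- splice_report(events, models)

  res <- list(models = models, introns = introns, junctions = junctions,
              events = events, features = features, quants = quants,
              specificity = specificity, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(junctions, file.path(out_dir, "junctions_filtered.tsv"))
    readr::write_tsv(events, file.path(out_dir, "event_catalog.tsv"))
    readr::write_tsv(features, file.path(out_dir, "intron_features.tsv"))
    readr::write_tsv(quants, file.path(out_dir, "event_quant.tsv"))
    readr::write_tsv(specificity, file.path(out_dir, "specificity.tsv"))
    jsonlite::write_json(
      list(n_events = report$n_events, n_as_genes = report$n_as_genes,
           events_per_gene = report$events_per_gene,
           as_gene_pct = report$as_gene_pct,
           by_type = report$by_type, by_region = report$by_region),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  res
}
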