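#' Detect alternative-splicing events by pairwise isoform comparison
#'
#' For every unordered pair of isoforms within a gene, local differences in
#' exon structure are classified into the five event types:
#' \describe{
#'   \item{SE}{skipped exon: both isoforms share an upstream donor and a
#'     downstream acceptor; one carries exactly one intervening exon, the
#'     other splices the donor directly to the acceptor.}
#'   \item{RI}{retained intron: one isoform's single exon exactly spans the
#'     other's two exons plus the intervening intron.}
#'   \item{A5SS/A3SS}{two introns sharing one boundary but not the other,
#'     with overlapping flanking exons on the alternative side; the labels
#'     are strand-aware (an alternative genomic-left boundary is A5SS on
#'     `+` and A3SS on `-`).}
#'   \item{MXE}{shared flanking donor and acceptor; each isoform contains
#'     exactly one of two disjoint, non-identical middle exons.}
#' }
#' Events are deduplicated by a canonical key that is invariant to the
#' order of the isoform pair, so nested alternatives emit the maximal set
#' of simple pairwise events. Inclusion junctions (EII, the isoform with
#' the shorter intron) and exclusion junctions (EEI, the larger intron)
#' follow the convention that for RI the inclusion (retention) form has no
#' junction and is quantified from retention counts.
#'
#' @param models Exon table (see [read_gtf()]); genes with fewer than two
#'   isoforms yield no events.
#' @return An event catalog tibble: `event_id`, `event_type`, `gene_id`,
#'   `chrom`, `strand`, `defining_start`, `defining_end`, `anchors`
#'   (comma-separated coordinate tuple), `inclusion_junctions`,
#'   `exclusion_junctions` (span strings, see [event_junctions()]).
#' @examples
#' m <- tibble::tibble(
#'   chrom = "chr1", strand = "+", feature = "exon", gene_id = "g",
#'   novelty = "known",
#'   transcript_id = rep(c("t1", "t2"), c(3, 2)),
#'   start = c(0L, 200L, 400L, 0L, 400L),
#'   end = c(100L, 300L, 500L, 100L, 500L))
#' detect_events(m)
#' @export
detect_events <- function(models) {
  exons <- models %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)
  genes <- split(exons, exons$gene_id)
  out <- purrr::map(genes, detect_events_gene)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(event_id = character(), event_type = character(),
                          gene_id = character(), chrom = character(),
                          strand = character(), defining_start = integer(),
                          defining_end = integer(), anchors = character(),
                          inclusion_junctions = character(),
                          exclusion_junctions = character()))
  }
  res %>%
    dplyr::distinct(.data$event_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$chrom, .data$defining_start, .data$event_id)
}

detect_events_gene <- function(exons) {
  txs <- split(exons[, c("start", "end")], exons$transcript_id)
  txs <- lapply(txs, function(d) d[order(d$start), , drop = FALSE])
  ids <- names(txs)
  if (length(ids) < 2L) return(NULL)
  chrom <- exons$chrom[1]
  strand <- exons$strand[1]
  gene_id <- exons$gene_id[1]
  found <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      found[[length(found) + 1L]] <-
        compare_isoform_pair(txs[[i]], txs[[j]], chrom, strand, gene_id)
    }
  }
  dplyr::bind_rows(found)
}

# introns plus the bounds of their flanking exons
tx_introns <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(s = integer(), e = integer(),
                      up_start = integer(), down_end = integer()))
  }
  data.frame(s = ex$end[-n], e = ex$start[-1],
             up_start = ex$start[-n], down_end = ex$end[-1])
}

compare_isoform_pair <- function(exA, exB, chrom, strand, gene_id) {
  iA <- tx_introns(exA)
  iB <- tx_introns(exB)
  evs <- list()
  add <- function(ev) evs[[length(evs) + 1L]] <<- ev

  se_scan <- function(exX, iY) {
    nX <- nrow(exX)
    if (nX < 3L) return()
    for (m in 2:(nX - 1L)) {
      d <- exX$end[m - 1L]; a <- exX$start[m + 1L]
      if (any(iY$s == d & iY$e == a)) {
        s1 <- exX$start[m]; s2 <- exX$end[m]
        add(make_event("SE", chrom, strand, gene_id,
                       anchors = c(d, s1, s2, a),
                       defining = c(s1, s2),
                       incl = list(s = c(d, s2), e = c(s1, a)),
                       excl = list(s = d, e = a)))
      }
    }
  }
  se_scan(exA, iB); se_scan(exB, iA)

  ri_scan <- function(exX, exY) {
    nX <- nrow(exX)
    if (nX < 2L) return()
    for (m in seq_len(nX - 1L)) {
      x1 <- exX$start[m]; x2 <- exX$end[m]
      x3 <- exX$start[m + 1L]; x4 <- exX$end[m + 1L]
      if (any(exY$start == x1 & exY$end == x4)) {
        add(make_event("RI", chrom, strand, gene_id,
                       anchors = c(x1, x2, x3, x4),
                       defining = c(x2, x3),
                       incl = list(s = integer(), e = integer()),
                       excl = list(s = x2, e = x3)))
      }
    }
  }
  ri_scan(exA, exB); ri_scan(exB, exA)

  # alternative boundaries: introns sharing exactly one end, with
  # overlapping flanking exons on the alternative side
  if (nrow(iA) > 0L && nrow(iB) > 0L) {
    for (p in seq_len(nrow(iA))) {
      for (q in seq_len(nrow(iB))) {
        a <- iA[p, ]; b <- iB[q, ]
        if (a$s == b$s && a$e != b$e) {
          # alternative genomic-right boundary
          if (overlap_width(a$e, a$down_end, b$e, b$down_end) > 0L) {
            type <- if (strand == "-") "A5SS" else "A3SS"
            e1 <- min(a$e, b$e); e2 <- max(a$e, b$e)
            add(make_event(type, chrom, strand, gene_id,
                           anchors = c(a$s, e1, e2),
                           defining = c(e1, e2),
                           incl = list(s = a$s, e = e1),   # shorter intron
                           excl = list(s = a$s, e = e2)))  # larger intron
          }
        } else if (a$e == b$e && a$s != b$s) {
          # alternative genomic-left boundary
          if (overlap_width(a$up_start, a$s, b$up_start, b$s) > 0L) {
            type <- if (strand == "-") "A3SS" else "A5SS"
            s1 <- min(a$s, b$s); s2 <- max(a$s, b$s)
            add(make_event(type, chrom, strand, gene_id,
                           anchors = c(s1, s2, a$e),
                           defining = c(s1, s2),
                           incl = list(s = s2, e = a$e),
                           excl = list(s = s1, e = a$e)))
          }
        }
      }
    }
  }

  # MXE: consecutive intron pairs sharing outer donor/acceptor with
  # disjoint middle exons
  mxe_scan <- function(exX, exY) {
    nX <- nrow(exX); nY <- nrow(exY)
    if (nX < 3L || nY < 3L) return()
    for (m in 2:(nX - 1L)) {
      d <- exX$end[m - 1L]; a <- exX$start[m + 1L]
      m1s <- exX$start[m]; m1e <- exX$end[m]
      for (k in 2:(nY - 1L)) {
        if (exY$end[k - 1L] != d || exY$start[k + 1L] != a) next
        m2s <- exY$start[k]; m2e <- exY$end[k]
        if (m1s == m2s && m1e == m2e) next
        disjoint <- m1e <= m2s || m2e <= m1s
        if (!disjoint) next
        first <- if (m1s < m2s) c(m1s, m1e, m2s, m2e) else c(m2s, m2e, m1s, m1e)
        add(make_event("MXE", chrom, strand, gene_id,
                       anchors = c(d, first, a),
                       defining = c(first[1], first[4]),
                       incl = list(s = c(d, first[2]), e = c(first[1], a)),
                       excl = list(s = c(d, first[4]), e = c(first[3], a))))
      }
    }
  }
  mxe_scan(exA, exB)

  dplyr::bind_rows(evs)
}

make_event <- function(type, chrom, strand, gene_id, anchors, defining,
                       incl, excl) {
  tibble::tibble(
    event_id = paste(c(type, chrom, strand, anchors), collapse = "|"),
    event_type = type, gene_id = gene_id, chrom = chrom, strand = strand,
    defining_start = as.integer(defining[1]),
    defining_end = as.integer(defining[2]),
    anchors = paste(anchors, collapse = ","),
    inclusion_junctions = encode_spans(incl$s, incl$e),
    exclusion_junctions = encode_spans(excl$s, excl$e)
  )
}

#' Unnest an event catalog's junction spans
#'
#' @param events Event catalog from [detect_events()].
#' @return Long tibble: `event_id`, `event_type`, `chrom`, `strand`,
#'   `role` (`"inclusion"`/`"exclusion"`), `start`, `end`. RI events have
#'   no inclusion rows (retention evidence is not a junction).
#' @export
event_junctions <- function(events) {
  long <- events %>%
    dplyr::select("event_id", "event_type", "chrom", "strand",
                  inclusion = "inclusion_junctions",
                  exclusion = "exclusion_junctions") %>%
    tidyr::pivot_longer(c("inclusion", "exclusion"), names_to = "role",
                        values_to = "spans")
  long %>%
    dplyr::mutate(sp = purrr::map(.data$spans, decode_spans)) %>%
    dplyr::select(-"spans") %>%
    tidyr::unnest("sp")
}

#' Assign events to gene regions
#'
#' Each event's defining span (SE: the skipped exon; RI: the retained
#' intron; A5SS/A3SS: the interval between the two alternative boundaries;
#' MXE: the hull of the two exons) is assigned to the representative
#' isoform region (5'UTR, CDS, 3'UTR) with the largest overlap; ties go to
#' the more 5' region in transcript orientation. Events of genes without a
#' CDS partition are labelled `unpartitioned`.
#'
#' @param events Event catalog from [detect_events()].
#' @param partitions Region table from [partition_regions()].
#' @return `events` with a `region` column.
#' @export
assign_region <- function(events, partitions) {
  if (nrow(events) == 0L) return(dplyr::mutate(events, region = character()))
  ov <- events %>%
    dplyr::select("event_id", "gene_id", "defining_start", "defining_end") %>%
    dplyr::inner_join(partitions, by = "gene_id",
                      relationship = "many-to-many") %>%
    dplyr::mutate(
      ov = overlap_width(.data$defining_start, .data$defining_end,
                         .data$start, .data$end),
      prio = match(.data$region, c("5UTR", "CDS", "3UTR"))
    ) %>%
    dplyr::filter(.data$ov > 0L) %>%
    dplyr::group_by(.data$event_id) %>%
    dplyr::arrange(dplyr::desc(.data$ov), .data$prio, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select("event_id", "region")
  events %>%
    dplyr::left_join(ov, by = "event_id") %>%
    dplyr::mutate(region = dplyr::coalesce(.data$region, "unpartitioned"))
}

#' Summarise an event catalog
#'
#' Per-type counts and percentages of the total, the number of AS genes
#' (genes with at least one event), and — when events carry regions — the
#' per-region by type count matrix.
#'
#' @param events Event catalog, optionally after [assign_region()].
#' @return A list with `events` (the input), `by_type`, `n_events`,
#'   `n_genes`, `events_per_gene`, and `by_region` (NULL without regions).
#' @export
event_catalog <- function(events) {
  by_type <- events %>%
    dplyr::count(.data$event_type, name = "n") %>%
    dplyr::mutate(pct = pct_of(.data$n, sum(.data$n)))
  by_region <- NULL
  if ("region" %in% names(events)) {
    by_region <- events %>%
      dplyr::count(.data$region, .data$event_type, name = "n") %>%
      dplyr::group_by(.data$region) %>%
      dplyr::mutate(pct = pct_of(.data$n, sum(.data$n))) %>%
      dplyr::ungroup()
  }
  n_genes <- dplyr::n_distinct(events$gene_id)
  list(events = events, by_type = by_type, by_region = by_region,
       n_events = nrow(events), n_genes = n_genes,
       events_per_gene = if (n_genes > 0) per_gene_rate(nrow(events), n_genes)
                         else NA_real_)
}
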