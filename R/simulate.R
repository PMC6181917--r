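#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: the
#' goat-like AS-type mix (RI-dominated), a log-normal intron length
#' distribution with median 1,472 nt whose mean/median ratio implies
#' `sdlog = 1.69` (which also puts ~2% of unconstrained draws above
#' 50 kb; that enormous tail is off by default via `allow_enormous`),
#' 98% canonical GT-AG borders, intron AU content of 0.53, and a
#' 5-tissue x 4-stage x 3-replicate design.
#'
#' @param n_genes Number of genes to simulate.
#' @param exons_per_gene Integer range (min, max) of backbone exon counts.
#' @param exon_length_range Integer range of exon lengths (nt).
#' @param extra_isoform_weights Probabilities of a gene carrying 0..k
#'   additional isoforms (each extra isoform realises one planted event).
#' @param as_type_proportions Named proportions over
#'   `SE`, `RI`, `A3SS`, `A5SS`, `MXE`; must sum to 1.
#' @param intron_length_meanlog,intron_length_sdlog Log-normal intron
#'   length parameters.
#' @param min_intron_length Shortest allowed intron (nt).
#' @param allow_enormous Keep draws above 50 kb? Default FALSE
#'   (resampled).
#' @param canonical_border_fraction Probability an intron gets GT-AG
#'   borders; the remainder are GC-AG, AT-AC or random dinucleotides.
#' @param intron_au_target Target A+T fraction of intronic sequence.
#' @param cds_fraction Fraction of genes given a CDS (and hence UTRs).
#' @param tissues,stages Group labels of the design.
#' @param replicates Biological replicates per tissue x stage.
#' @param coverage_mean Mean per-event junction coverage per sample
#'   (Poisson).
#' @param fraction_specific_events Fraction of events made
#'   tissue-specific (inclusion support zeroed outside one tissue).
#' @param rho Beta-binomial overdispersion of inclusion counts (0 =
#'   binomial).
#' @param artifact_rate Per-junction probability of planting a nearby
#'   mismatch-only artifact junction (for filter testing).
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param seed Integer RNG seed; all outputs are deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 200L,
                              exons_per_gene = c(5L, 9L),
                              exon_length_range = c(80L, 300L),
                              extra_isoform_weights = c(0.15, 0.45, 0.28, 0.12),
                              as_type_proportions = c(SE = 0.3290, RI = 0.3704,
                                                      A3SS = 0.1598,
                                                      A5SS = 0.1274,
                                                      MXE = 0.0134),
                              intron_length_meanlog = log(1472),
                              intron_length_sdlog = 1.69,
                              min_intron_length = 80L,
                              allow_enormous = FALSE,
                              canonical_border_fraction = 0.98,
                              intron_au_target = 0.53,
                              cds_fraction = 0.9,
                              tissues = c("heart", "liver", "spleen",
                                          "kidney", "muscle"),
                              stages = c("fetus", "M2", "Y1", "adult"),
                              replicates = 3L,
                              coverage_mean = 50,
                              fraction_specific_events = 0.1,
                              rho = 0,
                              artifact_rate = 0,
                              n_chromosomes = 2L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_range = as.integer(exon_length_range),
              extra_isoform_weights = extra_isoform_weights,
              as_type_proportions = as_type_proportions,
              intron_length_meanlog = intron_length_meanlog,
              intron_length_sdlog = intron_length_sdlog,
              min_intron_length = as.integer(min_intron_length),
              allow_enormous = allow_enormous,
              canonical_border_fraction = canonical_border_fraction,
              intron_au_target = intron_au_target,
              cds_fraction = cds_fraction,
              tissues = tissues, stages = stages,
              replicates = as.integer(replicates),
              coverage_mean = coverage_mean,
              fraction_specific_events = fraction_specific_events,
              rho = rho, artifact_rate = artifact_rate,
              n_chromosomes = as.integer(n_chromosomes),
              seed = as.integer(seed))
  if (abs(sum(cfg$as_type_proportions) - 1) > 1e-9) {
    stop_spliceland("as_type_proportions must sum to 1")
  }
  if (!all(names(cfg$as_type_proportions) %in%
           c("SE", "RI", "A3SS", "A5SS", "MXE"))) {
    stop_spliceland("as_type_proportions must be named with the five event types")
  }
  fracs <- c(cfg$canonical_border_fraction, cfg$intron_au_target,
             cfg$cds_fraction, cfg$fraction_specific_events, cfg$rho)
  if (any(fracs < 0 | fracs > 1)) {
    stop_spliceland("fractions must lie in [0, 1]")
  }
  if (cfg$exons_per_gene[1] < 5L) {
    stop_spliceland("need at least 5 exons per gene to place events")
  }
  class(cfg) <- "sim_config"
  cfg
}

draw_intron_lengths <- function(n, cfg) {
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(stats::rlnorm(n, cfg$intron_length_meanlog,
                                        cfg$intron_length_sdlog)))
    x <- x[x >= cfg$min_intron_length]
    if (!cfg$allow_enormous) x <- x[x <= 50000L]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

# draw a border dinucleotide pair for one intron
draw_border <- function(canonical_fraction) {
  if (stats::runif(1) < canonical_fraction) return(c("GT", "AG"))
  pick <- sample(c("GC-AG", "AT-AC", "random"), 1, prob = c(0.5, 0.3, 0.2))
  if (pick == "GC-AG") return(c("GC", "AG"))
  if (pick == "AT-AC") return(c("AT", "AC"))
  bases <- c("A", "C", "G", "T")
  c(paste(sample(bases, 2, replace = TRUE), collapse = ""),
    paste(sample(bases, 2, replace = TRUE), collapse = ""))
}

#' Simulate a genome and annotation with planted AS events
#'
#' Builds each gene exon-by-exon on a synthetic random-nucleotide genome:
#' a multi-exon backbone isoform plus one additional isoform per planted
#' event, realised exactly per the pairwise event definitions used by
#' [detect_events()] (so detection on noise-free output recovers the
#' plantings exactly). Event loci within a gene are kept at least two
#' exons apart so pairwise comparison introduces no emergent events.
#' Intron borders are GT-AG with probability
#' `canonical_border_fraction`, otherwise GC-AG, AT-AC or random;
#' intronic base composition is tuned to `intron_au_target`.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `genome` (named [Biostrings::DNAStringSet]),
#'   `models` (exon table as from [read_gtf()]), `manifest` (list with
#'   `events` — the planted-event catalog in the same shape as
#'   [detect_events()] output — and `genes`), and `config`.
#' @export
simulate_annotation <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  chrom_pieces <- rep(list(list()), cfg$n_chromosomes)
  chrom_len <- integer(cfg$n_chromosomes)
  models <- list()
  planted <- list()
  gene_rows <- list()

  for (gi in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", gi)
    strand <- sample(c("+", "-"), 1)
    ci <- ((gi - 1L) %% cfg$n_chromosomes) + 1L
    chrom <- sprintf("chr%d", ci)

    n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
    ex_len <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                     n_ex, replace = TRUE)
    in_len <- draw_intron_lengths(n_ex - 1L, cfg)

    n_extra <- sample(seq_along(cfg$extra_isoform_weights) - 1L, 1,
                      prob = cfg$extra_isoform_weights)
    slots <- seq(2L, n_ex - 1L, by = 2L)
    slots <- sample(slots)[seq_len(min(n_extra, length(slots)))]
    types <- if (length(slots) > 0) {
      sample(names(cfg$as_type_proportions), length(slots), replace = TRUE,
             prob = cfg$as_type_proportions)
    } else character(0)

    # per-event geometry parameters; may enlarge the intron they use
    deltas <- integer(length(slots))
    mxe_len <- integer(length(slots))
    mxe_off <- integer(length(slots))
    for (k in seq_along(slots)) {
      m <- slots[k]
      if (types[k] %in% c("A5SS", "A3SS")) {
        deltas[k] <- sample(8:40, 1)
        in_len[m] <- max(in_len[m], deltas[k] + 60L)
      } else if (types[k] == "MXE") {
        mxe_len[k] <- sample(60:150, 1)
        need <- 50L + mxe_len[k] + 50L
        in_len[m] <- max(in_len[m], need + 20L)
        mxe_off[k] <- sample(50:(in_len[m] - mxe_len[k] - 50L), 1)
      }
    }

    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- 0L
    for (e in seq_len(n_ex)) {
      ex_start[e] <- pos
      ex_end[e] <- pos + ex_len[e]
      pos <- ex_end[e] + if (e < n_ex) in_len[e] else 0L
    }
    L <- ex_end[n_ex]

    # isoforms in sense coordinates; backbone first
    isoforms <- list(t1 = data.frame(start = ex_start, end = ex_end))
    ev_rows <- list()
    for (k in seq_along(slots)) {
      m <- slots[k]; ty <- types[k]
      bb <- isoforms$t1
      if (ty == "SE") {
        alt <- bb[-m, , drop = FALSE]
        anch <- c(ex_end[m - 1L], ex_start[m], ex_end[m], ex_start[m + 1L])
      } else if (ty == "RI") {
        alt <- bb
        alt$end[m] <- bb$end[m + 1L]
        alt <- alt[-(m + 1L), , drop = FALSE]
        anch <- c(ex_start[m], ex_end[m], ex_start[m + 1L], ex_end[m + 1L])
      } else if (ty == "A5SS") {
        # alternative donor: alt isoform's exon m extends into the intron
        alt <- bb
        alt$end[m] <- bb$end[m] + deltas[k]
        anch <- c(ex_end[m], ex_end[m] + deltas[k], ex_start[m + 1L])
      } else if (ty == "A3SS") {
        # alternative acceptor: alt isoform's exon m+1 starts earlier
        alt <- bb
        alt$start[m + 1L] <- bb$start[m + 1L] - deltas[k]
        anch <- c(ex_end[m], ex_start[m + 1L] - deltas[k], ex_start[m + 1L])
      } else { # MXE
        m2s <- ex_end[m] + mxe_off[k]
        m2e <- m2s + mxe_len[k]
        alt <- bb
        alt$start[m] <- m2s; alt$end[m] <- m2e
        anch <- c(ex_end[m - 1L], ex_start[m], ex_end[m], m2s, m2e,
                  ex_start[m + 1L])
      }
      tx_id <- sprintf("%s.t%d", gene_id, k + 1L)
      isoforms[[tx_id]] <- alt
      ev_rows[[k]] <- list(type = ty, anchors_sense = anch)
    }
    names(isoforms)[1] <- sprintf("%s.t1", gene_id)

    # all distinct introns across isoforms, for sequence borders
    gintrons <- unique(do.call(rbind, lapply(isoforms, function(d) {
      n <- nrow(d)
      if (n < 2L) return(NULL)
      data.frame(s = d$end[-n], e = d$start[-1])
    })))

    # sense sequence: exonic uniform, intronic AU-tuned, then borders
    p_at <- cfg$intron_au_target / 2
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                        prob = c(p_at, 0.5 - p_at, 0.5 - p_at, p_at))
    for (e in seq_len(n_ex)) {
      idx <- (ex_start[e] + 1L):ex_end[e]
      seq_chars[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                               replace = TRUE)
    }
    written_donor <- integer(0)
    written_acceptor <- integer(0)
    for (r in seq_len(nrow(gintrons))) {
      b <- draw_border(cfg$canonical_border_fraction)
      s <- gintrons$s[r]; e <- gintrons$e[r]
      if (!s %in% written_donor) {
        seq_chars[(s + 1L):(s + 2L)] <- strsplit(b[1], "")[[1]]
        written_donor <- c(written_donor, s)
      }
      if (!e %in% written_acceptor) {
        seq_chars[(e - 1L):e] <- strsplit(b[2], "")[[1]]
        written_acceptor <- c(written_acceptor, e)
      }
    }
    gene_seq <- paste(seq_chars, collapse = "")

    # place on chromosome (reverse-complement for '-' genes)
    spacer_len <- 200L
    spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE),
                    collapse = "")
    offset <- chrom_len[ci] + spacer_len
    placed <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_seq)))
    } else {
      gene_seq
    }
    chrom_pieces[[ci]] <- c(chrom_pieces[[ci]], list(spacer, placed))
    chrom_len[ci] <- offset + L

    map_pos <- function(p) {
      if (strand == "+") offset + p else offset + L - p
    }
    map_interval <- function(s, e) {
      if (strand == "+") cbind(offset + s, offset + e)
      else cbind(offset + L - e, offset + L - s)
    }

    # CDS in sense coordinates
    has_cds <- stats::runif(1) < cfg$cds_fraction
    cds_sense <- if (has_cds) {
      c(floor((ex_start[2] + ex_end[2]) / 2),
        floor((ex_start[n_ex - 1L] + ex_end[n_ex - 1L]) / 2))
    } else NULL

    for (tx_id in names(isoforms)) {
      iso <- isoforms[[tx_id]]
      gi_iv <- map_interval(iso$start, iso$end)
      models[[length(models) + 1L]] <- tibble::tibble(
        chrom = chrom, start = as.integer(gi_iv[, 1]),
        end = as.integer(gi_iv[, 2]), strand = strand, feature = "exon",
        gene_id = gene_id, transcript_id = tx_id, novelty = "known")
      if (has_cds) {
        cs <- pmax(iso$start, cds_sense[1])
        ce <- pmin(iso$end, cds_sense[2])
        keep <- ce > cs
        if (any(keep)) {
          cds_iv <- map_interval(cs[keep], ce[keep])
          models[[length(models) + 1L]] <- tibble::tibble(
            chrom = chrom, start = as.integer(cds_iv[, 1]),
            end = as.integer(cds_iv[, 2]), strand = strand, feature = "CDS",
            gene_id = gene_id, transcript_id = tx_id, novelty = "known")
        }
      }
    }

    for (er in ev_rows) {
      anch_g <- sort(vapply(er$anchors_sense, map_pos, numeric(1)))
      planted[[length(planted) + 1L]] <-
        planted_event_row(er$type, chrom, strand, gene_id, anch_g)
    }
    gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      n_isoforms = length(isoforms), has_cds = has_cds,
      gene_start = as.integer(offset), gene_end = as.integer(offset + L))
  }

  seqs <- vapply(chrom_pieces, function(p) paste(unlist(p), collapse = ""),
                 character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("chr%d", seq_len(cfg$n_chromosomes))

  manifest <- list(
    events = if (length(planted) > 0) dplyr::bind_rows(planted) else
      detect_events(tibble::tibble(chrom = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   feature = character(), gene_id = character(),
                                   transcript_id = character(),
                                   novelty = character())),
    genes = dplyr::bind_rows(gene_rows)
  )
  list(genome = genome, models = dplyr::bind_rows(models),
       manifest = manifest, config = cfg)
}

# build the manifest row for a planted event from its sorted genomic
# anchor boundaries, mirroring the detector's conventions
planted_event_row <- function(type, chrom, strand, gene_id, a) {
  a <- as.integer(a)
  if (type == "SE") {
    make_event("SE", chrom, strand, gene_id, anchors = a,
               defining = a[2:3],
               incl = list(s = c(a[1], a[3]), e = c(a[2], a[4])),
               excl = list(s = a[1], e = a[4]))
  } else if (type == "RI") {
    make_event("RI", chrom, strand, gene_id, anchors = a,
               defining = a[2:3],
               incl = list(s = integer(), e = integer()),
               excl = list(s = a[2], e = a[3]))
  } else if (type %in% c("A5SS", "A3SS")) {
    right_alt <- (type == "A3SS") == (strand == "+")
    if (right_alt) {
      make_event(type, chrom, strand, gene_id, anchors = a,
                 defining = a[2:3],
                 incl = list(s = a[1], e = a[2]),
                 excl = list(s = a[1], e = a[3]))
    } else {
      make_event(type, chrom, strand, gene_id, anchors = a,
                 defining = a[1:2],
                 incl = list(s = a[2], e = a[3]),
                 excl = list(s = a[1], e = a[3]))
    }
  } else {
    make_event("MXE", chrom, strand, gene_id, anchors = a,
               defining = c(a[2], a[5]),
               incl = list(s = c(a[1], a[3]), e = c(a[2], a[6])),
               excl = list(s = c(a[1], a[5]), e = c(a[4], a[6])))
  }
}

#' Simulate replicate junction-count tables with planted PSI structure
#'
#' For every sample of the tissue x stage x replicate design, each planted
#' event receives Poisson coverage split between inclusion and exclusion
#' evidence as Binomial(coverage, PSI_true) — or Beta-Binomial with
#' overdispersion `rho` — where PSI_true is the event's planted per-tissue
#' value. Tissue-specific events have inclusion support zeroed outside
#' their tissue. Constitutive junctions get independent Poisson counts.
#' Retained-intron inclusion evidence is emitted as a separate retention
#' count table. Optionally plants mismatch-only artifact junctions within
#' 10 nt of true junctions for filter testing.
#'
#' @param sim Output of [simulate_annotation()].
#' @param cfg A [simulation_config()]; defaults to the one inside `sim`.
#' @return A list: `junctions` (long junction tibble across samples),
#'   `retention` (RI retention counts), `samples` (sample sheet),
#'   `truth` (per-event per-tissue-stage true PSI and specificity labels),
#'   `artifacts` (planted artifact junction spans).
#' @export
simulate_junction_counts <- function(sim, cfg = sim$config) {
  set.seed(cfg$seed + 1L)
  samples <- tidyr::expand_grid(tissue = cfg$tissues, stage = cfg$stages,
                                replicate = seq_len(cfg$replicates)) %>%
    dplyr::mutate(sample_id = paste(.data$tissue, .data$stage,
                                    paste0("r", .data$replicate), sep = "_"))
  events <- sim$manifest$events
  n_ev <- nrow(events)

  n_specific <- round(cfg$fraction_specific_events * n_ev)
  specific_idx <- if (n_specific > 0) sample(n_ev, n_specific) else integer(0)
  specific_tissue <- rep(NA_character_, n_ev)
  specific_tissue[specific_idx] <- sample(cfg$tissues, n_specific,
                                          replace = TRUE)
  base_psi <- ifelse(is.na(specific_tissue),
                     stats::runif(n_ev, 0.15, 0.85),
                     stats::runif(n_ev, 0.5, 0.9))
  truth <- tidyr::expand_grid(
    tibble::tibble(event_id = events$event_id,
                   specific_tissue = specific_tissue,
                   base_psi = base_psi),
    tissue = cfg$tissues, stage = cfg$stages) %>%
    dplyr::mutate(psi_true = ifelse(
      is.na(.data$specific_tissue) | .data$tissue == .data$specific_tissue,
      .data$base_psi, 0))

  grid <- tidyr::expand_grid(event_row = seq_len(n_ev),
                             sample_row = seq_len(nrow(samples)))
  ev <- events[grid$event_row, ]
  sm <- samples[grid$sample_row, ]
  key <- paste(ev$event_id, sm$tissue, sm$stage)
  tkey <- paste(truth$event_id, truth$tissue, truth$stage)
  p_true <- truth$psi_true[match(key, tkey)]
  n_cov <- stats::rpois(nrow(grid), cfg$coverage_mean)
  p_draw <- p_true
  if (cfg$rho > 0) {
    mid <- p_true > 0 & p_true < 1
    a <- p_true[mid] * (1 - cfg$rho) / cfg$rho
    b <- (1 - p_true[mid]) * (1 - cfg$rho) / cfg$rho
    p_draw[mid] <- stats::rbeta(sum(mid), a, b)
  }
  I <- stats::rbinom(nrow(grid), n_cov, p_draw)
  E <- n_cov - I

  # per-event junction geometry (up to 2 inclusion and 2 exclusion spans)
  incl_spans <- lapply(events$inclusion_junctions, decode_spans)
  excl_spans <- lapply(events$exclusion_junctions, decode_spans)
  span_col <- function(lst, i, col) {
    vapply(lst, function(d) if (nrow(d) >= i) d[[col]][i] else NA_integer_,
           integer(1))
  }
  geo <- tibble::tibble(
    n_inc = vapply(incl_spans, nrow, integer(1)),
    n_exc = vapply(excl_spans, nrow, integer(1)),
    i1s = span_col(incl_spans, 1L, "start"), i1e = span_col(incl_spans, 1L, "end"),
    i2s = span_col(incl_spans, 2L, "start"), i2e = span_col(incl_spans, 2L, "end"),
    x1s = span_col(excl_spans, 1L, "start"), x1e = span_col(excl_spans, 1L, "end"),
    x2s = span_col(excl_spans, 2L, "start"), x2e = span_col(excl_spans, 2L, "end"))
  g <- geo[grid$event_row, ]
  N <- nrow(grid)
  I1 <- ifelse(g$n_inc == 2L, stats::rbinom(N, I, 0.5), I)
  I2 <- I - I1
  E1 <- ifelse(g$n_exc == 2L, stats::rbinom(N, E, 0.5), E)
  E2 <- E - E1
  jpart <- function(sel, s, e, cnt) {
    tibble::tibble(sample_id = sm$sample_id[sel],
                   chrom = ev$chrom[sel], strand = ev$strand[sel],
                   start = s[sel], end = e[sel],
                   reads_dedup = as.integer(cnt[sel]))
  }
  event_j <- dplyr::bind_rows(
    jpart(g$n_inc >= 1L, g$i1s, g$i1e, I1),
    jpart(g$n_inc == 2L, g$i2s, g$i2e, I2),
    jpart(g$n_exc >= 1L, g$x1s, g$x1e, E1),
    jpart(g$n_exc == 2L, g$x2s, g$x2e, E2)
  ) %>%
    dplyr::group_by(.data$sample_id, .data$chrom, .data$strand,
                    .data$start, .data$end) %>%
    dplyr::summarise(reads_dedup = sum(.data$reads_dedup), .groups = "drop")
  is_ri <- ev$event_type == "RI"
  ret_rows <- list(tibble::tibble(
    sample_id = sm$sample_id[is_ri], chrom = ev$chrom[is_ri],
    strand = ev$strand[is_ri], start = ev$defining_start[is_ri],
    end = ev$defining_end[is_ri], count = as.integer(I[is_ri])))
  if (sum(is_ri) == 0L) ret_rows <- list()

  # constitutive junctions: annotation introns not used by any event
  all_introns <- extract_introns(sim$models) %>%
    dplyr::distinct(.data$chrom, .data$strand, .data$start, .data$end)
  used <- dplyr::bind_rows(
    event_junctions(events)[, c("chrom", "start", "end")],
    events %>% dplyr::filter(.data$event_type == "RI") %>%
      dplyr::select("chrom", start = "defining_start", end = "defining_end"))
  const <- dplyr::anti_join(all_introns, used, by = c("chrom", "start", "end"))
  const_j <- tidyr::expand_grid(const, sample_id = samples$sample_id) %>%
    dplyr::mutate(reads_dedup = stats::rpois(dplyr::n(), cfg$coverage_mean))

  junctions <- dplyr::bind_rows(event_j, const_j) %>%
    dplyr::mutate(reads_total = .data$reads_dedup,
                  reads_perfect = .data$reads_dedup,
                  reads_mismatch = 0L, novelty = "unassigned") %>%
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start, .data$end)

  artifacts <- NULL
  if (cfg$artifact_rate > 0) {
    base <- junctions %>%
      dplyr::distinct(.data$chrom, .data$strand, .data$start, .data$end) %>%
      dplyr::filter(stats::runif(dplyr::n()) < cfg$artifact_rate) %>%
      dplyr::mutate(
        shift = sample(c(-10:-1, 1:10), dplyr::n(), replace = TRUE),
        side = sample(c("donor", "acceptor"), dplyr::n(), replace = TRUE),
        start = ifelse(.data$side == "donor", .data$start + .data$shift,
                       .data$start),
        end = ifelse(.data$side == "acceptor", .data$end + .data$shift,
                     .data$end)) %>%
      dplyr::select("chrom", "strand", "start", "end")
    artifacts <- base
    art_j <- tidyr::expand_grid(base, sample_id = samples$sample_id) %>%
      dplyr::mutate(reads_total = 2L, reads_dedup = 2L, reads_perfect = 0L,
                    reads_mismatch = 2L, novelty = "unassigned")
    junctions <- dplyr::bind_rows(junctions, art_j)
  }

  retention <- if (length(ret_rows) > 0) dplyr::bind_rows(ret_rows) else
    tibble::tibble(sample_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer(),
                   count = integer())

  list(junctions = junctions, retention = retention, samples = samples,
       truth = truth, artifacts = artifacts)
}

#' Write a simulation to disk as plain-text files
#'
#' Emits genome FASTA, annotation GTF, a long junction-support TSV, a
#' retention-count TSV, a sample sheet CSV and a ground-truth manifest
#' JSON into `dir`.
#'
#' @param sim Output of [simulate_annotation()].
#' @param counts Output of [simulate_junction_counts()] (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, counts = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$models, file.path(dir, "annotation.gtf"))
  manifest <- list(events = sim$manifest$events, genes = sim$manifest$genes,
                   config = unclass(sim$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(counts)) {
    readr::write_tsv(counts$junctions, file.path(dir, "junctions.tsv"))
    readr::write_tsv(counts$retention, file.path(dir, "retention.tsv"))
    readr::write_csv(counts$samples, file.path(dir, "sample_sheet.csv"))
    readr::write_tsv(counts$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}
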