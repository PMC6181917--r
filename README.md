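# spliceland

Alternative-splicing landscape analysis from transcript models and
splice-junction counts, in tidy R.

Bulk RNA-seq studies of non-model animals typically assemble transcript
models, catalogue local alternative-splicing (AS) events, and then ask
which events are tissue- or stage-specific and which change between
conditions. spliceland implements that analysis path as a tested,
pipe-friendly package for researchers who have a GTF of (assembled or
reference) transcript models and per-sample junction support tables —
for example from an RI-dominated ruminant transcriptome — and do not
want to re-run a monolithic pipeline to get defensible statistics.

## What it computes

* **Junction filtering** — per-sample splice-junction cleaning: ≥2
  deduplicated reads, removal of mismatch-only junctions, and removal of
  mismatch-supported junctions whose donor or acceptor sits within 10 nt
  of a perfectly supported junction; known/novel classification against
  an annotation.
* **Event catalog** — the five local AS event types (SE, RI, A5SS, A3SS,
  MXE) detected by pairwise isoform comparison with canonical
  deduplicated keys, assigned to 5′UTR/CDS/3′UTR of the longest isoform.
* **Intron features** — length (with the >50 kb "enormous" class),
  AU-richness, strand-corrected border dinucleotides, and log-odds PWM
  splice-site scores (9-nt donor / 23-nt acceptor windows), with
  Wilcoxon rank-sum group comparisons.
* **Quantification** — per event and sample,

  `PSI = C_EII / (C_EII + C_EEI)`,  `AS score = (PSI − 0.5) / 0.5`,

  summing junction support for the exon-inclusion (EII) and
  exon-exclusion (EEI, larger-intron) isoforms; FPKM and
  intronic/relative-expression transcript filters.
* **Specificity** — the Tau index
  `τ = Σ(1 − x̂ᵢ)/(n − 1)`, `x̂ᵢ = xᵢ/max(x)` over per-group CPM, with a
  read-count ≥3 eligibility floor and the single-group rule at the
  default threshold τ = 1.
* **Differential splicing** — a closed-form binomial likelihood-ratio
  test on replicate inclusion/exclusion counts (χ², 1 df) with
  Benjamini–Hochberg FDR; results come back as a fit object with broom
  `tidy()`/`glance()` methods and a volcano `autoplot()`.
* **Synthetic data** — a generator that plants events (goat-like type
  proportions), intron length/AU/border composition and per-tissue PSI
  structure with a ground-truth manifest, so every stage has an oracle.

## Worked example

Simulate a small annotated genome with planted events, detect and
quantify them, then call tissue-specific and differential events:

```r
library(spliceland)
library(dplyr)

cfg    <- simulation_config(n_genes = 40, seed = 1)
sim    <- simulate_annotation(cfg)
counts <- simulate_junction_counts(sim)

events <- detect_events(sim$models) |>
  assign_region(partition_regions(sim$models))
splice_report(events, sim$models)
#> AS landscape: 50 events in 37 AS genes (1.35 events/gene)
#>   100% of 37 multi-isoform genes undergo AS
#>   by type:
#>     A3SS      2 ( 4.00%)
#>     A5SS      6 (12.00%)
#>     MXE       2 ( 4.00%)
#>     RI       15 (30.00%)
#>     SE       25 (50.00%)

quants <- count_event_support(events, counts$junctions,
                              retention = counts$retention,
                              samples = counts$samples)
quants |> head(4)
#> # A tibble: 4 × 7
#>   event_id             event_type sample_id counts_EII counts_EEI   psi as_score
#>   <chr>                <chr>      <chr>          <int>      <int> <dbl>    <dbl>
#> 1 SE|chr1|+|2096|3554… SE         heart_fe…         17         37 0.315   -0.370
#> 2 SE|chr1|+|2096|3554… SE         heart_fe…         16         35 0.314   -0.373
#> 3 SE|chr1|+|2096|3554… SE         heart_fe…         16         40 0.286   -0.429
#> 4 SE|chr1|+|2096|3554… SE         heart_M2…         10         31 0.244   -0.512

aggregate_groups(quants, counts$samples) |>
  coverage_filter() |>
  call_specific() |>
  filter(specific) |>
  nrow()
#> [1] 5

diff <- differential_splicing(quants, counts$samples,
                              condition = "tissue",
                              groups = c("heart", "muscle"))
glance(diff)
#> # A tibble: 1 × 7
#>   condition group_a group_b n_tested n_skipped n_significant alpha
#>   <chr>     <chr>   <chr>      <int>     <int>         <int> <dbl>
#> 1 tissue    heart   muscle        50         0             4  0.05
```

The first block reads: 50 planted events across 37 AS genes, 1.35 events
per AS gene, with the per-type shares of this particular draw. The PSI
column estimates the planted inclusion level of each event in each
sample (e.g. 0.315 ≈ the event's true PSI of ~0.3); AS scores below 0
mean the exclusion isoform dominates. Five isoform sides are expressed
in exactly one tissue (τ = 1), and 4 of the 50 events splice
differentially between heart and muscle at FDR < 0.05 — driven by the
planted muscle-specific events.

File-based workflows use `run_pipeline()` (or the thin CLI in
`inst/cli/spliceland.R`), which runs junction filtering → event catalog
→ intron features → quantification → specificity on
GTF/FASTA/TSV inputs and writes schema-stable TSV and JSON outputs.

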