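---
title: "Models and methods behind spliceland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceland)
library(dplyr)
```

spliceland characterises an alternative-splicing (AS) landscape from two
kinds of evidence: assembled transcript models (a GTF) and per-sample
splice-junction support tables. This vignette explains the statistical
machinery, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the numerical corner cases.

## Coordinate conventions and data shapes

All internal coordinates are 0-based half-open; GTF I/O converts to and
from the standard 1-based inclusive dialect. Every user-facing function
takes a tibble and returns one, so analyses chain with the pipe: gene and
transcript models are a tidy exon table (one row per exon/CDS feature),
introns, junctions, events and quantifications are all long tables keyed
by stable identifiers.

## Junction filtering

Spliced alignments produce junction artifacts, chiefly from reads with
mismatches that wobble one splice site by a few nucleotides. Three ordered
rules clean a per-sample junction set:

* **R1** — fewer than 2 deduplicated supporting reads (PCR duplicates are
  reads with identical alignment endpoints supporting the same junction);
* **R2** — support consists exclusively of mismatch-carrying reads;
* **R3** — any mismatch-carrying support, and the donor or acceptor lies
  within 10 nt of the corresponding site of a *different* junction that
  has perfect-match support.

The 10 nt proximity is measured per site (donor-to-donor,
acceptor-to-acceptor) because misalignment moves one splice site, not the
whole intron. The source description of the mismatch handling is
ambiguous about whether mismatch-only junctions are removed outright or
only when near a perfect junction; both behaviours are available
(`apply_r2`, `apply_r3`), with R2+R3 the default. Filtering is idempotent
and partitions the input into kept and reason-tagged removed rows.

## Intron features

For each intron the package computes length (flagging the >50 kb
"enormous" class), AU-richness (A+T fraction over non-N bases of the full
intron sequence, matching the genome-wide percentages this quantity is
usually quoted at), strand-corrected border dinucleotides (canonical
introns read GT..AG in spliced orientation), and a position-weight-matrix
(PWM) splice-site score.

The PWM uses a 9-nt donor window (last 3 exonic + first 6 intronic nt)
and a 23-nt acceptor window (last 20 intronic + first 3 exonic nt), the
window sizes popularised by classic splice-site models. Scores are
log-odds in bits, `sum(log2(p_pos(base)/background(base)))`, with a
pseudocount (default 1) guaranteeing positive frequencies; the background
is pooled over all window positions of the training set. The consensus
sequence attains the maximal score by construction. Because no published
scoring tool is being reproduced, absolute score values are meaningful
only relative to the same PWM; analyses should compare groups (e.g.
constitutive versus alternative introns) with the Wilcoxon rank-sum test
exposed as `compare_groups()`, not across differently trained models.
Introns shorter than 26 nt (overlapping windows) or with windows beyond
chromosome ends are excluded from training and scored `NA`. `N` bases are
skipped and counted, not treated as mismatches.

Constitutive status follows a containment-restricted universality rule:
an intron is constitutive iff every isoform of its gene whose genomic
span covers the intron carries it with an identical span. Restricting to
covering isoforms stops 5'/3'-truncated isoforms from demoting shared
internal introns.

## Event detection

The five local AS event types (SE, RI, A5SS, A3SS, MXE) are extracted
from every unordered isoform pair within a gene, SUPPA-style, and
deduplicated by a canonical, pair-order-invariant key. A5SS/A3SS labels
are strand-aware. Beyond the literal "two introns sharing one boundary"
condition, A5SS/A3SS detection requires the flanking exons on the
alternative side to overlap; without this, a skipped-exon isoform pair
also satisfies the literal condition and would emit spurious
alternative-site events. Nested alternatives emit the maximal set of
simple pairwise events; there are no compound types. Cross-gene and
cross-strand events are impossible by construction because isoforms are
compared only within a gene.

Each event's defining span (SE: skipped exon; RI: retained intron;
A5SS/A3SS: interval between the alternative boundaries; MXE: hull of the
two exons) is assigned to the 5'UTR/CDS/3'UTR region of the
representative isoform with the largest overlap, ties going to the more
5' region in transcript orientation. The representative isoform is the
one with the greatest summed exon length — mature transcript length, not
genomic span — with deterministic tie-breaks (smaller start, then
transcript id).

## Quantification

For an event with inclusion-isoform junctions `J_inc` and
exclusion-isoform junctions `J_exc`,

$$\mathrm{PSI} = \frac{C_{EII}}{C_{EII} + C_{EEI}}, \qquad
\mathrm{AS\ score} = \frac{\mathrm{PSI} - 0.5}{0.5},$$

where `C_EII`/`C_EEI` sum deduplicated junction reads over the
corresponding set. The exon-exclusion isoform is the one with the larger
intron. Retained introns have no inclusion junction, so inclusion
evidence arrives as an optional per-intron retention count (reads inside
the retained interval), supplied by the simulator or any external
counter — the package itself never touches alignments. Raw junction
counts are used without form-length normalisation; a hook for custom
library sizes exists where normalisation matters (group aggregation).
PSI is undefined (NA) at zero total evidence, and the AS score maps
[0, 1] onto [-1, 1] with 0 meaning equal isoform abundance.

Transcript-level cleaning discards isoforms with intronic read fraction
above 0.15 **or** FPKM below 10% of the gene's major isoform. The OR
combination mirrors the fact that the two thresholds originate as
independent assembler parameters; AND is available. The major isoform is
exempt from the relative rule, and if an expressed gene would lose every
isoform (all failing the intronic rule), the major isoform is retained
and flagged `rescued`, so downstream per-gene statistics never divide by
zero. FPKM is the plain `1e9 * fragments / (length * library_size)` with
no effective-length or cross-library geometric normalisation.

## Specificity (Tau)

Group abundances are obtained by summing an event's EII and EEI counts
over the samples of each tissue (or tissue x stage) and converting to
counts per million within the group; the library size defaults to each
sample's total event-junction counts and can be supplied explicitly.
Counts rather than PSI feed Tau because specificity of an *isoform side*
is the quantity of interest (a PSI mode is a one-line change on the
aggregated table). Sides whose maximum per-group raw count is below 3
are ineligible — presence/absence statements are meaningless below that
coverage. Tau is

$$\tau = \frac{\sum_{i=1}^{n} (1 - \hat x_i)}{n - 1}, \qquad
\hat x_i = \frac{x_i}{\max_i x_i},$$

which is 0 for uniform abundance, 1 for single-group abundance, and
scale-invariant. With the default threshold of 1 the call reduces to the
literal rule "non-zero in exactly one group" (tested as an exact oracle
equivalence); the threshold is exposed because strict zeros are fragile
under sequencing noise.

## Differential splicing

Replicate-level inclusion/exclusion counts are modelled as binomial with
a condition-specific inclusion probability under the alternative and a
shared probability under the null. Because this is a binomial GLM with a
single two-level factor, both maximum-likelihood estimates are pooled
ratios in closed form, and the likelihood-ratio statistic
`2(ll_alt - ll_null)` is referred to chi-square with 1 df (the
agreement with `glm(..., family = binomial)` is pinned by a test). A
hierarchical/paired model with overdispersion was deliberately not
reimplemented: the plain binomial LRT is fully testable and calibrated
(type-I error is checked under the null), and the simulator's
beta-binomial mode quantifies how overdispersion inflates replicate
variance. Complete separation (a condition entirely inclusion or
exclusion) puts the MLE on the boundary; the statistic remains the
finite profile log-likelihood ratio under the `0 log 0 = 0` convention
and the event is flagged `boundary`. Events lacking counts in either
condition are skipped, p-values are BH-adjusted, and `q < 0.05` (the
conventional FDR level) defines significance.

## The synthetic-data generator

`simulate_annotation()` builds each gene as a multi-exon backbone plus
one extra isoform per planted event; `simulate_junction_counts()` layers
a tissue x stage x replicate count design on top. Defaults encode the
study conditions the package targets:

* AS-type mix RI 37.04%, SE 32.90%, A3SS 15.98%, A5SS 12.74%, MXE 1.34%
  — the RI-dominated profile characteristic of the goat transcriptome
  (the MXE value is taken as 0.0134 so the five proportions sum to 1).
* Intron lengths log-normal with median 1,472 nt and `sdlog = 1.69`,
  chosen so the mean/median ratio matches the reported 6,103.75/1,472
  and the unconstrained tail puts ~2% of introns above 50 kb. That
  enormous tail is truncated by default (`allow_enormous = FALSE`)
  because desk-scale genomes otherwise balloon; switching it on restores
  the tail.
* 98% canonical GT-AG borders (remainder GC-AG 50%, AT-AC 30%, random
  20% — minor-class shares are a package choice, with GC-AG the most
  common minor class in mammals), intronic AU content 0.53, exonic
  composition uniform.
* Five tissues, four stages, three replicates; per-event junction
  coverage Poisson with mean 50 per sample, a typical depth for a
  well-expressed event in bulk RNA-seq; 10% of events tissue-specific
  (inclusion evidence zeroed outside one tissue); binomial counts by
  default with a beta-binomial `rho` option.

Event loci within a gene are kept at least two exons apart. This is not
cosmetic: adjacent loci create emergent pairwise events (two skipped
exons one position apart read as an MXE between the two alternative
isoforms), which would make "detected = planted" unachievable by any
detector. With separation, detection on noise-free output recovers
plantings exactly, which is verified over a 20-seed sweep.

What the generator does **not** emulate: repeat sequence, GC isochores,
alignment errors beyond the planted mismatch-only artifact junctions,
expression-level variation between genes, stage-dependent PSI
trajectories, and any read-level phenomena (no FASTQ). Passing tests on
this material therefore demonstrates correctness of the algorithms under
their stated models, not robustness to every artifact of real libraries.

## Problem sizes and determinism

Tests and the acceptance script run at desk scale chosen to keep
binomial/multinomial standard errors well inside the asserted bounds:
border composition on ~2,400 introns (350 genes), planted-event recovery
at 200 genes x 20 seeds, estimator calibration at 2,000-4,000 simulated
events. Every stochastic step flows from a single integer seed in the
configuration; annotation and count generation use distinct derived
seeds so the two stages can be regenerated independently.

## Known limitations

* RI inclusion evidence must be supplied externally; without a retention
  table RI events quantify as PSI 0.
* The event catalog is annotation-driven; events present in reads but
  absent from the supplied transcript models are invisible.
* Junction strand is trusted when present and ignored when `*`; on
  strand-ambiguous data A5SS/A3SS labels follow the annotation strand.
* Tau is computed on aggregated counts; heavy depth imbalance between
  groups should be handled by passing explicit library sizes.
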