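---
title: "Calling isoform-specific direct targets from binding and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling isoform-specific direct targets from binding and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobind)
```

## The analysis model

`isobind` operationalizes a common design for dissecting two regulator
isoforms — here written for the *Drosophila* SIN3 187 / SIN3 220 pair, but
generic in its mechanics. The design crosses two measurements per isoform:

1. **Binding**: ChIP-seq peak sets, two biological replicates per isoform,
   with per-peak fold enrichment over an input (chromatin) control.
2. **Regulation**: two differential-expression contrasts. The predominant
   isoform (220) is assayed by knocking the gene down in cells where it
   dominates, so a gene *up* upon knockdown is a candidate for repression
   by 220. The other isoform (187) is assayed by overexpressing it (which
   also displaces 220), so a gene *down* upon overexpression is a
   candidate for repression by 187. The sign conventions are opposite
   because the perturbations are opposite; `call_direct_targets()` makes
   this inversion explicit in one place.

A **direct target** is a gene that both responds in the relevant contrast
and is bound by the isoform. Crossing the two isoforms' direct-target
calls yields a seven-label partition of the union of direct targets:
`A_r`/`A_a` (direct for 220 only), `B_r`/`B_a` (direct for both, same
direction), `C_r`/`C_a` (direct for 187 only), and `D` (direct for both,
opposing directions). Genes regulated but unbound are retained with
`direct = none`, so indirect-target counts stay reportable.

### Assumptions

* DE tables are taken at face value: no count modeling or dispersion
  estimation happens here (that belongs to the upstream RNA-seq pipeline).
* Peak calling is upstream too; the package starts from called peaks and
  an input-enrichment value per peak.
* Binding anywhere in the promoter-to-terminator window is treated as
  binding of the gene; the window model does not distinguish promoter
  binding from gene-body binding for target calling (the feature
  annotation reports that separately).
* One gene = one model: multi-transcript genes are collapsed on read.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_fold` | 3 | fold over input | the "three fold or more enriched over input" peak filter; inclusive |
| `concordance_min_frac` | 0.5 | fraction of peak length | replicate-reproducibility filter (see below) |
| `overlap_min_frac` | 0.5 | fraction of peak length | "at least 50 % overlap" rule for calling two isoforms' peaks the same site; inclusive |
| `upstream` / `downstream` | 1000 / 100 | bp | assignment window, TSS − 1 kb to TES + 100 bp, strand-aware |
| `kd_min_fold`, `kd_max_fdr` | 1.5, 0.05 | linear fold, q-value | knockdown DE regime; both inclusive |
| `oe_min_fold`, `oe_max_fdr` | 2, 0.001 | linear fold, q-value | stringent overexpression regime (the transgene is overexpressed, so a stronger threshold guards against dosage artifacts) |
| `go_cutoff` | 0.05 | p-value | strict (`<`) cutoff for pooling enriched terms |
| `metagene_flank`, bins | 2000 bp; 100/200/100 | bp; bins | −2 kb TSS → +2 kb TES averaging grid |

Every default is overridable through `pipeline_params()`.

## Design choices where the design was open

**Replicate concordance instead of IDR.** The irreproducible-discovery-rate
procedure operates on ranked peak lists with a copula mixture model; it is
a method of its own and is not reimplemented here.
`replicate_concordant()` is a deliberate, simple stand-in: keep a
replicate-1 peak when some single replicate-2 peak covers at least half of
it. It is documented as such and its stringency is tunable.

**Directional overlap.** The 50 % overlap criterion is evaluated relative
to each peak's own length, summed across (merged) partners in the other
set. This directional reading is what allows the two sets to report
different percentages (e.g. 86 % of the smaller set against 73 % of the
larger); a mutual-50 % reading would force symmetric counts. The boundary
is inclusive.

**Assignment requires one base.** Peak-to-gene assignment uses ≥ 1 bp
overlap with the window: the 50 % rule is specific to peak-to-peak
comparison, and no minimum is stated for assignment. One peak may be
assigned to several genes (genes can be close or nested in real genomes);
the monotonicity property — enlarging the window never unbinds a gene —
is part of the test suite.

**Midpoint feature categories.** Each peak is categorized by its midpoint
so that every peak lands in exactly one of the eight categories and
percentages sum to 100. When the midpoint lies in overlapping annotations
of different genes, precedence is promoter ≤ 1 kb > 5′UTR > 3′UTR >
coding exon > intron > promoter 1–2 kb > promoter 2–3 kb > distal
intergenic — promoter-proximal first, consistent with TSS-centred
binding. UTRs derive from CDS bounds; genes without a CDS contribute no
UTR or coding-exon intervals, and introns are the literal gaps between
exons, so a midpoint inside a non-coding gene's exon falls through to a
promoter tier of a neighbouring gene or to distal intergenic rather than
being mislabelled intronic.

**Union-span gene collapsing.** Multi-transcript genes are collapsed to
one model per `gene_id`: span = union of transcript spans, exons = merged
exon union, CDS = outer hull. How the original study collapsed transcripts
is not recoverable; the union rule is the least surprising for
window-based assignment (a peak touching any transcript's promoter
window should count) and is configurable via `collapse = FALSE`.

**Class D is strict.** `D` requires a gene to be a *direct* target of both
isoforms in opposing directions. The looser reading — lumping in genes
directly called for one isoform and regulated-but-unbound in the other
contrast — is representable from the output (the calls table carries both
DE statuses and both bound flags) but is not the default label.

**Enrichment statistics.** `enrich()` offers the textbook one-sided
hypergeometric tail and the EASE variant (hit count reduced by one before
taking the tail), the conservative score popularized by DAVID; EASE is the
default to mirror common practice, and the plain hypergeometric mode is
what the closed-form tests verify. No multiple-testing correction is
applied by default because the pooling step consumes raw p < 0.05 values;
a Benjamini–Hochberg column is available by flag. The background universe
is always an explicit argument — whole annotation vs detected genes is a
choice the user must make consciously.

**Percent of input.** The input Ct is adjusted for the input dilution d by
`Ct_input − log2(1/d)` (the Ct a 100 % input would have shown), and the
recovered fraction is `100 · 2^(Ct_input_adj − Ct_IP)` — equivalently
`100 · d · 2^(Ct_input − Ct_IP)`. Amplification efficiency is fixed at
perfect doubling, matching the plain 2^−ΔΔCt convention; no standard-curve
correction is attempted.

## Numerical conventions

* All internal coordinates are 0-based half-open (BED convention); GTF's
  1-based closed coordinates are converted on read. The TSS of a `-`
  strand gene is `end − 1`.
* All thresholds quoted as "≥ x" or "≤ y" are inclusive; the enrichment
  pooling cutoff ("< 0.05") is strict.
* Percentages are reported to the nearest integer via
  `round(100·k/n)`; a zero denominator reports `NA`, never 0.
* Metagene bodies: genes at least as long as `body_bins` are averaged per
  bin by dealing bases to bins (`floor((i−1)·bins/n)`); shorter genes are
  linearly interpolated. Minus-strand genes are reversed before averaging;
  each gene carries equal weight; signal is 0 where the track is
  undefined.
* Peaks with identical coordinates are deduplicated on read with a
  warning; ties elsewhere are resolved by stable (chrom, start) sorting.

## The synthetic-data generator

`simulate_config()` / `simulate_bundle()` produce a complete,
internally consistent study: five euchromatic arms plus a small
heterochromatic chromosome; non-overlapping genes with two exons and a CDS
each, spaced so that the intergenic gap exceeds the assignment window plus
the widest peak (planted binding is therefore unambiguous); TSS-centred
peaks for every planted bound gene, with sub-threshold noise peaks and a
~1 % heterochromatic complement; Gaussian TSS signal bumps over a uniform
background; DE tables in which planted genes draw fold changes above and
q-values below the regime thresholds and null genes the reverse; and
marker terms per class for the enrichment stage. The planted quantities —
class counts, bound sets, DE directions, per-peak overlap partners — are
returned as ground truth, and with zero noise the pipeline recovers them
exactly (the central recovery test). `de_flip_rate` corrupts a fraction of
null genes to study graceful degradation; recovery error grows
monotonically with it in expectation.

Default scale is ~1,000 genes and ~1,800 peaks per isoform, which keeps
the full recovery test under a minute; `config_study_scale()` scales the
same generator to ~14,500 genes so that expected totals sit at the
published scale of the SIN3-isoform study (4903/5810 peaks, 263/349 and
605/669 regulated genes, 86 %/73 % overlap). The preset's class-B and
class-D sizes are chosen to make the knockdown-side direct-target counts
exact (243 repressed, 162 activated); the published per-class counts
cannot all be satisfied simultaneously under the strict partition, so the
overexpression-side totals land close to, not on, their published values
(267/328 vs 282/338) — a direct consequence of the strict class-D
definition discussed above.

What the generator does **not** emulate: read-level noise, peak-shape and
summit-offset variation, correlated replicates with ranked significance
(hence no meaningful IDR), overlapping or nested genes (an explicit
adversarial fixture in the tests covers interval edge cases instead), and
realistic fold-change/q-value joint distributions. Passing recovery tests
therefore demonstrates the correctness of the integration arithmetic, not
robustness to upstream noise in real data.

## Running the pieces

```{r example, eval = FALSE}
bundle <- simulate_bundle(simulate_config(seed = 1))
result <- run_pipeline(list(annotation = bundle$annotation,
                            peaks = bundle$peaks, de = bundle$de,
                            signal = bundle$signal, terms = bundle$terms,
                            pool_map = bundle$pool_map))
glance(result)
tidy(result$summary)
plot_metagene(result$metagene)
write_pipeline_report(result, "report/")
```

Stages are plain functions (`filter_by_fold()`, `replicate_concordant()`,
`compare_peaksets()`, `assign_peaks_to_genes()`, `chrom_distribution()`,
`annotate_features()`, `metagene()`, `filter_de()`,
`call_direct_targets()`, `classify_genes()`, `summarize_counts()`,
`enrich()`, `pool_categories()`, `percent_input()`, `ddct_fold()`) that
take and return tibbles, so any subset can be rearranged in a dplyr
chain.

## Known limitations

* The replicate-concordance filter is a stand-in for IDR, not an
  approximation of it; stringencies are not comparable.
* Feature categorization by midpoint under a fixed precedence is one of
  several defensible conventions; tools differ here, and percentages are
  not directly comparable across conventions.
* The metagene averages a single track per isoform; it does not normalize
  ChIP to input internally (provide a pre-normalized track if that is
  wanted).
* Enrichment assumes a flat term structure; no ontology-graph propagation
  is performed, and pooling follows a user-supplied map.
* qPCR formulas assume perfect amplification efficiency.
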