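---
title: "Rare-variant discovery from overlapping-pool DNA sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant discovery from overlapping-pool DNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolRSV)
```

# The problem

Screening hundreds of case and control individuals for rare, highly penetrant
single-nucleotide variants (RSVs) in a candidate-gene panel is expensive if
every sample is sequenced individually. Pooled DNA sequencing reduces the
cost: DNA from many individuals is mixed into one library, and the panel is
sequenced once per pool at very high depth. The price is that a variant call
no longer names its carrier, and a heterozygous singleton is diluted to a tiny
allele fraction that sits near the sequencing error floor.

poolRSV implements the complete discovery workflow for the two-replicate
overlapping pool design, in which each sample is placed in exactly two pools
and no two samples share the same pool pair. The motivating application is a
severe early-onset obesity screen: 463 patients and 480 controls, each cohort
distributed over 48 pools of 20 samples, targeting the coding exons of 15
appetite-regulation candidate genes (the leptin–melanocortin axis and
GWAS-implicated genes), with carrier burden compared between cohorts.

# Pool design and dilution arithmetic

With pools of $K$ diploid samples, $c$ alternate allele copies in a pool are
expected in a fraction

$$f = \frac{c}{2K}$$

of the reads: one heterozygous allele in a 20-sample pool appears in
$1/40 = 2.5\%$ of reads, two copies (one homozygote, or two carriers sharing
a pool) in $5\%$. Because every sample sits in two pools and the
sample $\to$ pool-pair map is injective, a singleton het variant is seen in
exactly two pools and the pair identifies the carrier uniquely.

`build_pool_design()` constructs the assignment by greedy randomized pairing
(draw an unused pair among pools with free slots; restart on dead ends). Any
injective, capacity-respecting assignment is equivalent for decoding, so the
construction algorithm is not load-bearing; `validate_pool_design()` checks
the invariants that are (two distinct pools per sample, pool capacity,
injectivity, slot arithmetic $2n \le PK$). Feasibility requires
$2\,n_\text{samples} \le n_\text{pools} K$ and
$n_\text{samples} \le \binom{n_\text{pools}}{2}$; both violations raise
capacity errors. The study geometry, 463 samples in 48 pools of 20, uses 926
of 960 slots.

# The simulated sequencing regime

`simulate_cohort()` generates per-pool, per-site pileup count rows (depth,
alt count, mean base quality, forward-strand fraction) rather than reads;
alignment, indel realignment and mapping artifacts are out of scope. The
generator's defaults are the study conditions:

* **Depth**: rounded normal, mean 2396, SD 574 (the patient-pool coverage;
  control pools use 3428/660), truncated below at 400 — the regime in which
  more than 98% of targeted sites exceed 400x and a 2.5% allele still
  contributes tens of reads.
* **Substitution error**: $\varepsilon = 10^{-3}$ per base, $\varepsilon/3$
  per specific alternate base. At several-thousand-fold depth this puts a
  nonzero error count at almost every site, which is precisely why a filter
  stack is needed. The error rate is a free knob (the original experiment
  does not report one); $10^{-3}$ keeps a 1% allele fraction detectable at
  ~2400x while producing realistic noise density.
* **Alt-read probability at a planted site** with $c$ carrier copies:
  $p = f(1-\varepsilon) + (1-f)\varepsilon/3 = f(1 - \tfrac{4}{3}\varepsilon)
  + \varepsilon/3$ — an allele read survives miscalling with probability
  $1-\varepsilon$, and a reference read is miscalled to the specific
  alternate with probability $\varepsilon/3$.
* **Base qualities**: reads supporting a real allele draw mean BQ from
  $\mathcal{N}(30, 3)$; error and artifact reads from $\mathcal{N}(8, 3)$
  (clipped at 0). These bracket the BQ > 15 filter from both sides so the
  filter's behaviour is testable in both directions; they are stand-ins, not
  claims about any particular instrument.
* **Strand**: real alleles split forward/reverse as Binomial$(k, 1/2)/k$;
  injected strand-type artifacts are forced outside the $[0.2, 0.8]$ band.

`inject_artifacts()` plants artifact entries at random sites in random single
pools with allele fractions drawn inside $[2\%, 8\%]$ — deliberately inside
the caller's keep-window, so only the base-quality and strand filters can
reject them. That construction makes the zero-survivors specificity property
a test of those filters rather than of the fraction window.

What the simulation does *not* emulate: mapping and alignment error,
systematic (context-dependent) error hotspots, indels, batch effects between
pools, and capture bias. Passing tests therefore demonstrate the pipeline's
internal correctness and its behaviour under the stated statistical regime,
not performance on any particular real instrument run.

# The caller and filter stack

Real low-fraction callers generate candidates with a somatic-style
likelihood-ratio test; the bespoke part of this workflow is the filter stack,
so the caller is self-contained. `score_candidate()` computes a Phred-scaled
binomial likelihood ratio

$$\mathrm{score} = 10\log_{10}
\frac{L(k \mid n, \hat f)}{L(k \mid n, \varepsilon/3)},
\qquad \hat f = \max(k/n,\ \varepsilon/3),$$

clipped below at zero. The Phred scaling makes the published "score over 5"
threshold directly applicable. The scoring $\varepsilon$ defaults to the
simulation's but is an independent argument — on real data it would be
estimated from the run.

`apply_filters()` applies four independent per-call predicates, retaining
failed calls with explanatory flags:

| filter | rule | boundary |
|---|---|---|
| `low_score` | score > 5 | strict: 5 fails |
| `low_bq` | mean BQ > 15 | strict: 15 fails |
| `strand_bias` | fwd fraction in [0.20, 0.80] | inclusive: 0.20/0.80 pass |
| `fraction_out_of_range` | AF in [0.01, 0.10] | inclusive: 0.01/0.10 pass |

The boundary semantics follow the literal reading of the thresholds ("over
5", "over 15", "between 1 and 10%", "<20% or >80%"). The AF ceiling encodes
that three or more carrier alleles in one pool (AF > 10%) is too common to be
a rare highly penetrant variant; the floor discards sub-1% fractions as
artifacts. Because the predicates are per-call and independent, filter order
is irrelevant — a property the tests verify over permutations. The score/BQ
conditions must hold in both pools where the variant is observed; this falls
out of decoding, which only consumes passing calls and requires both pools of
the carrier pair.

`flag_low_coverage()` marks calls at depth strictly under 1000x for manual
review without excluding them, mirroring individual assessment of
low-coverage positions; reports list them separately.

# Carrier decoding

`decode_variants()` groups passing calls by variant and intersects supporting
pools with the design. Two pools forming an assigned pair decode to that
sample (`unique`); more than two pools trigger an exhaustive search for the
smallest sample set whose pool pairs exactly cover the supporting pools
(`multi_carrier` when the minimal cover is unique, `ambiguous` when several
exist); one pool, or no consistent cover, is `undecodable`. The search is
capped at 3 carriers per variant: the 10% AF ceiling removes variants common
enough to need more. The same variant in two samples sharing one pool yields
three supporting pools with ~5% fraction in the shared pool;
`estimate_copies()` (`round(f * 2K)`) reports per-pool copy numbers
consistent with the cover. Ambiguous and undecodable variants are always
reported — they are the design's measurable failure modes, and the evaluation
counts a planted variant as detected only when decoded to exactly its true
carrier set.

The exhaustive cover search is this package's explicit completion of a step
the original custom decoding scripts left unspecified; at these pool counts
the search space is tiny, so no heuristic is needed.

# Prioritization cascade

`prioritize_variants()` applies, in order: a region filter (exonic
consequences and splice variants within ±6 of the exon boundary; offset 7 is
out), a rarity filter (maximum population frequency across databases at most
1/1000 — strictly: a 1/945 variant fails — and no homozygote ever observed;
missing annotation excludes conservatively), then classification:
experimentally validated variants are `known_pathogenic`; nonsense,
frameshift and canonical-splice variants are `likely_pathogenic`; missense
variants with Condel > 0.522 **and** CADD > 20 are `likely_pathogenic`;
everything else surviving the filters is `rare_RSV`. Synonymous variants can
survive the filters but never reach `likely_pathogenic`.

Gene-level constraint (pLI > 0.50 and missense Z > 0) is attached as a
per-variant flag, not used as a gate: the constraint metrics inform
interpretation of which genes accumulate burden, and gating on them would
change the carrier counts. Annotation is consumed from a flat table (the
maximum-frequency column collapses the per-database columns); nothing is
fetched live.

# Burden statistics

`tabulate_carriers()` counts *distinct individuals* carrying at least one
qualifying variant per cohort (a sample with two qualifying variants counts
once). The headline statistic, `ratio_statistic()`, is the ratio of carrier
proportions $(a/n_a)/(b/n_b)$. The published association values it must
reproduce (1.61, 2.98, 7.78, 1.69, 6.55) are labelled "OR" in the source
table but arithmetically are proportion ratios — e.g. 48/463 vs 31/480 gives
a proportion ratio of 1.605 and a classical odds ratio of 1.675. The package
therefore implements the proportion ratio as the headline statistic and
reports the classical `odds_ratio()` alongside, clearly labelled.

`fisher_exact_2x2()` computes the exact two-sided p by full enumeration of
the hypergeometric support, summing the probabilities of all tables no more
probable than the observed one (the standard minimum-likelihood rule, with a
$1 + 10^{-7}$ relative guard against floating-point tie loss). A
`choose()`-based enumeration written from first principles, and
`stats::fisher.test`, serve as independent oracles in the test suite. The
source study does not name its test; its printed p-values are reproduced by
this exact test on the printed counts (0.0342, 0.0055, 0.0306, 0.0002), but
only the ratio statistics and percentages are treated as must-match figures.

Display rounding is half-away-from-zero: 2 decimals for ratios and
percentages (table style; the headline carrier rate 23/463 is 5.0% at 1
decimal), with sensitivity reported as a whole percent (6/7 → 86%) while
stored unrounded.

# Pipeline, evaluation and problem sizes

`run_config()` bundles every parameter with a mandatory master seed;
per-cohort stage seeds are derived from it, so identical configurations give
byte-identical outputs, and the configuration round-trips through YAML.
`run_pipeline()` executes design → simulate → inject → call → decode
(→ prioritize → burden) and `evaluate_run()` reports sensitivity (planted
variants decoded to exactly their true carriers), the artifact survival count
(specificity proxy), the decoding ambiguity rate, and a per-filter exclusion
ledger that conserves candidates (exclusions + passing = total calls).

Problem sizes used in the shipped tests and analysis scripts were chosen to
give stable statistics at desk scale: dilution checks use 100 het and 50
homozygous singletons in a 200-pool design (≥200 carrier-pool observations
per class, empirical means within 3 Monte-Carlo SEs of 2.5%/5%); the
matched-regime sensitivity run uses the full study geometry (463 samples, 48
pools of 20, coverage 2396/574, $\varepsilon = 10^{-3}$) with 60 planted
singletons over a 300-bp target. In that regime the pipeline decodes
essentially every planted singleton (the 86% sensitivity floor observed in
the original experiment reflects real-data failure modes — one known variant
sat at low quality scores — that the clean statistical regime does not
reproduce; the simulation shows the regime supports it with margin).

# Numerical and degenerate-input choices

* Scores are clipped at 0; `alt_count = 0` gives likelihood ratio 1, score 0.
* `estimate_copies()` rounds halves away from zero (nearest whole allele).
* Proportion ratios with a zero denominator cohort return `Inf` (undefined
  marker) rather than an error; odds ratios with any zero cell likewise, with
  no continuity correction.
* Empty variant sets, empty pileups and empty truth tables flow through:
  evaluation on an empty truth is flagged inapplicable rather than reported
  as 0% or 100%.
* Coordinates are 1-based fully closed internally; BED input (0-based
  half-open) is converted on read via `rtracklayer`.

# Known limitations

The caller treats each (site, alternate base) independently — no indels, no
multi-allelic joint modelling, no base-quality recalibration. Decoding
assumes the two-replicate design; higher replication or probabilistic
(likelihood-weighted) decoding is out of scope. The burden module compares
carrier proportions with an exact test; regression-based burden frameworks
(SKAT and relatives) and multiple-testing correction across genes are
deliberately not provided. Constraint metrics and deleteriousness scores are
consumed as given, never computed.
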