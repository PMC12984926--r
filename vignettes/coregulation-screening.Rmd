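---
title: "Screening for co-regulated phosphosites: model, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for co-regulated phosphosites: model, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscoreg)
```

## The setting

A curated phosphoproteomic corpus is a collection of *differential
datasets* — treatment-vs-control comparisons, each reporting per-phosphosite
fold changes and p-values — grouped into studies (PMIDs), plus *profiling
datasets* that are detection inventories without a control arm. The screen
asks two things of such a corpus: which phosphosites of a kinase of
interest recur most often (its *predominant* sites), and which phosphosites
on other proteins (the POp universe) are co-differentially regulated with a
predominant site across unrelated conditions.

The central assumption is that consistent co-movement across many
independent experimental contexts is evidence of shared regulation —
upstream kinase, complex membership, or pathway coupling — even though any
single comparison proves nothing. Everything in the package is built to
make that aggregation honest: exact inference on small discrete tables,
evidence filters that demand breadth across studies, and a generator that
lets the false-positive and recovery rates be measured rather than assumed.

## From records to calls

Each differential record carries a fold change (treatment/control, ratio
scale), a p-value, and localization evidence. Processing is a fixed
sequence:

1. **Class-1 filtering.** A record is retained iff its localization
   probability is ≥ 0.75 *or* its A-score exceeds 13. The boundary
   semantics follow the wording of the conventional definition: the
   probability cut is inclusive, the A-score cut strict. Records carrying
   neither field are dropped and counted in the log.
2. **Regulation calling.** `U` iff fold change > 1.3 and p < 0.05; `D` iff
   fold change < 0.76 and p < 0.05; otherwise `N`. Both fold-change
   boundaries are strict, so a fold change of exactly 1.3 or 0.76 is never
   called. An optional `log2_fold_change` input column is converted by
   `2^x` before thresholding. Records without a p-value default to `N`,
   because "significant in the originating study" cannot be asserted;
   corpora whose records were pre-filtered for significance upstream can
   set `allow_missing_p = TRUE` in `differential_thresholds()`.
3. **Matrix assembly.** Calls are arranged into a sites × conditions matrix
   with every unobserved cell set to `N`. A site that was quantified but
   unchanged and a site that was not detected at all are deliberately *not*
   distinguished: the contingency table's "neither called" cell collapses
   both. This is an interpretation choice — heterogeneous corpora rarely
   report which proteins were measurable in which study, so the
   distinction is not recoverable in practice. Conflicting duplicate calls
   for one (site, condition) are an error, not a vote.

## The co-detection exact test

For an anchor a and partner p, every condition contributes one of six joint
states: `UU`, `DD` (concordant), `UD`, `DU` (discordant), both-`N`, or
exactly-one-`N`. These tally into the 2×2 table with cells a (both `N`),
b (exactly one called), c (discordant) and d (concordant); a+b+c+d equals
the condition count by construction, which is asserted in tests.

Significance is the two-sided Fisher's exact test computed from scratch:
hypergeometric point probabilities for all tables with the observed
margins, summed over tables whose point probability does not exceed the
observed one. Two numerical choices matter:

* factorials are evaluated in log space (`lgamma`), so tables with n in the
  hundreds are exact to machine precision;
* the "at least as extreme" comparison uses a relative tolerance of 1e-12,
  because opposite-tail tables often have *mathematically equal* point
  probabilities that differ in floating point by an ulp — without the
  tolerance such tables are silently lost and the two-sided p is
  underestimated. When every admissible table qualifies, the p-value is
  returned as exactly 1 rather than a rounding neighbour of it.

The test suite sweeps every 2×2 table with n ≤ 40 (135,750 tables) against
an independent brute-force enumeration built on `stats::dhyper`, with
`stats::fisher.test` as a second cross-check on random tables.

Direction is assigned by dominance: positive iff d > c (and
d/max(c,1) reaches `dominance_ratio`, default 1), negative symmetrically,
ties `none`. A call is high-confidence only if *all* of: FET p < 0.05
(raw, matching the screen this package operationalizes; Benjamini–Hochberg
adjustment is available behind `adjust_p` but off by default), supporting
events (d for positive, c for negative) ≥ 10% of the anchor's differential
frequency, ≥ 3 supporting studies, and ≥ 3 supporting conditions. The
supporting studies/conditions are those contributing the direction's own
events — concordant conditions for a positive call, discordant for a
negative one.

One subtlety of this table layout is worth stating plainly: a perfectly
negatively co-regulated pair that is *always* co-detected (a = b = 0,
d = 0) yields a degenerate table with p = 1, because with both margins
fixed there is only one admissible table. Negative co-regulation is only
detectable against variation in co-detection — which real sparse corpora
always have, but hand-built toy matrices may not.

## Predominance

A site's differential frequency counts conditions with a `U` or `D` call —
not mere quantification — and its profiling frequency counts distinct
profiling datasets detecting it. Ranking is by differential frequency,
ties broken by profiling frequency then position, making the order a pure
function of the data. The conventional "observed in at least 50% of
datasets" inclusion rule is exposed as `min_fraction` but defaults to 0:
published screens of this design report predominant sites whose observed
frequencies sit well below 50% of their own corpus (e.g. a second-ranked
site near 34%), so the rule cannot be what actually selects them. Rank
with a rank-1 override — the top site is predominant even if no site
clears the fraction — reproduces the operative behaviour without the
inconsistency.

## Conservation scoring

Published family-conservation scores for phosphosites come from resources
whose exact formulas are not public. The package therefore defines its own
fully specified surrogate and documents it as such; it is *not* expected
to reproduce any external resource's values, and the package's guarantees
about it are property-based (bounds, permutation invariance,
monotonicity), not value-matching.

Given a family alignment and a reference site, the score is

    score = w * acceptor_fraction + (1 - w) * window_identity,  w = 0.5

where `acceptor_fraction` is the fraction of non-reference members with a
phospho-acceptor in the site's column (S and T interchangeable, because a
site conserved as serine in one paralog and threonine in another is the
same functional site; Y sites require Y), and `window_identity` is the
mean per-column identity to the reference over the ±5-residue window.
Columns where the reference is gapped are skipped — there is no reference
residue to match — which also covers all-gap columns; a gap opposite a
reference residue counts as a mismatch. The window truncates at sequence
ends rather than padding. A single-member family scores 1 by convention
(no counter-evidence). Classification is inclusive at the 0.75 threshold
so a score printed as "0.75" classifies as conserved; both the threshold
and the mixing weight are parameters.

## Enrichment and annotation

"Enrichment" here is hypergeometric over-representation of the passing
partners' proteins within user-supplied gene sets (GMT), with the protein
universe taken from the ingested corpus: the screen's output is a discrete
protein set with no ranking metric, so rank-based enrichment would be
ill-posed. `stats::phyper` provides the tail; tests verify it against a
direct log-space mass summation. Kinase/substrate/interactor edges and
disease expression labels are user-supplied tables joined by protein
symbol — provenance is carried as free-text evidence tags, with no
cross-database confidence model, and any prediction-score cutoffs are
applied by the user when preparing the tables. Networks are exported as
SIF, attribute-complete edge TSV (with fixed 15-significant-digit numeric
formatting so exports round-trip byte-identically), and GraphML.

## What the generator emulates — and what it does not

`simulate_corpus()` produces corpora with the statistical structure the
screen assumes: studies of `conditions_per_study = 3` conditions each
(making the three-study filter non-trivially satisfiable), sparse
detection, one anchor site, planted positive/negative partners, and
independent null sites. Defaults are the screen's reference conditions:
200 conditions, anchor detection probability 0.5, partner detection
coupling 0.9, agreement probability 0.9, up-probability 0.5. Null-site
detection probability 0.15 and 50 null sites are the package's own choice
of a realistic sparse background — most phosphosites in heterogeneous
corpora are observed in a small minority of comparisons. Fold changes are
drawn from log-normal distributions truncated to the calling regions, with
a 10% "near-miss" fraction (fold change inside (0.76, 1.3), or p ≥ 0.05)
so the caller's `N` branch is exercised by realistic records rather than
only by absence. One global seed drives a single random stream;
`withr::with_seed` restores the caller's RNG state.

The generator does *not* emulate: mass-spectrometry intensities,
missing-not-at-random detection (dropout is independent Bernoulli given
the anchor), batch or laboratory effects, correlated null sites, or
study-size heterogeneity. Passing tests therefore demonstrate that the
pipeline recovers planted structure under clean sparsity — they do not
certify behaviour under confounded real corpora, where the evidence
filters (studies, conditions) are the main guard.

## Measured operating characteristics

The acceptance suite and `scripts/acceptance.R` compute, at run time:
exactness of the test against enumeration (n ≤ 40); the type-I fraction on
2,000 independent null pairs at α = 0.05 (bounded at 0.07 — the exact test
is conservative on discrete tables, and a Monte-Carlo margin is included);
recovery of 200 planted positive partners at the default coupling (≥ 90%
significant and correctly signed, with planted negatives never called
positive); rank-1 recovery of an anchor with twice the background
detection probability over 200 replicate corpora of 100 conditions
(≥ 95%); and byte-level determinism of corpora and pipeline outputs under
fixed seeds. Problem sizes (2,000 null pairs, 200 partners, 200 × 100
replicate conditions) were chosen once as the smallest corpora at which
the binomial noise on each measured fraction is well inside its margin.

## Known limitations

* The screen is correlational; a passing pair is a hypothesis about shared
  regulation, not a kinase–substrate claim.
* Collapsing "unchanged" and "undetected" into `N` deflates the a-cell's
  information content; corpora with reliable detection inventories would
  support a finer three-way treatment the current tables do not attempt.
* Raw p < 0.05 across thousands of partner tests is the screen's
  convention, deliberately reproduced; the BH column exists for users who
  want error-rate control over the partner list.
* Conservation scores are surrogate values for classification, not
  comparable across alignments of different depth.
* Identifier normalization is table-driven; without an alias table,
  distinct symbols for one protein are distinct sites.
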