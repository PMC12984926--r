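# phoscoreg

Screening phosphoproteomic corpora for phosphosites co-regulated with a
kinase's predominant phosphosites.

## The problem

Large-scale phosphoproteomic studies each report, for thousands of
phosphosites, whether the site went up or down in a handful of
treatment-vs-control comparisons. Aggregated over hundreds of such studies,
two questions become answerable for a kinase of interest:

1. **Which of its phosphosites are predominant** — recurrently detected and
   differentially regulated across unrelated experimental conditions?
2. **Which phosphosites on *other* proteins (POp) move together with a
   predominant site** — consistently in the same direction (positive
   co-regulation) or the opposite direction (negative co-regulation) —
   hinting at shared upstream regulation or pathway membership?

`phoscoreg` implements this screen end to end for any anchor kinase site:
ingest and quality filtering, frequency ranking, an exact co-detection test
with stringent evidence filters, family conservation scoring, annotation
overlay and network export. Because published corpora of this kind are
assembled by manual curation and are rarely redistributable, the package
also ships a synthetic-corpus generator with planted co-regulation
structure, so every stage is testable and its error rates measurable.

## The statistic at the core

For an anchor site and one candidate partner, each experimental condition
contributes one joint observation: the anchor's call and the partner's call,
each `U` (up, fold change > 1.3 at p < 0.05), `D` (down, fold change < 0.76
at p < 0.05) or `N` (not called). Over all `n` conditions these tally into a
2×2 table

|            |                         |                          |
|------------|-------------------------|--------------------------|
| **a**      | neither site called     | **b** exactly one called |
| **c**      | discordant (UD or DU)   | **d** concordant (UU or DD) |

and the association is tested with a two-sided Fisher's exact test: the sum
of hypergeometric point probabilities

P_i = (a+b)! (c+d)! (a+c)! (b+d)! / ( n! a_i! b_i! c_i! d_i! )

over every table with the observed margins whose point probability does not
exceed the observed table's. The direction is `positive` when the
concordant count d dominates (d > c), `negative` when c dominates. A pair is
high-confidence only if it additionally clears: supporting events ≥ 10% of
the anchor's differential frequency, evidence from ≥ 3 studies (PMIDs), and
≥ 3 distinct conditions.

Ingest applies class-1 site confidence (localization probability ≥ 0.75 or
A-score > 13). Conservation of a site across its kinase family is scored on
a supplied alignment over a ±5-residue window (acceptor fraction at the site
column, S/T interchangeable, mixed 50:50 with window identity) and
classified conserved at ≥ 0.75.

## Worked example

```r
library(phoscoreg)

corpus  <- simulate_corpus(simulation_config(n_conditions = 200,
                                             n_null_sites = 50, seed = 42))
records <- call_regulation(filter_class1(corpus$differential))
m       <- build_regulation_matrix(records)
freqs   <- site_frequencies(m, corpus$profiling)
screen  <- coregulation_screen(m, "KINA:S100")
print(screen, n = 3)
#> <coregulation_screen> anchor KINA:S100 (differential frequency 76 over 200 conditions)
#>   52 partners screened, 3 pass all filters (2 positive, 1 negative)
#> # A tibble: 52 x 24
#>   partner     protein residue position    uu    dd    ud    du     a     b     c
#> 1 POSP001:S1… POSP001 S            101    36    20     2     4    94    44     6
#> 2 NEGP001:S1… NEGP001 S            101     4     2    33    19    91    51    52
#> 3 NULL032:S1… NULL032 S            132     1     4     0     0   103    92     0
```

The planted positive partner (`POSP001:S101`, 56 concordant vs 6 discordant
conditions) and the planted negative partner (`NEGP001:S101`, 52 discordant
vs 6 concordant) top the screen; the 50 independent null sites fall behind.
`glance(screen)` summarizes the filter funnel (here 6 partners pass the FET
threshold and 3 survive all evidence filters), `tidy(screen)` returns the
plain per-partner table and `autoplot(screen)` draws the
supporting-events-vs-p overview.

Conservation of the anchor site in the bundled synthetic three-member
family alignment:

```r
fam <- read_family_alignment(system.file("extdata",
         "synthetic_kinase_family.afa", package = "phoscoreg"))
conservation_score(fam, "KINA", c("S100", "S45"))
#> # A tibble: 2 x 6
#>   site  alignment_column acceptor_fraction window_identity score conserved
#> 1 S100               100                 1           0.864 0.932 TRUE
#> 2 S45                 45                 0           0.545 0.273 FALSE
```

S100 sits in a deliberately conserved window with acceptors in both
paralogs (score 0.93, conserved); S45 does not (0.27).

`run_pipeline()` chains all stages — ingest, ranking, screening,
conservation, annotation overlay, enrichment and network export — writes
every stage's TSV plus a resolved-config echo to an output directory, and
logs the record funnel. A subcommand wrapper for shell use is in
`inst/scripts/phoscoreg.R`.

## Layout

- `R/` — ingest, predominance ranking, exact test, co-regulation screen,
  conservation, annotation/network, simulator, pipeline orchestration.
- `vignettes/coregulation-screening.Rmd` — the model, its assumptions,
  parameter choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  enumeration/hand-computed oracles.
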