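# tsat — a toxicity study assessment tool for nano- and microplastics

`tsat` screens and prioritizes in vivo and in vitro toxicity studies of
nano- and microplastic particles (NMPs) for use in human-health risk
assessment. It is written for risk assessors and systematic reviewers
who score studies against a QA/QC rubric and need the bookkeeping —
validation, multi-rater consensus, aggregation, classification,
reporting — to be transparent and reproducible.

## The method

Each study is scored against a **criteria registry**: an ordered rubric
of criteria in three areas (particle characterization, study design,
applicability for risk assessment), each scored

* `2` — adequate,
* `1` — adequate with restrictions,
* `0` — inadequate.

All criteria have equal weight. The **total assessment score** is

    TAS = Σ_c s_c,   s_c ∈ {0, 1, 2},   TAS_max = 2 · |criteria|

with TAS_max = 52 for the shipped in vivo registry (26 criteria) and 46
for the in vitro registry (23 criteria). Studies are evaluated by at
least two raters; consensus is the per-criterion minimum by default
(majority-with-low-tie-break and strict agreement are available), with
all discordant criteria reported.

Three screening schemes are computed side by side:

1. **Tier-1 red-criteria gate** — pass iff every *red* (critical)
   criterion scores ≥ 1, regardless of TAS. Red-passing studies are the
   ones prioritized for Tier-2 expert elicitation. The shipped red set
   is particle size, shape, polymer type, source, endpoints,
   dose-response and (in vivo) effect threshold; it is fully
   configurable.
2. **Fernández-Cruz reliability classes** — *reliable* if the fraction
   of criteria at the maximum score exceeds 0.85 and the red criteria
   are met; *reliable with restrictions* in 0.61–0.85; *not reliable*
   otherwise.
3. **de Ruijter adequacy** — adequate iff no criterion scores 0.

## Worked example

```r
library(tsat)

reg <- default_registry("in_vivo")
reg
#> <tsat_registry> nmp_tsat_invivo (v1.0), in_vivo
#>   26 criteria (particle_characterization: 8, study_design: 13, risk_assessment: 5), 7 red, max TAS 52

# a 15-study demonstration corpus, two raters per study
fx <- generate_fixture(demo_corpus_spec(seed = 7))
corpus <- consensus_corpus(fx$evaluations, rule = "min")

screening <- tier1_screen(corpus, reg)
head(screening[, c("study_id", "tas", "tas_percent", "red_pass",
                   "fernandez_class")], 4)
#>      study_id tas tas_percent red_pass            fernandez_class
#> 1    ong_2020  44          85     TRUE reliable_with_restrictions
#> 2    lim_2021  37          71     TRUE               not_reliable
#> 3 mahock_2012  37          71     TRUE               not_reliable
#> 4 amereh_2019  34          65     TRUE               not_reliable

sum(screening$tier1_prioritized)
#> [1] 15
```

All 15 studies pass the red gate (the demo corpus is built that way),
so all 15 would move to Tier-2 review; the top study scores 44 of 52
(85%), and its 76.9% of criteria at the maximum score places it in the
reliable-with-restrictions class.

The same pipeline runs from a shell:

```sh
tsat fixtures --demo --seed 7 --out fx/
tsat screen fx/evaluations.csv --metadata fx/study_metadata.csv --out screening.csv
tsat report fx/evaluations.csv --metadata fx/study_metadata.csv --out report.md
```

Evaluation sheets are long-format CSV/TSV
(`study_id, rater_id, study_system, criterion_id, score`); registries
are YAML or JSON and can be edited freely — see
`vignettes/tsat-methods.Rmd` for the schema, the scheme definitions and
the design choices.

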