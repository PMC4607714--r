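# sarclean

Quality curation for literature-extracted bioactivity data.

Structure–activity (SAR) databases aggregate hundreds of thousands of
measurements (IC50, Ki, Kd, EC50, …) hand-extracted from medicinal-chemistry
publications. Before that data can feed QSAR models, selectivity analyses or
target prediction, it has to survive a gauntlet of problems the literature
itself introduces: the same endpoint published under dozens of type spellings
and more than a hundred unit dialects, log-scale reporting (pKi, logIC50),
values cited from earlier papers as if they were new measurements, and
mis-transcribed units that shift a potency by exactly three or six orders of
magnitude.

`sarclean` implements the automated curation workflow such databases run
before each release, as a reusable, fully testable R pipeline:

1. **Standardisation** — published types are normalised through a synonym
   table (`'Half life'`, `'t(1/2)'` → `T1/2`), logarithmic endpoints are
   unlogged (pKi = 9 → Ki = 1 nM, with censored relations flipped),
   concentration dialects are converted to nM, mass concentrations to
   µg·mL⁻¹, AUC dialects to ng·h·mL⁻¹, and values are rounded
   arithmetically (half-up): 3 significant figures below 10, two decimals
   otherwise. Published fields are never touched.
2. **Validity flagging** — one comment per record, earlier steps take
   precedence: `'Potential missing data'` (no value and no activity
   comment), `'Non standard unit for type'` (units outside the allowed set
   for the standard type), `'Outside typical range'` (outside an inclusive
   window, 0.01 nM–100 µM for the dose–response endpoints, with the upper
   bound relaxed ×100 for fragment compounds of MW < 350).
3. **Redundancy detection** — within groups sharing compound, target,
   standard type and unit, cross-publication pairs that are equal or
   related by 1–3-significant-figure rounding are citation duplicates: all
   records except those of the earliest publication get the
   `potential_duplicate` flag. Pairs whose values differ by exactly 10³ or
   10⁶ (after rounding-aware mantissa matching) are unit transcription
   errors: the later publication's record is flagged.
4. **pChEMBL** — for clean, exact, positive nM dose–response records
   (IC50, XC50, EC50, AC50, Ki, Kd, Potency):
   `pChEMBL = −log10(value in M) = 9 − log10(value in nM)`.
5. **Assay & target annotation** — deterministic keyword cascades assign
   the five assay types (B/F/A/T/P, with ADME precedence and the
   cytotoxicity efficacy-vs-toxicity split) and the BioAssay Ontology
   format (organism > tissue > cell > biochemical); ambiguous cell-line
   tokens such as `H4` are reported with their candidate identities.
   Target records are validated against the component taxonomy
   (SINGLE PROTEIN, PROTEIN FAMILY, PROTEIN COMPLEX, PROTEIN COMPLEX
   GROUP).

Because no external database is required, the package ships a seeded
generator of messy literature-style corpora (`generate_corpus()`) with
per-record ground truth for every injected defect, so each flagging rule can
be scored by precision and recall.

## Worked example

```r
library(sarclean)

corpus <- generate_corpus(corpus_params(n_compounds = 40, n_targets = 5,
                                        n_documents = 12, seed = 2024))
res <- curate(corpus$records, corpus$compounds, corpus$assays)
res
#> <curation_result> 399 records curated
#>
#>  step                                      name         data_validity_comment
#>     1                   Flag missing activities        Potential missing data
#>     2 Flag non-standard units for activity type    Non standard unit for type
#>     3               Convert log activity values                          <NA>
#>     4                  Flag out of range values         Outside typical range
#>     5           Flag potential duplicate values                          <NA>
#>     6       Flag potential transcription errors Potential transcription error
#>     7    Calculate standard negative log values                          <NA>
#>  count percentage
#>      3  0.7518797
#>      0  0.0000000
#>     77 19.2982456
#>     19  4.7619048
#>     10  2.5062657
#>      2  0.5012531
#>    375 93.9849624
```

Of 399 synthetic records, 3 had neither a value nor an activity comment,
77 arrived as pKi/pIC50 and were unlogged, 19 fell outside the
0.01 nM–100 µM window, 10 were later-publication citations of an earlier
measurement, 2 were decade unit slips, and 375 clean dose–response records
received a pChEMBL value.

```r
glance(res)
#> # A tibble: 1 × 5
#>   n_records n_flagged n_duplicate n_pchembl pct_flagged
#>       <int>     <int>       <int>     <int>       <dbl>
#> 1       399        24          10       375        6.02

evaluate_flags(res$records, corpus$truth)
#> # A tibble: 3 × 6
#>   flag                   tp    fp    fn precision recall
#>   <chr>               <int> <int> <int>     <dbl>  <dbl>
#> 1 missing                 3     0     0       1      1
#> 2 potential_duplicate     9     1     0       0.9    1
#> 3 transcription_error     2     0     3       1      0.4
```

Duplicate recall is 1: every injected citation was caught. Transcription
recall is 0.4 *under the default configuration* because a slipped value
usually also leaves the typical range, and the single data-validity-comment
column gives the earlier out-of-range step precedence; run with the range
table disabled (an opt-in table) to measure the detector in isolation — the
methods vignette discusses this interplay. `tidy(res)` returns the report
as a tibble and `autoplot(res)` plots it.

A command-line front end wrapping these functions is installed at
`inst/scripts/curate` with verbs `run`, `simulate`, `evaluate` and
`validate-config`.

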