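# ctriaudit

Auditing ethics-committee (EC) data quality in CTRI-style clinical-trial
registry records.

## The problem

The Clinical Trials Registry–India (CTRI) asks registrants to list every
trial site (*Name of Site*, *Site Address*, principal investigator) and every
ethics committee that approved the study (*Name of the Committee*, approval
status). The two tables are free text and are not linked row-to-row, so a
reader — or a program — must reconstruct which committee oversees which site.
In practice the fields carry blank EC tables, mismatched site/EC counts,
repeated rows, generic names ("Institutional Ethics Committee"), file
numbers or message text in place of names, unexplained acronyms, and
acronyms shared by different organisations. `ctriaudit` is for
meta-researchers and registry curators who want to quantify these
deficiencies, link sites to committees with an auditable evidence trail, and
prototype the registration-time logic rules that would prevent the errors in
the first place.

## What the package does

* **Record model & ingest** — `parse_record_html()` reads a single
  CTRI-style record page keyed on field labels; `save_snapshot()` /
  `load_snapshot()` store collections as a plain-text relational snapshot
  (four CSV tables: trial, site, ec, raw_field, keyed by `ctri_id` + row
  index, with a schema version); `write_jsonl()` / `read_jsonl()` are the
  line-oriented interchange format. All verbatim text is preserved.
* **Cohort selection** — `select_cohort()` applies a parameterised cascade
  (registration window, trial type, phase-2/phase-3 sets with combined-phase
  labels in both, recruitment status, single/multi-site split, merge with
  the overlap counted once) and reports the survivor count at every step.
* **Count classification** — `classify_counts()` assigns each trial to
  exactly one of NO_EC, MORE_SITES, MORE_ECS, EQUAL_SINGLE, EQUAL_MULTI.
* **Site–EC matching** — `match_trial()` scores every site–EC pair on
  name similarity (token overlap + edit distance over canonicalised text,
  computed against the institution part of the committee name), an acronym
  crosswalk, city agreement, a PI-name linkage bonus, and an
  address fallback. A one-to-one assignment over above-threshold pairs is
  solved exactly; a margin test separates clear ("direct") calls from
  contested ones; the last remaining committee is assigned to the last
  remaining site by elimination. Trials grade as ALL_CLEAR, ONE_UNCLEAR or
  MULTI_UNCLEAR.
* **Deficiency linter** — `lint_trial()` applies 15 per-trial rules
  (R01 blank EC … R15 retrospective registration) and `lint_cohort()` adds
  cross-trial rules (acronym collisions, shared file numbers, inconsistent
  EC naming); `validate_for_registration()` rejects records that fire an
  error-severity rule. `rule_catalogue()` documents every rule.
* **Synthetic benchmark** — `generate_trials()` produces CTRI-like records
  from a fictitious institution pool with a known true site↔EC mapping, and
  injects any of the catalogued deficiencies at configurable rates while
  logging ground truth; `rule_benchmark()` measures per-rule precision and
  recall; `make_fixture_suite()` holds 32 curated problem-pattern fixtures
  with expected-findings manifests.
* **Orchestration** — `run_audit()` chains filter → classify → match → lint
  and `write_audit_bundle()` emits deterministic CSV/JSONL reports. A thin
  CLI lives at `inst/cli/audit.R`.

## Worked example

```r
library(ctriaudit)

gen <- generate_trials(generator_config(
  n_trials = 200, seed = 1,
  injection_rates = c(R06 = 0.15, R03 = 0.05, R10 = 0.10)
))
report <- run_audit(gen$records, spec = cohort_spec())
report
#> <audit_report> 200 trials audited
#> partition:
#> # A tibble: 6 × 2
#>   label            n
#>   <chr>        <int>
#> 1 NO_EC            0
#> 2 MORE_SITES       0
#> 3 MORE_ECS        11
#> 4 EQUAL_SINGLE   146
#> 5 EQUAL_MULTI     43
#> 6 EQUAL          189
#> match grades ( 200 matchable trials ):
#> # A tibble: 3 × 2
#>   grade             n
#>   <chr>         <int>
#> 1 ALL_CLEAR       153
#> 2 ONE_UNCLEAR      47
#> 3 MULTI_UNCLEAR     0
#> findings: 131
```

The partition says how site and EC counts compare per trial (here 11 trials
gained an extra EC row from the repeated-committee injection). The match
grades say for how many trials every site–EC link was unambiguous: the
generic-name injection (R06) strips the institution from a committee name,
so affected single-site trials degrade to ONE_UNCLEAR (their committee is
assignable only because it is the last one left). The 131 findings are the
linter's itemised deficiencies; each carries a rule id, severity, locus and
evidence string:

```r
head(report$findings[, c("rule_id", "ctri_id", "severity", "evidence")], 3)
#>   rule_id             ctri_id severity                                                            evidence
#> 1     R06 CTRI/2020/09/000001  warning             generic/casual EC name 'Institutional Ethics Committee'
#> 2     R10 CTRI/2020/09/000001     info no EC registration number (ECR) in 'Institutional Ethics Committee'
#> 3     R06 CTRI/2018/05/000011  warning            generic/casual EC name 'Institutional Ethics Committee'
```

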