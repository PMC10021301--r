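---
title: "Methods: auditing ethics-committee data in registry records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing ethics-committee data in registry records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctriaudit)
```

## The audit model

A CTRI-style trial record carries two parallel free-text tables: the sites
of study (name, address, principal investigator) and the ethics committees
(ECs) from which approval was sought. Nothing in the record links a
committee row to a site row. `ctriaudit` treats the audit of such records as
four composable problems:

1. **Cohort selection** — which registered trials are in scope;
2. **Count classification** — how the site and EC row counts compare;
3. **Site–EC matching** — which committee most plausibly oversees each site,
   with an explicit evidence trail and an honest "don't know";
4. **Deficiency linting** — which record-level problems are present, stated
   as reproducible rules that could run at registration time.

The package's working assumption is that row counts are meaningful as
entered: a repeated site inflates the site count and a duplicated committee
inflates the EC count. Deduplicating silently would hide exactly the
data-quality problems the audit is looking for, so duplicates are kept for
classification and reported by the linter instead.

## Text normalisation

All comparisons run on a canonical form: diacritics folded to ASCII, `&`
mapped to `and`, case lowered, punctuation collapsed to single spaces, and a
small editable abbreviation table applied (`govt` → `government`, `hosp` →
`hospital`, `inst` → `institute`, ...). Canonicalisation is idempotent, and
verbatim source text is never modified — normalized companions live beside
the raw fields.

On top of the canonical form the package extracts:

* **literal acronyms** — maximal runs of ≥2 capitals, excluding committee
  boilerplate (EC, IEC, IRB), registry syntax (the fields of an
  `ECR/...` registration number are not institution acronyms) and roman
  numerals (committee ordinals such as IEC-II);
* **derived acronyms** — initials of a multi-word title-case name, skipping
  connectives, so *Kempegowda Institute Of Medical Sciences* yields KIMS
  rather than KIOMS;
* **cities** — matched against a bundled, editable gazetteer of Indian
  cities; the last (and longest) match wins because cities usually close a
  name or address. Unknown cities are simply absent, never guessed;
* **person names** — substrings introduced by honorifics (Dr, Prof, ...),
  stopping at institution or committee keywords;
* **CDSCO registration numbers** — `ECR/serial/kind/region/year[/suffix]`,
  parsed case-insensitively into components that reconstruct the original;
* **shape flags** — generic/casual committee names (nothing identifying an
  institution once committee words, connectives and numerals are removed),
  apparent file numbers (digit/slash runs with no two consecutive
  alphabetic tokens and no ECR), and message text (>15 tokens containing
  correspondence phrases such as "please"/"consider").

### Similarity

`similarity()` blends a token-overlap component (Jaccard index of token
sets, weight 0.6) with an edit-distance component (1 − Levenshtein/longer
length, weight 0.4), plus a +0.2 crosswalk bonus when a literal acronym on
one side equals a literal or derived acronym of the other. The weights
favour token overlap because word order and filler words vary freely in
registry text, while the edit component still separates close spellings.
Derived-versus-derived acronym matches are deliberately excluded: two
different "X Institute of Medical Sciences" would otherwise reinforce each
other — which is precisely the acronym-ambiguity problem, not evidence of a
match.

One property worth stating precisely: no symmetric, normalised set
similarity can be non-increasing under deletion of an *arbitrary* token
from one side (deleting a token the other side lacks necessarily helps any
normalised measure). The invariant the package guarantees, and tests, is
the meaningful one: deleting a *shared* token never increases the token
component.

## Cohort selection

`cohort_spec()` parameterises the cascade: registration window (default
2016-06-01 to 2021-02-19, inclusive on both ends), trial type (default
Interventional), phase rule, and allowed recruitment status for India
(default Completed / Closed to Recruitment, matched on the India status
field only). The phase-2 set is defined as "phases contain P2", so a
combined *Phase 2/ Phase 3* label belongs to both the phase-2 and phase-3
sets; the merged cohort is their union with the overlap counted exactly
once. `select_cohort()` reports the count surviving every step so the
cascade can be compared against any published selection table. Trials with
zero site rows stay in the cohort (a blank site table is itself a finding)
and count as single-site in the multiplicity split so the partition remains
exhaustive.

## Count classification

`classify_counts()` is total and mutually exclusive over all count pairs:
NO_EC (no committee rows), MORE_SITES (sites outnumber a non-empty EC
table), MORE_ECS (committees outnumber sites — including the degenerate
zero-site case, which real corpora may not contain but a total partition
must place somewhere; the linter flags it), EQUAL_SINGLE (1/1) and
EQUAL_MULTI (equal, >1).

## Site–EC matching

`score_pair()` combines, per site–committee pair:

| evidence | default | rationale |
|---|---|---|
| name similarity vs the *institution part* of the EC name | weight 1 | committee words ("Institutional Ethics Committee"), registration numbers and numerals are stripped before comparison |
| generic-name cap | 0.30 | a generic or casual committee name can never identify an institution on its own |
| address fallback | ×0.9 | when the organisation appears only in the site address, slightly discounted |
| city agreement | +0.15 / −0.25 | both sides carry a city: agreement is weak positive evidence, disagreement is strong negative evidence |
| PI linkage | +0.35 | a doctor's name in the EC field matching the site's PI is often the only usable link for generic committees |
| acronym crosswalk | +0.2 (inside similarity) | "KIMS Ethics Committee" vs *Kalinga Institute of Medical Sciences* |

`match_trial()` then proceeds in two phases. **Phase A** solves the
one-to-one assignment that maximises total score over pairs at or above the
acceptance threshold (default 0.75), exactly, by depth-first search with an
optimistic bound — instances are tiny (≤12 sites) and candidate sets
sparse, and the optimum is verified against an exhaustive search in the
tests. A per-site margin test (default 0.10) then separates **direct** calls
(the assigned committee is the site's best candidate and beats the
runner-up by at least the margin) from contested ones; a contested site is
reported as *ambiguous*, never resolved by index order. **Phase B** assigns
the last remaining committee to the last remaining site *by elimination*.

The split matters for the design: the assignment optimum is defined over
all above-threshold pairs (that is the quantity with a clean oracle), while
the margin is a per-site confidence statement. A site can therefore occupy
a committee in the Phase-A optimum yet still be reported unresolved; its
committee returns to the pool for elimination.

Trial grades follow from the per-site outcomes: **ALL_CLEAR** means every
site resolved directly; **ONE_UNCLEAR** means exactly one site was resolved
only by elimination or left unresolved — this package's formalisation of
"the linkage could be determined only because it was the last committee
left"; **MULTI_UNCLEAR** means two or more such sites. Matching a trial
with no committees is refused with a pointer to the count classifier:
NO_EC records have nothing to match.

Threshold and margin defaults were chosen once from the structure of the
score scale (an exact institution match scores ~0.85–1.0 against its own
committee, cross-institution pairs of the same type and city peak near the
threshold) and are exposed in `match_config()` for sensitivity analysis.

## The deficiency rules

`rule_catalogue()` documents all rules. Severities are this package's own
ranking — *error* marks entries that `validate_for_registration()` treats
as blocking (R01 blank EC table for an interventional trial, R04 repeated
site with the same PI, R07 message text as a committee, R08 a site name
echoed as the committee), *warning* marks entries that need confirmation,
*info* marks sub-optimal but tolerable entries. Three choices deserve
explanation:

* **R02 (count mismatch)** requires a non-empty EC table so that a blank
  table raises exactly one finding (R01), not two.
* **R14 (shared-committee city condition)** implements the post-2019-03-25
  requirement that a committee reviewing for a site without its own EC be
  in the same city or within 50 km. Registry addresses are free text, so
  the implementable proxy is city-string equality via the gazetteer; the
  50 km geodesic check would require geocoding free text and is out of
  scope. Sites or committees without an extractable city are not flagged —
  the rule only fires on positive evidence of a mismatch.
* **R10 (missing ECR)** is *info*, not warning: most real records omit the
  registration number today, but listing it is the single best improvement
  a registrant can make, so the linter keeps it visible.

Cross-trial rules aggregate over a collection: C01 reports an acronym
standing for two or more distinct site organisations in two or more trials
(derived acronyms count, so a misspelled organisation name creates a
phantom second organisation — deliberately); C02 reports identical
file-number strings across trials; C03 reports one organisation (keyed by
its sorted institution tokens) listing its committee under different names.

## The synthetic benchmark

`generate_trials()` emulates the structures the audit consumes, not the
clinical content of a registry. A pool of fictitious institutions (name =
fictitious prefix + institutional type; real Indian city; CDSCO-style
registration number; derived acronym kept unique across the pool unless a
deliberate collision group is configured) yields clean records: one
committee per site named "*Institution* Institutional Ethics Committee,
*City* (*ECR*)", addresses that carry the city but — by construction — no
institution keywords in street names, PI names with honorifics, and a
public title that spells the organisation out. Clean committee names
include the registration number, mirroring the best observed records and
making the missing-ECR rule injectable. The default site-count distribution
puts 0.745 of its mass on single-site trials, matching the single-site
share of the audit cohort the package is modelled on (1012 of 1359), with
a thin tail to 12 sites.

Injectors rewrite clean records per rule semantics — dropping the EC table,
appending a stray committee, duplicating rows, genericising names,
substituting messages or file numbers, stripping registration numbers,
collapsing a site to its acronym while removing every expansion, and so on
— and log each edit as ground truth. Selection is by per-trial uniform
draws, so for a fixed seed the injected set at a lower rate nests inside
the set at a higher rate; the monotone-degradation test exploits this to
check exactly, not just on average, that more generic names never improve
the matcher's clear fraction. The R14 injector first makes a trial eligible
(post-rule registration date, a second site, a single committee) and then
forces the city mismatch; its truth entry records the reshaped record.

What the generator does **not** emulate: real institution names and their
idiosyncratic spellings, multi-committee cells ("IEC-I, II, III" in one
row), geographic realism beyond city labels, AYUSH-stream records, and the
long-tail formatting noise of scraped HTML. Passing the synthetic
benchmarks therefore demonstrates that the pipeline's logic is correct and
its detectors are calibrated to their own injection semantics — it does not
certify recall on real registry text, where name variation is richer than
any generator.

Benchmark sizes used by the tests and the acceptance script — 500 clean
trials for the recovery check, 1000 trials per rule at injection rate 0.3,
500–1000 random assignment instances up to 5×5 — were chosen to make
binomial noise negligible relative to the 0.95 precision/recall bar while
keeping a full run in the low minutes on one CPU.

## Storage formats

The snapshot is a directory of four relational CSV tables (`trial`, `site`,
`ec`, `raw_field`, keyed by `ctri_id` plus row index) with a `schema.json`
version stamp; loading a snapshot with a different schema version fails
with a versioned error, and duplicated registry ids are rejected by name.
Output is byte-stable: fixed column order, rows sorted by id and index, no
timestamps. JSON Lines (one record per line) is the interchange format; CSV
exports of the site and EC tables are available for spreadsheet work. The
HTML parser is keyed on field labels, not table positions, so modest layout
drift in record pages is tolerated; the only hard requirement is a
recognisable CTRI number, whose absence is a parse error naming the missing
anchor.

## Known limitations

* Matching "clears" a site–committee link; it does not identify the
  committee uniquely. An institution may operate several committees, and a
  generic listing cannot distinguish them.
* Undeclared independent committees cannot be detected from the record
  alone; the package flags the declared ones (name or registration kind)
  and stops there.
* City equality is a coarse proxy for the same-city/50 km rule.
* The per-rule precision/recall figures are properties of the injection
  benchmark; real-corpus performance must be validated against manually
  audited records.
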