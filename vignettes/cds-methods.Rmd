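---
title: "Measuring cognitive distortion markers in chat transcripts: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognitive distortion markers in chat transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsmark)
```

## The problem and the model

Cognitive-behavioral theory describes depression and suicidality as
entangled with *cognitive distortions* — rigid, exaggerated, unrealistic
thought patterns conventionally grouped into 12 types (catastrophizing,
dichotomous reasoning, disqualifying the positive, emotional reasoning,
fortune-telling, labeling and mislabeling, magnification and
minimization, mental filtering, mindreading, overgeneralizing,
personalizing, should statements). A *cognitive distortion schema* (CDS)
is a short word pattern — an n-gram or a small regular expression —
designed to mark the lexical surface of one distortion type regardless
of topic or context. `cdsmark` ships a 12-category Dutch CDS lexicon and
implements the full measurement pipeline around it.

The measurement model is deliberately simple. A chat corpus is a set of
sessions $S$; each session is a time-ordered list of messages $m_i$,
each tagged with a role $r_{m_i} \in \{h, o, b\}$ (help seeker,
counselor, system). System messages are excluded from all analysis. For
a CDS set $C$, the matching function

$$g_C(m_i) \in \{0, 1\}$$

is 1 iff the message contains at least one pattern of $C$. Presence
semantics only: repeated hits in one message still count once, because
the target statistic is the fraction of messages carrying a marker, not
a hit rate. The **cohort prevalence** for role $r$ is the pooled
(message-weighted) fraction

$$P_C(r, S) = \frac{\#\{m : r_m = r,\ g_C(m) = 1\}}{\#\{m : r_m = r\}},$$

and the **prevalence ratio** between two roles is
$R_C(r_1, r_2, S) = P_C(r_1, S) / P_C(r_2, S)$. Two further views are
computed: the *within-session* prevalence (the same fraction inside one
session; its distribution across sessions is the unit of the cohort
statistical tests), and the *monthly* prevalence (messages binned by the
calendar month of their session's start date). The same machinery
serves social-media timelines (one "session" per individual) and flat
sentence collections (a single degenerate session), so prevalences from
very different corpora are directly comparable.

## The lexicon and its printed dialect

The packaged lexicon is a byte-for-byte copy of the published table of
Dutch schemata, one category per row, patterns separated by the
two-character delimiter comma-then-space (commas *inside* patterns,
as in `top,? maar`, are never followed by a space and survive the
split). The printed text is a small regex dialect: alternations
`(zal|gaat)`, optional elements `slechtste?`, character classes
`zwart[-/]wit`, and a gap construct `(.+ |)` meaning "one or more
words, or nothing, between the flanks".

Parsing and compilation apply a handful of documented conventions:

* **Typographic artifacts.** Two printed rows contain stray quote
  characters (`"`, `”`); these are stripped from the normalized pattern
  but preserved in the `raw` column for provenance.
* **Gap repair.** The printed rows are inconsistent about spacing
  around the gap (`ik zal(.+ |) niet` vs `het zal(.+ |)niet`); taken
  literally, one variant demands a double space and the other glues
  words together. Both are canonicalized to `" (.+ )?"` — a space,
  optionally followed by filler and a further space — the minimal
  repair that keeps every printed variant usable. A configurable cap on
  gap length (`match_options(gap_cap = )`, default unlimited within one
  message) is exposed for sensitivity analysis; matching is strictly
  per message, so no gap ever crosses a message boundary.
* **Word boundaries.** A boundary anchor is inserted at a pattern edge
  exactly when the edge character is alphanumeric. This keeps 1-grams
  such as `zou` or `alleen` from firing inside longer words while
  leaving class- or optional-suffix edges (`zwart[-/]wit`,
  `slechtste?`) intact.
* **Normalization.** Both pattern and text are NFC-normalized,
  lower-cased, and have whitespace runs collapsed before matching, so
  composed and decomposed accents (`é`) compare equal. The source study
  does not state its tokenization or case conventions; this is a
  declared convention of the package, not a reconstruction.

**Known count discrepancy.** Applying the split rule reproduces the
published per-category totals for seven categories (fortune-telling 8,
emotional reasoning 10, magnification/minimization 9, mental filtering
16, mindreading 72, personalizing 15, should statements 4) but not for
the other five (parsed 21/27/11/42/18 against published 25/25/14/47/20
for catastrophizing, dichotomous reasoning, disqualifying the positive,
labeling, overgeneralizing), and the parsed total is 253 against a
published 265. The printed rows cannot be reconciled with the published
totals under any consistent delimiter; plausibly alternations were
counted as several schemata or patterns were lost in typesetting. The
package treats the printed rows as canonical and reports both counts
side by side (`lexicon_census()`) rather than forcing agreement.

```{r census}
lexicon_census(load_builtin_lexicon())
```

## Statistics

Cohort comparisons operate on the within-session prevalence
distributions, one value per session (or timeline): a Bartlett test of
equal variances (two-group closed form, $\chi^2_1$ reference), then —
since helpline cohorts show clearly unequal spreads — a Welch
unequal-variance t test with Welch–Satterthwaite degrees of freedom,
an effect size, and a Bonferroni adjustment $\alpha/m$ over the $m$
pairwise comparisons. Two-sided p-values throughout.

Numerical conventions that were genuinely open:

* **Effect size.** The source study reports a *d* without naming a
  variant. The package uses pooled-SD Cohen's d (n−1 weighting) even
  when variances differ, because it is the default reading of an
  unqualified "d"; with very unequal variances it should be
  interpreted as a descriptive standardization, not an exact
  noncentrality parameter.
* **Monthly interval.** The summary interval for a monthly series is
  the empirical 2.5/97.5 percentile across monthly values. The study's
  printed monthly interval is asymmetric, which a normal approximation
  cannot produce, but the actual method is unstated; percentiles are a
  declared convention.
* **Degenerate inputs.** Zero-variance samples, empty cohorts, and
  zero denominator prevalences raise explicit errors rather than
  returning infinities: a ratio against a zero-prevalence cohort is
  *undefined*, not infinite.
* **Ranked ratio report.** Per-category ratios are ranked descending
  with ties broken alphabetically by category code; categories whose
  denominator prevalence is zero sort last with an `NA` ratio.

## The synthetic world

No public corpus of helpline sessions exists, so the package carries a
first-class generator whose defaults *are* the documented conditions of
the source setting: sessions of roughly alternating help-seeker and
counselor messages averaging ~47 and ~43 per session respectively
(matching the published aggregate of 3.3M/3.0M messages over 71,148
sessions), start dates uniform over July 2017 – June 2021, a small
system-message rate (2 per session; the study is silent, the rate
exists to exercise the exclusion rule), and per-message injection
probabilities of 0.2219 (help seeker) and 0.1378 (counselor) overall,
distributed over categories using the published per-category figures
(dichotomous reasoning 0.13/0.07, should statements 0.05/0.02,
overgeneralizing 0.03/0.02) with the remainder uniform over the other
nine categories.

Each generated message is a sentence of *verified* filler words into
which, with the configured probability, one realization of one
uniformly chosen pattern is embedded at a random position. Two design
points matter:

* **Filler is verified, not assumed.** Several patterns are extremely
  common Dutch words (`alleen`, `altijd`, `nooit`, `niets`), so naive
  neutral text would leak matches. `build_filler_vocabulary()` runs a
  mandatory build-time sweep — every candidate word alone, every
  ordered word pair, and a seeded set of random probe sentences are
  matched against the full lexicon, and offending words are removed
  (erroring if the vocabulary exhausts). Consequently filler text
  matches nothing, by construction *and* by test.
* **At most one injection per message** (default), so the message-level
  indicator is an exact Bernoulli draw and recovery bounds are
  analytic: the pooled estimator equals the empirical injection
  fraction exactly, and across seeds it is unbiased with variance
  $p(1-p)/n$. An independent-injection mode (off by default) allows
  multi-category co-occurrence.

`realize_pattern()` inverts the matcher: it draws a concrete string
from a pattern's language (branches uniform, optional elements with
probability ½, gaps empty or one filler word) and verifies it against
the pattern's own compiled matcher. This gives the generator its exact
ground truth: on synthetic data the matcher's output and the injection
labels agree perfectly on the overall indicator, and the injected
category's flag is always set.

**What a green test does not establish.** The generator emulates the
*statistical* structure of helpline chats (roles, session lengths,
dates, marker rates), not their linguistics: filler text is a bag of
neutral words, there is no grammar, no topic, no lexical entrainment
between roles, and no ambiguity about what a marker is. Passing
recovery tests therefore validates the pipeline's arithmetic and the
matcher's fidelity to the printed patterns — it says nothing about
construct validity of the lexicon on real language. Note also that the
categories overlap lexically (the mental-filtering pattern
`ik zie alleen` contains the dichotomous-reasoning 1-gram `alleen`), so
when several categories are injected at once, per-category prevalences
are upper bounds; single-category recovery is exact.

The source study's headline numbers (22.19% vs 13.78% prevalence;
ratios 20.22/7.87/4.53; Bartlett T=14,581; Welch t=177; d=0.94) require
its private 71,148-session corpus and are **not reproducible** here;
the package's acceptance checks are instead exact lexicon checks plus
property-based verification on the synthetic world, at synthetic scale.

## Limitations

* The lexicon count discrepancy above is unresolved by design.
* Matching is context-free: negation, irony, and quoted speech all
  count, exactly as in the source method.
* Timeline and sentence modes reuse the chat machinery; "session"
  statistics there mean per-individual or whole-collection statistics.
* The monthly binning assigns whole sessions to the month of their
  start date; sessions spanning midnight of a month boundary are not
  split.
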