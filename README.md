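# cdsmark

Lexicon-based measurement of **cognitive distortion markers** in Dutch
chat transcripts.

Crisis and suicide-prevention helplines increasingly run on text chat,
and cognitive-behavioral theory ties depression and suicidality to
*cognitive distortions* — rigid, exaggerated thought patterns such as
catastrophizing or dichotomous reasoning. `cdsmark` is for researchers
and helpline analytics teams who want to quantify the lexical traces of
those distortions in role-tagged chat data. It ships a 12-category
Dutch lexicon of *cognitive distortion schemata* (CDS): short n-grams
and small regular expressions, each marking one distortion type
independent of topic.

The core quantities, for a pattern set $C$, role $r \in \{h, o\}$
(help seeker, counselor; system messages $b$ are excluded) and session
set $S$:

- matching function $g_C(m) \in \{0,1\}$ — message $m$ contains at
  least one pattern of $C$;
- **prevalence** $P_C(r, S)$ — the pooled fraction of role-$r$ messages
  with $g_C(m) = 1$;
- **prevalence ratio** $R_C(r_1, r_2, S) = P_C(r_1,S) / P_C(r_2,S)$;
- within-session and monthly variants, and cohort comparisons of the
  within-session distributions (Bartlett variance test, Welch t test,
  Cohen's d, Bonferroni adjustment).

Because real helpline data are private, the package includes a seeded
synthetic chat-corpus generator with controlled, role- and
category-specific marker-injection rates, so the whole pipeline is
testable end to end with known ground truth.

## Worked example

Generate a synthetic corpus with help-seeker/counselor injection rates
of 0.22 / 0.14, annotate it, and recover the statistics:

```r
library(cdsmark)

lex <- load_builtin_lexicon()
cfg <- simulation_config(n_sessions = 50, seed = 1,
                         injection = injection_rates(0.22, 0.14))
sim <- generate_corpus(cfg, lex)
ann <- annotate_corpus(lex, sim$corpus)

cohort_prevalence(ann, "h")
#> P_overall(h) = 561/2415 = 0.2323  [cohort scope]
cohort_prevalence(ann, "o")
#> P_overall(o) = 315/2128 = 0.1480  [cohort scope]
prevalence_ratio(ann, "h", "o")$ratio
#> [1] 1.569
```

So 23.2% of the 2,415 help-seeker messages and 14.8% of the 2,128
counselor messages carry a marker — within binomial noise of the
injected 22%/14% — and help-seeker language is 1.57× richer in markers
overall. Per category, ranked by ratio as in the study's headline
figure:

```r
head(prevalence_by_category(ann, "h", "o"), 4)
#>   code                       name         p_h         p_o    ratio
#> 1   ss          Should statements 0.054244306 0.023026316 2.355753
#> 2    o           Overgeneralizing 0.032298137 0.016917293 1.909179
#> 3   dr      Dichotomous reasoning 0.158592133 0.097274436 1.630358
#> 4  dtp Disqualifying the positive 0.003312629 0.002819549 1.174879
```

Cohort comparison on the within-session prevalence distributions (one
value per session and role):

```r
compare_cohorts(list(h = within_session_prevalence(ann, "h")$values,
                     o = within_session_prevalence(ann, "o")$values))
#>     pair bartlett_T  welch_t welch_df  cohen_d welch_significant
#> 1 h vs o     2.0923 6.682021 94.03018 1.336404              TRUE
```

At 50 sessions the Welch test already separates the cohorts (t = 6.68,
df ≈ 94) while the Bartlett test does not reject equal variances at
this scale.

The packaged lexicon itself:

```r
category_counts(lex)   # patterns per category code (253 total)
lexicon_census(lex)    # parsed vs published counts, side by side
```

A command-line front-end with `simulate`, `score`, `report` and
`compare` subcommands lives at `inst/cli/cdsmark.R`:

```sh
Rscript inst/cli/cdsmark.R simulate --seed 1 --sessions 100 --out sim/
Rscript inst/cli/cdsmark.R score --input sim/corpus.jsonl --out scored/
Rscript inst/cli/cdsmark.R report --input scored/annotations.tsv --out report/
```

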