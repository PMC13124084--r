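Package: cdsmark
Title: Cognitive Distortion Markers in Chat Transcripts
Version: 0.1.0
Authors@R:
    person("cdsmark", "developers", email = "cdsmark@example.org",
           role = c("aut", "cre"))
Description: Lexicon-based detection of cognitive distortion schemata (CDS)
    in Dutch chat transcripts. Ships the 12-category Dutch CDS lexicon,
    compiles its printed regex dialect into Unicode-aware matchers, annotates
    role-tagged chat sessions (help seeker, counselor, system) at the message
    level, and computes cohort, within-session, and monthly prevalence,
    prevalence ratios between roles, and cohort comparisons (Bartlett
    variance test, Welch t test, Cohen's d, Bonferroni adjustment). Includes
    a seeded synthetic chat-corpus generator with controlled marker-injection
    rates for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
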