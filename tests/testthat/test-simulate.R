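test_that("realize_pattern inverts the matcher", {
  set.seed(2)
  # a literal pattern realizes to itself
  expect_identical(realize_pattern("zou"), "zou")
  # alternation + gap: every realization lies in the pattern language
  row <- lex_builtin[lex_builtin$raw == "(zal|gaat)(.+ |)falen", ]
  opts <- stringi::stri_opts_regex(case_insensitive = TRUE)
  for (k in 1:20) {
    r <- realize_pattern(row, fillers_builtin)
    expect_true(stringi::stri_detect_regex(r, row$regex,
                                           opts_regex = opts))
    expect_match(r, "^(zal|gaat) (\\S+ )?falen$")
  }
  # self-match sweep over the whole lexicon, a few draws per pattern
  set.seed(3)
  for (i in seq_len(nrow(lex_builtin))) {
    for (k in 1:3) {
      expect_silent(realize_pattern(lex_builtin[i, ], fillers_builtin))
    }
  }
})

test_that("filler vocabulary is verified non-matching", {
  # dangerous candidates are rejected by the sweep
  v <- build_filler_vocabulary(
    lex_builtin, candidates = c(filler_candidates(), "altijd", "nooit"))
  expect_false(any(c("altijd", "nooit") %in% v))
  # the packaged candidates all survive
  expect_setequal(fillers_builtin, normalize_text(filler_candidates()))
  # seeded filler sentences never match any category
  set.seed(14)
  sents <- vapply(1:300, function(i)
    paste(sample(fillers_builtin, 8, replace = TRUE), collapse = " "),
    character(1))
  s <- data.frame(session_id = "s1", start_date = as.Date("2020-01-01"))
  m <- data.frame(session_id = "s1", role = "h",
                  t = seq_along(sents), text = sents)
  ann <- annotate_corpus(lex_builtin, cds_corpus(s, m))
  expect_equal(sum(ann$any_cds), 0L)
  # a vocabulary that cannot be repaired errors out
  expect_error(
    build_filler_vocabulary(lex_builtin,
                            candidates = c("alleen", "altijd", "nooit")),
    "exhausted")
})

test_that("simulation_config validates the stated world", {
  expect_error(simulation_config(10), "seed")
  bad <- injection_rates(0.22, 0.14)
  bad["h", "dr"] <- 1.5
  expect_error(simulation_config(10, seed = 1, injection = bad),
               "\\[0, 1\\]")
  bad <- injection_rates(0.9, 0.1)
  bad["h", ] <- 0.09  # total 1.08
  expect_error(simulation_config(10, seed = 1, injection = bad),
               "exceeds 1")
  expect_error(simulation_config(10, seed = 1,
                                 months = as.Date(c("2020-01-01",
                                                    "2019-01-01"))),
               "ascending")
})

test_that("generation is seeded and byte-reproducible", {
  cfg <- simulation_config(4, seed = 99,
                           mean_messages = c(h = 6, o = 5, b = 1))
  a <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  b <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_sessions_jsonl(a$corpus, fa)
  write_sessions_jsonl(b$corpus, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$truth, b$truth)
  # and a different seed changes the corpus
  c2 <- generate_corpus(simulation_config(4, seed = 100,
                                          mean_messages = c(h = 6, o = 5,
                                                            b = 1)),
                        lex_builtin, fillers_builtin)
  expect_false(identical(a$corpus$messages$text,
                         c2$corpus$messages$text))
})

test_that("zero injection produces a match-free corpus", {
  z <- injection_rates(0, 0)
  cfg <- simulation_config(5, seed = 21,
                           mean_messages = c(h = 8, o = 8, b = 1),
                           injection = z)
  sim <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  ann <- annotate_corpus(lex_builtin, sim$corpus)
  expect_equal(sum(ann$any_cds), 0L)
  expect_true(all(is.na(sim$truth$category)))
})

test_that("ground truth and matcher agree exactly on synthetic data", {
  cfg <- simulation_config(30, seed = 77,
                           mean_messages = c(h = 12, o = 10, b = 1),
                           injection = injection_rates(0.3, 0.2))
  sim <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  ann <- annotate_corpus(lex_builtin, sim$corpus)
  tr <- sim$truth[sim$truth$role != "b", ]
  expect_equal(nrow(tr), nrow(ann))
  inj <- !is.na(tr$category)
  # filler never matches; injected messages always match
  expect_identical(ann$any_cds, as.integer(inj))
  # the injected category's flag is always set
  for (i in which(inj)) {
    expect_equal(ann[i, tr$category[i]][[1]], 1L)
  }
  # and the injected pattern id is among the matched ids
  for (i in which(inj)) {
    ids <- as.integer(strsplit(ann$matched_pattern_ids[i], ";")[[1]])
    expect_true(tr$pattern_id[i] %in% ids)
  }
})

test_that("single-category injection rates are recovered", {
  inj <- injection_rates(0, 0)
  inj["h", "p"] <- 0.2
  cfg <- simulation_config(120, seed = 13,
                           mean_messages = c(h = 20, o = 5, b = 0),
                           injection = inj)
  sim <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  ann <- annotate_corpus(lex_builtin, sim$corpus)
  p <- cohort_prevalence(ann, "h", "p")
  se <- sqrt(0.2 * 0.8 / p$denominator)
  expect_lt(abs(p$prevalence - 0.2), 3 * se)
  # the estimator equals the empirical injection fraction exactly
  tr <- sim$truth[sim$truth$role == "h", ]
  expect_equal(p$prevalence, mean(!is.na(tr$category)))
})

test_that("independent-injection mode can co-inject categories", {
  inj <- injection_rates(0, 0)
  inj["h", c("p", "ss")] <- 0.5
  cfg <- simulation_config(20, seed = 5,
                           mean_messages = c(h = 10, o = 2, b = 0),
                           injection = inj, independent_injection = TRUE)
  sim <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  expect_true(any(grepl(";", sim$truth$category, fixed = TRUE)))
})

test_that("generated corpora round-trip through both writers", {
  cfg <- simulation_config(3, seed = 42,
                           mean_messages = c(h = 5, o = 4, b = 1))
  sim <- generate_corpus(cfg, lex_builtin, fillers_builtin)
  jl <- withr::local_tempfile(); cs <- withr::local_tempfile()
  write_sessions_jsonl(sim$corpus, jl)
  write_sessions_csv(sim$corpus, cs)
  from_jl <- read_sessions_jsonl(jl)
  from_cs <- read_sessions_csv(cs)
  expect_identical(from_jl$messages, sim$corpus$messages)
  expect_identical(from_cs$messages, sim$corpus$messages)
  expect_identical(from_jl$sessions, sim$corpus$sessions)
})
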