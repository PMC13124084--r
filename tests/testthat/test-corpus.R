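test_that("JSONL and CSV readers produce identical corpora", {
  corpus <- tiny_corpus()
  jl <- withr::local_tempfile(fileext = ".jsonl")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_sessions_jsonl(corpus, jl)
  write_sessions_csv(corpus, cs)
  from_jl <- read_sessions_jsonl(jl)
  from_cs <- read_sessions_csv(cs)
  expect_identical(from_jl$sessions, from_cs$sessions)
  expect_identical(from_jl$messages, from_cs$messages)
  # round trip conserves everything
  expect_identical(from_jl$messages, corpus$messages)
  expect_identical(from_jl$sessions, corpus$sessions)
})

test_that("quoted CSV text with commas and newlines survives a round trip", {
  sessions <- data.frame(session_id = "s1",
                         start_date = as.Date("2020-01-01"))
  messages <- data.frame(session_id = "s1", role = "h", t = 0,
                         text = "eerst, dan\nen \"daarna\"")
  corpus <- cds_corpus(sessions, messages)
  cs <- withr::local_tempfile(fileext = ".csv")
  write_sessions_csv(corpus, cs)
  back <- read_sessions_csv(cs)
  expect_identical(back$messages$text, messages$text)
})

test_that("messages are stably sorted by t", {
  sessions <- data.frame(session_id = "s1",
                         start_date = as.Date("2020-01-01"))
  messages <- data.frame(session_id = "s1",
                         role = c("h", "o", "h"),
                         t = c(20, 5, 5),
                         text = c("derde", "eerste", "tweede"))
  corpus <- cds_corpus(sessions, messages)
  expect_identical(corpus$messages$text, c("eerste", "tweede", "derde"))
  expect_identical(corpus$messages$msg_index, 1:3)
})

test_that("reader validation: roles, malformed lines, missing columns", {
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"session_id":"a","start_date":"2020-01-01","messages":[{"role":"h","t":0,"text":"hoi"}]}',
    '{"session_id":"b","start_date":"2020-01-01","messages":[{"role":"x","t":0,"text":"hoi"}]}'),
    jl)
  expect_error(read_sessions_jsonl(jl), "line 2.*'x'")

  writeLines(c('{"session_id":"a"', "", "x"), jl)
  expect_error(read_sessions_jsonl(jl), "line 1")

  cs <- withr::local_tempfile(fileext = ".csv")
  writeLines("session_id,start_date,role,t", cs)
  expect_error(read_sessions_csv(cs), "text")
  writeLines("session_id,start_date,role,t,text", cs)
  empty <- read_sessions_csv(cs)
  expect_equal(nrow(empty$messages), 0L)
})

test_that("sentence corpora drop blank lines and tolerate empty files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("eerste zin", "", "tweede zin", "   ", "derde zin"), f)
  corpus <- read_sentence_corpus(f)
  expect_identical(corpus$mode, "sentence_collection")
  expect_equal(nrow(corpus$messages), 3L)
  expect_true(all(corpus$messages$role == "h"))
  expect_true(all(corpus$messages$t == 0))

  writeLines(character(), f)
  degenerate <- read_sentence_corpus(f)
  expect_equal(nrow(degenerate$sessions), 1L)
  expect_equal(nrow(degenerate$messages), 0L)
})

test_that("exclude_system_messages removes exactly the b messages", {
  corpus <- tiny_corpus()
  kept <- exclude_system_messages(corpus)
  expect_identical(kept$messages$role[kept$messages$session_id == "s1"],
                   c("h", "o", "h"))
  n_role <- function(cp, r) sum(cp$messages$role == r)
  expect_identical(n_role(kept, "h"), n_role(corpus, "h"))
  expect_identical(n_role(kept, "o"), n_role(corpus, "o"))
  expect_identical(n_role(kept, "b"), 0L)
  # idempotent on a corpus without system messages
  expect_identical(exclude_system_messages(kept), kept)

  # an all-system session is retained as an empty session
  sessions <- data.frame(session_id = "only_b",
                         start_date = as.Date("2020-01-01"))
  messages <- data.frame(session_id = "only_b", role = "b", t = 0,
                         text = "systeem")
  stripped <- exclude_system_messages(cds_corpus(sessions, messages))
  expect_equal(nrow(stripped$sessions), 1L)
  expect_equal(nrow(stripped$messages), 0L)
  # and downstream annotation tolerates it
  ann <- annotate_corpus(lex_builtin, stripped)
  expect_equal(nrow(ann), 0L)
})

test_that("corpus constructor validates its inputs", {
  s <- data.frame(session_id = "s1", start_date = as.Date("2020-01-01"))
  m <- data.frame(session_id = "s1", role = "h", t = 0, text = "x")
  expect_error(cds_corpus(s, transform(m, role = "z")), "unknown role")
  expect_error(cds_corpus(s, transform(m, t = -1)), "non-negative")
  expect_error(cds_corpus(s, transform(m, session_id = "ghost")),
               "unknown session_id")
  expect_error(cds_corpus(s[, "session_id", drop = FALSE], m),
               "start_date")
})
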